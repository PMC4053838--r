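frag_df <- function(seqs, source = "de-novo") {
  data.frame(id = paste0("f", seq_along(seqs)), sequence = seqs,
             source = source, stringsAsFactors = FALSE)
}

test_that("an exact substring is placed at its interval with 100% identity", {
  z <- random_dna(1000, seed = 61)
  fr <- frag_df(substr(z, 201, 500))
  lay <- place_fragments(fr, z)
  expect_equal(nrow(lay$placements), 1L)
  expect_equal(lay$placements$scaffold_start, 200)
  expect_equal(lay$placements$scaffold_end, 500)
  expect_equal(lay$placements$identity, 100)
  expect_equal(lay$placements$orientation, "+")
  # its reverse complement lands on the same interval, minus orientation
  lay2 <- place_fragments(frag_df(revcomp(substr(z, 201, 500))), z)
  expect_equal(lay2$placements$scaffold_start, 200)
  expect_equal(lay2$placements$scaffold_end, 500)
  expect_equal(lay2$placements$orientation, "-")
})

test_that("unrelated fragments are reported unplaced", {
  z <- random_dna(600, seed = 62)
  lay <- place_fragments(frag_df(random_dna(200)), z)
  expect_equal(nrow(lay$placements), 0L)
  expect_equal(nrow(lay$unplaced), 1L)
})

test_that("two exact overlapping halves reconstruct the source exactly", {
  z <- random_dna(1000, seed = 63)
  fr <- frag_df(c(substr(z, 1, 500), substr(z, 451, 1000)))
  m <- bridge_gaps(merge_overlaps(place_fragments(fr, z)))
  expect_identical(m$consensus, z)
  expect_equal(length(m$contigs), 1L)
  # single placed fragment: consensus equals that fragment
  m1 <- bridge_gaps(merge_overlaps(place_fragments(frag_df(substr(z, 101, 700)), z)))
  expect_identical(m1$consensus, substr(z, 101, 700))
})

test_that("gaps are bridged with Ns sized by the scaffold distance", {
  z <- random_dna(900, seed = 64)
  fr <- frag_df(c(substr(z, 1, 400), substr(z, 501, 900)))
  m <- bridge_gaps(merge_overlaps(place_fragments(fr, z)))
  expect_equal(nchar(m$consensus), 900)
  expect_identical(substr(m$consensus, 401, 500), strrep("N", 100))
  expect_equal(nrow(m$bridged), 1L)
  expect_equal(m$bridged$consensus_start, 400)
  expect_equal(m$bridged$consensus_end, 500)
  # abutting contigs join with zero Ns
  fr2 <- frag_df(c(substr(z, 1, 400), substr(z, 401, 900)))
  m2 <- bridge_gaps(merge_overlaps(place_fragments(fr2, z), min_overlap = 40))
  expect_identical(m2$consensus, z)
  expect_equal(nrow(m2$bridged), 0L)
})

test_that("a seven-fragment tiling assembles into one complete contig", {
  tr <- random_cds(300, seed = 65)
  fr <- fragmentize(tr, 7, min_overlap = 60, orphan_prob = 0, seed = 66)
  # structural checks on the generator first: full cover, 6 overlaps
  expect_equal(min(fr$true_start), 0L)
  expect_equal(max(fr$true_end), nchar(tr))
  o <- order(fr$true_start)
  expect_true(all(fr$true_end[o][-7] - fr$true_start[o][-1] >= 60))
  a <- assemble_w_transcript(fr, tr)
  expect_equal(length(a$contigs), 1L)
  expect_identical(a$consensus, tr)
  expect_equal(a$completeness, 1.0)
})

test_that("fragmentize validates, tiles and reproduces deterministically", {
  tr <- random_dna(500, seed = 67)
  expect_error(fragmentize(tr, 10, min_overlap = 60), "exceeds")
  one <- fragmentize(tr, 1)
  expect_identical(one$sequence, tr)
  f1 <- fragmentize(tr, 3, seed = 5)
  f2 <- fragmentize(tr, 3, seed = 5)
  expect_identical(f1, f2)
  # truth-coordinate concatenation reconstructs the transcript
  o <- order(f1$true_start)
  rec <- rep(NA_character_, nchar(tr))
  for (i in o) {
    s <- f1$sequence[i]
    if (f1$orientation[i] == "-") s <- revcomp(s)
    rec[(f1$true_start[i] + 1):f1$true_end[i]] <- strsplit(s, "")[[1]]
  }
  expect_identical(paste(rec, collapse = ""), tr)
})

test_that("assembly round-trips any fragmentation when overlaps are intact", {
  set.seed(68)
  for (rep in 1:5) {
    tr <- random_cds(sample(150:400, 1))
    nf <- sample(2:8, 1)
    fr <- fragmentize(tr, nf, min_overlap = 60, orphan_prob = 0)
    a <- assemble_w_transcript(fr, tr)
    expect_identical(a$consensus, tr)
  }
})

test_that("diverged W fragments place at their true intervals", {
  set.seed(69)
  placed <- 0; total <- 0; near <- 0
  for (rep in 1:5) {
    z <- random_cds(300)
    w <- simulate_gametologue_pair(z, omega = 0.2,
                                   expected_subs_per_codon = 0.3)$w_cds
    fr <- fragmentize(w, 6, min_overlap = 60, orphan_prob = 0)
    lay <- place_fragments(fr, z)
    total <- total + nrow(fr)
    placed <- placed + nrow(lay$placements)
    m <- match(lay$placements$id, fr$id)
    near <- near + sum(abs(lay$placements$scaffold_start - fr$true_start[m]) <= 5 &
                       abs(lay$placements$scaffold_end - fr$true_end[m]) <= 5)
  }
  expect_gte(placed / total, 0.95)
  expect_gte(near / placed, 0.95)
})

test_that("reverse-complementing an input fragment leaves the consensus unchanged", {
  z <- random_cds(250, seed = 70)
  w <- simulate_gametologue_pair(z, seed = 71)$w_cds
  fr <- fragmentize(w, 5, min_overlap = 60, orphan_prob = 0, seed = 72)
  a1 <- assemble_w_transcript(fr, z)
  fr2 <- fr
  fr2$sequence[2] <- revcomp(fr2$sequence[2])
  a2 <- assemble_w_transcript(fr2, z)
  expect_identical(a1$consensus, a2$consensus)
})

test_that("consensus length is bounded and completeness grows with fragments", {
  z <- random_cds(300, seed = 73)
  fr <- fragmentize(z, 6, min_overlap = 60, orphan_prob = 0, seed = 74)
  o <- order(fr$true_start)
  comp <- numeric(0)
  for (k in seq_along(o)) {
    a <- assemble_w_transcript(fr[o[seq_len(k)], ], z)
    comp <- c(comp, a$completeness)
    expect_lte(nchar(gsub("N", "", a$consensus)), sum(nchar(fr$sequence[o[seq_len(k)]])))
    expect_gte(nchar(a$consensus), max(nchar(fr$sequence[o[seq_len(k)]])))
  }
  expect_true(all(diff(comp) > -1e-12))
  expect_equal(comp[length(comp)], 1.0)
})

test_that("dropped-overlap junctions reappear as N-bridges at true positions", {
  set.seed(75)
  found_gap <- FALSE
  for (rep in 1:6) {
    z <- random_cds(300)
    w <- simulate_gametologue_pair(z, omega = 0.2,
                                   expected_subs_per_codon = 0.3)$w_cds
    fr <- fragmentize(w, 7, min_overlap = 60, orphan_prob = 0.5)
    jn <- attr(fr, "junctions")
    if (!any(jn$type == "gap")) next
    found_gap <- TRUE
    a <- assemble_w_transcript(fr, z)
    expect_lt(a$completeness, 1)
    expect_gt(nrow(a$bridged), 0)
    # every N-bridge sits at a dropped-overlap junction
    gaps <- jn$position[jn$type == "gap"]
    for (b in seq_len(nrow(a$bridged)))
      expect_true(any(abs(a$bridged$scaffold_start[b] - gaps) <= 31))
  }
  expect_true(found_gap)
})

test_that("unplaceable input yields an empty assembly with a diagnostic", {
  z <- random_dna(500, seed = 76)
  a <- assemble_w_transcript(frag_df(random_dna(150)), z)
  expect_equal(a$consensus, "")
  expect_equal(a$completeness, 0)
  expect_match(a$diagnostic, "no fragments placed")
})

test_that("exact duplicates across sources are removed before assembly", {
  z <- random_dna(800, seed = 77)
  piece <- substr(z, 101, 400)
  sets <- list(
    data.frame(id = "e1", sequence = piece, source = "annotation"),
    data.frame(id = "c1", sequence = piece, source = "genome-guided"),
    data.frame(id = "d1", sequence = revcomp(piece), source = "de-novo"))
  a <- assemble_w_transcript(sets, z)
  expect_equal(a$report$n_fragments_in, 1L)
  expect_equal(a$layout$placements$source, "annotation")
  expect_identical(a$consensus, piece)
})
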