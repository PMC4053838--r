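test_that("the female-specificity screen follows its thresholds", {
  cand <- candidate_transcripts(
    id = c("w_like", "balanced", "z_like", "silent"),
    sequence = rep(random_dna(300, seed = 51), 4),
    fpkm = data.frame(
      fpkm_blastoderm_F = c(12, 20, 10, 0.2),
      fpkm_blastoderm_M = c(0, 18, 16, 0.05),
      fpkm_gonad_F = c(5, 25, 11, 0.3),
      fpkm_gonad_M = c(0.05, 22, 17, 0.02)))
  sc <- female_specific_screen(cand)
  expect_equal(sc$female_specific,
               c(TRUE, FALSE, FALSE, FALSE))
  expect_error(female_specific_screen(cand[, 1:2]), "both sexes")
})

test_that("true W transcripts pass the screen and decoys are eliminated", {
  zw <- default_zw()
  sc <- female_specific_screen(zw$candidates)
  expect_gte(mean(sc$female_specific[sc$is_true_w]), 0.95)
  flagged <- sc[sc$female_specific, , drop = FALSE]
  rv <- retroviral_filter(flagged)
  expect_equal(sum(rv$retained$is_decoy), 0L)
  expect_equal(sum(rv$removed$is_true_w), 0L)
  ps <- pseudogene_filter(rv$retained, zw$z_proteins)
  # overall recall through screen + both filters
  expect_gte(sum(ps$retained$is_true_w) / sum(sc$is_true_w), 0.95)
  expect_equal(sum(ps$retained$is_decoy), 0L)
  # retained and removed partition the input at each step
  expect_setequal(c(rv$retained$id, rv$removed$id), flagged$id)
  expect_length(intersect(rv$retained$id, rv$removed$id), 0)
  expect_setequal(c(ps$retained$id, ps$removed$id), rv$retained$id)
})

test_that("decoys from the generator are removed by the e-value filter", {
  panel <- load_retro_panel()
  decoys <- make_retroviral_decoys(5, panel, seed = 52)
  cand <- candidate_transcripts(names(decoys), unname(decoys))
  rv <- retroviral_filter(cand, panel)
  expect_equal(nrow(rv$removed), 5L)
  expect_true(all(rv$report$best_evalue < 0.001))
  # noiseless back-translation encodes a panel protein exactly
  clean <- make_retroviral_decoys(1, panel, codon_noise = 0, seed = 53)
  orfs <- find_orfs(clean[[1]], min_aa = 30)
  expect_true(any(orfs$protein %in% unname(panel)))
  expect_equal(length(make_retroviral_decoys(0, panel)), 0L)
  expect_error(make_retroviral_decoys(2, character(0)), "non-empty")
})

test_that("a perfect panel self-hit has a vanishing e-value", {
  panel <- load_retro_panel()
  prot <- substr(panel[[1]], 1, 100)
  cds <- paste0(vapply(strsplit(prot, "")[[1]], function(a) {
    gc <- Biostrings::GENETIC_CODE
    names(gc)[gc == a][1]
  }, character(1)), collapse = "")
  cand <- candidate_transcripts("self", paste0(cds, "TAA"))
  rv <- retroviral_filter(cand, panel)
  expect_equal(rv$report$decision, "removed")
  expect_lt(rv$report$best_evalue, 1e-10)
})

test_that("a transcript with no qualifying ORF is retained", {
  s <- strrep("TTA", 100)  # no G anywhere, so no start codon in any frame
  expect_equal(nrow(find_orfs(s, min_aa = 30)), 0L)
  rv <- retroviral_filter(candidate_transcripts("r", s))
  expect_equal(rv$report$decision, "retained")
  expect_equal(rv$report$reason, "no_orf")
})

test_that("e-values decrease monotonically in the alignment score", {
  ev <- karlin_altschul_evalue(seq(20, 200, by = 20), 300, 200)$evalue
  expect_true(all(diff(ev) < 0))
})

test_that("pseudogene filtering removes truncated and stop-interrupted ORFs", {
  set.seed(55)
  z <- random_cds(200)
  prot <- sub("\\*$", "", translate_cds(z))
  refs <- c(REF = prot)
  intact <- candidate_transcripts("intact", z)
  expect_equal(pseudogene_filter(intact, refs)$report$decision, "retained")
  # single-codon stop injection mid-ORF
  broken <- z
  substr(broken, 301, 303) <- "TAA"
  res <- pseudogene_filter(candidate_transcripts("broken", broken), refs)
  expect_equal(res$report$decision, "removed")
  # truncation to under a third of the protein
  trunc <- paste0(substr(z, 1, 180), "TAA")
  res2 <- pseudogene_filter(candidate_transcripts("trunc", trunc), refs)
  expect_equal(res2$report$decision, "removed")
  expect_equal(res2$report$reason, "low_coverage")
})
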