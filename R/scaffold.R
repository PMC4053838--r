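#' Place transcript fragments on a Z-gametologue scaffold
#'
#' Locally aligns every fragment to the Z cDNA in both orientations
#' (match +2, mismatch -3, gap open 5, extend 2) and places it at its best
#' location when the alignment spans at least \code{min_len} bp with at
#' least \code{min_identity} percent identity. Ties are broken by leftmost
#' scaffold start, then plus orientation. W/Z gametologues diverge mostly
#' by substitution, so when a gapless interpretation of the best alignment
#' (the fragment projected at a constant offset) reaches the identity
#' threshold the full fragment is placed gaplessly; this extends local
#' alignments whose mismatching terminal bases were clipped. Otherwise the
#' fragment is projected column-by-column through the alignment (fragment
#' insertions relative to the scaffold are dropped).
#'
#' @param fragments a \code{\link{fragmentize}} table or data.frame with
#'   columns id, sequence and optionally source.
#' @param z_cdna Z gametologue cDNA (single DNA string).
#' @param min_identity minimum percent identity (default 80).
#' @param min_len minimum alignment span in bp (default 50).
#' @return object of class \code{scaffold_layout}: \code{placements}
#'   (id, orientation, scaffold_start/end 0-based half-open, identity,
#'   source, projected sequence), \code{unplaced} (id, reason),
#'   \code{z_cdna}.
#' @export
place_fragments <- function(fragments, z_cdna, min_identity = 80,
                            min_len = 50L) {
  stopifnot(is.character(z_cdna), length(z_cdna) == 1L, nchar(z_cdna) > 0)
  z_cdna <- toupper(z_cdna)
  Lz <- nchar(z_cdna)
  if (is.null(fragments$source)) fragments$source <- "de-novo"
  zchars <- strsplit(z_cdna, "")[[1]]

  placements <- list(); unplaced <- list()
  for (i in seq_len(nrow(fragments))) {
    seqs <- c("+" = toupper(fragments$sequence[i]))
    seqs["-"] <- revcomp(seqs["+"])
    alns <- lapply(seqs, align_dna, b = z_cdna, type = "local")
    sc <- vapply(alns, Biostrings::score, numeric(1))
    st <- vapply(alns, function(a)
      Biostrings::start(Biostrings::subject(a)), numeric(1))
    ord <- order(-sc, st, c(1, 2))  # score desc, leftmost, then '+'
    ori <- names(seqs)[ord[1]]
    aln <- alns[[ori]]
    oriented <- seqs[[ori]]

    span <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
    ident <- alignment_identity(aln)
    if (span < min_len || ident < min_identity) {
      unplaced[[length(unplaced) + 1L]] <- data.frame(
        id = fragments$id[i],
        reason = if (span < min_len) "short_alignment" else "low_identity",
        stringsAsFactors = FALSE)
      next
    }

    sstart <- Biostrings::start(Biostrings::subject(aln))
    pstart <- Biostrings::start(Biostrings::pattern(aln))
    offset0 <- sstart - pstart                # 0-based scaffold offset
    n <- nchar(oriented)
    a <- max(0L, offset0); b <- min(Lz, offset0 + n)
    frag_sub <- substr(oriented, a - offset0 + 1L, b - offset0)
    fchars <- strsplit(frag_sub, "")[[1]]
    gapless_id <- if (b > a)
      100 * sum(fchars == zchars[(a + 1L):b]) / (b - a) else 0

    if (gapless_id >= min_identity) {
      proj <- frag_sub
      scaf_start <- a; scaf_end <- b
      ident <- gapless_id
    } else {
      pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
      sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
      keep <- sa != "-"
      proj_chars <- pa[keep]
      proj_chars[proj_chars == "-"] <- "-"
      proj <- paste(proj_chars, collapse = "")
      scaf_start <- sstart - 1L
      scaf_end <- Biostrings::end(Biostrings::subject(aln))
    }

    placements[[length(placements) + 1L]] <- data.frame(
      id = fragments$id[i], orientation = ori,
      scaffold_start = scaf_start, scaffold_end = scaf_end,
      identity = ident, source = fragments$source[i],
      proj = proj, stringsAsFactors = FALSE)
  }

  pl <- if (length(placements)) do.call(rbind, placements) else
    data.frame(id = character(), orientation = character(),
               scaffold_start = integer(), scaffold_end = integer(),
               identity = numeric(), source = character(),
               proj = character(), stringsAsFactors = FALSE)
  pl <- pl[order(pl$scaffold_start, pl$scaffold_end), , drop = FALSE]
  rownames(pl) <- NULL
  up <- if (length(unplaced)) do.call(rbind, unplaced) else
    data.frame(id = character(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(placements = pl, unplaced = up, z_cdna = z_cdna),
            class = "scaffold_layout")
}

#' @export
print.scaffold_layout <- function(x, ...) {
  cat(sprintf("scaffold_layout: %d placed, %d unplaced on a %d nt scaffold\n",
              nrow(x$placements), nrow(x$unplaced), nchar(x$z_cdna)))
  if (nrow(x$placements))
    print(x$placements[, c("id", "orientation", "scaffold_start",
                           "scaffold_end", "identity", "source")],
          row.names = FALSE)
  invisible(x)
}

SOURCE_PRIORITY <- c(annotation = 1, `genome-guided` = 2, `de-novo` = 3)

# majority-vote consensus over placements covering [start, end) on the
# scaffold; ties broken by source priority, then placement order
consensus_run <- function(members, start, end) {
  width <- end - start
  votes <- matrix(NA_character_, nrow = nrow(members), ncol = width)
  for (i in seq_len(nrow(members))) {
    off <- members$scaffold_start[i] - start
    ch <- strsplit(members$proj[i], "")[[1]]
    ch[ch == "-"] <- NA_character_
    votes[i, off + seq_along(ch)] <- ch
  }
  prio <- SOURCE_PRIORITY[members$source]
  prio[is.na(prio)] <- 4
  cons <- character(width)
  depth <- integer(width)
  disagreements <- 0L
  for (j in seq_len(width)) {
    v <- votes[, j]
    ok <- !is.na(v)
    depth[j] <- sum(ok)
    if (!any(ok)) { cons[j] <- "N"; next }
    tab <- tapply(rep(1, sum(ok)), v[ok], sum)
    if (length(tab) > 1L) disagreements <- disagreements + 1L
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) == 1L) {
      cons[j] <- winners
    } else {
      cand <- which(ok & v %in% winners)
      cons[j] <- v[cand[order(prio[cand], cand)][1L]]
    }
  }
  list(consensus = paste(cons, collapse = ""), depth = depth,
       disagreements = disagreements)
}

pair_overlap_identity <- function(p1, p2) {
  s <- max(p1$scaffold_start, p2$scaffold_start)
  e <- min(p1$scaffold_end, p2$scaffold_end)
  if (e <= s) return(NA_real_)
  sub <- function(p) substr(p$proj, s - p$scaffold_start + 1L,
                            e - p$scaffold_start)
  a <- strsplit(sub(p1), "")[[1]]; b <- strsplit(sub(p2), "")[[1]]
  ok <- a != "-" & b != "-"
  if (!any(ok)) return(100)
  100 * sum(a[ok] == b[ok]) / sum(ok)
}

#' Merge overlapping placements into consensus contigs
#'
#' Walks the placements left to right on the scaffold and joins adjacent
#' placements whose projections overlap by at least \code{min_overlap}
#' scaffold positions with at least \code{min_identity} percent agreement.
#' The consensus of each contig is a per-column majority vote with the
#' per-base support depth recorded; tied columns fall back to source
#' priority (annotation > genome-guided > de-novo). Overlaps that fail the
#' identity threshold (or are shorter than \code{min_overlap}) leave both
#' sides in separate contigs and are logged as conflicts.
#'
#' @param layout a \code{\link{place_fragments}} result.
#' @param min_overlap minimum scaffold overlap in bp (default 40).
#' @param min_identity minimum percent agreement in the overlap
#'   (default 95).
#' @return object of class \code{merged_transcript} with \code{contigs}
#'   (scaffold interval, consensus, depth, member ids, disagreement
#'   count), \code{conflicts}, \code{provenance} and \code{z_cdna};
#'   the single bridged consensus is added by \code{\link{bridge_gaps}}.
#' @export
merge_overlaps <- function(layout, min_overlap = 40L, min_identity = 95) {
  stopifnot(inherits(layout, "scaffold_layout"))
  pl <- layout$placements
  conflicts <- list()
  contigs <- list()
  if (nrow(pl)) {
    group <- integer(nrow(pl))
    group[1L] <- 1L
    cur_end <- pl$scaffold_end[1L]
    for (i in seq_len(nrow(pl))[-1]) {
      ov <- cur_end - pl$scaffold_start[i]
      join <- FALSE
      if (ov >= min_overlap) {
        prev <- which(group == group[i - 1L])
        ids <- vapply(prev, function(k)
          pair_overlap_identity(pl[k, ], pl[i, ]), numeric(1))
        ids <- ids[!is.na(ids)]
        if (!length(ids) || min(ids) >= min_identity) {
          join <- TRUE
        } else {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            id = pl$id[i], type = "irreconcilable_overlap",
            overlap = ov, identity = min(ids), stringsAsFactors = FALSE)
        }
      } else if (ov > 0) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          id = pl$id[i], type = "short_overlap", overlap = ov,
          identity = NA_real_, stringsAsFactors = FALSE)
      }
      group[i] <- if (join) group[i - 1L] else max(group) + 1L
      cur_end <- if (join) max(cur_end, pl$scaffold_end[i]) else
        pl$scaffold_end[i]
    }
    for (g in unique(group)) {
      members <- pl[group == g, , drop = FALSE]
      s <- min(members$scaffold_start); e <- max(members$scaffold_end)
      cr <- consensus_run(members, s, e)
      contigs[[length(contigs) + 1L]] <- list(
        scaffold_start = s, scaffold_end = e, consensus = cr$consensus,
        depth = cr$depth, members = members$id,
        disagreements = cr$disagreements)
    }
  }
  provenance <- if (nrow(pl))
    data.frame(id = pl$id, scaffold_start = pl$scaffold_start,
               scaffold_end = pl$scaffold_end, source = pl$source,
               stringsAsFactors = FALSE)
  else data.frame(id = character(), scaffold_start = integer(),
                  scaffold_end = integer(), source = character())
  structure(list(contigs = contigs,
                 conflicts = if (length(conflicts))
                   do.call(rbind, conflicts) else
                   data.frame(id = character(), type = character(),
                              overlap = integer(), identity = numeric()),
                 provenance = provenance,
                 z_cdna = layout$z_cdna,
                 consensus = NULL, bridged = NULL, completeness = NA_real_),
            class = "merged_transcript")
}

#' Bridge between-contig gaps with N runs sized by the Z scaffold
#'
#' Joins ordered contigs into a single consensus, filling each gap with as
#' many Ns as the Z-scaffold distance between the contigs. Bridged
#' intervals are recorded in consensus coordinates (0-based half-open).
#' Contigs whose scaffold intervals overlap (a negative inferred gap, the
#' conflict case) are not joined: the longer chain is kept and the other
#' contig reported as secondary. Completeness is the fraction of the Z
#' ORF span (longest plus-frame ORF of the scaffold) covered by non-N
#' consensus.
#'
#' @param merged a \code{\link{merge_overlaps}} result.
#' @return the \code{merged_transcript} with \code{consensus},
#'   \code{scaffold_offset}, \code{bridged} intervals, \code{secondary}
#'   contigs and \code{completeness} filled in.
#' @export
bridge_gaps <- function(merged) {
  stopifnot(inherits(merged, "merged_transcript"))
  contigs <- merged$contigs
  if (!length(contigs)) {
    merged$consensus <- ""
    merged$completeness <- 0
    merged$bridged <- data.frame(consensus_start = integer(),
                                 consensus_end = integer())
    merged$diagnostic <- "no fragments placed on the scaffold"
    return(merged)
  }
  ord <- order(vapply(contigs, `[[`, numeric(1), "scaffold_start"))
  contigs <- contigs[ord]
  secondary <- list()
  chain <- list(contigs[[1L]])
  for (k in seq_along(contigs)[-1]) {
    cur <- chain[[length(chain)]]
    gap <- contigs[[k]]$scaffold_start - cur$scaffold_end
    if (gap >= 0) {
      chain[[length(chain) + 1L]] <- contigs[[k]]
    } else {
      # conflicting placement: keep the longer contig in the chain
      if (nchar(contigs[[k]]$consensus) > nchar(cur$consensus)) {
        secondary[[length(secondary) + 1L]] <- cur
        chain[[length(chain)]] <- contigs[[k]]
      } else {
        secondary[[length(secondary) + 1L]] <- contigs[[k]]
      }
    }
  }
  pieces <- character(0)
  bridged <- list()
  offset <- chain[[1L]]$scaffold_start
  pos <- 0L
  prev_end <- NULL
  for (ct in chain) {
    if (!is.null(prev_end)) {
      gap <- ct$scaffold_start - prev_end
      if (gap > 0) {
        bridged[[length(bridged) + 1L]] <- data.frame(
          consensus_start = pos, consensus_end = pos + gap,
          scaffold_start = prev_end, scaffold_end = ct$scaffold_start)
        pieces <- c(pieces, strrep("N", gap))
        pos <- pos + gap
      }
    }
    pieces <- c(pieces, ct$consensus)
    pos <- pos + nchar(ct$consensus)
    prev_end <- ct$scaffold_end
  }
  merged$contigs <- chain
  merged$secondary <- secondary
  merged$consensus <- paste(pieces, collapse = "")
  merged$scaffold_offset <- offset
  merged$bridged <- if (length(bridged)) do.call(rbind, bridged) else
    data.frame(consensus_start = integer(), consensus_end = integer(),
               scaffold_start = integer(), scaffold_end = integer())
  merged$completeness <- orf_completeness(merged)
  merged
}

# fraction of the scaffold's longest plus-frame ORF covered by non-N
# consensus positions
orf_completeness <- function(merged) {
  z <- merged$z_cdna
  orfs <- find_orfs(z, min_aa = 10L)
  orfs <- orfs[orfs$frame > 0, , drop = FALSE]
  if (nrow(orfs)) {
    j <- which.max(orfs$end - orfs$start)
    span <- c(orfs$start[j], orfs$end[j])
  } else span <- c(0L, nchar(z))
  chars <- strsplit(merged$consensus, "")[[1]]
  if (!length(chars)) return(0)
  scafpos <- merged$scaffold_offset + seq_along(chars) - 1L  # 0-based
  covered <- sum(chars != "N" & scafpos >= span[1] & scafpos < span[2])
  covered / (span[2] - span[1])
}

#' @export
print.merged_transcript <- function(x, ...) {
  cat(sprintf("merged_transcript: %d contig(s)", length(x$contigs)))
  if (!is.null(x$consensus))
    cat(sprintf(", consensus %d nt, completeness %.3f", nchar(x$consensus),
                x$completeness))
  cat("\n")
  if (!is.null(x$bridged) && nrow(x$bridged))
    cat(sprintf("  %d N-bridge(s) totalling %d nt\n", nrow(x$bridged),
                sum(x$bridged$consensus_end - x$bridged$consensus_start)))
  if (nrow(x$conflicts))
    cat(sprintf("  %d overlap conflict(s)\n", nrow(x$conflicts)))
  if (!is.null(x$diagnostic)) cat("  note:", x$diagnostic, "\n")
  invisible(x)
}

#' Assemble a W transcript from multi-source fragments
#'
#' Runs the full scaffolding pipeline: exact-duplicate removal across
#' sources (keeping the highest-priority source; reverse-complement
#' duplicates count as duplicates), placement on the Z gametologue cDNA,
#' overlap-consensus merging and N-bridging. The report lists per-source
#' contribution intervals and the final (longest, plus-frame) ORF of the
#' consensus.
#'
#' @param fragment_sets one fragment table or a list of per-source tables
#'   (see \code{\link{place_fragments}}).
#' @param z_cdna Z gametologue cDNA.
#' @param min_identity,min_len placement thresholds
#'   (\code{\link{place_fragments}}).
#' @param min_overlap,merge_identity merge thresholds
#'   (\code{\link{merge_overlaps}}).
#' @return a \code{merged_transcript} with an additional \code{report}
#'   element (layout, per-source intervals, final ORF).
#' @export
assemble_w_transcript <- function(fragment_sets, z_cdna, min_identity = 80,
                                  min_len = 50L, min_overlap = 40L,
                                  merge_identity = 95) {
  if (is.data.frame(fragment_sets)) fragment_sets <- list(fragment_sets)
  frags <- do.call(rbind, lapply(fragment_sets, function(f)
    data.frame(id = f$id, sequence = toupper(f$sequence),
               source = if (is.null(f$source)) "de-novo" else f$source,
               stringsAsFactors = FALSE)))
  if (!nrow(frags)) stop("at least one fragment is required")
  canon <- pmin(frags$sequence, revcomp(frags$sequence))
  prio <- SOURCE_PRIORITY[frags$source]
  prio[is.na(prio)] <- 4
  keep <- !duplicated(canon[order(prio, seq_len(nrow(frags)))])
  frags <- frags[order(prio, seq_len(nrow(frags)))[keep], , drop = FALSE]

  layout <- place_fragments(frags, z_cdna, min_identity = min_identity,
                            min_len = min_len)
  merged <- merge_overlaps(layout, min_overlap = min_overlap,
                           min_identity = merge_identity)
  merged <- bridge_gaps(merged)
  merged$layout <- layout

  per_source <- if (nrow(merged$provenance))
    split(merged$provenance[, c("id", "scaffold_start", "scaffold_end")],
          merged$provenance$source)
  else list()
  final_orf <- if (nchar(merged$consensus) >= 30) {
    orfs <- find_orfs(merged$consensus, min_aa = 10L)
    orfs <- orfs[orfs$frame > 0, , drop = FALSE]
    if (nrow(orfs)) orfs[which.max(orfs$end - orfs$start), , drop = FALSE]
    else NULL
  } else NULL
  merged$report <- list(per_source_intervals = per_source,
                        final_orf = final_orf,
                        n_fragments_in = nrow(frags),
                        n_placed = nrow(layout$placements),
                        n_unplaced = nrow(layout$unplaced))
  merged
}
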