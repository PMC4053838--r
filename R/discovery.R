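#' Candidate transcript table for W-gene discovery
#'
#' @param id character ids.
#' @param sequence DNA sequences (ACGTN).
#' @param source source label per candidate: annotation, genome-guided or
#'   de-novo.
#' @param chrom claimed pseudo-chromosome (optional).
#' @param fpkm data.frame (or NULL) with columns
#'   \code{fpkm_blastoderm_F}, \code{fpkm_blastoderm_M},
#'   \code{fpkm_gonad_F}, \code{fpkm_gonad_M}.
#' @return data.frame of class \code{candidate_set}.
#' @export
candidate_transcripts <- function(id, sequence, source = "de-novo",
                                  chrom = NA_character_, fpkm = NULL) {
  sequence <- toupper(sequence)
  if (!length(id)) {
    out <- data.frame(id = character(), sequence = character(),
                      source = character(), chrom = character(),
                      stringsAsFactors = FALSE)
  } else {
    if (!is_valid_dna(sequence))
      stop("candidate sequences must be non-empty ACGTN")
    out <- data.frame(id = id, sequence = sequence,
                      source = rep_len(source, length(id)),
                      chrom = rep_len(chrom, length(id)),
                      stringsAsFactors = FALSE)
  }
  if (!is.null(fpkm)) {
    need <- c("fpkm_blastoderm_F", "fpkm_blastoderm_M",
              "fpkm_gonad_F", "fpkm_gonad_M")
    if (!all(need %in% names(fpkm)))
      stop("fpkm must have columns: ", paste(need, collapse = ", "))
    if (any(as.matrix(fpkm[need]) < 0, na.rm = TRUE))
      stop("expression summaries must be >= 0")
    out <- cbind(out, fpkm[need])
  }
  class(out) <- c("candidate_set", class(out))
  out
}

#' Female-specificity screen for candidate W transcripts
#'
#' Flags candidates expressed in females (FPKM at or above
#' \code{expressed_floor} in at least one tissue) and silent in males
#' (FPKM at or below \code{male_ceiling} in all tissues).
#'
#' @param candidates a \code{\link{candidate_transcripts}} table with FPKM
#'   summaries.
#' @param expressed_floor minimum female FPKM in >= 1 tissue (default 1).
#' @param male_ceiling maximum male FPKM in every tissue (default 0.1).
#' @return the candidate table with a logical \code{female_specific}
#'   column.
#' @export
female_specific_screen <- function(candidates, expressed_floor = 1,
                                   male_ceiling = 0.1) {
  need <- c("fpkm_blastoderm_F", "fpkm_blastoderm_M",
            "fpkm_gonad_F", "fpkm_gonad_M")
  if (!all(need %in% names(candidates)))
    stop("candidates lack expression summaries for both sexes")
  f_ok <- candidates$fpkm_blastoderm_F >= expressed_floor |
          candidates$fpkm_gonad_F >= expressed_floor
  m_ok <- candidates$fpkm_blastoderm_M <= male_ceiling &
          candidates$fpkm_gonad_M <= male_ceiling
  candidates$female_specific <- f_ok & m_ok
  candidates
}

# best panel hit over all ORFs of one sequence
best_panel_hit <- function(sequence, panel, min_aa = 30L) {
  orfs <- find_orfs(sequence, min_aa = min_aa)
  best <- list(evalue = Inf, bits = -Inf, panel = NA_character_,
               n_orfs = nrow(orfs))
  if (!nrow(orfs)) return(best)
  for (i in seq_len(nrow(orfs))) {
    prot <- gsub("[^A-Z]", "X", orfs$protein[i])
    sc <- panel_scores(prot, panel)
    ka <- karlin_altschul_evalue(sc, nchar(prot), nchar(panel))
    j <- which.min(ka$evalue)
    if (ka$evalue[j] < best$evalue)
      best <- list(evalue = ka$evalue[j], bits = ka$bits[j],
                   panel = names(panel)[j], n_orfs = nrow(orfs))
  }
  best
}

#' Remove candidates with retroviral protein homology
#'
#' Scans each candidate's open reading frames (six frames, >=
#' \code{min_aa} aa) and aligns each ORF protein locally (BLOSUM62, affine
#' gaps 11/1) against every panel protein. Scores are converted to
#' Karlin-Altschul e-values; a candidate is removed when any ORF achieves
#' an e-value below \code{evalue_threshold} (default 0.001).
#'
#' @param candidates a \code{candidate_set} (or data.frame with id and
#'   sequence).
#' @param protein_panel named character vector of panel proteins; the
#'   packaged synthetic panel by default.
#' @param evalue_threshold removal threshold.
#' @param min_aa minimum ORF protein length scanned.
#' @return list with \code{retained}, \code{removed} (both subsets of the
#'   input) and \code{report} (id, decision, reason, best e-value, best
#'   panel protein).
#' @export
retroviral_filter <- function(candidates, protein_panel = NULL,
                              evalue_threshold = 0.001, min_aa = 30L) {
  if (is.null(protein_panel)) protein_panel <- load_retro_panel()
  if (!length(protein_panel)) stop("protein panel must be non-empty")
  if (!is_valid_protein(protein_panel))
    stop("panel entries contain non-amino-acid characters")
  hits <- lapply(candidates$sequence, best_panel_hit, panel = protein_panel,
                 min_aa = min_aa)
  ev <- vapply(hits, `[[`, numeric(1), "evalue")
  removed <- ev < evalue_threshold
  report <- data.frame(
    id = candidates$id,
    decision = ifelse(removed, "removed", "retained"),
    reason = ifelse(removed, "retroviral_homology",
             ifelse(is.finite(ev), "no_significant_hit", "no_orf")),
    best_evalue = ev,
    best_panel = vapply(hits, `[[`, character(1), "panel"),
    stringsAsFactors = FALSE)
  list(retained = candidates[!removed, , drop = FALSE],
       removed = candidates[removed, , drop = FALSE],
       report = report)
}

#' Remove pseudogene-like candidates
#'
#' A candidate is treated as a pseudogene relic when, against its
#' best-matching gametologue protein, (a) its best ORF covers less than
#' \code{min_coverage} of the protein length, or (b) the best-matching
#' reading frame contains an internal stop codon within the span aligned
#' to the protein. The frame translation is aligned with stops recoded to
#' X so that a homologous region interrupted by a stop is still detected.
#'
#' @param candidates a \code{candidate_set}.
#' @param gametologue_proteins named character vector of reference
#'   (Z-gametologue) proteins.
#' @param min_coverage minimum ORF / protein length ratio (default 0.5).
#' @param min_aa minimum ORF length considered.
#' @return list with \code{retained}, \code{removed} and \code{report}
#'   (id, decision, reason, coverage, best protein).
#' @export
pseudogene_filter <- function(candidates, gametologue_proteins,
                              min_coverage = 0.5, min_aa = 10L) {
  if (!length(gametologue_proteins)) stop("no gametologue proteins supplied")
  n <- nrow(candidates)
  decision <- character(n); reason <- character(n)
  coverage <- numeric(n); best_prot <- character(n)
  for (i in seq_len(n)) {
    seqi <- candidates$sequence[i]
    orfs <- find_orfs(seqi, min_aa = min_aa)
    if (!nrow(orfs)) {
      decision[i] <- "removed"; reason[i] <- "no_orf"
      coverage[i] <- 0; best_prot[i] <- NA_character_
      next
    }
    # best ORF x protein pair by local alignment score
    best <- list(score = -Inf, orf = NA_integer_, prot = NA_character_)
    for (j in seq_len(nrow(orfs))) {
      sc <- panel_scores(orfs$protein[j], gametologue_proteins)
      k <- which.max(sc)
      if (sc[k] > best$score)
        best <- list(score = sc[k], orf = j,
                     prot = names(gametologue_proteins)[k])
    }
    best_prot[i] <- best$prot
    plen <- nchar(gametologue_proteins[[best$prot]])
    coverage[i] <- nchar(orfs$protein[best$orf]) / plen
    # stop-in-span check on the best ORF's frame
    frame_prot <- frame_translation(seqi, orfs$frame[best$orf])
    aln <- align_protein(chartr("*", "X", frame_prot),
                         gametologue_proteins[[best$prot]], type = "local")
    span_start <- Biostrings::start(Biostrings::pattern(aln))
    span_end <- Biostrings::end(Biostrings::pattern(aln))
    # local alignments never end on a mismatching column, so a genuine
    # terminal stop sits outside the span; any stop inside is internal
    stop_in_span <- grepl("*", substr(frame_prot, span_start, span_end),
                          fixed = TRUE)
    if (coverage[i] < min_coverage) {
      decision[i] <- "removed"; reason[i] <- "low_coverage"
    } else if (stop_in_span) {
      decision[i] <- "removed"; reason[i] <- "internal_stop"
    } else {
      decision[i] <- "retained"; reason[i] <- "intact"
    }
  }
  removed <- decision == "removed"
  report <- data.frame(id = candidates$id, decision = decision,
                       reason = reason, coverage = coverage,
                       best_protein = best_prot, stringsAsFactors = FALSE)
  list(retained = candidates[!removed, , drop = FALSE],
       removed = candidates[removed, , drop = FALSE],
       report = report)
}

# translation of one frame (+1..+3 / -1..-3) of a transcript
frame_translation <- function(sequence, frame) {
  s <- if (frame > 0) sequence else revcomp(sequence)
  off <- abs(frame) - 1L
  n_cod <- (nchar(s) - off) %/% 3L
  if (n_cod < 1L) return("")
  translate_cds(substr(s, off + 1L, off + 3L * n_cod))
}
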