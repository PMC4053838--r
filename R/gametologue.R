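#' Find the Z gametologue of a W transcript
#'
#' Locally aligns the W transcript against every member of a Z transcript
#' set and returns the best-scoring hit whose alignment covers at least
#' \code{min_coverage} of both sequences (reciprocal coverage). Returns
#' \code{NULL} when no hit qualifies — the situation of a W gene without a
#' surviving Z partner.
#'
#' @param w_transcript W transcript (DNA string).
#' @param z_transcript_set named character vector of Z transcripts.
#' @param min_coverage reciprocal coverage threshold (default 0.5).
#' @return list with \code{id}, \code{score}, \code{identity},
#'   \code{coverage_w}, \code{coverage_z}, or \code{NULL}.
#' @export
find_z_gametologue <- function(w_transcript, z_transcript_set,
                               min_coverage = 0.5) {
  if (!length(z_transcript_set)) stop("z_transcript_set must be non-empty")
  best <- NULL
  for (id in names(z_transcript_set)) {
    aln <- align_dna(toupper(w_transcript),
                     toupper(z_transcript_set[[id]]), type = "local")
    cw <- Biostrings::width(Biostrings::pattern(aln)) / nchar(w_transcript)
    cz <- Biostrings::width(Biostrings::subject(aln)) /
      nchar(z_transcript_set[[id]])
    if (cw < min_coverage || cz < min_coverage) next
    sc <- Biostrings::score(aln)
    if (is.null(best) || sc > best$score)
      best <- list(id = id, score = sc, identity = alignment_identity(aln),
                   coverage_w = cw, coverage_z = cz)
  }
  best
}

#' Full divergence comparison of a W/Z gametologue pair
#'
#' Computes DNA and protein identity (end-gap-free global alignments),
#' whole-gene Nei-Gojobori dN/dS after codon alignment, and the
#' sliding-window omega profile.
#'
#' @param w_cds,z_cds coding sequences of the W and Z copies.
#' @param pair_id label for the pair.
#' @param window_codons,step_codons sliding-window parameters.
#' @return object of class \code{gametologue_comparison}.
#' @export
gametologue_compare <- function(w_cds, z_cds, pair_id = "pair",
                                window_codons = 50L, step_codons = 10L) {
  w_cds <- toupper(w_cds); z_cds <- toupper(z_cds)
  dna_id <- global_align_identity(w_cds, z_cds, "dna")
  aligned <- codon_align(w_cds, z_cds)
  prot_w <- translate_cds(aligned$w)
  prot_z <- translate_cds(aligned$z)
  prot_id <- global_align_identity(prot_w, prot_z, "protein")
  est <- nei_gojobori_dnds(aligned$w, aligned$z)
  profile <- if (nchar(aligned$w) >= 3L * step_codons)
    suppressWarnings(sliding_window_dnds(aligned$w, aligned$z,
                                         window_codons, step_codons))
  else NULL
  structure(list(pair_id = pair_id, dna_identity = dna_id,
                 protein_identity = prot_id, dN = est$dN, dS = est$dS,
                 omega = est$omega, status = est$status,
                 estimate = est, window_profile = profile),
            class = "gametologue_comparison")
}

#' @export
print.gametologue_comparison <- function(x, ...) {
  cat(sprintf("gametologue pair %s\n", x$pair_id))
  cat(sprintf("  DNA identity %.1f%%, protein identity %.1f%%\n",
              x$dna_identity, x$protein_identity))
  om <- if (x$status == "ZERO") "0.000"
        else if (is.na(x$omega)) x$status
        else sprintf("%.3f", x$omega)
  cat(sprintf("  dN %.4f, dS %.4f, dN/dS %s\n",
              ifelse(is.na(x$dN), NaN, x$dN),
              ifelse(is.na(x$dS), NaN, x$dS), om))
  invisible(x)
}

#' Compare combined female W+Z expression with male ZZ expression
#'
#' For one gametologue pair, sums the W and Z counts within each sample:
#' in females the total reflects W + Z transcription, in males the two Z
#' alleles. Per tissue, the summed counts are tested for a sex difference
#' with the negative-binomial likelihood-ratio sex test, flagged at
#' \code{p_threshold} (default 0.01). The W share of the female total is
#' reported per tissue from FPKM.
#'
#' @param experiment a \code{\link{count_experiment}} containing both pair
#'   members.
#' @param w_gene,z_gene gene ids of the W and Z copies.
#' @param dispersion NB dispersion for the summed counts (a single value;
#'   default the common dispersion estimated from the experiment, or 0.04
#'   when estimation is not possible).
#' @param p_threshold significance flag threshold.
#' @return object of class \code{combined_expression_verdict}: per-tissue
#'   female and male mean FPKM totals, W share of the female total,
#'   p-values and significance flags.
#' @export
combined_expression_compare <- function(experiment, w_gene, z_gene,
                                        dispersion = NULL,
                                        p_threshold = 0.01) {
  stopifnot(inherits(experiment, "count_experiment"))
  y <- experiment$counts
  if (!all(c(w_gene, z_gene) %in% rownames(y)))
    stop("both pair members must be present in the experiment")
  if (is.null(dispersion)) {
    dispersion <- tryCatch(estimate_dispersions(experiment)$common,
                           error = function(e) 0.04)
  }
  des <- experiment$design
  eff <- normalize_library_sizes(experiment)$effective_lib_sizes
  total <- y[w_gene, ] + y[z_gene, ]
  lens <- experiment$annotation$length[
    match(c(w_gene, z_gene), experiment$annotation$gene_id)]
  fpkm <- compute_fpkm(y[c(w_gene, z_gene), , drop = FALSE],
                       lengths = lens, lib_sizes = eff)
  total_fpkm <- colSums(fpkm)

  per_tissue <- lapply(levels(des$tissue), function(ti) {
    sel <- des$tissue == ti
    female <- sel & des$sex == "F"
    male <- sel & des$sex == "M"
    X <- cbind(intercept = 1, female = as.numeric(des$sex[sel] == "F"))
    offset <- log(eff[sel])
    full <- fit_nb_glm(total[sel], X, offset, dispersion)
    red <- fit_nb_glm(total[sel], X[, 1, drop = FALSE], offset, dispersion)
    stat <- max(red$deviance - full$deviance, 0)
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
    fw <- mean(fpkm[w_gene, female])
    fz <- mean(fpkm[z_gene, female])
    list(tissue = ti,
         female_total = mean(total_fpkm[female]),
         male_total = mean(total_fpkm[male]),
         w_share = if (fw + fz > 0) fw / (fw + fz) else 0,
         p_value = p, significant = p < p_threshold)
  })
  tab <- do.call(rbind, lapply(per_tissue, as.data.frame))
  structure(list(pair = c(W = w_gene, Z = z_gene), table = tab,
                 dispersion = dispersion, p_threshold = p_threshold),
            class = "combined_expression_verdict")
}

#' @export
print.combined_expression_verdict <- function(x, ...) {
  cat(sprintf("combined expression, W=%s vs Z=%s (flag at P < %g)\n",
              x$pair["W"], x$pair["Z"], x$p_threshold))
  print(x$table, row.names = FALSE)
  invisible(x)
}
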