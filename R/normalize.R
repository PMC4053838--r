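#' TMM normalisation of library sizes
#'
#' Computes trimmed-mean-of-M-values scaling factors relative to a
#' reference sample (the sample whose upper-quartile expression is closest
#' to the mean upper quartile). For each sample, genes are doubly trimmed —
#' 30\% from each tail of the log-ratio (M) distribution and 5\% from each
#' tail of the average-abundance (A) distribution — and the factor is the
#' precision-weighted mean of the remaining M values. Factors are rescaled
#' so their geometric mean is 1; effective library sizes are raw library
#' sizes times the factors.
#'
#' @param experiment a \code{\link{count_experiment}}, or a count matrix.
#' @param lib_sizes raw library sizes (taken from the experiment if given).
#' @param logratio_trim,abundance_trim per-tail trim fractions for M and A.
#' @return list with \code{factors} and \code{effective_lib_sizes}.
#' @export
normalize_library_sizes <- function(experiment, lib_sizes = NULL,
                                    logratio_trim = 0.3,
                                    abundance_trim = 0.05) {
  if (inherits(experiment, "count_experiment")) {
    counts <- experiment$counts
    if (is.null(lib_sizes)) lib_sizes <- experiment$lib_sizes
  } else {
    counts <- as.matrix(experiment)
    if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  }
  if (ncol(counts) < 2L) stop("need at least 2 samples")
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))

  # reference: upper-quartile of scaled counts closest to the mean
  f75 <- apply(counts, 2, function(y) quantile(y, 0.75)) / lib_sizes
  ref <- which.min(abs(f75 - mean(f75)))

  factors <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], counts[, ref], lib_sizes[j], lib_sizes[ref],
                    logratio_trim, abundance_trim)
  }, numeric(1))
  factors <- factors / exp(mean(log(factors)))
  names(factors) <- colnames(counts)
  list(factors = factors,
       effective_lib_sizes = lib_sizes * factors)
}

# TMM factor of one sample against the reference
tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                            logratio_trim, abundance_trim) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  keep <- obs > 0 & ref > 0
  if (!any(keep)) return(1)
  m <- log2(p_obs[keep] / p_ref[keep])
  a <- 0.5 * log2(p_obs[keep] * p_ref[keep])
  # asymptotic inverse variance of M (delta method, binomial sampling)
  w <- (n_obs - obs[keep]) / (n_obs * obs[keep]) +
       (n_ref - ref[keep]) / (n_ref * ref[keep])
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1
  hi_a <- n + 1 - lo_a
  keep2 <- rank(m) >= lo_m & rank(m) <= hi_m &
           rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep2)) return(1)
  f <- sum(m[keep2] / w[keep2], na.rm = TRUE) /
       sum(1 / w[keep2], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Fragments per kilobase per million mapped fragments
#'
#' \eqn{FPKM_{gs} = c_{gs} / (L_g/10^3 \cdot N_s/10^6)}.
#'
#' @param counts count matrix (genes x samples) or a
#'   \code{count_experiment}.
#' @param lengths gene lengths in bp (from the annotation if an experiment
#'   is given).
#' @param lib_sizes effective library sizes (raw sizes if omitted).
#' @return numeric matrix of FPKM values.
#' @export
compute_fpkm <- function(counts, lengths = NULL, lib_sizes = NULL) {
  if (inherits(counts, "count_experiment")) {
    if (is.null(lengths)) lengths <- counts$annotation$length
    if (is.null(lib_sizes)) lib_sizes <- counts$lib_sizes
    counts <- counts$counts
  }
  counts <- as.matrix(counts)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (length(lengths) != nrow(counts)) stop("one length per gene required")
  if (any(lengths <= 0)) stop("gene lengths must be > 0")
  sweep(counts / (lengths / 1e3), 2, lib_sizes / 1e6, "/")
}

#' Z-chromosome dosage ratio (male:female)
#'
#' For each expressed Z-linked gene (mean FPKM at or above
#' \code{expressed_floor} in at least one sex) computes the ratio of mean
#' male FPKM to mean female FPKM, then summarises by a trimmed mean
#' (5\% by default) taken on the log scale (a trimmed geometric mean, so
#' that swapping sex labels exactly inverts the estimate). Reported per
#' tissue and pooled across tissues. Non-finite per-gene ratios (a zero
#' mean in either sex) are dropped before averaging.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param design design data.frame (columns sample, tissue, sex).
#' @param annotation annotation data.frame with gene_id and class.
#' @param expressed_floor minimum mean FPKM in at least one sex.
#' @param trim trim fraction for the trimmed mean.
#' @return named numeric vector with elements \code{blastoderm},
#'   \code{gonad} and \code{pooled}.
#' @export
z_dosage_ratio <- function(fpkm, design, annotation, expressed_floor = 1,
                           trim = 0.05) {
  z <- annotation$gene_id[annotation$class == "Z"]
  z <- intersect(z, rownames(fpkm))
  if (!length(z)) stop("no Z-linked genes in the data")
  ratio_in <- function(samples_f, samples_m) {
    mf <- rowMeans(fpkm[z, samples_f, drop = FALSE])
    mm <- rowMeans(fpkm[z, samples_m, drop = FALSE])
    expressed <- pmax(mf, mm) >= expressed_floor
    if (!any(expressed)) stop("no expressed Z-linked genes above the floor")
    r <- log((mm / mf)[expressed])
    r <- r[is.finite(r)]
    exp(trimmed_mean(r, trim))
  }
  out <- c(
    blastoderm = ratio_in(
      design$sample[design$tissue == "blastoderm" & design$sex == "F"],
      design$sample[design$tissue == "blastoderm" & design$sex == "M"]),
    gonad = ratio_in(
      design$sample[design$tissue == "gonad" & design$sex == "F"],
      design$sample[design$tissue == "gonad" & design$sex == "M"]),
    pooled = ratio_in(design$sample[design$sex == "F"],
                      design$sample[design$sex == "M"])
  )
  out
}
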