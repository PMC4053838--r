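#' Configuration for the synthetic ZW mini-genome generator
#'
#' Collects the generative parameters of the synthetic experiment: a
#' factorial RNA-seq design (tissue x sex x replicate) over genes
#' partitioned into chromosome classes (autosome, Z, W, W_random,
#' Un_random), with negative-binomial counts, incomplete Z dosage
#' compensation (male:female mean ratio \code{z_male_ratio} on
#' non-compensated Z genes), strictly female-expressed W genes, an
#' MHM-like female-only Z locus, and tissue-specific autosomal
#' dimorphism.
#'
#' @param n_genes_per_class named integer vector with entries
#'   \code{autosome}, \code{Z}, \code{W}, \code{W_random}, \code{Un_random}.
#' @param z_noncompensated_fraction fraction of Z genes carrying the male
#'   bias, in [0, 1].
#' @param z_male_ratio male:female mean expression ratio for
#'   non-compensated Z genes (> 0).
#' @param w_female_fpkm_range length-2 positive interval; female FPKM of
#'   W-class genes is drawn log-uniformly from it.
#' @param dispersion_prior scale of the NB dispersion; per-gene dispersions
#'   are drawn log-normally around it (sdlog 0.5). Variance model is
#'   \eqn{\mu + \phi \mu^2}.
#' @param n_dimorphic_autosomal_per_tissue number of autosomal genes made
#'   dimorphic in each tissue (and only that tissue).
#' @param dimorphic_fold_change fold change of dimorphic autosomal genes
#'   (> 0; 1 disables dimorphism).
#' @param library_size expected fragments per sample (> 0).
#' @param n_mhm_genes number of Z genes in the female-only MHM-like locus.
#' @param un_random_w_fraction fraction of Un_random genes that behave as
#'   mis-assigned W genes (female-restricted).
#' @param w_leaky if TRUE, W genes receive a small male leak (1\% of the
#'   female mean) instead of hard zeros; for robustness studies only.
#' @param n_replicates replicates per tissue x sex cell (default 2).
#' @param seed integer seed; a fixed seed makes all outputs byte-identical.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_genes_per_class = c(autosome = 5000L, Z = 500L,
                                             W = 20L, W_random = 6L,
                                             Un_random = 40L),
                       z_noncompensated_fraction = 1,
                       z_male_ratio = 1.6,
                       w_female_fpkm_range = c(1, 100),
                       dispersion_prior = 0.04,
                       n_dimorphic_autosomal_per_tissue = 50L,
                       dimorphic_fold_change = 2,
                       library_size = 2e6,
                       n_mhm_genes = 3L,
                       un_random_w_fraction = 0.5,
                       w_leaky = FALSE,
                       n_replicates = 2L,
                       seed = 1L) {
  classes <- c("autosome", "Z", "W", "W_random", "Un_random")
  if (!all(classes %in% names(n_genes_per_class)))
    stop("n_genes_per_class must name all of: ",
         paste(classes, collapse = ", "))
  n_genes_per_class <- setNames(as.integer(n_genes_per_class[classes]),
                                classes)
  if (any(n_genes_per_class < 0L)) stop("gene counts must be >= 0")
  if (z_noncompensated_fraction < 0 || z_noncompensated_fraction > 1)
    stop("z_noncompensated_fraction must lie in [0, 1]")
  if (un_random_w_fraction < 0 || un_random_w_fraction > 1)
    stop("un_random_w_fraction must lie in [0, 1]")
  if (z_male_ratio <= 0) stop("z_male_ratio must be > 0")
  if (dimorphic_fold_change <= 0) stop("dimorphic_fold_change must be > 0")
  if (library_size <= 0) stop("library_size must be > 0")
  if (dispersion_prior <= 0) stop("dispersion_prior must be > 0")
  if (length(w_female_fpkm_range) != 2L || any(w_female_fpkm_range <= 0) ||
      diff(w_female_fpkm_range) < 0)
    stop("w_female_fpkm_range must be a positive, increasing interval")
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  structure(list(
    n_genes_per_class = n_genes_per_class,
    z_noncompensated_fraction = z_noncompensated_fraction,
    z_male_ratio = z_male_ratio,
    w_female_fpkm_range = as.numeric(w_female_fpkm_range),
    dispersion_prior = dispersion_prior,
    n_dimorphic_autosomal_per_tissue = as.integer(n_dimorphic_autosomal_per_tissue),
    dimorphic_fold_change = dimorphic_fold_change,
    library_size = library_size,
    n_mhm_genes = as.integer(n_mhm_genes),
    un_random_w_fraction = un_random_w_fraction,
    w_leaky = isTRUE(w_leaky),
    n_replicates = as.integer(n_replicates),
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("ZW synthetic experiment configuration\n")
  cat("  genes: ", paste(sprintf("%s=%d", names(x$n_genes_per_class),
                                 x$n_genes_per_class), collapse = ", "), "\n")
  cat(sprintf("  design: 2 tissues x 2 sexes x %d replicates\n",
              x$n_replicates))
  cat(sprintf("  Z male:female ratio %.2f on %.0f%% of Z genes; %d MHM-like female-only Z genes\n",
              x$z_male_ratio, 100 * x$z_noncompensated_fraction, x$n_mhm_genes))
  cat(sprintf("  dispersion prior %.3f; library size %.3g; seed %d\n",
              x$dispersion_prior, x$library_size, x$seed))
  invisible(x)
}

#' Null (no-dimorphism) configuration
#'
#' All genes autosome-like with no sex or tissue effects; used for type-I
#' error calibration of the dimorphism tests.
#'
#' @param n_genes number of genes.
#' @param ... overrides passed to \code{\link{sim_config}}.
#' @return a \code{sim_config}.
#' @export
sim_config_null <- function(n_genes = 2000L, ...) {
  sim_config(n_genes_per_class = c(autosome = as.integer(n_genes), Z = 0L,
                                   W = 0L, W_random = 0L, Un_random = 0L),
             z_noncompensated_fraction = 0,
             z_male_ratio = 1,
             n_dimorphic_autosomal_per_tissue = 0L,
             dimorphic_fold_change = 1,
             n_mhm_genes = 0L,
             un_random_w_fraction = 0,
             ...)
}
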