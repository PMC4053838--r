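#' Fit the factorial NB dimorphism model and run all likelihood-ratio tests
#'
#' Fits, per gene, a negative-binomial GLM with log link and offsets equal
#' to the log effective library sizes, under the full tissue * sex model
#' and its nested reductions, and performs four 1-df likelihood-ratio
#' tests:
#' \describe{
#'   \item{sex_blastoderm / sex_gonad}{female vs male within each tissue
#'     (the sex contrast of the interaction model).}
#'   \item{ratio_difference}{the tissue x sex interaction — does the
#'     female:male ratio differ between tissues?}
#'   \item{tissue_average}{the tissue main effect with sexes pooled —
#'     does average expression ((male+female)/2) change between tissues?}
#' }
#' P-values are chi-square (1 df); FDR is controlled by Benjamini-Hochberg
#' separately within each named test. Log2 fold changes are computed after
#' adding an offset-scaled pseudo-count of 0.125 so that structural zeros
#' (for example W genes in males) yield finite estimates; positive values
#' mean female-biased (sex tests), more female-biased in gonad
#' (ratio_difference), or higher in gonad (tissue_average).
#'
#' @param experiment a \code{\link{count_experiment}}.
#' @param dispersions optional \code{\link{estimate_dispersions}} result;
#'   estimated if omitted.
#' @param prior_count pseudo-count fraction used only for fold-change
#'   reporting (default 0.125).
#' @return object of class \code{dimorphism_fit}; per-test result tables
#'   are available through \code{\link{dimorphism_results}}.
#' @export
dimorphism_fit <- function(experiment, dispersions = NULL,
                           prior_count = 0.125) {
  stopifnot(inherits(experiment, "count_experiment"))
  if (is.null(dispersions)) dispersions <- estimate_dispersions(experiment)
  designs <- dimorphism_designs(experiment$design)
  eff <- dispersions$effective_lib_sizes
  if (is.null(eff)) eff <- normalize_library_sizes(experiment)$effective_lib_sizes
  offset <- log(eff)
  y <- experiment$counts
  G <- nrow(y)
  phi <- dispersions$tagwise[rownames(y)]
  if (anyNA(phi)) stop("dispersions do not cover all genes")

  dev <- matrix(NA_real_, nrow = G, ncol = length(designs),
                dimnames = list(rownames(y), names(designs)))
  ll_full <- numeric(G)
  for (g in seq_len(G)) {
    for (m in names(designs)) {
      f <- fit_nb_glm(y[g, ], designs[[m]], offset, phi[g])
      dev[g, m] <- f$deviance
      if (m == "full") ll_full[g] <- f$loglik
    }
  }

  stats_tab <- cbind(
    sex_blastoderm = pmax(dev[, "no_sex_blastoderm"] - dev[, "full"], 0),
    sex_gonad = pmax(dev[, "no_sex_gonad"] - dev[, "full"], 0),
    ratio_difference = pmax(dev[, "additive"] - dev[, "full"], 0),
    tissue_average = pmax(dev[, "sex_only"] - dev[, "additive"], 0)
  )
  pvals <- pchisq(stats_tab, df = 1, lower.tail = FALSE)

  # pseudo-count fold changes on the normalised scale
  pseudo <- prior_count * eff / mean(eff)
  yp <- sweep(y, 2, pseudo, "+")
  rate <- sweep(yp, 2, eff, "/")
  des <- experiment$design
  cell_mean <- function(tissue, sex)
    rowMeans(rate[, des$tissue == tissue & des$sex == sex, drop = FALSE])
  fb <- cell_mean("blastoderm", "F"); mb <- cell_mean("blastoderm", "M")
  fg <- cell_mean("gonad", "F"); mg <- cell_mean("gonad", "M")
  lfc_sexb <- log2(fb / mb)
  lfc_sexg <- log2(fg / mg)
  lfc_inter <- lfc_sexg - lfc_sexb
  lfc_tissue <- log2(((fg + mg) / 2) / ((fb + mb) / 2))
  lfc <- cbind(sex_blastoderm = lfc_sexb, sex_gonad = lfc_sexg,
               ratio_difference = lfc_inter, tissue_average = lfc_tissue)

  results <- lapply(colnames(stats_tab), function(test) {
    p <- pvals[, test]
    direction <- switch(test,
      sex_blastoderm = ,
      sex_gonad = ifelse(lfc[, test] > 0, "F", ifelse(lfc[, test] < 0, "M", "none")),
      ratio_difference = ifelse(lfc[, test] > 0, "more_dimorphic_in_gonad",
                         ifelse(lfc[, test] < 0, "more_dimorphic_in_blastoderm",
                                "no_difference")),
      tissue_average = ifelse(lfc[, test] > 0, "higher_in_gonad",
                       ifelse(lfc[, test] < 0, "higher_in_blastoderm",
                              "no_change")))
    data.frame(gene_id = rownames(y), test = test,
               log2fc = unname(lfc[, test]),
               stat = unname(stats_tab[, test]),
               pvalue = unname(p), qvalue = unname(bh_adjust(p)),
               direction = direction,
               stringsAsFactors = FALSE, row.names = NULL)
  })
  names(results) <- colnames(stats_tab)

  structure(list(results = results, dispersions = dispersions,
                 effective_lib_sizes = eff,
                 deviances = dev, loglik_full = ll_full,
                 design = experiment$design,
                 annotation = experiment$annotation),
            class = "dimorphism_fit")
}

#' Extract one test's result table from a dimorphism fit
#'
#' @param fit a \code{\link{dimorphism_fit}}.
#' @param test one of \code{sex_blastoderm}, \code{sex_gonad},
#'   \code{ratio_difference}, \code{tissue_average}.
#' @return data.frame with columns gene_id, test, log2fc, stat, pvalue,
#'   qvalue, direction.
#' @export
dimorphism_results <- function(fit, test = c("sex_blastoderm", "sex_gonad",
                                             "ratio_difference",
                                             "tissue_average")) {
  stopifnot(inherits(fit, "dimorphism_fit"))
  test <- match.arg(test)
  fit$results[[test]]
}

#' @export
print.dimorphism_fit <- function(x, ...) {
  cat(sprintf("NB dimorphism fit: %d genes, %d samples\n",
              nrow(x$deviances), nrow(x$design)))
  for (t in names(x$results)) {
    r <- x$results[[t]]
    cat(sprintf("  %-18s %5d significant at FDR 0.05\n", t,
                sum(r$qvalue < 0.05)))
  }
  invisible(x)
}

#' @export
summary.dimorphism_fit <- function(object, fdr = 0.05, ...) {
  tab <- do.call(rbind, lapply(names(object$results), function(t) {
    r <- object$results[[t]]
    sig <- r$qvalue < fdr
    data.frame(test = t, n_genes = nrow(r), n_significant = sum(sig),
               n_female_biased = if (t %in% c("sex_blastoderm", "sex_gonad"))
                 sum(sig & r$direction == "F") else NA_integer_,
               n_male_biased = if (t %in% c("sex_blastoderm", "sex_gonad"))
                 sum(sig & r$direction == "M") else NA_integer_,
               stringsAsFactors = FALSE)
  }))
  structure(list(table = tab, fdr = fdr, common_dispersion =
                   object$dispersions$common),
            class = "summary.dimorphism_fit")
}

#' @export
print.summary.dimorphism_fit <- function(x, ...) {
  cat(sprintf("Dimorphism test summary (FDR < %g; common dispersion %.4f)\n",
              x$fdr, x$common_dispersion))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
coef.dimorphism_fit <- function(object, ...) {
  sapply(object$results, function(r) setNames(r$log2fc, r$gene_id))
}

#' Mean-difference plot of one dimorphism test
#'
#' @param x a \code{\link{dimorphism_fit}}.
#' @param test which test to plot.
#' @param fdr significance threshold for highlighting.
#' @param ... passed to \code{plot}.
#' @importFrom graphics abline legend points
#' @export
plot.dimorphism_fit <- function(x, test = "sex_blastoderm", fdr = 0.05, ...) {
  r <- dimorphism_results(x, test)
  sig <- r$qvalue < fdr
  plot(r$stat, r$log2fc, pch = 16, cex = 0.4,
       col = ifelse(sig, "red", "grey50"),
       xlab = "LRT statistic", ylab = "log2 fold change",
       main = test, ...)
  abline(h = 0, lty = 2)
  legend("topright", legend = c(sprintf("FDR < %g", fdr), "ns"),
         col = c("red", "grey50"), pch = 16, bty = "n")
  invisible(x)
}

#' Test sexual dimorphism within one tissue
#'
#' Convenience wrappers running the factorial NB fit and returning the
#' requested likelihood-ratio test table.
#'
#' @param experiment a \code{\link{count_experiment}}.
#' @param dispersions optional \code{dispersion_estimates}.
#' @param tissue \code{blastoderm} or \code{gonad}.
#' @return result data.frame (see \code{\link{dimorphism_results}}).
#' @export
test_sex_within_tissue <- function(experiment, dispersions = NULL,
                                   tissue = c("blastoderm", "gonad")) {
  tissue <- match.arg(tissue)
  fit <- dimorphism_fit(experiment, dispersions)
  dimorphism_results(fit, paste0("sex_", tissue))
}

#' @rdname test_sex_within_tissue
#' @export
test_ratio_difference <- function(experiment, dispersions = NULL) {
  fit <- dimorphism_fit(experiment, dispersions)
  dimorphism_results(fit, "ratio_difference")
}

#' @rdname test_sex_within_tissue
#' @export
test_tissue_average <- function(experiment, dispersions = NULL) {
  fit <- dimorphism_fit(experiment, dispersions)
  dimorphism_results(fit, "tissue_average")
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with enforced monotonicity
#' (delegates to \code{stats::p.adjust}).
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}
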