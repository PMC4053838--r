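#' Chromosome-class tallies of dimorphic genes
#'
#' Cross-tabulates significant genes (q below \code{fdr}) by chromosome
#' class and bias direction for each within-tissue sex test, and assigns
#' every dimorphic gene an inter-tissue pattern (from the ratio-difference
#' test: more dimorphic in blastoderm / gonad / no difference) and an
#' expression-level pattern (from the tissue-average test: higher in
#' blastoderm / gonad / no change).
#'
#' @param fit a \code{\link{dimorphism_fit}}.
#' @param annotation annotation data.frame (gene_id, class); taken from the
#'   fit if omitted.
#' @param fdr significance threshold.
#' @return object of class \code{class_tally}: list with \code{sex_bias}
#'   (per test: class x direction counts and percentages),
#'   \code{inter_tissue} and \code{expression_level} pattern counts over
#'   the union of dimorphic genes, \code{dimorphic_genes}, and
#'   \code{unannotated} (gene ids lacking annotation, excluded).
#' @export
classify_tallies <- function(fit, annotation = NULL, fdr = 0.05) {
  stopifnot(inherits(fit, "dimorphism_fit"))
  if (is.null(annotation)) annotation <- fit$annotation
  sex_tests <- c("sex_blastoderm", "sex_gonad")
  classes <- c("autosome", "Z", "W", "W_random", "Un_random")

  sex_bias <- lapply(sex_tests, function(t) {
    r <- dimorphism_results(fit, t)
    sig <- r[r$qvalue < fdr, , drop = FALSE]
    cls <- annotation$class[match(sig$gene_id, annotation$gene_id)]
    keep <- !is.na(cls)
    tab <- table(factor(cls[keep], levels = classes),
                 factor(sig$direction[keep], levels = c("F", "M")))
    pct <- if (sum(tab) > 0) 100 * prop.table(tab, margin = 2) else tab
    list(counts = tab, percent_of_direction = pct,
         n_significant = nrow(sig))
  })
  names(sex_bias) <- sex_tests

  rb <- dimorphism_results(fit, "sex_blastoderm")
  rg <- dimorphism_results(fit, "sex_gonad")
  dimorphic <- union(rb$gene_id[rb$qvalue < fdr], rg$gene_id[rg$qvalue < fdr])
  unannot <- setdiff(dimorphic, annotation$gene_id)
  if (length(unannot))
    warning(length(unannot), " dimorphic gene(s) lack annotation; excluded")
  dimorphic <- setdiff(dimorphic, unannot)

  rd <- dimorphism_results(fit, "ratio_difference")
  rd <- rd[match(dimorphic, rd$gene_id), ]
  inter <- ifelse(rd$qvalue < fdr, rd$direction, "no_difference")
  inter <- table(factor(inter, levels = c("more_dimorphic_in_blastoderm",
                                          "more_dimorphic_in_gonad",
                                          "no_difference")))

  rt <- dimorphism_results(fit, "tissue_average")
  rt <- rt[match(dimorphic, rt$gene_id), ]
  lev <- ifelse(rt$qvalue < fdr, rt$direction, "no_change")
  lev <- table(factor(lev, levels = c("higher_in_blastoderm",
                                      "higher_in_gonad", "no_change")))

  structure(list(sex_bias = sex_bias, inter_tissue = inter,
                 expression_level = lev, dimorphic_genes = dimorphic,
                 unannotated = unannot, fdr = fdr),
            class = "class_tally")
}

#' @export
print.class_tally <- function(x, ...) {
  cat(sprintf("Chromosome-class tallies (FDR < %g)\n", x$fdr))
  for (t in names(x$sex_bias)) {
    cat(sprintf("  %s: %d significant genes\n", t,
                x$sex_bias[[t]]$n_significant))
    print(x$sex_bias[[t]]$counts)
  }
  cat("  inter-tissue pattern over", length(x$dimorphic_genes),
      "dimorphic genes:\n")
  print(x$inter_tissue)
  cat("  expression-level pattern:\n")
  print(x$expression_level)
  invisible(x)
}

#' Fisher enrichment of a curated gene list among significant genes
#'
#' Two-sided Fisher's exact test on the 2x2 table of membership in the
#' significant set against membership in an annotated list, over a stated
#' gene universe.
#'
#' @param significant_genes character vector of significant gene ids.
#' @param annotated_list curated list (must be a subset of the universe).
#' @param universe all tested gene ids.
#' @return list with \code{odds_ratio}, \code{p_value}, \code{table}.
#' @export
enrichment_fisher <- function(significant_genes, annotated_list, universe) {
  if (!length(universe)) stop("empty gene universe")
  if (!all(annotated_list %in% universe))
    stop("annotated_list must be a subset of the universe")
  significant_genes <- intersect(significant_genes, universe)
  in_sig <- universe %in% significant_genes
  in_list <- universe %in% annotated_list
  tab <- table(significant = factor(in_sig, levels = c(TRUE, FALSE)),
               in_list = factor(in_list, levels = c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}
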