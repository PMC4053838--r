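#' Load the W-chromosome gene catalog
#'
#' Reads and validates a TSV catalog of W-linked genes: symbol,
#' description, genomic location class(es), female FPKM in blastoderm and
#' gonad, DNA/protein identity with the Z gametologue, dN/dS, and flags
#' (small RNA, novel, lacks a Z gametologue). The packaged catalog
#' compiles the embryonic chicken W transcriptome: 26 protein-coding genes
#' and 5 intronic small RNAs, with a single gene (FAF) lacking any Z
#' gametologue.
#'
#' @param path TSV path; defaults to the packaged catalog.
#' @return data.frame of class \code{w_catalog}.
#' @export
load_w_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "w_catalog.tsv", package = "wseq",
                        mustWork = TRUE)
  required <- c("symbol", "description", "location",
                "fpkm_blastoderm_female", "fpkm_gonad_female",
                "dna_identity", "protein_identity", "dnds",
                "is_small_rna", "is_novel", "lacks_z_gametologue")
  header <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  if (length(header) == 0L || all(header == "")) {
    warning("empty catalog file")
    out <- as.data.frame(setNames(rep(list(logical(0)), length(required)),
                                  required))
    class(out) <- c("w_catalog", class(out))
    return(out)
  }
  if (!identical(header, required))
    stop("catalog header does not match the expected schema; expected: ",
         paste(required, collapse = ", "))
  cat_df <- read.delim(path, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cat_df))) {
    row <- cat_df[i, ]
    if (is.na(row$symbol) || row$symbol == "")
      stop("malformed row at line ", i + 1L, ": missing symbol")
    for (fl in c("is_small_rna", "is_novel", "lacks_z_gametologue"))
      if (!is.logical(cat_df[[fl]]) || is.na(row[[fl]]))
        stop("malformed row at line ", i + 1L, ": flag ", fl,
             " must be TRUE/FALSE")
    if (row$is_small_rna && !is.na(row$dnds))
      stop("malformed row at line ", i + 1L,
           ": small-RNA entries cannot carry dN/dS")
  }
  if (anyDuplicated(cat_df$symbol))
    stop("duplicate symbols in catalog")
  if (sum(cat_df$lacks_z_gametologue) != 1L)
    stop("exactly one catalog entry must lack a Z gametologue")
  class(cat_df) <- c("w_catalog", class(cat_df))
  cat_df
}

#' @export
print.w_catalog <- function(x, ...) {
  cat(sprintf("W gene catalog: %d entries (%d protein-coding, %d small RNAs)\n",
              nrow(x), sum(!x$is_small_rna), sum(x$is_small_rna)))
  coding <- x[!x$is_small_rna & !is.na(x$dna_identity), ]
  if (nrow(coding))
    cat(sprintf("  mean W/Z identity: DNA %.1f%%, protein %.1f%%\n",
                mean(coding$dna_identity),
                mean(coding$protein_identity, na.rm = TRUE)))
  if (any(x$lacks_z_gametologue))
    cat("  no Z gametologue:",
        paste(x$symbol[x$lacks_z_gametologue], collapse = ", "), "\n")
  invisible(x)
}
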