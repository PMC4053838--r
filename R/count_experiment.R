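#' Container for a factorial count experiment
#'
#' Bundles a genes x samples matrix of non-negative integer counts with its
#' sample design (tissue, sex, replicate), raw library sizes and a gene
#' annotation table (chromosome class and length).
#'
#' @param counts integer matrix, genes x samples, with row and column names.
#' @param design data.frame with columns \code{sample}, \code{tissue}
#'   (\code{blastoderm}/\code{gonad}), \code{sex} (\code{F}/\code{M}) and
#'   \code{replicate}; one row per column of \code{counts}.
#' @param lib_sizes positive numeric vector of raw library sizes, one per
#'   sample; defaults to the column sums.
#' @param annotation data.frame with columns \code{gene_id}, \code{class}
#'   (one of autosome, Z, W, W_random, Un_random) and \code{length} (bp);
#'   one row per row of \code{counts}.
#' @return object of class \code{count_experiment}.
#' @export
count_experiment <- function(counts, design, lib_sizes = colSums(counts),
                             annotation) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have row (gene) and column (sample) names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"
  req <- c("sample", "tissue", "sex", "replicate")
  if (!all(req %in% names(design)))
    stop("design must have columns: ", paste(req, collapse = ", "))
  design <- design[match(colnames(counts), design$sample), , drop = FALSE]
  if (anyNA(design$sample)) stop("design does not cover all samples")
  if (anyNA(design$tissue) || anyNA(design$sex))
    stop("every sample needs a tissue and a sex")
  design$tissue <- factor(design$tissue, levels = c("blastoderm", "gonad"))
  design$sex <- factor(design$sex, levels = c("M", "F"))
  if (anyNA(design$tissue) || anyNA(design$sex))
    stop("tissue must be blastoderm/gonad and sex must be F/M")
  if (length(lib_sizes) != ncol(counts) || any(lib_sizes <= 0))
    stop("lib_sizes must be positive, one per sample")
  annotation <- annotation[match(rownames(counts), annotation$gene_id), ,
                           drop = FALSE]
  if (anyNA(annotation$gene_id)) stop("annotation does not cover all genes")
  if (any(annotation$length <= 0)) stop("gene lengths must be > 0")
  structure(list(counts = counts, design = design,
                 lib_sizes = setNames(as.numeric(lib_sizes), colnames(counts)),
                 annotation = annotation),
            class = "count_experiment")
}

#' @export
print.count_experiment <- function(x, ...) {
  cat(sprintf("count_experiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(x$design$tissue, x$design$sex)
  cat("  design:\n")
  print(tab)
  cat("  classes: ", paste(sprintf("%s=%d", names(table(x$annotation$class)),
                                   table(x$annotation$class)), collapse = ", "),
      "\n")
  invisible(x)
}

#' @export
dim.count_experiment <- function(x) dim(x$counts)

#' Write / read a count experiment as TSV files
#'
#' Counts are written as a gene_id column plus one column per sample
#' (sample names TISSUE_SEX_REP); the design and annotation go to separate
#' TSVs alongside.
#'
#' @param x a \code{count_experiment}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return (write) the directory, invisibly; (read) a
#'   \code{count_experiment}.
#' @export
write_count_experiment <- function(x, dir, prefix = "experiment") {
  stopifnot(inherits(x, "count_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cts <- data.frame(gene_id = rownames(x$counts), x$counts,
                    check.names = FALSE)
  write.table(cts, file.path(dir, paste0(prefix, "_counts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  des <- x$design
  des$lib_size <- x$lib_sizes[des$sample]
  write.table(des, file.path(dir, paste0(prefix, "_design.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(x$annotation, file.path(dir, paste0(prefix, "_annotation.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' @rdname write_count_experiment
#' @export
read_count_experiment <- function(dir, prefix = "experiment") {
  cts <- read.delim(file.path(dir, paste0(prefix, "_counts.tsv")),
                    check.names = FALSE)
  des <- read.delim(file.path(dir, paste0(prefix, "_design.tsv")))
  ann <- read.delim(file.path(dir, paste0(prefix, "_annotation.tsv")))
  m <- as.matrix(cts[, -1, drop = FALSE])
  rownames(m) <- cts$gene_id
  count_experiment(m, des, lib_sizes = des$lib_size[match(colnames(m),
                                                          des$sample)],
                   annotation = ann)
}
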