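#' @importFrom stats dnbinom optimize rnbinom rlnorm runif rpois rbinom
#'   setNames p.adjust fisher.test pchisq quantile sd median coef
#' @importFrom utils read.delim write.table head tail
NULL

# Deterministic per-stage seed derivation: a single pipeline seed is combined
# with the stage name so that stages are reproducible independently of
# execution order. Kept below 2^31 (R integers are 32-bit).
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) + h * 131071) %% (.Machine$integer.max - 1) + 1)
}

DNA_BASES <- c("A", "C", "G", "T")

is_valid_dna <- function(x) {
  all(grepl("^[ACGTN]+$", x))
}

#' Reverse-complement DNA sequences
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Codon -> amino acid lookup (standard code); "*" marks stops.
codon_table <- function() {
  as.list(Biostrings::GENETIC_CODE)
}

split_codons <- function(seq) {
  n <- nchar(seq)
  stopifnot(n %% 3L == 0L)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Translate a coding sequence
#'
#' Standard genetic code; codons containing N translate to \code{X};
#' stop codons translate to \code{*}.
#'
#' @param cds a single DNA string with length divisible by 3.
#' @return single-character protein string.
#' @export
translate_cds <- function(cds) {
  stopifnot(is.character(cds), length(cds) == 1L)
  gc <- Biostrings::GENETIC_CODE
  codons <- split_codons(toupper(cds))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_internal_stop <- function(cds) {
  prot <- translate_cds(cds)
  body <- substr(prot, 1L, nchar(prot) - 1L)
  grepl("*", body, fixed = TRUE)
}

#' Read sequences from a FASTA file
#'
#' Sequences are normalised to upper case on read.
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' Write sequences to a FASTA file
#'
#' @param x named character vector of sequences.
#' @param path output path.
#' @param width line width (default 60 columns).
#' @export
write_fasta <- function(x, path, width = 60L) {
  stopifnot(is.character(x), !is.null(names(x)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(x), filepath = path,
                              width = width)
  invisible(path)
}

trimmed_mean <- function(x, trim = 0.05) {
  mean(x, trim = trim)
}
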