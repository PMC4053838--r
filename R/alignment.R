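# Pairwise alignment wrappers. Scoring follows the package-wide defaults:
# DNA match +2 / mismatch -3, gap open 5 / extend 2; protein BLOSUM62,
# gap open 11 / extend 1.

AA_ALPHABET20 <- "ACDEFGHIKLMNPQRSTVWYX"

is_valid_protein <- function(x) {
  all(grepl(paste0("^[", AA_ALPHABET20, "]+$"), x))
}

dna_submat <- function(match = 2, mismatch = -3) {
  Biostrings::nucleotideSubstitutionMatrix(match = match, mismatch = mismatch,
                                           baseOnly = FALSE)
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

align_dna <- function(a, b, type = "local", gap_open = 5, gap_extend = 2) {
  Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = type,
    substitutionMatrix = dna_submat(),
    gapOpening = gap_open, gapExtension = gap_extend)
}

align_protein <- function(a, b, type = "local", gap_open = 11,
                          gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = type,
    substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend)
}

# local-alignment scores of one query protein against a whole panel
# (single vectorised pairwiseAlignment call)
panel_scores <- function(query, panel, gap_open = 11, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(unname(panel)), Biostrings::AAString(query),
    type = "local", substitutionMatrix = blosum62(),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE)
}

# identity over aligned columns where neither sequence is gapped, percent
alignment_identity <- function(aln) {
  m <- Biostrings::nmatch(aln)
  mm <- Biostrings::nmismatch(aln)
  if (m + mm == 0) return(0)
  100 * m / (m + mm)
}

#' Global (end-gap-free) alignment identity
#'
#' Aligns two sequences globally with free terminal gaps and reports the
#' percent identity over aligned columns where neither sequence has a gap
#' (terminal overhangs are excluded). DNA scoring is +2/-3 with gap open 5
#' and extension 2; protein scoring uses BLOSUM62 with gap open 11 and
#' extension 1.
#'
#' @param seq_a,seq_b sequences (single strings).
#' @param alphabet \code{"dna"} or \code{"protein"}.
#' @return identity percentage in [0, 100].
#' @export
global_align_identity <- function(seq_a, seq_b,
                                  alphabet = c("dna", "protein")) {
  alphabet <- match.arg(alphabet)
  stopifnot(nchar(seq_a) > 0, nchar(seq_b) > 0)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (alphabet == "dna") {
    if (!is_valid_dna(c(seq_a, seq_b)))
      stop("sequences contain characters outside ACGTN")
    aln <- align_dna(seq_a, seq_b, type = "overlap")
  } else {
    if (!is_valid_protein(c(seq_a, seq_b)))
      stop("sequences contain non-amino-acid characters")
    aln <- align_protein(seq_a, seq_b, type = "overlap")
  }
  alignment_identity(aln)
}

#' Karlin-Altschul e-value for a local protein alignment score
#'
#' Converts a raw local alignment score to a bit score
#' \eqn{S' = (\lambda S - \ln K)/\ln 2} and an expectation value
#' \eqn{E = m n \, 2^{-S'}} for sequence lengths m and n. Default
#' parameters are the fixed BLOSUM62 constants \eqn{\lambda = 0.267},
#' \eqn{K = 0.041}.
#'
#' @param score raw alignment score.
#' @param m,n lengths of the two sequences.
#' @param lambda,K Karlin-Altschul parameters.
#' @return list with \code{bits} and \code{evalue}.
#' @export
karlin_altschul_evalue <- function(score, m, n, lambda = 0.267, K = 0.041) {
  bits <- (lambda * score - log(K)) / log(2)
  list(bits = bits, evalue = m * n * 2^(-bits))
}
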