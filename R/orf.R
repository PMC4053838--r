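#' Six-frame open reading frame scan
#'
#' Finds all maximal ATG-to-stop spans in all six reading frames with a
#' protein length of at least \code{min_aa}. "Maximal" means the span from
#' the first ATG of each stop-delimited segment; a trailing ORF without a
#' stop codon is included if it runs to the end of the sequence.
#' Coordinates are 0-based half-open on the input transcript and exclude
#' the stop codon; for minus frames they refer to the plus strand (frame
#' -1 is frame +1 of the reverse complement).
#'
#' @param sequence a single DNA string (A/C/G/T/N).
#' @param min_aa minimum protein length in amino acids (default 30).
#' @return data.frame with columns \code{frame} (+1..+3, -1..-3),
#'   \code{start}, \code{end}, \code{protein}, ordered by frame then start.
#' @export
find_orfs <- function(sequence, min_aa = 30L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (!is_valid_dna(sequence))
    stop("sequence contains characters outside ACGTN")
  if (min_aa < 1L) stop("min_aa must be >= 1")
  L <- nchar(sequence)
  out <- list()
  for (strand in c(1L, -1L)) {
    s <- if (strand == 1L) sequence else revcomp(sequence)
    for (off in 0:2) {
      n_cod <- (L - off) %/% 3L
      if (n_cod < 1L) next
      cod <- substring(s, off + 1L + 3L * (seq_len(n_cod) - 1L),
                       off + 3L * seq_len(n_cod))
      aa <- unname(Biostrings::GENETIC_CODE[cod])
      aa[is.na(aa)] <- "X"
      is_stop <- aa == "*"
      is_atg <- cod == "ATG"
      seg_start <- 1L
      i <- 1L
      while (i <= n_cod) {
        if (is_stop[i] || i == n_cod) {
          seg_end <- if (is_stop[i]) i - 1L else i  # last coding codon
          atg <- which(is_atg[seg_start:seg_end])
          if (length(atg)) {
            a <- seg_start + atg[1L] - 1L
            n_aa <- seg_end - a + 1L
            if (n_aa >= min_aa) {
              start_s <- off + 3L * (a - 1L)        # 0-based on strand s
              end_s <- off + 3L * seg_end
              if (strand == 1L) {
                start <- start_s; end <- end_s
              } else {
                start <- L - end_s; end <- L - start_s
              }
              out[[length(out) + 1L]] <- data.frame(
                frame = strand * (off + 1L), start = start, end = end,
                protein = paste(aa[a:seg_end], collapse = ""),
                stringsAsFactors = FALSE)
            }
          }
          seg_start <- i + 1L
        }
        i <- i + 1L
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$frame, res$start), , drop = FALSE]
}
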