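#' Random coding sequence
#'
#' ATG start, random stop-free codons, optional terminal stop codon.
#'
#' @param n_codons number of codons including the start (and excluding the
#'   terminal stop).
#' @param terminal_stop append a TAA stop codon?
#' @param seed optional integer seed.
#' @return a single DNA string.
#' @export
random_cds <- function(n_codons, terminal_stop = TRUE, seed = NULL) {
  stopifnot(n_codons >= 2)
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  body <- sample(sense, n_codons - 1L, replace = TRUE)
  paste0("ATG", paste(body, collapse = ""),
         if (terminal_stop) "TAA" else "")
}

#' Evolve a W gametologue from a Z coding sequence
#'
#' Applies codon substitutions under an omega-acceptance scheme: proposals
#' are uniform single-nucleotide changes; synonymous changes are accepted
#' with probability 1, nonsynonymous changes with probability \code{omega};
#' changes creating stop codons are always rejected, so the reading frame
#' and stop-free property are preserved. The number of accepted
#' substitutions is Poisson with mean
#' \code{expected_subs_per_codon * n_codons}.
#'
#' @param z_cds coding sequence, length divisible by 3, no internal stops.
#' @param omega relative acceptance probability of nonsynonymous changes.
#' @param expected_subs_per_codon expected accepted substitutions per codon.
#' @param seed optional integer seed.
#' @return list with \code{w_cds}, \code{z_cds} and \code{n_substitutions}.
#' @export
simulate_gametologue_pair <- function(z_cds, omega = 0.2,
                                      expected_subs_per_codon = 0.3,
                                      seed = NULL) {
  stopifnot(is.character(z_cds), length(z_cds) == 1L)
  z_cds <- toupper(z_cds)
  if (nchar(z_cds) %% 3L != 0L) stop("z_cds length must be divisible by 3")
  if (has_internal_stop(z_cds)) stop("z_cds contains an internal stop codon")
  if (omega < 0) stop("omega must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  gc <- Biostrings::GENETIC_CODE
  w <- strsplit(z_cds, "")[[1]]
  n_codons <- length(w) %/% 3L
  # the start codon and a terminal stop are kept intact: both are under
  # absolute constraint in expressed gametologues, and mutating the stop
  # would unbalance the pair's reading frames
  mutable <- seq_along(w)
  last_cod <- substr(z_cds, nchar(z_cds) - 2L, nchar(z_cds))
  if (identical(unname(gc[last_cod]), "*"))
    mutable <- mutable[seq_len(length(w) - 3L)]
  if (startsWith(z_cds, "ATG")) mutable <- setdiff(mutable, 1:3)
  target <- rpois(1L, expected_subs_per_codon * n_codons)
  accepted <- 0L
  tries <- 0L
  max_tries <- 1000L * (target + 10L)
  while (accepted < target && tries < max_tries) {
    tries <- tries + 1L
    pos <- sample(mutable, 1L)
    base <- sample(setdiff(DNA_BASES, w[pos]), 1L)
    ci <- (pos - 1L) %/% 3L
    old_codon <- paste(w[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    new <- w
    new[pos] <- base
    new_codon <- paste(new[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
    if (gc[new_codon] == "*") next
    syn <- gc[new_codon] == gc[old_codon]
    if (syn || runif(1L) < omega) {
      w <- new
      accepted <- accepted + 1L
    }
  }
  list(w_cds = paste(w, collapse = ""), z_cds = z_cds,
       n_substitutions = accepted)
}

#' Fragment a transcript into overlapping source-labelled pieces
#'
#' Splits a transcript into \code{n_fragments} tiling pieces. Adjacent
#' pieces overlap by at least \code{min_overlap} bases except that, with
#' probability \code{orphan_prob} per junction, the overlap is replaced by
#' a short uncovered gap (5-30 bp). A random subset of fragments (never a
#' lone complete fragment) is reverse-complemented, and each fragment gets
#' a fake source label (annotation / genome-guided / de-novo) and
#' pseudo-chromosome (W_random / Un_random / autosome).
#'
#' @param transcript DNA string.
#' @param n_fragments number of pieces (>= 1).
#' @param min_overlap minimum junction overlap in bp.
#' @param orphan_prob per-junction probability of a coverage gap.
#' @param seed optional integer seed.
#' @param id_prefix prefix for fragment ids.
#' @return data.frame of class \code{fragment_set}: columns \code{id},
#'   \code{sequence}, \code{source}, \code{chrom}, and the generative truth
#'   \code{true_start}, \code{true_end} (0-based half-open on the
#'   transcript) and \code{orientation}; attribute \code{junctions} records
#'   each junction's position and type (overlap/gap).
#' @export
fragmentize <- function(transcript, n_fragments, min_overlap = 60L,
                        orphan_prob = 0, seed = NULL, id_prefix = "frag") {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  transcript <- toupper(transcript)
  if (!is_valid_dna(transcript)) stop("transcript must be ACGTN")
  L <- nchar(transcript)
  n_fragments <- as.integer(n_fragments)
  if (n_fragments < 1L) stop("n_fragments must be >= 1")
  if (n_fragments * min_overlap > L)
    stop("n_fragments x min_overlap exceeds the transcript length")
  if (!is.null(seed)) set.seed(seed)

  if (n_fragments == 1L) {
    out <- data.frame(id = paste0(id_prefix, "_1"), sequence = transcript,
                      source = "annotation", chrom = "W_random",
                      true_start = 0L, true_end = L, orientation = "+",
                      stringsAsFactors = FALSE)
    attr(out, "junctions") <- data.frame(position = integer(),
                                         type = character())
    class(out) <- c("fragment_set", class(out))
    return(out)
  }

  # jittered equal-spaced junction points
  breaks <- round(L * seq_len(n_fragments - 1L) / n_fragments +
                  runif(n_fragments - 1L, -L / (4 * n_fragments),
                        L / (4 * n_fragments)))
  breaks <- sort(pmin(pmax(breaks, 3L), L - 3L))
  for (i in seq_len(n_fragments - 1L)[-1])
    if (breaks[i] <= breaks[i - 1L]) breaks[i] <- breaks[i - 1L] + 1L

  starts <- integer(n_fragments); ends <- integer(n_fragments)
  starts[1L] <- 0L; ends[n_fragments] <- L
  jtype <- character(n_fragments - 1L)
  for (i in seq_len(n_fragments - 1L)) {
    ends[i] <- breaks[i]
    gap_case <- runif(1L) < orphan_prob
    if (gap_case) {
      g <- sample(5:30, 1L)
      starts[i + 1L] <- min(breaks[i] + g, L - 1L)
      jtype[i] <- "gap"
    } else {
      ov <- min_overlap + sample.int(max(min_overlap %/% 2L, 1L), 1L) - 1L
      starts[i + 1L] <- max(breaks[i] - ov, 0L)
      jtype[i] <- "overlap"
    }
  }
  # guard monotone, non-empty fragments
  for (i in seq_len(n_fragments - 1L))
    if (starts[i + 1L] <= starts[i]) starts[i + 1L] <- starts[i] + 1L
  ends <- pmax(ends, starts + 1L)

  seqs <- substring(transcript, starts + 1L, ends)
  orientation <- ifelse(runif(n_fragments) < 0.5, "+", "-")
  seqs[orientation == "-"] <- revcomp(seqs[orientation == "-"])
  sources <- sample(c("annotation", "genome-guided", "de-novo"),
                    n_fragments, replace = TRUE)
  chroms <- sample(c("W_random", "Un_random", "autosome"),
                   n_fragments, replace = TRUE)
  out <- data.frame(id = sprintf("%s_%d", id_prefix, seq_len(n_fragments)),
                    sequence = seqs, source = sources, chrom = chroms,
                    true_start = starts, true_end = ends,
                    orientation = orientation, stringsAsFactors = FALSE)
  attr(out, "junctions") <- data.frame(position = breaks, type = jtype,
                                       stringsAsFactors = FALSE)
  class(out) <- c("fragment_set", class(out))
  out
}

#' Generate retroviral decoy transcripts
#'
#' Back-translates proteins from a panel (gag/pol-like toy proteins ship
#' with the package) into open reading frames with up to
#' \code{codon_noise} codon-level noise (random non-stop codon
#' replacements, start codon preserved), embedded between random UTRs.
#' Used to exercise the retroviral homology filter.
#'
#' @param n number of decoys.
#' @param protein_panel named character vector of panel proteins; defaults
#'   to the packaged synthetic panel.
#' @param codon_noise per-codon replacement probability (<= 0.10).
#' @param seed optional integer seed.
#' @return named character vector of decoy transcripts with attribute
#'   \code{panel_source}.
#' @export
make_retroviral_decoys <- function(n, protein_panel = NULL, codon_noise = 0.1,
                                   seed = NULL) {
  if (is.null(protein_panel)) protein_panel <- load_retro_panel()
  if (!length(protein_panel)) stop("protein panel must be non-empty")
  if (!is_valid_protein(protein_panel))
    stop("panel entries contain non-amino-acid characters")
  if (codon_noise < 0 || codon_noise > 0.10)
    stop("codon_noise must lie in [0, 0.10]")
  if (!is.null(seed)) set.seed(seed)
  if (n == 0L) return(setNames(character(0), character(0)))
  gc <- Biostrings::GENETIC_CODE
  codons_for <- split(names(gc), gc)
  sense <- names(gc)[gc != "*"]
  src <- sample(names(protein_panel), n, replace = TRUE)
  decoys <- vapply(seq_len(n), function(i) {
    aa <- strsplit(protein_panel[[src[i]]], "")[[1]]
    cod <- vapply(aa, function(a) sample(codons_for[[a]], 1L), character(1))
    if (codon_noise > 0 && length(cod) > 1L) {
      flip <- which(runif(length(cod) - 1L) < codon_noise) + 1L
      cod[flip] <- sample(sense, length(flip), replace = TRUE)
    }
    utr5 <- paste(sample(DNA_BASES, sample(30:120, 1L), replace = TRUE),
                  collapse = "")
    utr3 <- paste(sample(DNA_BASES, sample(30:120, 1L), replace = TRUE),
                  collapse = "")
    paste0(utr5, paste(cod, collapse = ""), "TAA", utr3)
  }, character(1))
  names(decoys) <- sprintf("decoy_%03d", seq_len(n))
  attr(decoys, "panel_source") <- setNames(src, names(decoys))
  decoys
}

#' Load the packaged synthetic retroviral protein panel
#'
#' A small set of synthetic gag/pol-like toy proteins (not real viral
#' sequences) used as the homology target of the retroviral filter.
#'
#' @return named character vector of proteins.
#' @export
load_retro_panel <- function() {
  read_fasta(system.file("extdata", "retro_panel_synthetic.fa",
                         package = "wseq", mustWork = TRUE))
}
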