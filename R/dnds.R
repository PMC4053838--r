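# Nei-Gojobori counting estimator of synonymous and nonsynonymous
# divergence with Jukes-Cantor correction, plus codon alignment and
# sliding-window profiles.

# synonymous site count of each sense codon: sum over the three codon
# positions of the fraction of possible changes at that position that are
# synonymous (equivalently, synonymous single-nucleotide changes / 3);
# changes creating stops count as nonsynonymous
codon_syn_fraction <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    sense <- names(gc)[gc != "*"]
    out <- setNames(numeric(length(sense)), sense)
    for (cod in sense) {
      ch <- strsplit(cod, "")[[1]]
      syn <- 0
      for (pos in 1:3) for (b in setdiff(DNA_BASES, ch[pos])) {
        alt <- ch; alt[pos] <- b
        alt <- paste(alt, collapse = "")
        if (gc[alt] != "*" && gc[alt] == gc[cod]) syn <- syn + 1
      }
      out[cod] <- syn / 3
    }
    cache <<- out
    out
  }
})

# average synonymous / nonsynonymous step counts over all equally-weighted
# minimal mutational pathways between two codons; pathways through stop
# codons are excluded (all-paths fallback if every path is blocked)
codon_path_counts <- function(c1, c2) {
  gc <- Biostrings::GENETIC_CODE
  ch1 <- strsplit(c1, "")[[1]]; ch2 <- strsplit(c2, "")[[1]]
  diff_pos <- which(ch1 != ch2)
  nd <- length(diff_pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  perms <- switch(nd,
                  `1` = list(diff_pos),
                  `2` = list(diff_pos, rev(diff_pos)),
                  `3` = {
                    p <- diff_pos
                    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
                         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
                  })
  walk <- function(order_pos, allow_stops) {
    cur <- ch1
    sd <- 0; ndn <- 0
    for (pos in order_pos) {
      nxt <- cur; nxt[pos] <- ch2[pos]
      aa_cur <- gc[paste(cur, collapse = "")]
      aa_nxt <- gc[paste(nxt, collapse = "")]
      if (aa_nxt == "*" && !allow_stops) return(NULL)
      if (aa_cur == aa_nxt && aa_nxt != "*") sd <- sd + 1 else ndn <- ndn + 1
      cur <- nxt
    }
    c(sd = sd, nd = ndn)
  }
  res <- Filter(Negate(is.null), lapply(perms, walk, allow_stops = FALSE))
  if (!length(res)) res <- lapply(perms, walk, allow_stops = TRUE)
  cnt <- Reduce(`+`, res) / length(res)
  cnt
}

validate_cds_pair <- function(w_cds, z_cds) {
  w_cds <- toupper(w_cds); z_cds <- toupper(z_cds)
  if (nchar(w_cds) != nchar(z_cds))
    stop("sequences must be codon-aligned to equal length")
  if (nchar(w_cds) %% 3L != 0L)
    stop("sequence length must be divisible by 3")
  if (grepl("-", paste0(w_cds, z_cds), fixed = TRUE))
    stop("gapped codons must be removed before dN/dS estimation")
  # drop a shared terminal stop codon
  gc <- Biostrings::GENETIC_CODE
  last_w <- substr(w_cds, nchar(w_cds) - 2L, nchar(w_cds))
  last_z <- substr(z_cds, nchar(z_cds) - 2L, nchar(z_cds))
  if (identical(unname(gc[last_w]), "*") && identical(unname(gc[last_z]), "*")) {
    w_cds <- substr(w_cds, 1L, nchar(w_cds) - 3L)
    z_cds <- substr(z_cds, 1L, nchar(z_cds) - 3L)
  }
  if (has_internal_stop(paste0(w_cds, "TAA")) ||
      has_internal_stop(paste0(z_cds, "TAA")))
    stop("internal stop codon in coding sequence")
  list(w = w_cds, z = z_cds)
}

#' Nei-Gojobori dN/dS between two codon-aligned coding sequences
#'
#' Counts synonymous (S) and nonsynonymous (N = 3 x codons - S) sites as
#' the per-codon fraction of single-nucleotide changes that are
#' synonymous, averaged over the two sequences; partitions observed
#' differences into synonymous (Sd) and nonsynonymous (Nd) counts by
#' averaging over all equally-weighted minimal mutational pathways
#' (pathways through stop codons excluded); applies the Jukes-Cantor
#' multiple-hit correction \eqn{d = -\frac{3}{4}\ln(1 - \frac{4}{3}p)}.
#'
#' Sentinel conventions: dN = 0 is reported as omega 0 (status
#' \code{ZERO}); dS = 0 with dN > 0 gives omega NA (status
#' \code{UNDEFINED}); ps or pn at or above 3/4 makes the correction
#' impossible (status \code{SATURATED}, omega NA).
#'
#' @param w_cds,z_cds equal-length, gap-free, codon-aligned CDS pair (a
#'   shared terminal stop codon is dropped). See \code{\link{codon_align}}.
#' @return object of class \code{dnds_estimate}: list with S, N, Sd, Nd,
#'   ps, pn, dS, dN, omega and status.
#' @export
nei_gojobori_dnds <- function(w_cds, z_cds) {
  pair <- validate_cds_pair(w_cds, z_cds)
  cod_w <- split_codons(pair$w); cod_z <- split_codons(pair$z)
  sf <- codon_syn_fraction()
  s_w <- sum(sf[cod_w]); s_z <- sum(sf[cod_z])
  S <- (s_w + s_z) / 2
  N <- 3 * length(cod_w) - S
  Sd <- 0; Nd <- 0
  for (k in seq_along(cod_w)) {
    if (cod_w[k] == cod_z[k]) next
    cnt <- codon_path_counts(cod_w[k], cod_z[k])
    Sd <- Sd + cnt["sd"]; Nd <- Nd + cnt["nd"]
  }
  ps <- if (S > 0) Sd / S else 0
  pn <- if (N > 0) Nd / N else 0
  status <- "OK"
  dS <- dN <- NA_real_
  if (ps >= 0.75 || pn >= 0.75) {
    status <- "SATURATED"
    omega <- NA_real_
  } else {
    dS <- -0.75 * log(1 - 4 / 3 * ps)
    dN <- -0.75 * log(1 - 4 / 3 * pn)
    if (dN == 0) {
      omega <- 0; status <- "ZERO"
    } else if (dS == 0) {
      omega <- NA_real_; status <- "UNDEFINED"
    } else omega <- dN / dS
  }
  structure(list(S = unname(S), N = unname(N), Sd = unname(Sd),
                 Nd = unname(Nd), ps = unname(ps), pn = unname(pn),
                 dS = unname(dS), dN = unname(dN), omega = unname(omega),
                 status = status, n_codons = length(cod_w)),
            class = "dnds_estimate")
}

#' @export
print.dnds_estimate <- function(x, ...) {
  cat(sprintf("Nei-Gojobori estimate over %d codons\n", x$n_codons))
  cat(sprintf("  S %.2f  N %.2f  Sd %.2f  Nd %.2f\n", x$S, x$N, x$Sd, x$Nd))
  if (x$status == "SATURATED") {
    cat("  saturated (p >= 3/4): Jukes-Cantor correction impossible\n")
  } else {
    cat(sprintf("  dS %.4f  dN %.4f  omega %s (%s)\n", x$dS, x$dN,
                ifelse(is.na(x$omega), "undefined",
                       sprintf("%.3f", x$omega)), x$status))
  }
  invisible(x)
}

#' Codon alignment of two coding sequences
#'
#' Translates both sequences, aligns the proteins globally (BLOSUM62, gap
#' 11/1, free end gaps), back-maps the protein alignment to nucleotides
#' and drops codon columns gapped in either sequence, yielding an
#' equal-length, gap-free codon-aligned pair.
#'
#' @param w_cds,z_cds coding sequences (length divisible by 3, no internal
#'   stops; a terminal stop is allowed and removed).
#' @return list with aligned \code{w} and \code{z} strings.
#' @export
codon_align <- function(w_cds, z_cds) {
  strip <- function(s) {
    s <- toupper(s)
    if (nchar(s) %% 3L != 0L) stop("CDS length must be divisible by 3")
    prot <- translate_cds(s)
    if (substr(prot, nchar(prot), nchar(prot)) == "*") {
      s <- substr(s, 1L, nchar(s) - 3L)
      prot <- substr(prot, 1L, nchar(prot) - 1L)
    }
    if (grepl("*", prot, fixed = TRUE)) stop("internal stop codon in CDS")
    list(cds = s, prot = prot)
  }
  w <- strip(w_cds); z <- strip(z_cds)
  aln <- align_protein(w$prot, z$prot, type = "overlap")
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  iw <- Biostrings::start(Biostrings::pattern(aln)) - 1L
  iz <- Biostrings::start(Biostrings::subject(aln)) - 1L
  w_out <- character(0); z_out <- character(0)
  for (k in seq_along(pa)) {
    if (pa[k] != "-" && sa[k] != "-") {
      w_out <- c(w_out, substr(w$cds, iw * 3L + 1L, iw * 3L + 3L))
      z_out <- c(z_out, substr(z$cds, iz * 3L + 1L, iz * 3L + 3L))
    }
    if (pa[k] != "-") iw <- iw + 1L
    if (sa[k] != "-") iz <- iz + 1L
  }
  list(w = paste(w_out, collapse = ""), z = paste(z_out, collapse = ""))
}

#' Sliding-window dN/dS profile
#'
#' Applies \code{\link{nei_gojobori_dnds}} in windows along a codon-aligned
#' pair. Windows whose estimate is saturated or undefined are emitted with
#' \code{NA} omega rather than dropped, keeping the axis complete.
#'
#' @param w_cds,z_cds codon-aligned pair (as for
#'   \code{\link{nei_gojobori_dnds}}).
#' @param window_codons window width in codons (default 50).
#' @param step_codons step between window starts in codons (default 10).
#' @return data.frame of class \code{dnds_profile}: \code{midpoint}
#'   (codon), \code{omega}, \code{dN}, \code{dS}, \code{status}.
#' @export
sliding_window_dnds <- function(w_cds, z_cds, window_codons = 50L,
                                step_codons = 10L) {
  pair <- validate_cds_pair(w_cds, z_cds)
  n <- nchar(pair$w) %/% 3L
  if (window_codons > n) {
    warning("window longer than the alignment; using a single window")
    window_codons <- n
  }
  starts <- seq(1L, n - window_codons + 1L, by = step_codons)
  rows <- lapply(starts, function(s) {
    i <- (s - 1L) * 3L + 1L
    j <- (s + window_codons - 1L) * 3L
    est <- nei_gojobori_dnds(substr(pair$w, i, j), substr(pair$z, i, j))
    data.frame(midpoint = s + window_codons / 2 - 0.5,
               omega = est$omega, dN = est$dN, dS = est$dS,
               status = est$status, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("dnds_profile", class(out))
  out
}

#' Plot a sliding-window dN/dS profile
#'
#' @param x a \code{\link{sliding_window_dnds}} profile.
#' @param ... passed to \code{plot}.
#' @export
plot.dnds_profile <- function(x, ...) {
  plot(x$midpoint, x$omega, type = "b", pch = 16,
       xlab = "codon midpoint", ylab = expression(omega == dN / dS), ...)
  abline(h = 1, lty = 2, col = "grey50")
  invisible(x)
}
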