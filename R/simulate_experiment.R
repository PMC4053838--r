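#' Simulate a complete synthetic ZW experiment
#'
#' One call producing every input the downstream stages consume: a count
#' experiment with truth (\code{\link{simulate_counts}}), codon-evolved
#' W/Z gametologue pairs for a subset of the W genes, per-gene fragment
#' sets emulating transcripts split across pseudo-chromosome pieces
#' (\code{\link{fragmentize}}), retroviral decoy transcripts, and a
#' candidate pool with FPKM summaries for the discovery filters.
#'
#' @param config a \code{\link{sim_config}}; its seed drives every stage
#'   through derived per-stage seeds.
#' @param n_pairs number of W genes given explicit gametologue sequences.
#' @param n_codons codons per simulated CDS.
#' @param omega generative dN/dS of the gametologue pairs.
#' @param subs_per_codon expected substitutions per codon between W and Z.
#' @param fragments_range range of fragment counts per gene.
#' @param frag_min_overlap junction overlap passed to
#'   \code{\link{fragmentize}}.
#' @param orphan_prob per-junction gap probability.
#' @param n_decoys number of retroviral decoy transcripts.
#' @param n_background number of autosomal and of Z genes added to the
#'   candidate pool as non-W background.
#' @return list with \code{experiment}, \code{truth}, \code{fpkm},
#'   \code{pairs} (per pair: w_cds, z_cds, omega, gene ids),
#'   \code{fragment_sets}, \code{decoys}, \code{candidates},
#'   \code{z_proteins} and \code{config}.
#' @export
simulate_zw_experiment <- function(config = sim_config(), n_pairs = 10L,
                                   n_codons = 300L, omega = 0.2,
                                   subs_per_codon = 0.3,
                                   fragments_range = c(5L, 9L),
                                   frag_min_overlap = 60L, orphan_prob = 0,
                                   n_decoys = 10L, n_background = 30L) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_counts(config)
  ann <- sim$experiment$annotation
  norm <- normalize_library_sizes(sim$experiment)
  fpkm <- compute_fpkm(sim$experiment, lib_sizes = norm$effective_lib_sizes)

  set.seed(derive_seed(config$seed, "sequences"))
  # every true W transcript carries a Z gametologue (as in the embryonic W
  # catalog, where a single gene lacks one); pairs cover all W-like genes
  pair_ids <- sim$truth$gene_id[sim$truth$is_w_like]
  pairs <- lapply(pair_ids, function(id) {
    z <- random_cds(n_codons)
    p <- simulate_gametologue_pair(z, omega = omega,
                                   expected_subs_per_codon = subs_per_codon)
    list(pair_id = id, w_gene = id, z_gene = paste0(id, "_Z"),
         w_cds = p$w_cds, z_cds = p$z_cds, omega = omega,
         n_substitutions = p$n_substitutions)
  })
  names(pairs) <- pair_ids

  fragment_sets <- lapply(pairs[seq_len(min(n_pairs, length(pairs)))],
                          function(p) {
    nf <- sample(seq(fragments_range[1], fragments_range[2]), 1L)
    # short transcripts cannot host arbitrarily many overlapping pieces
    nf <- max(1L, min(nf, nchar(p$w_cds) %/% (2L * frag_min_overlap)))
    fragmentize(p$w_cds, n_fragments = nf, min_overlap = frag_min_overlap,
                orphan_prob = orphan_prob,
                id_prefix = paste0(p$pair_id, "_frag"))
  })

  decoys <- make_retroviral_decoys(n_decoys)

  # candidate pool: all W-like truth transcripts, non-W background, decoys
  mean_fpkm <- function(ids, tissue, sex) {
    des <- sim$experiment$design
    rowMeans(fpkm[ids, des$tissue == tissue & des$sex == sex, drop = FALSE])
  }
  w_like_ids <- sim$truth$gene_id[sim$truth$is_w_like]
  bg_aut <- head(ann$gene_id[ann$class == "autosome"], n_background)
  bg_z <- head(ann$gene_id[ann$class == "Z"], n_background)
  pool_ids <- c(w_like_ids, bg_aut, bg_z)
  pool_seq <- vapply(pool_ids, function(id) {
    if (!is.null(pairs[[id]])) pairs[[id]]$w_cds
    else random_cds(sample(120:400, 1L))
  }, character(1))
  pool_fpkm <- data.frame(
    fpkm_blastoderm_F = mean_fpkm(pool_ids, "blastoderm", "F"),
    fpkm_blastoderm_M = mean_fpkm(pool_ids, "blastoderm", "M"),
    fpkm_gonad_F = mean_fpkm(pool_ids, "gonad", "F"),
    fpkm_gonad_M = mean_fpkm(pool_ids, "gonad", "M"))
  cand <- candidate_transcripts(
    id = pool_ids, sequence = unname(pool_seq),
    source = "genome-guided",
    chrom = ann$class[match(pool_ids, ann$gene_id)],
    fpkm = pool_fpkm)
  if (n_decoys > 0) {
    decoy_fpkm <- data.frame(
      fpkm_blastoderm_F = exp(runif(n_decoys, log(5), log(50))),
      fpkm_blastoderm_M = 0,
      fpkm_gonad_F = exp(runif(n_decoys, log(5), log(50))),
      fpkm_gonad_M = 0)
    cand_decoy <- candidate_transcripts(
      id = names(decoys), sequence = unname(decoys), source = "genome-guided",
      chrom = "Un_random", fpkm = decoy_fpkm)
    cand <- rbind(cand, cand_decoy)
    class(cand) <- c("candidate_set", "data.frame")
  }
  cand$is_true_w <- cand$id %in% w_like_ids
  cand$is_decoy <- cand$id %in% names(decoys)

  z_proteins <- vapply(pairs, function(p)
    sub("\\*$", "", translate_cds(p$z_cds)), character(1))
  names(z_proteins) <- vapply(pairs, `[[`, character(1), "z_gene")

  list(experiment = sim$experiment, truth = sim$truth, fpkm = fpkm,
       effective_lib_sizes = norm$effective_lib_sizes,
       pairs = pairs, fragment_sets = fragment_sets, decoys = decoys,
       candidates = cand, z_proteins = z_proteins, config = config)
}
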