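#' Simulate a ZW factorial count experiment with ground truth
#'
#' Generates a genes x samples matrix of negative-binomial counts under the
#' configured ZW expression structure: non-compensated Z genes expressed
#' \code{z_male_ratio}-fold higher in males, W/W_random genes (and a
#' configurable share of Un_random genes) restricted to females with hard
#' zeros in males, an MHM-like female-only Z locus, and a designated set of
#' autosomal genes dimorphic in exactly one tissue. Per-gene dispersions
#' are drawn log-normally around \code{dispersion_prior} (sdlog 0.5) and
#' counts follow NB(mu, phi) with variance \eqn{\mu + \phi\mu^2}.
#'
#' Expected counts are FPKM-scaled: \eqn{\mu_{gs} = F_{gs} \cdot L_g/10^3
#' \cdot N_s/10^6} for gene length \eqn{L_g} and library size \eqn{N_s}
#' (drawn uniformly within +/-20\% of the configured size).
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with elements \code{experiment} (a
#'   \code{\link{count_experiment}}) and \code{truth} (data.frame of
#'   per-gene generative truth: class, baseline FPKM, dimorphism flags per
#'   tissue, sex of bias, true fold changes female/male per tissue,
#'   MHM flag, dispersion).
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, "counts"))

  npc <- config$n_genes_per_class
  classes <- rep(names(npc), npc)
  G <- length(classes)
  if (G == 0L) stop("no genes configured")
  prefix <- c(autosome = "AUT", Z = "Z", W = "W", W_random = "WR",
              Un_random = "UR")
  ids <- paste0(prefix[classes],
                unlist(lapply(npc, function(n) sprintf("%04d", seq_len(n)))))

  lengths <- sample(500:5000, G, replace = TRUE)
  base_fpkm <- rlnorm(G, meanlog = log(20), sdlog = 1.2)
  w_like <- classes %in% c("W", "W_random")
  # a share of Un_random genes are mis-assigned W genes (female-restricted)
  idx_ur <- which(classes == "Un_random")
  n_ur_w <- round(config$un_random_w_fraction * length(idx_ur))
  ur_w <- idx_ur[seq_len(n_ur_w)]
  w_like[ur_w] <- TRUE
  lr <- log(config$w_female_fpkm_range)
  base_fpkm[w_like] <- exp(runif(sum(w_like), lr[1], lr[2]))

  tissues <- c("blastoderm", "gonad")
  sexes <- c("F", "M")
  design <- expand.grid(replicate = seq_len(config$n_replicates),
                        sex = sexes, tissue = tissues,
                        stringsAsFactors = FALSE)[, 3:1]
  design$sample <- sprintf("%s_%s_%d", design$tissue, design$sex,
                           design$replicate)
  S <- nrow(design)
  lib_sizes <- config$library_size * runif(S, 0.8, 1.2)

  # per-gene, per-(tissue,sex) FPKM multipliers; baseline refers to females
  eff <- array(1, dim = c(G, 2L, 2L),
               dimnames = list(ids, tissues, sexes))

  sex_of_bias <- rep("none", G)
  fc_blast <- rep(1, G)  # female/male true fold change per tissue
  fc_gonad <- rep(1, G)
  is_mhm <- rep(FALSE, G)

  # Z: incomplete dosage compensation (male-biased), MHM locus female-only
  idx_z <- which(classes == "Z")
  n_mhm <- min(config$n_mhm_genes, length(idx_z))
  mhm <- idx_z[seq_len(n_mhm)]
  is_mhm[mhm] <- TRUE
  z_rest <- setdiff(idx_z, mhm)
  n_nc <- round(config$z_noncompensated_fraction * length(z_rest))
  z_nc <- z_rest[seq_len(n_nc)]
  if (config$z_male_ratio != 1 && length(z_nc)) {
    eff[z_nc, , "M"] <- config$z_male_ratio
    sex_of_bias[z_nc] <- "M"
    fc_blast[z_nc] <- 1 / config$z_male_ratio
    fc_gonad[z_nc] <- 1 / config$z_male_ratio
  }
  if (length(mhm)) {
    eff[mhm, , "M"] <- 0
    sex_of_bias[mhm] <- "F"
    fc_blast[mhm] <- Inf
    fc_gonad[mhm] <- Inf
  }

  # W-like genes: strictly female (hard zero in males unless leaky)
  if (any(w_like)) {
    eff[w_like, , "M"] <- if (config$w_leaky) 0.01 else 0
    sex_of_bias[w_like] <- "F"
    fc_blast[w_like] <- Inf
    fc_gonad[w_like] <- Inf
  }

  # autosomal genes dimorphic in exactly one tissue, half per direction
  idx_aut <- which(classes == "autosome")
  fcd <- config$dimorphic_fold_change
  if (fcd != 1 && config$n_dimorphic_autosomal_per_tissue > 0L) {
    need <- 2L * config$n_dimorphic_autosomal_per_tissue
    if (need > length(idx_aut))
      stop("not enough autosomal genes for the dimorphic sets")
    pick <- sample(idx_aut, need)
    for (k in 1:2) {
      ti <- tissues[k]
      sel <- pick[seq((k - 1L) * config$n_dimorphic_autosomal_per_tissue + 1L,
                      k * config$n_dimorphic_autosomal_per_tissue)]
      half <- length(sel) %/% 2L
      f_up <- sel[seq_len(half)]
      m_up <- setdiff(sel, f_up)
      eff[f_up, ti, "F"] <- fcd
      eff[m_up, ti, "M"] <- fcd
      sex_of_bias[f_up] <- "F"
      sex_of_bias[m_up] <- "M"
      if (ti == "blastoderm") {
        fc_blast[f_up] <- fcd; fc_blast[m_up] <- 1 / fcd
      } else {
        fc_gonad[f_up] <- fcd; fc_gonad[m_up] <- 1 / fcd
      }
    }
  }

  phi <- rlnorm(G, meanlog = log(config$dispersion_prior), sdlog = 0.5)

  counts <- matrix(0, nrow = G, ncol = S, dimnames = list(ids, design$sample))
  for (s in seq_len(S)) {
    f <- base_fpkm * eff[, design$tissue[s], design$sex[s]]
    mu <- f * (lengths / 1e3) * (lib_sizes[s] / 1e6)
    if (any(mu > .Machine$integer.max / 4))
      stop("expected counts overflow: reduce library_size or expression")
    y <- rnbinom(G, mu = mu, size = 1 / phi)
    y[mu == 0] <- 0  # hard zeros (W genes in males)
    counts[, s] <- y
  }

  annotation <- data.frame(gene_id = ids, class = classes, length = lengths,
                           stringsAsFactors = FALSE)
  truth <- data.frame(
    gene_id = ids, class = classes, length = lengths,
    baseline_fpkm = base_fpkm,
    is_w_like = w_like,
    is_mhm = is_mhm,
    sex_of_bias = sex_of_bias,
    true_fc_blastoderm = fc_blast,
    true_fc_gonad = fc_gonad,
    is_dimorphic_blastoderm = fc_blast != 1,
    is_dimorphic_gonad = fc_gonad != 1,
    dispersion = phi,
    stringsAsFactors = FALSE
  )
  experiment <- count_experiment(counts, design, lib_sizes = lib_sizes,
                                 annotation = annotation)
  list(experiment = experiment, truth = truth)
}
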