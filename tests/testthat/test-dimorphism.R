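# hand-built experiment: 8 samples (2 tissues x 2 sexes x 2 reps) with
# known per-gene structure
toy_experiment <- function(counts) {
  design <- expand.grid(replicate = 1:2, sex = c("F", "M"),
                        tissue = c("blastoderm", "gonad"),
                        stringsAsFactors = FALSE)[, 3:1]
  design$sample <- sprintf("%s_%s_%d", design$tissue, design$sex,
                           design$replicate)
  colnames(counts) <- design$sample
  rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  ann <- data.frame(gene_id = rownames(counts), class = "autosome",
                    length = 1000L)
  count_experiment(counts, design, lib_sizes = rep(1e6, 8), annotation = ann)
}

toy_dispersions <- function(ex, phi = 0.05) {
  structure(list(common = phi,
                 tagwise = setNames(rep(phi, nrow(ex$counts)),
                                    rownames(ex$counts)),
                 prior_weight = 10,
                 effective_lib_sizes = ex$lib_sizes),
            class = "dispersion_estimates")
}

test_that("a gene with identical counts in both sexes is null in every test", {
  # order: blastoderm F F M M, gonad F F M M
  counts <- rbind(rep(100, 8),                        # flat everywhere
                  c(100, 100, 100, 100, 500, 500, 500, 500))  # tissue only
  ex <- toy_experiment(counts)
  fit <- dimorphism_fit(ex, toy_dispersions(ex))
  for (t in c("sex_blastoderm", "sex_gonad", "ratio_difference")) {
    r <- dimorphism_results(fit, t)
    expect_equal(r$log2fc[1], 0, tolerance = 1e-9)
    expect_gt(r$pvalue[1], 0.99)
  }
  # equal F:M ratio in both tissues, 5x tissue effect: interaction null,
  # tissue test strongly significant with gonad direction
  r_int <- dimorphism_results(fit, "ratio_difference")
  expect_gt(r_int$pvalue[2], 0.9)
  r_tis <- dimorphism_results(fit, "tissue_average")
  expect_lt(r_tis$pvalue[2], 1e-6)
  expect_equal(r_tis$direction[2], "higher_in_gonad")
})

test_that("FOXL2-like gonad-only dimorphism is caught by the interaction test", {
  set.seed(21)
  # dimorphic only in gonad (F 4x), flat in blastoderm
  g <- c(rnbinom(2, mu = 200, size = 20), rnbinom(2, mu = 200, size = 20),
         rnbinom(2, mu = 800, size = 20), rnbinom(2, mu = 200, size = 20))
  counts <- rbind(g, matrix(rnbinom(40 * 8, mu = 150, size = 20), ncol = 8))
  ex <- toy_experiment(counts)
  fit <- dimorphism_fit(ex, toy_dispersions(ex))
  r <- dimorphism_results(fit, "ratio_difference")
  expect_lt(r$qvalue[1], 0.05)
  expect_equal(r$direction[1], "more_dimorphic_in_gonad")
  # DMRT1-like: same F:M ratio, 5x higher in gonad
  r2 <- dimorphism_results(fit, "tissue_average")
  expect_lt(r2$pvalue[1], 0.05)
})

test_that("swapping tissue labels flips the tissue-test direction, not p", {
  set.seed(22)
  counts <- matrix(rnbinom(30 * 8, mu = 100, size = 20), ncol = 8)
  counts[, 5:8] <- counts[, 5:8] * 3L
  ex <- toy_experiment(counts)
  fit <- dimorphism_fit(ex, toy_dispersions(ex))
  des2 <- ex$design
  des2$tissue <- factor(ifelse(des2$tissue == "gonad", "blastoderm", "gonad"),
                        levels = c("blastoderm", "gonad"))
  ex2 <- count_experiment(ex$counts, des2, ex$lib_sizes, ex$annotation)
  fit2 <- dimorphism_fit(ex2, toy_dispersions(ex2))
  r <- dimorphism_results(fit, "tissue_average")
  r2 <- dimorphism_results(fit2, "tissue_average")
  expect_equal(r$pvalue, r2$pvalue, tolerance = 1e-6)
  expect_equal(r$log2fc, -r2$log2fc, tolerance = 1e-9)
})

test_that("every strictly female-specific W gene is significant in both tissues", {
  sim <- small_sim()
  fit <- small_fit()
  w <- sim$truth$gene_id[sim$truth$class %in% c("W", "W_random")]
  for (t in c("sex_blastoderm", "sex_gonad")) {
    r <- dimorphism_results(fit, t)
    rw <- r[match(w, r$gene_id), ]
    expect_true(all(rw$qvalue < 0.05))
    expect_true(all(rw$log2fc > 0))
  }
})

test_that("type-I error of all three LRTs is calibrated on null data", {
  fit <- null_fit()
  for (t in c("sex_blastoderm", "sex_gonad", "ratio_difference")) {
    frac <- mean(dimorphism_results(fit, t)$pvalue < 0.05)
    expect_gt(frac, 0.03)
    expect_lt(frac, 0.07)
  }
})

test_that("power reaches 0.8 for 2-fold dimorphism at mean count >= 100", {
  sim <- small_sim()   # dimorphic_fold_change = 2 in the generator
  fit <- small_fit()
  y <- sim$experiment$counts
  des <- sim$experiment$design
  for (ti in c("blastoderm", "gonad")) {
    truth_col <- paste0("is_dimorphic_", ti)
    dim_genes <- sim$truth$gene_id[sim$truth[[truth_col]] &
                                   sim$truth$class == "autosome"]
    expressed <- rowMeans(y[dim_genes, des$tissue == ti, drop = FALSE]) >= 100
    r <- dimorphism_results(fit, paste0("sex_", ti))
    # power at the same nominal level the size invariant is checked at
    hits <- r$pvalue[match(dim_genes[expressed], r$gene_id)] < 0.05
    expect_gte(mean(hits), 0.8)
  }
})

test_that("the LRT statistic equals twice the log-likelihood difference", {
  # internal consistency of the deviance-based statistic
  set.seed(23)
  counts <- matrix(rnbinom(10 * 8, mu = 120, size = 10), ncol = 8)
  counts[1:3, c(1, 2, 5, 6)] <- counts[1:3, c(1, 2, 5, 6)] * 3L
  ex <- toy_experiment(counts)
  disp <- toy_dispersions(ex, phi = 0.08)
  fit <- dimorphism_fit(ex, disp)
  X_full <- cbind(1, gonad = rep(c(0, 1), each = 4),
                  female = rep(c(1, 1, 0, 0), 2))
  X_full <- cbind(X_full, inter = X_full[, 2] * X_full[, 3])
  off <- log(disp$effective_lib_sizes)
  for (g in 1:5) {
    y <- ex$counts[g, ]
    ll <- function(X) {
      f <- suppressWarnings(stats::glm.fit(X, y, offset = off,
        family = MASS::negative.binomial(theta = 1 / 0.08)))
      sum(dnbinom(y, mu = f$fitted.values, size = 1 / 0.08, log = TRUE))
    }
    stat_direct <- 2 * (ll(X_full) - ll(X_full[, -4]))
    r <- dimorphism_results(fit, "ratio_difference")
    expect_equal(r$stat[g], stat_direct, tolerance = 1e-4)
  }
})

test_that("missing factor levels are rejected", {
  sim <- small_sim()
  ex <- sim$experiment
  keep <- ex$design$tissue == "blastoderm"
  des <- droplevels(ex$design[keep, ])
  expect_error(
    dimorphism_fit(count_experiment(ex$counts[, keep], des,
                                    ex$lib_sizes[keep], ex$annotation),
                   small_dispersions()),
    "both tissues")
})

test_that("BH adjustment matches the step-up definition", {
  # brute-force oracle: q_i = min over j with p_(j) >= p_(i) of p_(j) m / j
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- cummin(rev(p[o] * m / seq_len(m)))
    pmin(rev(q_sorted), 1)[order(o)]
  }
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(24)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(c(1, 3), 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p and q monotone in p-rank
  p <- runif(100)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) > -1e-12))
})
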