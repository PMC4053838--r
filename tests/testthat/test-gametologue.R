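test_that("global identity handles the elementary cases", {
  s <- random_dna(200, seed = 91)
  expect_equal(global_align_identity(s, s, "dna"), 100)
  expect_equal(global_align_identity("ACGT", "ACGA", "dna"), 75)
  expect_equal(global_align_identity("MKTW", "MKTW", "protein"), 100)
  expect_error(global_align_identity("AC-T", "ACGT", "dna"), "ACGTN")
})

test_that("identity is invariant to order and joint reverse-complement", {
  set.seed(92)
  for (rep in 1:5) {
    z <- random_cds(120)
    w <- simulate_gametologue_pair(z, expected_subs_per_codon = 0.2)$w_cds
    id1 <- global_align_identity(w, z, "dna")
    expect_equal(id1, global_align_identity(z, w, "dna"), tolerance = 1e-9)
    expect_equal(id1, global_align_identity(revcomp(w), revcomp(z), "dna"),
                 tolerance = 1e-9)
  }
})

test_that("gametologue search returns the true donor and rejects noise", {
  set.seed(93)
  zset <- setNames(lapply(1:6, function(i) random_cds(250)),
                   paste0("Z", 1:6))
  zset <- vapply(zset, identity, character(1))
  w <- simulate_gametologue_pair(zset[["Z3"]], omega = 0.2,
                                 expected_subs_per_codon = 0.3)$w_cds
  hit <- find_z_gametologue(w, zset)
  expect_equal(hit$id, "Z3")
  expect_gt(hit$identity, 80)
  # an exact copy gives full coverage
  hit2 <- find_z_gametologue(zset[["Z1"]], zset)
  expect_equal(hit2$id, "Z1")
  expect_gte(hit2$coverage_w, 0.999)
  # unrelated sequence: no qualifying hit (the no-gametologue case)
  expect_null(find_z_gametologue(random_dna(250), zset))
})

test_that("gametologue_compare summarises divergence coherently", {
  z <- random_cds(200, seed = 94)
  w <- simulate_gametologue_pair(z, omega = 0.2,
                                 expected_subs_per_codon = 0.3,
                                 seed = 95)$w_cds
  g <- gametologue_compare(w, z, pair_id = "toy")
  expect_gt(g$dna_identity, 80); expect_lt(g$dna_identity, 100)
  expect_true(g$protein_identity >= 0 && g$protein_identity <= 100)
  expect_gt(g$omega, 0); expect_lt(g$omega, 1)
  expect_s3_class(g$window_profile, "dnds_profile")
  # identical pair mirrors the catalog convention: identity 100, dN/dS 0
  g0 <- gametologue_compare(z, z)
  expect_equal(g0$protein_identity, 100)
  expect_equal(g0$omega, 0)
  expect_equal(g0$status, "ZERO")
})

combined_toy <- function(w_female_fpkm, z_fpkm, seed = 96) {
  set.seed(seed)
  design <- expand.grid(replicate = 1:2, sex = c("F", "M"),
                        tissue = c("blastoderm", "gonad"),
                        stringsAsFactors = FALSE)[, 3:1]
  design$sample <- sprintf("%s_%s_%d", design$tissue, design$sex,
                           design$replicate)
  lib <- 1e6
  len <- 1000
  mu_w <- ifelse(design$sex == "F", w_female_fpkm, 0)
  mu_z <- ifelse(design$sex == "F", z_fpkm, 2 * z_fpkm)  # two Z alleles in males
  counts <- rbind(
    W = rnbinom(8, mu = mu_w * len / 1e3 * lib / 1e6, size = 25),
    Z = rnbinom(8, mu = mu_z * len / 1e3 * lib / 1e6, size = 25))
  counts["W", design$sex == "M"] <- 0
  colnames(counts) <- design$sample
  filler <- matrix(rnbinom(50 * 8, mu = 100, size = 25), ncol = 8,
                   dimnames = list(paste0("g", 1:50), design$sample))
  m <- rbind(counts, filler)
  ann <- data.frame(gene_id = rownames(m), class = "autosome", length = len)
  ann$class[1:2] <- c("W", "Z")
  count_experiment(m, design, lib_sizes = rep(lib, 8), annotation = ann)
}

test_that("a compensated pair is non-significant with an even W share", {
  # female W + Z matches the male ZZ total; W and Z contribute equally
  ex <- combined_toy(w_female_fpkm = 100, z_fpkm = 100)
  v <- combined_expression_compare(ex, "W", "Z", dispersion = 0.04)
  expect_true(all(!v$table$significant))
  expect_true(all(abs(v$table$w_share - 0.5) < 0.15))
})

test_that("a HINT-like pair shows a significant female excess driven by W", {
  ex <- combined_toy(w_female_fpkm = 1500, z_fpkm = 100)
  v <- combined_expression_compare(ex, "W", "Z", dispersion = 0.04)
  expect_true(all(v$table$significant))
  expect_true(all(v$table$female_total > v$table$male_total))
  expect_true(all(v$table$w_share > 0.8))
})

test_that("zero W expression collapses the female total onto Z", {
  ex <- combined_toy(w_female_fpkm = 0, z_fpkm = 100)
  v <- combined_expression_compare(ex, "W", "Z", dispersion = 0.04)
  expect_true(all(v$table$w_share == 0))
  expect_error(combined_expression_compare(ex, "absent", "Z"),
               "present")
})
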