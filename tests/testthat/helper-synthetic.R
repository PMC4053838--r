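# Shared synthetic fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fixtures))
    assign(name, force(expr), envir = .fixtures)
  get(name, envir = .fixtures)
}

# a compact ZW experiment exercising every gene class
small_config <- function(seed = 42)
  sim_config(n_genes_per_class = c(autosome = 800L, Z = 100L, W = 10L,
                                   W_random = 4L, Un_random = 20L),
             n_dimorphic_autosomal_per_tissue = 20L,
             n_mhm_genes = 2L, seed = seed)

small_sim <- function() memo("small_sim", simulate_counts(small_config()))

small_dispersions <- function()
  memo("small_disp", estimate_dispersions(small_sim()$experiment))

small_fit <- function()
  memo("small_fit",
       dimorphism_fit(small_sim()$experiment, small_dispersions()))

# 2000-gene null simulation for calibration checks
null_sim <- function()
  memo("null_sim", simulate_counts(sim_config_null(2000L, seed = 1)))

null_fit <- function()
  memo("null_fit", {
    s <- null_sim()
    dimorphism_fit(s$experiment, estimate_dispersions(s$experiment))
  })

# full default-scale synthetic experiment (seed 42), shared with the
# discovery and dosage checks
default_zw <- function()
  memo("default_zw", simulate_zw_experiment(sim_config(seed = 42)))

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
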