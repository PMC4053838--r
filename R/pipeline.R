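#' Run the full analysis pipeline
#'
#' Executes the five stages — simulate (optional), dimorphism, discover,
#' scaffold, gametologue — writing each stage's outputs under its own
#' subdirectory of \code{out_dir} and a run manifest (inputs, seeds,
#' parameters, per-file checksums) at the top level. Any stage can also be
#' run standalone through the exported functions it wraps.
#'
#' The configuration is a YAML file or list. With \code{simulate: true}
#' the synthetic generator provides all inputs (fields under
#' \code{sim} override \code{\link{sim_config}} defaults). With
#' \code{simulate: false} the config must name \code{counts},
#' \code{design} and \code{annotation} TSV paths as written by
#' \code{\link{write_count_experiment}}.
#'
#' @param config YAML path or list.
#' @param out_dir run directory (created; an existing run is only
#'   overwritten with \code{force = TRUE}).
#' @param seed global seed; overrides the config seed. Stage seeds are
#'   derived from it.
#' @param force overwrite an existing run directory.
#' @return the run directory path, invisibly; the manifest is
#'   \code{manifest.json} inside it.
#' @export
run_pipeline <- function(config = list(simulate = TRUE), out_dir,
                         seed = NULL, force = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(config$simulate)) config$simulate <- FALSE
  if (file.exists(file.path(out_dir, "manifest.json")) && !force)
    stop("run directory ", out_dir,
         " already contains a run; use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(stages = list(), parameters = config)
  log_msg <- function(...) message("[wseq] ", sprintf(...))

  stage_dir <- function(name) {
    d <- file.path(out_dir, name)
    dir.create(d, showWarnings = FALSE)
    d
  }
  finish_stage <- function(name, dir) {
    files <- list.files(dir, full.names = TRUE, recursive = TRUE)
    manifest$stages[[name]] <<- list(
      dir = basename(dir),
      files = as.list(setNames(unname(tools::md5sum(files)),
                               basename(files))))
    log_msg("stage %s: %d file(s)", name, length(files))
  }
  run_stage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  # ---- stage 1: simulate / load ----
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim
    if (is.null(sim_args)) sim_args <- list()
    # YAML parses named vectors as lists; flatten them back
    sim_args <- lapply(sim_args, function(x) if (is.list(x)) unlist(x) else x)
    if (!is.null(seed)) sim_args$seed <- seed
    cfg <- do.call(sim_config, sim_args)
    manifest$seed <- cfg$seed
    zw <- run_stage("simulate", function() {
      sim_extra <- config$simulate_experiment
      if (is.null(sim_extra)) sim_extra <- list()
      sim_extra <- lapply(sim_extra, function(x)
        if (is.list(x)) unlist(x) else x)
      do.call(simulate_zw_experiment, c(list(config = cfg), sim_extra))
    })
    d <- stage_dir("01_simulate")
    write_count_experiment(zw$experiment, d)
    write.table(zw$truth, file.path(d, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_fasta(setNames(vapply(zw$pairs, `[[`, character(1), "w_cds"),
                         names(zw$pairs)), file.path(d, "w_cds.fa"))
    write_fasta(setNames(vapply(zw$pairs, `[[`, character(1), "z_cds"),
                         vapply(zw$pairs, `[[`, character(1), "z_gene")),
                file.path(d, "z_cds.fa"))
    if (length(zw$decoys))
      write_fasta(zw$decoys, file.path(d, "decoys.fa"))
    finish_stage("simulate", d)
    experiment <- zw$experiment
  } else {
    for (key in c("counts", "design", "annotation"))
      if (is.null(config[[key]]))
        stop("config is missing required key '", key,
             "' (paths are required when simulate: false)")
    zw <- NULL
    experiment <- run_stage("load", function() {
      cts <- read.delim(config$counts, check.names = FALSE)
      m <- as.matrix(cts[, -1, drop = FALSE])
      rownames(m) <- cts[[1]]
      des <- read.delim(config$design)
      ls <- if (!is.null(des$lib_size)) des$lib_size else colSums(m)
      count_experiment(m, des, lib_sizes = ls,
                       annotation = read.delim(config$annotation))
    })
    manifest$seed <- seed
    manifest$stages[["simulate"]] <- list(skipped = TRUE,
                                          inputs = config[c("counts",
                                                            "design",
                                                            "annotation")])
  }

  # ---- stage 2: dimorphism ----
  fdr <- if (is.null(config$fdr)) 0.05 else config$fdr
  fit <- run_stage("dimorphism", function() dimorphism_fit(experiment))
  d <- stage_dir("02_dimorphism")
  all_res <- do.call(rbind, lapply(names(fit$results), function(t)
    dimorphism_results(fit, t)))
  write.table(all_res, file.path(d, "dimorphism_results.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tal <- classify_tallies(fit, fdr = fdr)
  jsonlite::write_json(list(
    fdr = fdr,
    sex_bias = lapply(tal$sex_bias, function(s)
      list(n_significant = s$n_significant,
           counts = as.data.frame.matrix(s$counts))),
    inter_tissue = as.list(tal$inter_tissue),
    expression_level = as.list(tal$expression_level)),
    file.path(d, "tallies.json"), auto_unbox = TRUE, digits = NA)
  fpkm <- compute_fpkm(experiment,
                       lib_sizes = fit$effective_lib_sizes)
  dosage <- tryCatch(z_dosage_ratio(fpkm, experiment$design,
                                    experiment$annotation),
                     error = function(e) NULL)
  if (!is.null(dosage))
    jsonlite::write_json(as.list(dosage), file.path(d, "z_dosage.json"),
                         auto_unbox = TRUE, digits = NA)
  finish_stage("dimorphism", d)

  # ---- stages 3-5 need sequence inputs (simulation only) ----
  if (!is.null(zw)) {
    d <- stage_dir("03_discover")
    disc <- run_stage("discover", function() {
      screened <- female_specific_screen(zw$candidates)
      flagged <- screened[screened$female_specific, , drop = FALSE]
      rv <- retroviral_filter(flagged)
      ps <- pseudogene_filter(rv$retained, zw$z_proteins)
      list(screened = screened, retro = rv, pseudo = ps)
    })
    report <- rbind(
      data.frame(id = disc$screened$id[!disc$screened$female_specific],
                 decision = "removed", reason = "not_female_specific",
                 stringsAsFactors = FALSE),
      disc$retro$report[disc$retro$report$decision == "removed",
                        c("id", "decision", "reason")],
      disc$pseudo$report[, c("id", "decision", "reason")])
    write.table(report, file.path(d, "discovery_report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (nrow(disc$pseudo$retained))
      write_fasta(setNames(disc$pseudo$retained$sequence,
                           disc$pseudo$retained$id),
                  file.path(d, "retained_candidates.fa"))
    finish_stage("discover", d)

    d <- stage_dir("04_scaffold")
    assemblies <- run_stage("scaffold", function()
      lapply(names(zw$fragment_sets), function(id)
        assemble_w_transcript(zw$fragment_sets[[id]], zw$pairs[[id]]$z_cds)))
    names(assemblies) <- names(zw$fragment_sets)
    cons <- vapply(assemblies, `[[`, character(1), "consensus")
    write_fasta(cons[nchar(cons) > 0], file.path(d, "consensus.fa"))
    layout_tab <- do.call(rbind, lapply(names(assemblies), function(id) {
      pl <- assemblies[[id]]$layout$placements
      if (!nrow(pl)) return(NULL)
      data.frame(gene = id, fragment = pl$id, orientation = pl$orientation,
                 scaffold_start = pl$scaffold_start,
                 scaffold_end = pl$scaffold_end,
                 identity = pl$identity, stringsAsFactors = FALSE)
    }))
    write.table(layout_tab, file.path(d, "layout.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      lapply(assemblies, function(a)
        list(completeness = a$completeness,
             n_bridges = nrow(a$bridged),
             n_placed = a$report$n_placed,
             n_unplaced = a$report$n_unplaced)),
      file.path(d, "scaffold_report.json"), auto_unbox = TRUE, digits = NA)
    finish_stage("scaffold", d)

    d <- stage_dir("05_gametologue")
    gam <- run_stage("gametologue", function()
      lapply(zw$pairs, function(p)
        gametologue_compare(p$w_cds, p$z_cds, pair_id = p$pair_id)))
    gam_tab <- do.call(rbind, lapply(gam, function(g)
      data.frame(gene = g$pair_id, dna_id = g$dna_identity,
                 prot_id = g$protein_identity, dN = g$dN, dS = g$dS,
                 dnds = ifelse(g$status == "ZERO", 0, g$omega),
                 status = g$status, stringsAsFactors = FALSE)))
    write.table(gam_tab, file.path(d, "gametologue_divergence.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    windows <- do.call(rbind, lapply(gam, function(g)
      if (!is.null(g$window_profile))
        cbind(gene = g$pair_id, g$window_profile)))
    if (!is.null(windows))
      write.table(windows, file.path(d, "window_profiles.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    finish_stage("gametologue", d)
  }

  manifest$n_stages <- length(manifest$stages)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
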