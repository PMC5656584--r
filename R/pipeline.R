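#' Run the full analysis pipeline from a configuration
#'
#' Wires the stages end to end: (optionally) simulate a synthetic study,
#' preprocess intensities into the standardized change matrix, select
#' gene sets by the GA under repeated cross-validation, and write
#' downstream summaries.  Every artifact carries a provenance header
#' with the package version and master seed; a rerun with an identical
#' configuration is bit-identical.
#'
#' The configuration is a YAML file or an equivalent nested list with
#' blocks `simulate` (arguments of [simulation_design()] and
#' [synthetic_truth()], plus `growth_noise_frac`) or `inputs` (paths
#' `expression`, `meta`, `operons`, `growth`), `preprocess` (`floor`,
#' `var_threshold`), `select` (`n_genes`, `population`, `elite_frac`,
#' `cycles`, `n_repeats`, `stratify`), and a top-level `seed`.  Unknown
#' keys are rejected.
#'
#' @param config path to a YAML file, or a list.
#' @param outdir output directory, created if needed.
#' @return invisibly, a list with the in-memory results (`expr`, `X`,
#'   `growth`, `selection`, `frequency`, `uncertainty`).
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- c("simulate", "inputs", "preprocess", "select", "seed")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown configuration key: ", unknown[1], call. = FALSE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  pp <- config$preprocess
  floor_v <- if (is.null(pp$floor)) 100 else pp$floor
  var_thr <- if (is.null(pp$var_threshold)) 0.01 else pp$var_threshold
  sel <- config$select
  if (is.null(sel$n_genes)) stop("select$n_genes is required", call. = FALSE)
  population <- if (is.null(sel$population)) 1000 else sel$population
  elite_frac <- if (is.null(sel$elite_frac)) 0.05 else sel$elite_frac
  cycles <- if (is.null(sel$cycles)) 300 else sel$cycles
  n_repeats <- if (is.null(sel$n_repeats)) 10 else sel$n_repeats
  stratify <- if (is.null(sel$stratify)) TRUE else sel$stratify
  check_ga_config(population, elite_frac, cycles, 1, 1)  # bounds only

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    dn <- intersect(names(sim_args), names(formals(simulation_design)))
    design <- do.call(simulation_design, sim_args[dn])
    tn <- setdiff(intersect(names(sim_args),
                            names(formals(synthetic_truth))),
                  c("design", "operons", "seed"))
    gnf <- sim_args$growth_noise_frac
    sim <- do.call(simulate_dataset,
                   c(list(design = design, seed = seed,
                          growth_noise_frac = gnf, floor = floor_v,
                          var_threshold = var_thr), sim_args[tn]))
    expr <- sim$expr; operons <- sim$operons
    growth <- sim$growth; prep <- sim$prep
    write_expression(expr, file.path(outdir, "expression.tsv"),
                     file.path(outdir, "samples.tsv"), seed = seed)
    write_operon_map(operons, file.path(outdir, "operons.tsv"), seed = seed)
    write_growth_table(growth, file.path(outdir, "growth_changes.tsv"),
                       seed = seed)
    jsonlite::write_json(
      list(planted_genes = sim$truth$planted_genes,
           alpha_true = sim$truth$alpha_true,
           beta_true = as.list(sim$truth$beta_true),
           noise_sd_growth = sim$truth$noise_sd_growth,
           seed = sim$truth$seed),
      file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    expr <- read_expression(inp$expression, inp$meta)
    operons <- read_operon_map(inp$operons)
    growth <- read_growth_changes(inp$growth)
    prep <- preprocess_expression(expr, operons, floor = floor_v,
                                  var_threshold = var_thr)
  } else {
    stop("configuration needs a `simulate` or `inputs` block",
         call. = FALSE)
  }
  X <- prep$X
  write_tsv_matrix(X, file.path(outdir, "X.tsv"), "gene_id", seed = seed)
  jsonlite::write_json(as.list(prep$report),
                       file.path(outdir, "filter_report.json"),
                       auto_unbox = TRUE)

  strains <- intersect(colnames(X), rownames(growth))
  part <- cv_partition(strains, k = 5,
                       stratify_by = if (stratify) strain_stress(strains),
                       seed = derive_seed(seed, 21))
  ev <- evaluate_partition(X, growth, part, sel$n_genes, population,
                           elite_frac, cycles, seed = derive_seed(seed, 22))
  freq <- selection_frequency(X, growth, sel$n_genes,
                              n_repeats = n_repeats,
                              population = population,
                              elite_frac = elite_frac, cycles = cycles,
                              stratify = stratify,
                              seed = derive_seed(seed, 23))
  unc <- prediction_with_uncertainty(X, growth, sel$n_genes,
                                     n_repeats = max(2, n_repeats),
                                     population = population,
                                     elite_frac = elite_frac,
                                     cycles = cycles, stratify = stratify,
                                     seed = derive_seed(seed, 24))

  best <- lapply(ev$folds, function(f)
    list(genes = f$genes, fitness = f$fitness, test_R = f$test_R))
  jsonlite::write_json(list(per_fold = best, pooled_test_R = ev$test_R),
                       file.path(outdir, "best_sets.json"),
                       auto_unbox = TRUE, digits = NA)
  traces <- vapply(ev$folds, `[[`, numeric(length(ev$folds[[1]]$trace)),
                   "trace")
  rownames(traces) <- seq_len(nrow(traces)) - 1L
  write_tsv_matrix(traces, file.path(outdir, "fitness_traces.tsv"),
                   "cycle", seed = seed)
  con <- file(file.path(outdir, "selection_frequency.tsv"), "w")
  writeLines(comment_header(seed), con)
  write.table(freq$freq, con, sep = "\t", quote = FALSE,
              row.names = FALSE)
  close(con)
  write_tsv_matrix(unc$mean, file.path(outdir, "prediction_mean.tsv"),
                   "strain_id", seed = seed)
  write_tsv_matrix(unc$sd, file.path(outdir, "prediction_sd.tsv"),
                   "strain_id", seed = seed)
  yaml::write_yaml(config, file.path(outdir, "config_resolved.yaml"))
  invisible(list(expr = expr, X = X, growth = growth, selection = ev,
                 frequency = freq, uncertainty = unc))
}
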