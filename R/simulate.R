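#' Describe a synthetic laboratory-evolution study
#'
#' The generator emulates the design of a stress-evolution experiment:
#' `n_stresses` stress conditions with `n_lines_per_stress` independently
#' evolved resistant strains each (defaults 11 and 5, i.e. 55 resistant
#' strains), plus the shared parental strain.  Each resistant strain is
#' assayed by expression profiling under its own evolution stress; the
#' parent is assayed under every stress, in `n_replicates` biological
#' replicates.  A fraction `frac_low_expression` of genes sits below the
#' 100 a.u. quantification floor in every sample, and genes are grouped
#' into operons whose sizes follow `operon_size_distribution`.
#'
#' @param n_stresses number of stress conditions.
#' @param n_lines_per_stress parallel evolved lines per stress.
#' @param n_genes size of the gene universe.
#' @param n_replicates biological replicates per (strain, stress) assay.
#' @param operon_size_distribution data frame with columns `size` and
#'   `prob` (probabilities summing to 1); default approximates bacterial
#'   operon-length statistics (mean just under 2 genes per operon).
#' @param frac_low_expression fraction of genes kept below the intensity
#'   floor in all samples, in `[0, 1)`.
#' @param seed integer seed driving the structural draws.
#' @return an object of class `simulation_design`.
#' @export
simulation_design <- function(n_stresses = 11, n_lines_per_stress = 5,
                              n_genes = 1000, n_replicates = 3,
                              operon_size_distribution = data.frame(
                                size = 1:5,
                                prob = c(0.55, 0.20, 0.12, 0.08, 0.05)),
                              frac_low_expression = 0.4,
                              seed = 1L) {
  stopifnot(n_stresses >= 1, n_lines_per_stress >= 1, n_genes >= 1,
            n_replicates >= 1)
  d <- operon_size_distribution
  if (!is.data.frame(d) || !all(c("size", "prob") %in% names(d)) ||
      any(d$size < 1) || any(d$prob < 0))
    stop("operon_size_distribution needs columns size >= 1 and prob >= 0",
         call. = FALSE)
  if (abs(sum(d$prob) - 1) > 1e-9)
    stop("operon size probabilities must sum to 1", call. = FALSE)
  if (frac_low_expression < 0 || frac_low_expression >= 1)
    stop("frac_low_expression must be in [0, 1)", call. = FALSE)
  structure(list(n_stresses = as.integer(n_stresses),
                 n_lines_per_stress = as.integer(n_lines_per_stress),
                 n_genes = as.integer(n_genes),
                 n_replicates = as.integer(n_replicates),
                 operon_size_distribution = d,
                 frac_low_expression = frac_low_expression,
                 seed = as.integer(seed)),
            class = "simulation_design")
}

design_gene_ids <- function(design)
  sprintf("g%04d", seq_len(design$n_genes))

design_stress_ids <- function(design)
  sprintf("S%02d", seq_len(design$n_stresses))

design_strain_ids <- function(design) {
  as.vector(t(outer(design_stress_ids(design),
                    seq_len(design$n_lines_per_stress),
                    function(s, l) paste0(s, "_r", l))))
}

#' Evolution stress encoded in a generated strain id
#'
#' Synthetic strain ids have the form `<stress>_r<line>`; this strips the
#' line suffix, recovering the stress the strain evolved under (useful as
#' a stratification factor for partitioning).
#'
#' @param strain character vector of strain ids.
#' @return character vector of stress ids.
#' @export
strain_stress <- function(strain) sub("_r[0-9]+$", "", strain)

#' Generate a gene-to-operon map
#'
#' Operon sizes are drawn i.i.d. from the design's size distribution and
#' consecutive gene ids are grouped until the universe is exhausted (the
#' final operon is truncated to fit).  Every gene belongs to exactly one
#' operon.
#'
#' @param design a [simulation_design].
#' @return data frame with columns `gene_id`, `operon_id`.
#' @export
generate_operon_map <- function(design) {
  stopifnot(inherits(design, "simulation_design"))
  local_seed(derive_seed(design$seed, 1))
  d <- design$operon_size_distribution
  n <- design$n_genes
  # draw enough sizes in blocks, then cut at n genes
  sizes <- integer(0)
  while (sum(sizes) < n) {
    k <- max(16L, ceiling((n - sum(sizes)) / max(1, sum(d$size * d$prob))))
    draw <- sample.int(nrow(d), k, replace = TRUE, prob = d$prob)
    sizes <- c(sizes, d$size[draw])
  }
  keep <- which(cumsum(sizes) >= n)[1]
  sizes <- sizes[seq_len(keep)]
  sizes[keep] <- sizes[keep] - (sum(sizes) - n)
  sizes <- sizes[sizes > 0]
  data.frame(gene_id = design_gene_ids(design),
             operon_id = rep(sprintf("op%04d", seq_along(sizes)), sizes),
             stringsAsFactors = FALSE)
}

#' Plant the ground truth of a synthetic study
#'
#' Fixes the planted informative genes and the per-stress linear-model
#' coefficients used to generate growth-rate changes, together with the
#' noise scales of the generator.  Planted genes are sampled from
#' singleton operons (so the operon-representative filter retains them)
#' among the expressed fraction of the gene universe.
#'
#' Noise scales, all on the log10-intensity scale unless noted:
#' `expr_noise_sd` is the independent per-gene replicate noise and
#' `operon_sd` the per-operon-per-sample shared latent; their defaults
#' (0.02 each) calibrate replicate reproducibility so that more than 99%
#' of replicate expression ratios fall within 1.3-fold.  `effect_sd` and
#' `strain_effect_sd` are the stress-level and strain-level expression
#' shifts of planted genes in resistant strains; `stress_shift_sd` and
#' `strain_shift_sd` are the diffuse shifts of all other expressed genes,
#' which make gene selection a nontrivial discrimination problem and make
#' strains cluster by evolution stress.  `noise_sd_growth` (1/h) is the
#' additive Gaussian noise on growth-rate changes.
#'
#' @param design a [simulation_design].
#' @param operons operon map from [generate_operon_map()].
#' @param n_planted number of planted informative genes.
#' @param alpha_sd sd of the per-stress coefficients over planted genes
#'   (growth change, 1/h, per unit standardized expression change).
#' @param beta_sd sd of per-stress intercepts (1/h).
#' @param effect_sd,strain_effect_sd planted-gene shift scales (log10).
#' @param stress_shift_sd,strain_shift_sd diffuse shift scales (log10).
#' @param operon_sd,expr_noise_sd measurement-noise scales (log10).
#' @param noise_sd_growth sd of growth-change noise (1/h).
#' @param seed integer seed.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(design, operons, n_planted = 5,
                            alpha_sd = 0.07, beta_sd = 0.02,
                            effect_sd = 0.3, strain_effect_sd = 0.1,
                            stress_shift_sd = 0.1, strain_shift_sd = 0.05,
                            operon_sd = 0.02, expr_noise_sd = 0.02,
                            noise_sd_growth = 0.02, seed = 1L) {
  stopifnot(inherits(design, "simulation_design"),
            noise_sd_growth >= 0, expr_noise_sd >= 0, operon_sd >= 0)
  operons <- validate_operon_map(operons)
  local_seed(derive_seed(seed, 2))
  low_n <- round(design$frac_low_expression * design$n_genes)
  # expressed genes occupy the head of the id order of the shuffled low set;
  # low genes are designated later by generate_expression with the same
  # design substream, so reproduce that draw here to avoid planting there.
  low_genes <- designated_low_genes(design)
  singleton <- operons$operon_id %in%
    names(which(table(operons$operon_id) == 1))
  pool <- setdiff(operons$gene_id[singleton], low_genes)
  if (length(pool) < n_planted)
    stop("not enough expressed singleton-operon genes to plant", call. = FALSE)
  planted <- sort(sample(pool, n_planted))
  k <- design$n_stresses
  alpha <- matrix(rnorm(k * n_planted, 0, alpha_sd), k, n_planted,
                  dimnames = list(design_stress_ids(design), planted))
  beta <- setNames(rnorm(k, 0, beta_sd), design_stress_ids(design))
  structure(list(planted_genes = planted, alpha_true = alpha,
                 beta_true = beta, effect_sd = effect_sd,
                 strain_effect_sd = strain_effect_sd,
                 stress_shift_sd = stress_shift_sd,
                 strain_shift_sd = strain_shift_sd,
                 operon_sd = operon_sd, expr_noise_sd = expr_noise_sd,
                 noise_sd_growth = noise_sd_growth,
                 seed = as.integer(seed)),
            class = "synthetic_truth")
}

# Which genes are below the quantification floor in every sample.
# Deterministic in the design seed; shared between synthetic_truth() and
# generate_expression().
designated_low_genes <- function(design) {
  local_seed(derive_seed(design$seed, 3))
  n_low <- round(design$frac_low_expression * design$n_genes)
  sort(sample(design_gene_ids(design), n_low))
}

#' Generate a synthetic expression matrix
#'
#' Log10 intensities are a sum of a per-gene baseline, a per-strain shift
#' (the planted and diffuse effects of `truth`), a per-operon-per-sample
#' latent shared by operon members, and independent replicate noise.
#' Expressed genes have baselines in `10^[2.3, 4.5]` a.u.; designated
#' low-expression genes have baselines below 10^1.7 and carry no strain
#' shifts, so they remain under the 100 a.u. floor in every sample.
#' Resistant strains are assayed under their own evolution stress; the
#' parent under every stress.
#'
#' @param design a [simulation_design].
#' @param operons operon map from [generate_operon_map()].
#' @param truth a [synthetic_truth()].
#' @return an [expression_set].
#' @export
generate_expression <- function(design, operons, truth) {
  stopifnot(inherits(design, "simulation_design"),
            inherits(truth, "synthetic_truth"))
  operons <- validate_operon_map(operons)
  genes <- design_gene_ids(design)
  if (!all(truth$planted_genes %in% genes))
    stop("planted gene not in gene universe: ",
         setdiff(truth$planted_genes, genes)[1], call. = FALSE)
  stresses <- design_stress_ids(design)
  strains <- design_strain_ids(design)
  low <- designated_low_genes(design)
  is_low <- genes %in% low
  is_planted <- genes %in% truth$planted_genes

  local_seed(derive_seed(design$seed, 4))
  base <- ifelse(is_low, runif(length(genes), 0.5, 1.7),
                 runif(length(genes), 2.3, 4.5))

  # strain shift matrix (genes x resistant strains), parent has none
  local_seed(derive_seed(truth$seed, 5))
  shift <- matrix(0, length(genes), length(strains),
                  dimnames = list(genes, strains))
  stress_of <- strain_stress(strains)
  diffuse <- which(!is_low & !is_planted)
  u <- matrix(rnorm(length(diffuse) * length(stresses), 0,
                    truth$stress_shift_sd),
              length(diffuse), length(stresses),
              dimnames = list(NULL, stresses))
  shift[diffuse, ] <- u[, stress_of] +
    rnorm(length(diffuse) * length(strains), 0, truth$strain_shift_sd)
  pl <- which(is_planted)
  w <- matrix(rnorm(length(pl) * length(stresses), 0, truth$effect_sd),
              length(pl), length(stresses), dimnames = list(NULL, stresses))
  shift[pl, ] <- w[, stress_of] +
    rnorm(length(pl) * length(strains), 0, truth$strain_effect_sd)

  # samples: parent under all stresses, each strain under its own stress
  meta <- rbind(
    expand.grid(strain_id = PARENT_ID, assay_stress = stresses,
                replicate = seq_len(design$n_replicates),
                stringsAsFactors = FALSE),
    expand.grid(strain_id = strains, replicate = seq_len(design$n_replicates),
                stringsAsFactors = FALSE)[, c(1, 2)] |>
      (\(d) data.frame(strain_id = d$strain_id,
                       assay_stress = strain_stress(d$strain_id),
                       replicate = d$replicate))())
  meta$evolution_stress <- ifelse(meta$strain_id == PARENT_ID, "none",
                                  strain_stress(meta$strain_id))
  meta$sample_id <- paste(meta$strain_id, meta$assay_stress,
                          paste0("rep", meta$replicate), sep = ".")
  meta <- meta[c("sample_id", "strain_id", "evolution_stress",
                 "assay_stress", "replicate")]

  op_of <- operons$operon_id[match(genes, operons$gene_id)]
  op_ids <- unique(op_of)
  n_s <- nrow(meta)
  lat <- matrix(rnorm(length(op_ids) * n_s, 0, truth$operon_sd),
                length(op_ids), n_s, dimnames = list(op_ids, NULL))
  eps <- matrix(rnorm(length(genes) * n_s, 0, truth$expr_noise_sd),
                length(genes), n_s)
  sh <- matrix(0, length(genes), n_s)
  res <- meta$strain_id != PARENT_ID
  sh[, res] <- shift[, meta$strain_id[res], drop = FALSE]
  logi <- base + sh + lat[op_of, , drop = FALSE] + eps
  values <- 10^logi
  # contract: designated low genes stay under the floor in every sample
  values[is_low, ] <- pmin(values[is_low, , drop = FALSE], 99.9)
  dimnames(values) <- list(genes, meta$sample_id)
  expression_set(values, meta)
}

#' Generate growth-rate changes from planted linear structure
#'
#' Applies the planted linear model to a standardized expression-change
#' matrix: for strain j and stress k, the growth change is
#' `sum_i alpha[k, i] * X[i, j] + beta[k]` plus Gaussian noise with sd
#' `truth$noise_sd_growth`.
#'
#' @param X standardized change matrix (genes x strains), e.g. from
#'   [preprocess_expression()].
#' @param truth a [synthetic_truth()].
#' @param noise_sd_growth overrides `truth$noise_sd_growth` when given.
#' @return strains-by-stresses matrix of growth-rate changes (1/h).
#' @export
generate_growth_changes <- function(X, truth, noise_sd_growth = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  missing_genes <- setdiff(truth$planted_genes, rownames(X))
  if (length(missing_genes))
    stop("planted gene missing from X: ", missing_genes[1], call. = FALSE)
  sdg <- if (is.null(noise_sd_growth)) truth$noise_sd_growth else noise_sd_growth
  Xp <- X[truth$planted_genes, , drop = FALSE]
  dg <- t(Xp) %*% t(truth$alpha_true) +
    matrix(truth$beta_true, ncol(X), length(truth$beta_true), byrow = TRUE)
  local_seed(derive_seed(truth$seed, 6))
  dg <- dg + rnorm(length(dg), 0, sdg)
  dimnames(dg) <- list(colnames(X), names(truth$beta_true))
  dg
}

#' Replicate-reproducibility of a synthetic (or real) expression set
#'
#' Fraction of gene-wise expression ratios between biological replicates
#' of the same (strain, assay stress) that fall within `fold`-fold, over
#' genes above the quantification floor (low-expression genes are
#' excluded first, as reproducibility is only assessed on quantifiable
#' signal).
#'
#' @param expr an [expression_set].
#' @param fold fold-change window (default 1.3).
#' @param floor intensity floor in a.u. (default 100).
#' @return fraction in `[0, 1]`.
#' @export
replicate_ratio_fraction <- function(expr, fold = 1.3, floor = 100) {
  stopifnot(inherits(expr, "expression_set"))
  keep <- apply(expr$values, 1, max) >= floor
  v <- expr$values[keep, , drop = FALSE]
  grp <- paste(expr$meta$strain_id, expr$meta$assay_stress)
  n_in <- 0; n_tot <- 0
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2) next
    pairs <- combn(idx, 2)
    for (p in seq_len(ncol(pairs))) {
      r <- v[, pairs[1, p]] / v[, pairs[2, p]]
      n_in <- n_in + sum(r >= 1 / fold & r <= fold)
      n_tot <- n_tot + length(r)
    }
  }
  if (n_tot == 0) stop("no replicate pairs found", call. = FALSE)
  n_in / n_tot
}

#' Simulate a complete synthetic study
#'
#' Convenience wrapper chaining [generate_operon_map()],
#' [synthetic_truth()], [generate_expression()], the preprocessing
#' pipeline, and [generate_growth_changes()].  Growth noise can be set
#' as a fraction of the noise-free signal sd via `growth_noise_frac`
#' (overriding `noise_sd_growth`).
#'
#' @param design a [simulation_design].
#' @param seed master seed; substreams are derived for each stage.
#' @param growth_noise_frac if non-NULL, growth noise sd is this fraction
#'   of the sd of the noise-free planted growth signal.
#' @param floor,var_threshold preprocessing parameters, see
#'   [preprocess_expression()].
#' @param ... passed to [synthetic_truth()].
#' @return list with elements `design`, `operons`, `truth`, `expr`,
#'   `prep` (preprocessing result), `X`, and `growth` (changes matrix).
#' @export
simulate_dataset <- function(design = simulation_design(), seed = 1L,
                             growth_noise_frac = NULL, floor = 100,
                             var_threshold = 0.01, ...) {
  design$seed <- as.integer(seed)
  operons <- generate_operon_map(design)
  truth <- synthetic_truth(design, operons, seed = derive_seed(seed, 11), ...)
  expr <- generate_expression(design, operons, truth)
  prep <- preprocess_expression(expr, operons, floor = floor,
                                var_threshold = var_threshold)
  X <- prep$X
  if (!is.null(growth_noise_frac)) {
    signal <- generate_growth_changes(X, truth, noise_sd_growth = 0)
    truth$noise_sd_growth <- growth_noise_frac * sd(signal)
  }
  growth <- generate_growth_changes(X, truth)
  list(design = design, operons = operons, truth = truth, expr = expr,
       prep = prep, X = X, growth = growth)
}
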