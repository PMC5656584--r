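#' Random 5-fold partition of strains
#'
#' Strains are randomly partitioned into `k` subgroups whose sizes
#' differ by at most one.  With stratification (the default when
#' `stratify_by` is supplied), each stress's strains are spread across
#' folds as evenly as possible, which guarantees that every stress
#' retains training strains in every fold.
#'
#' @param strains character vector of strain ids.
#' @param k number of folds (default 5).
#' @param stratify_by optional factor (e.g. evolution stress) of the
#'   same length as `strains`; `NULL` for a plain random partition.
#' @param seed integer seed.
#' @return named integer vector mapping each strain to a fold in `1..k`.
#' @export
cv_partition <- function(strains, k = 5, stratify_by = NULL, seed = NULL) {
  n <- length(strains)
  if (k > n) stop("more folds than strains", call. = FALSE)
  local_seed(seed)
  fold <- integer(n)
  names(fold) <- strains
  if (is.null(stratify_by)) {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  } else {
    stopifnot(length(stratify_by) == n)
    offset <- 0L
    for (g in unique(stratify_by)) {
      idx <- which(stratify_by == g)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
      offset <- offset + length(idx)
    }
  }
  fold
}

check_ga_config <- function(population, elite_frac, cycles, n_genes, pool) {
  if (population < 1) stop("population must be >= 1", call. = FALSE)
  if (elite_frac <= 0 || elite_frac > 1)
    stop("elite_frac must be in (0, 1]", call. = FALSE)
  n_elite <- round(population * elite_frac)
  if (n_elite < 1)
    stop("round(population * elite_frac) must be >= 1", call. = FALSE)
  if (cycles < 0) stop("cycles must be >= 0", call. = FALSE)
  if (n_genes > pool)
    stop("gene-set size ", n_genes, " exceeds candidate pool of ", pool,
         call. = FALSE)
  as.integer(n_elite)
}

train_matrices <- function(X, growth, train_strains) {
  missing_strains <- setdiff(train_strains, colnames(X))
  if (length(missing_strains))
    stop("strain not in X: ", missing_strains[1], call. = FALSE)
  list(Xc = X[, train_strains, drop = FALSE],
       Y = growth[train_strains, , drop = FALSE])
}

#' Gene-set selection by a crossover-free genetic algorithm
#'
#' Searches for the N-gene set whose linear growth model best fits the
#' training strains, scored by the pooled Pearson correlation between
#' fitted and observed growth changes.  The population starts from
#' `population` random N-gene sets; each cycle the top `elite_frac` by
#' fitness are kept as parents (elitism: they pass unchanged into the
#' next population) and every remaining slot is filled with a mutant of
#' a uniformly chosen parent, formed by replacing one uniformly chosen
#' member gene with a uniformly chosen non-member.  There is no
#' crossover.  Defaults follow the original protocol (population 1000,
#' top 5%, 300 cycles).
#'
#' @param X standardized change matrix (genes x strains); its rows are
#'   the candidate pool.
#' @param growth strains-by-stresses growth-change matrix.
#' @param train_strains training strains.
#' @param n_genes gene-set size N.
#' @param population population size.
#' @param elite_frac fraction of the population kept as parents.
#' @param cycles number of mutation-selection cycles.
#' @param seed integer seed.
#' @return object of class `ga_selection`: `genes` (the best set found),
#'   `fitness`, and `trace` (best fitness after initialization and after
#'   each cycle; non-decreasing).
#' @export
ga_select <- function(X, growth, train_strains = colnames(X), n_genes,
                      population = 1000, elite_frac = 0.05, cycles = 300,
                      seed = NULL) {
  n_elite <- check_ga_config(population, elite_frac, cycles, n_genes,
                             nrow(X))
  tm <- train_matrices(X, growth, train_strains)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max - 1, 1)
  res <- ga_search_cpp(tm$Xc, tm$Y, as.integer(n_genes),
                       as.integer(population), n_elite, as.integer(cycles),
                       as.integer(seed))
  structure(list(genes = rownames(X)[res$best], fitness = res$fitness,
                 trace = as.numeric(res$trace), n_genes = n_genes,
                 seed = as.integer(seed)),
            class = "ga_selection")
}

#' @export
print.ga_selection <- function(x, ...) {
  cat("GA gene-set selection: N =", x$n_genes,
      " fitness =", format(x$fitness, digits = 4), "\n")
  cat("  genes:", paste(sort(x$genes), collapse = ", "), "\n")
  invisible(x)
}

#' Exhaustive gene-set selection (enumeration oracle)
#'
#' Scores every N-subset of the candidate pool with the same fitness as
#' [ga_select()] and returns the global optimum.  Ties break to the
#' lexicographically smallest gene combination.  Intended as an oracle
#' for small pools.
#'
#' @inheritParams ga_select
#' @param enumeration_cap refuse to enumerate more than this many sets.
#' @return list with `genes` and `fitness`.
#' @export
exhaustive_select <- function(X, growth, train_strains = colnames(X),
                              n_genes, enumeration_cap = 1e6) {
  pool <- nrow(X)
  n_sets <- choose(pool, n_genes)
  if (n_sets > enumeration_cap)
    stop("enumeration of ", format(n_sets), " sets exceeds cap of ",
         format(enumeration_cap), call. = FALSE)
  tm <- train_matrices(X, growth, train_strains)
  ord <- order(rownames(X))          # lexicographic over gene ids
  sets <- combn(ord, n_genes)
  fit <- fitness_sets_cpp(tm$Xc, tm$Y, sets)
  best <- which.max(fit)             # first max = lexicographically smallest
  list(genes = rownames(X)[sets[, best]], fitness = fit[best])
}

#' Training fitness of explicit gene sets
#'
#' The pooled-correlation fitness that [ga_select()] maximizes, for one
#' or more explicit gene sets.
#'
#' @inheritParams ga_select
#' @param gene_sets a character vector (one set) or list of character
#'   vectors.
#' @return numeric vector of fitness values.
#' @export
set_fitness <- function(X, growth, train_strains = colnames(X), gene_sets) {
  if (!is.list(gene_sets)) gene_sets <- list(gene_sets)
  tm <- train_matrices(X, growth, train_strains)
  idx <- vapply(gene_sets, function(g) match(g, rownames(X)),
                integer(length(gene_sets[[1]])))
  if (anyNA(idx)) stop("gene not in X", call. = FALSE)
  as.numeric(fitness_sets_cpp(tm$Xc, tm$Y, as.matrix(idx)))
}

#' Cross-validated evaluation of one partition
#'
#' For each fold: run the GA on the other folds, refit the linear model
#' with the chosen genes on those training strains, and predict the
#' held-out strains.  Held-out strains never influence gene choice or
#' coefficients.
#'
#' @inheritParams ga_select
#' @param partition fold assignment from [cv_partition()].
#' @return object of class `cv_evaluation`: per-fold list (`genes`,
#'   `fit`, `test_R`, `predictions`), plus `predictions` (full
#'   strains-by-stresses matrix of held-out predictions) and `test_R`
#'   (pooled over all held-out cells).
#' @export
evaluate_partition <- function(X, growth, partition, n_genes,
                               population = 1000, elite_frac = 0.05,
                               cycles = 300, seed = NULL) {
  strains <- names(partition)
  pred <- matrix(NA_real_, length(strains), ncol(growth),
                 dimnames = list(strains, colnames(growth)))
  folds <- sort(unique(partition))
  per_fold <- vector("list", length(folds))
  names(per_fold) <- paste0("fold", folds)
  for (f in seq_along(folds)) {
    test <- strains[partition == folds[f]]
    train <- setdiff(strains, test)
    sel <- ga_select(X, growth, train, n_genes, population, elite_frac,
                     cycles, seed = derive_seed(seed, f))
    fit <- growth_model(X, growth, genes = sel$genes, strains = train)
    p <- predict(fit, X, test)
    pred[test, ] <- p
    obs <- growth[test, , drop = FALSE]
    r <- tryCatch(pooled_correlation(p, obs), error = function(e) NA_real_)
    per_fold[[f]] <- list(genes = sel$genes, fitness = sel$fitness,
                          trace = sel$trace, fit = fit, test_R = r,
                          predictions = p)
  }
  structure(list(folds = per_fold, predictions = pred,
                 test_R = pooled_correlation(pred, growth[strains, ,
                                                          drop = FALSE]),
                 n_genes = n_genes),
            class = "cv_evaluation")
}

#' @export
print.cv_evaluation <- function(x, ...) {
  cat("5-fold cross-validated evaluation, N =", x$n_genes, "\n")
  cat("  pooled held-out R:", format(x$test_R, digits = 4), "\n")
  cat("  per-fold R:",
      paste(format(vapply(x$folds, `[[`, numeric(1), "test_R"),
                   digits = 3), collapse = " "), "\n")
  invisible(x)
}

#' Held-out accuracy as a function of gene-set size
#'
#' For each candidate N, repeats `n_repeats` random 5-fold partitions,
#' evaluates each with [evaluate_partition()], and averages the pooled
#' held-out correlation.  Too few genes underfit (the linear combination
#' cannot represent the resistance changes); too many overfit and
#' held-out accuracy declines, so the mean curve has an interior
#' optimum.
#'
#' @inheritParams ga_select
#' @param n_values integer vector of gene-set sizes to try.
#' @param n_repeats partitions per N.
#' @param k folds.
#' @param stratify stratify partitions by evolution stress (the stress
#'   encoded in strain ids via the synthetic generator, or supplied as a
#'   vector through `stratify_by`).
#' @param stratify_by optional explicit stratification factor.
#' @return object of class `gene_sweep`: data frame `summary` (`n_genes`,
#'   `mean_R`, `sd_R`), matrix `R` (repeats x N values), and `best_n`.
#' @export
sweep_gene_count <- function(X, growth, n_values, n_repeats = 10,
                             population = 1000, elite_frac = 0.05,
                             cycles = 300, k = 5, stratify = TRUE,
                             stratify_by = NULL, seed = NULL) {
  stopifnot(length(n_values) >= 1, n_repeats >= 1)
  strains <- intersect(colnames(X), rownames(growth))
  if (stratify && is.null(stratify_by))
    stratify_by <- strain_stress(strains)
  R <- matrix(NA_real_, n_repeats, length(n_values),
              dimnames = list(NULL, n_values))
  for (r in seq_len(n_repeats)) {
    part <- cv_partition(strains, k = k,
                         stratify_by = if (stratify) stratify_by else NULL,
                         seed = derive_seed(seed, 1000 + r))
    for (i in seq_along(n_values)) {
      ev <- evaluate_partition(X, growth, part, n_values[i], population,
                               elite_frac, cycles,
                               seed = derive_seed(seed, r * 100 + i))
      R[r, i] <- ev$test_R
    }
  }
  summary <- data.frame(n_genes = n_values, mean_R = colMeans(R),
                        sd_R = apply(R, 2, sd))
  structure(list(summary = summary, R = R,
                 best_n = n_values[which.max(summary$mean_R)]),
            class = "gene_sweep")
}

#' @export
print.gene_sweep <- function(x, ...) {
  cat("Gene-count sweep (held-out pooled R):\n")
  print(transform(x$summary, mean_R = round(mean_R, 3),
                  sd_R = round(sd_R, 3)), row.names = FALSE)
  cat("best N:", x$best_n, "\n")
  invisible(x)
}

#' @export
plot.gene_sweep <- function(x, ...) {
  s <- x$summary
  plot(s$n_genes, s$mean_R, type = "b", log = "x",
       xlab = "genes in set (N)", ylab = "mean held-out R", ...)
  arrows(s$n_genes, s$mean_R - s$sd_R, s$n_genes, s$mean_R + s$sd_R,
         angle = 90, code = 3, length = 0.03)
  invisible(x)
}

#' Gene selection frequency over repeated training sets
#'
#' Repeats the GA on `n_repeats` different training datasets, each
#' obtained by randomly partitioning the strains into `k` subgroups and
#' training on `k - 1` of them, and counts how often each gene appears
#' in the best set — a measure of how informative its expression change
#' is for resistance.
#'
#' @inheritParams sweep_gene_count
#' @param n_repeats number of independent training partitions.
#' @return object of class `selection_frequency`: data frame `freq`
#'   (`gene`, `count`, sorted by decreasing count), plus `n_repeats` and
#'   `n_genes`.
#' @export
selection_frequency <- function(X, growth, n_genes, n_repeats = 10000,
                                population = 1000, elite_frac = 0.05,
                                cycles = 300, k = 5, stratify = TRUE,
                                stratify_by = NULL, seed = NULL) {
  stopifnot(n_repeats >= 1)
  strains <- intersect(colnames(X), rownames(growth))
  if (stratify && is.null(stratify_by))
    stratify_by <- strain_stress(strains)
  counts <- setNames(integer(nrow(X)), rownames(X))
  for (r in seq_len(n_repeats)) {
    part <- cv_partition(strains, k = k,
                         stratify_by = if (stratify) stratify_by else NULL,
                         seed = derive_seed(seed, 2000 + r))
    train <- names(part)[part != 1L]
    sel <- ga_select(X, growth, train, n_genes, population, elite_frac,
                     cycles, seed = derive_seed(seed, 3000 + r))
    counts[sel$genes] <- counts[sel$genes] + 1L
  }
  freq <- data.frame(gene = names(counts), count = as.integer(counts),
                     row.names = NULL)
  freq <- freq[order(-freq$count, freq$gene), ]
  structure(list(freq = freq, n_repeats = n_repeats, n_genes = n_genes),
            class = "selection_frequency")
}

#' @export
print.selection_frequency <- function(x, n = 10, ...) {
  cat("Gene selection frequency over", x$n_repeats,
      "training partitions (N =", x$n_genes, "):\n")
  print(head(x$freq, n), row.names = FALSE)
  invisible(x)
}

#' Held-out predictions with uncertainty over repeated partitions
#'
#' Every repeat draws a fresh partition and predicts each strain once
#' (from the fold in which it is held out); across repeats this yields a
#' distribution of held-out predictions per (strain, stress) cell, whose
#' mean and sd are reported (the sd is the error bar of the prediction).
#'
#' @inheritParams sweep_gene_count
#' @param n_repeats number of partitions (at least 2).
#' @return list with matrices `mean` and `sd` (strains x stresses) and
#'   `n_repeats`.
#' @export
prediction_with_uncertainty <- function(X, growth, n_genes, n_repeats = 10,
                                        population = 1000,
                                        elite_frac = 0.05, cycles = 300,
                                        k = 5, stratify = TRUE,
                                        stratify_by = NULL, seed = NULL) {
  stopifnot(n_repeats >= 2)
  strains <- intersect(colnames(X), rownames(growth))
  if (stratify && is.null(stratify_by))
    stratify_by <- strain_stress(strains)
  acc <- array(NA_real_, c(length(strains), ncol(growth), n_repeats),
               dimnames = list(strains, colnames(growth), NULL))
  for (r in seq_len(n_repeats)) {
    part <- cv_partition(strains, k = k,
                         stratify_by = if (stratify) stratify_by else NULL,
                         seed = derive_seed(seed, 4000 + r))
    ev <- evaluate_partition(X, growth, part, n_genes, population,
                             elite_frac, cycles,
                             seed = derive_seed(seed, 5000 + r))
    acc[, , r] <- ev$predictions[strains, , drop = FALSE]
  }
  list(mean = apply(acc, c(1, 2), mean),
       sd = apply(acc, c(1, 2), sd),
       n_repeats = n_repeats)
}
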