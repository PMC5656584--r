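test_that("cv partitions have balanced folds and are seed-deterministic", {
  strains <- sprintf("x%02d", 1:55)
  p <- cv_partition(strains, k = 5, seed = 1)
  expect_identical(as.integer(table(p)), rep(11L, 5))
  expect_setequal(names(p), strains)

  # n = k: singleton folds (leave-one-out structure)
  p5 <- cv_partition(strains[1:5], k = 5, seed = 2)
  expect_identical(sort(as.integer(table(p5))), rep(1L, 5))

  expect_identical(cv_partition(strains, seed = 9),
                   cv_partition(strains, seed = 9))
  expect_false(identical(cv_partition(strains, seed = 9),
                         cv_partition(strains, seed = 10)))
  expect_error(cv_partition(strains[1:3], k = 5), "folds")

  # stratified: each stress spread across folds as evenly as possible
  stress <- rep(sprintf("S%02d", 1:11), each = 5)
  ps <- cv_partition(strains, k = 5, stratify_by = stress, seed = 3)
  expect_identical(as.integer(table(ps)), rep(11L, 5))
  for (s in unique(stress))
    expect_identical(as.integer(table(ps[stress == s])), rep(1L, 5))
})

test_that("GA configuration bounds are enforced before any computation", {
  sim <- small_sim()
  expect_error(ga_select(sim$X, sim$growth, n_genes = 5, population = 10,
                         elite_frac = 0, cycles = 5), "elite_frac")
  expect_error(ga_select(sim$X, sim$growth, n_genes = 5, population = 10,
                         elite_frac = 0.001, cycles = 5), "round")
  expect_error(ga_select(sim$X, sim$growth, n_genes = nrow(sim$X) + 1,
                         population = 20, cycles = 5), "pool")
})

test_that("zero cycles returns the best of the initial population", {
  inst <- planted_pair_instance()
  sel <- ga_select(inst$X, inst$dg, n_genes = 2, population = 40,
                   cycles = 0, seed = 4)
  expect_length(sel$trace, 1)
  expect_equal(sel$fitness, sel$trace[1])
  # never better than the enumerated global optimum
  ex <- exhaustive_select(inst$X, inst$dg, n_genes = 2)
  expect_lte(sel$fitness, ex$fitness + 1e-12)
})

test_that("GA finds the planted pair and matches the exhaustive oracle", {
  inst <- planted_pair_instance()
  ex <- exhaustive_select(inst$X, inst$dg, n_genes = 2)
  expect_setequal(ex$genes, inst$planted)
  expect_equal(ex$fitness, 1, tolerance = 1e-10)
  hits <- 0
  for (s in 1:10) {
    sel <- ga_select(inst$X, inst$dg, n_genes = 2, population = 50,
                     cycles = 30, seed = s)
    expect_lte(sel$fitness, ex$fitness + 1e-12)
    expect_false(is.unsorted(sel$trace))
    if (setequal(sel$genes, inst$planted)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("exhaustive selection edge cases behave", {
  inst <- planted_pair_instance()
  # N = pool size: the full pool
  full <- exhaustive_select(inst$X, inst$dg, n_genes = 10)
  expect_setequal(full$genes, rownames(inst$X))
  # N = 1: argmax over marginal single-gene fits
  one <- exhaustive_select(inst$X, inst$dg, n_genes = 1)
  marg <- vapply(rownames(inst$X), function(g)
    set_fitness(inst$X, inst$dg, gene_sets = g), numeric(1))
  expect_identical(one$genes, names(which.max(marg)))
  expect_error(exhaustive_select(inst$X, inst$dg, n_genes = 5,
                                 enumeration_cap = 10), "cap")
})

test_that("kernel fitness equals the R fit/predict/correlation path", {
  sim <- small_sim()
  train <- colnames(sim$X)[seq(1, 55, by = 2)]
  set.seed(21)
  for (i in 1:5) {
    gs <- sample(rownames(sim$X), sample(c(2, 8, 30), 1))
    f_kernel <- set_fitness(sim$X, sim$growth, train, gs)
    fit <- growth_model(sim$X, sim$growth, genes = gs, strains = train)
    f_r <- pooled_correlation(fitted(fit), sim$growth[train, ])
    expect_equal(f_kernel, f_r, tolerance = 1e-10)
  }
})

test_that("cross-validated evaluation isolates held-out strains", {
  inst <- planted_pair_instance(n_strains = 20, seed = 6)
  part <- cv_partition(rownames(inst$dg), k = 5, seed = 7)
  ev <- evaluate_partition(inst$X, inst$dg, part, n_genes = 2,
                           population = 50, cycles = 20, seed = 8)
  # noiseless planted instance: held-out prediction is perfect
  expect_equal(ev$test_R, 1, tolerance = 1e-6)
  expect_false(anyNA(ev$predictions))

  # leakage check: corrupting one held-out strain's growth leaves that
  # fold's gene choice and coefficients unchanged
  test_strain <- names(part)[part == 1][1]
  dg2 <- inst$dg
  dg2[test_strain, ] <- dg2[test_strain, ] + 5
  ev2 <- evaluate_partition(inst$X, dg2, part, n_genes = 2,
                            population = 50, cycles = 20, seed = 8)
  expect_identical(ev2$folds$fold1$genes, ev$folds$fold1$genes)
  expect_equal(coef(ev2$folds$fold1$fit), coef(ev$folds$fold1$fit),
               tolerance = 1e-12)
})

test_that("gene-count sweep reduces to evaluate_partition at one repeat", {
  inst <- planted_pair_instance(n_strains = 20, seed = 9)
  sw <- sweep_gene_count(inst$X, inst$dg, n_values = 2, n_repeats = 1,
                         population = 40, cycles = 10, stratify = FALSE,
                         seed = 30)
  part <- cv_partition(rownames(inst$dg), k = 5, seed = derive_seed(30, 1001))
  ev <- evaluate_partition(inst$X, inst$dg, part, 2, population = 40,
                           cycles = 10, seed = derive_seed(30, 101))
  expect_equal(unname(sw$R[1, 1]), ev$test_R, tolerance = 1e-12)
  expect_identical(sw$best_n, 2)
  expect_output(print(sw), "best N")
})

test_that("selection frequency counts sum to N x repeats", {
  inst <- planted_pair_instance(n_strains = 20, seed = 10)
  freq <- selection_frequency(inst$X, inst$dg, n_genes = 2, n_repeats = 8,
                              population = 50, cycles = 20,
                              stratify = FALSE, seed = 11)
  expect_identical(sum(freq$freq$count), 2L * 8L)
  expect_true(all(freq$freq$count >= 0 & freq$freq$count <= 8))
  # deterministic planted instance: the pair is selected every time
  expect_setequal(freq$freq$gene[freq$freq$count == 8], inst$planted)

  f1 <- selection_frequency(inst$X, inst$dg, n_genes = 2, n_repeats = 1,
                            population = 50, cycles = 20,
                            stratify = FALSE, seed = 12)
  expect_identical(sort(unique(f1$freq$count)), c(0L, 1L))
  expect_identical(sum(f1$freq$count), 2L)
})

test_that("held-out predictions carry near-zero spread on noiseless data", {
  inst <- planted_pair_instance(n_strains = 20, seed = 13)
  unc <- prediction_with_uncertainty(inst$X, inst$dg, n_genes = 2,
                                     n_repeats = 3, population = 50,
                                     cycles = 20, stratify = FALSE,
                                     seed = 14)
  expect_identical(unc$n_repeats, 3)
  expect_false(anyNA(unc$mean))
  expect_lt(max(unc$sd), 1e-6)
  expect_equal(unname(unc$mean), unname(inst$dg), tolerance = 1e-6)
})
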