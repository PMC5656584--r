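test_that("quantile normalization meets its distributional contract", {
  # hand-computed 2x2 example: columns [1,3] and [2,4] both become [1.5, 3.5]
  v <- matrix(c(1, 3, 2, 4), 2, 2, dimnames = list(c("g1", "g2"),
                                                   c("s1", "s2")))
  q <- quantile_normalize(make_expr(v))
  expect_equal(unname(q$values), matrix(c(1.5, 3.5, 1.5, 3.5), 2, 2))

  # single sample: unchanged
  v1 <- matrix(c(5, 1, 3), 3, 1, dimnames = list(paste0("g", 1:3), "s1"))
  expect_equal(quantile_normalize(make_expr(v1))$values, v1)

  # any input: sorted columns identical afterwards, within-sample ranks kept
  set.seed(42)
  v2 <- matrix(10^runif(60, 1, 4), 12, 5,
               dimnames = list(sprintf("g%02d", 1:12), sprintf("s%d", 1:5)))
  q2 <- quantile_normalize(make_expr(v2))$values
  ref <- sort(q2[, 1])
  for (j in 2:5) expect_equal(unname(sort(q2[, j])), unname(ref))
  for (j in 1:5) expect_identical(order(q2[, j]), order(v2[, j]))

  # ties receive the mean of the reference values they span
  vt <- matrix(c(1, 2, 2, 4, 1, 3, 5, 7), 4, 2,
               dimnames = list(paste0("g", 1:4), c("s1", "s2")))
  qt <- quantile_normalize(make_expr(vt))$values
  ref <- rowMeans(apply(vt, 2, sort))
  expect_equal(unname(qt[2:3, "s1"]), rep(mean(ref[2:3]), 2))

  e0 <- make_expr(v)
  e0$values <- e0$values[0, , drop = FALSE]
  expect_error(quantile_normalize(e0), "empty")
})

test_that("low-expression filter keeps a gene iff one sample reaches the floor", {
  v <- rbind(low = c(99, 99, 99), edge = c(99, 100, 1), high = c(500, 2, 3))
  colnames(v) <- paste0("s", 1:3)
  f <- filter_low_expression(make_expr(v))
  expect_identical(rownames(f$values), c("edge", "high"))
  # idempotent
  expect_identical(filter_low_expression(f)$values, f$values)
  # floor = 0 removes nothing (intensities are nonnegative)
  expect_identical(nrow(filter_low_expression(make_expr(v), floor = 0)$values),
                   3L)
})

test_that("expression change is the replicate-averaged ratio to the parent", {
  v <- cbind(p1 = c(100, 200), p2 = c(300, 200),
             r1 = c(400, 800), r2 = c(400, 1200))
  rownames(v) <- c("gA", "gB")
  e <- make_expr(v, strain = c("parent", "parent", "str1", "str1"))
  ch <- expression_change(e, "str1", stress = "S01")
  expect_equal(ch, c(gA = 400 / 200, gB = 1000 / 200))

  # identical strain and parent: all ratios 1
  v4 <- cbind(p = c(10, 20), r = c(10, 20)) * 100
  rownames(v4) <- c("gA", "gB")
  e2 <- make_expr(v4, strain = c("parent", "str1"))
  expect_equal(unname(expression_change(e2, "str1", stress = "S01")),
               c(1, 1))
  # doubled everywhere: all ratios 2
  v5 <- cbind(p = c(10, 20), r = c(20, 40)) * 100
  rownames(v5) <- c("gA", "gB")
  e3 <- make_expr(v5, strain = c("parent", "str1"))
  expect_equal(unname(expression_change(e3, "str1", stress = "S01")),
               c(2, 2))
  expect_error(expression_change(e3, "str1", stress = "S09"), "S09")
})

test_that("planted log10 shifts come through the ratio exactly at zero noise", {
  des <- simulation_design(n_genes = 100, n_stresses = 2,
                           n_lines_per_stress = 2, seed = 31)
  ops <- generate_operon_map(des)
  tr <- synthetic_truth(des, ops, n_planted = 2, operon_sd = 0,
                        expr_noise_sd = 0, strain_effect_sd = 0, seed = 31)
  e <- generate_expression(des, ops, tr)
  g <- tr$planted_genes[1]
  ch <- expression_change(e, "S01_r1")
  # recover the planted stress-level shift for that gene from the ratio
  expect_equal(log10(ch[[g]]), log10(expression_change(e, "S01_r2")[[g]]),
               tolerance = 1e-9)
})

test_that("operon representative is the highest-mean-expression member", {
  v <- rbind(a = c(500, 500), b = c(700, 700), c = c(100, 100))
  colnames(v) <- c("s1", "s2")
  e <- make_expr(v)
  ch <- v * 0   # any per-gene matrix with these rownames
  ops <- data.frame(gene_id = c("a", "b", "c"),
                    operon_id = c("op1", "op1", "op2"))
  out <- operon_representatives(ch, ops, e)
  expect_identical(rownames(out), c("b", "c"))

  # all-singleton map: unchanged
  ops1 <- data.frame(gene_id = c("a", "b", "c"),
                     operon_id = c("o1", "o2", "o3"))
  expect_identical(rownames(operon_representatives(ch, ops1, e)),
                   c("a", "b", "c"))

  # tie on mean expression: lexicographically smallest id wins
  vt <- rbind(z = c(500, 500), a = c(500, 500))
  colnames(vt) <- c("s1", "s2")
  opst <- data.frame(gene_id = c("z", "a"), operon_id = "op1")
  out_t <- operon_representatives(vt * 0, opst, make_expr(vt))
  expect_identical(rownames(out_t), "a")

  expect_error(operon_representatives(ch, ops[-1, ], e), "a")
})

test_that("variance filter drops invariant genes, keeps planted ones", {
  ch <- rbind(flat = c(0, 0, 0), varying = c(-0.5, 0.1, 0.6))
  colnames(ch) <- paste0("s", 1:3)
  expect_identical(rownames(filter_by_variance(ch, 1e-6)), "varying")
  expect_identical(nrow(filter_by_variance(ch, 0)), 2L)
  # parent zero contributes: a constant nonzero change still has variance
  ch2 <- rbind(const = c(0.5, 0.5, 0.5))
  colnames(ch2) <- paste0("s", 1:3)
  expect_identical(nrow(filter_by_variance(ch2, 0.01)), 1L)
  expect_identical(nrow(filter_by_variance(ch2, 0.01,
                                           include_parent = FALSE)), 0L)

  sim <- small_sim()
  expect_true(all(sim$truth$planted_genes %in% rownames(sim$X)))
})

test_that("standardization yields zero mean and unit population sd per gene", {
  # changes [1, 10]: log10 = [0, 1], mean 0.5, population sd 0.5 -> [-1, 1]
  ch <- matrix(log10(c(1, 10)), 1, 2,
               dimnames = list("g", c("s1", "s2")))
  expect_equal(unname(standardize_changes(ch)), matrix(c(-1, 1), 1, 2))

  set.seed(8)
  m <- rand_mat(6, 9)
  X <- standardize_changes(m)
  expect_lt(max(abs(rowMeans(X))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(X^2)) - 1)), 1e-9)
  # location invariance
  expect_equal(standardize_changes(m + 3), X)
  expect_error(standardize_changes(rbind(m, zz = rep(1, 9))), "zz")
})

test_that("pipeline stage counts match construction on synthetic data", {
  sim <- small_sim()
  rep <- sim$prep$report
  expect_identical(unname(rep["input"]), 300L)
  expect_identical(unname(rep["above_floor"]),
                   180L)  # 60% retained by construction
  expect_identical(nrow(sim$X), unname(rep["variance_filtered"]))
  # deterministic pipeline
  again <- preprocess_expression(sim$expr, sim$operons)
  expect_identical(again$X, sim$X)
})
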