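test_that("exact coefficients are recovered from noiseless linear growth", {
  set.seed(10)
  X <- rand_mat(6, 9)
  dg <- cbind(A = 2 * X["g01", ] - 1 * X["g02", ] + 0.5)
  rownames(dg) <- colnames(X)
  fit <- growth_model(X, dg, genes = c("g01", "g02"))
  expect_equal(unname(coef(fit)["A", ]), c(0.5, 2, -1), tolerance = 1e-9)
  expect_equal(fitted(fit), dg, tolerance = 1e-9)
})

test_that("empty gene set reduces to per-stress intercepts", {
  set.seed(11)
  X <- rand_mat(4, 8)
  dg <- matrix(rnorm(16), 8, 2,
               dimnames = list(colnames(X), c("A", "B")))
  fit <- growth_model(X, dg, genes = character(0))
  expect_equal(fit$beta, colMeans(dg))
  expect_equal(unname(predict(fit, X)[1, ]), unname(colMeans(dg)))
})

test_that("OLS matches the normal-equations oracle on random instances", {
  set.seed(12)
  for (i in 1:25) {
    n <- sample(6:10, 1); p <- sample(1:5, 1)
    X <- rand_mat(p, n, seed = 100 + i)
    dg <- matrix(rnorm(2 * n), n, 2,
                 dimnames = list(colnames(X), c("A", "B")))
    fit <- growth_model(X, dg)
    A <- cbind(1, t(X))
    oracle <- solve(crossprod(A), crossprod(A, dg))   # normal equations
    expect_equal(unname(t(coef(fit))), unname(oracle), tolerance = 1e-8)
  }
})

test_that("underdetermined fits return the minimum-norm solution", {
  set.seed(13)
  X <- rand_mat(10, 4)   # 10 genes, 4 strains: 11 params, 4 observations
  dg <- matrix(rnorm(4), 4, 1, dimnames = list(colnames(X), "A"))
  fit <- growth_model(X, dg)
  # interpolates the training data
  expect_equal(fitted(fit), dg, tolerance = 1e-8)
  # minimum-norm: equals the Moore-Penrose solution
  A <- cbind(1, t(X))
  expect_equal(unname(c(coef(fit))), unname(c(MASS::ginv(A) %*% dg)),
               tolerance = 1e-8)
})

test_that("predictions follow the linear formula", {
  set.seed(14)
  X <- rand_mat(5, 7)
  dg <- matrix(rnorm(14), 7, 2, dimnames = list(colnames(X), c("A", "B")))
  fit <- growth_model(X, dg, genes = c("g02", "g04"))
  Xnew <- rand_mat(5, 3, prefix_c = "t")
  pred <- predict(fit, Xnew)
  oracle <- cbind(1, t(Xnew[c("g02", "g04"), ])) %*%
    rbind(fit$beta, t(fit$alpha))
  expect_equal(unname(pred), unname(oracle), tolerance = 1e-10)
  # all-zero expression column predicts the intercept
  Xz <- Xnew; Xz[, 1] <- 0
  expect_equal(unname(predict(fit, Xz)[1, ]), unname(fit$beta))
  expect_error(predict(fit, Xnew[-2, ]), "g02")
})

test_that("residuals are orthogonal to regressors and intercept", {
  set.seed(15)
  X <- rand_mat(3, 12)
  dg <- matrix(rnorm(24), 12, 2, dimnames = list(colnames(X), c("A", "B")))
  fit <- growth_model(X, dg)
  r <- residuals(fit)
  for (k in c("A", "B")) {
    expect_lt(abs(sum(r[, k])), 1e-8)
    for (g in rownames(X)) expect_lt(abs(sum(r[, k] * X[g, ])), 1e-8)
  }
})

test_that("missing growth cells are skipped in fitting and correlation", {
  set.seed(16)
  X <- rand_mat(2, 10)
  dg <- matrix(rnorm(20), 10, 2, dimnames = list(colnames(X), c("A", "B")))
  dg[c(1, 5), "A"] <- NA
  fit <- growth_model(X, dg)
  sub <- growth_model(X[, -c(1, 5)], dg[-c(1, 5), "A", drop = FALSE])
  expect_equal(coef(fit)["A", ], coef(sub)["A", ], tolerance = 1e-10)
  expect_true(all(is.na(fitted(fit)[c(1, 5), "A"])))
  expect_error(growth_model(X, dg * NA), "no training observation")
})

test_that("adding a gene never decreases pooled training correlation", {
  sim <- small_sim()
  set.seed(17)
  genes <- sample(rownames(sim$X), 12)
  r_prev <- -Inf
  for (n in c(1, 3, 6, 12)) {
    f <- growth_model(sim$X, sim$growth, genes = genes[seq_len(n)])
    r <- pooled_correlation(fitted(f), sim$growth)
    expect_gte(r, r_prev - 1e-10)
    r_prev <- r
  }
})

test_that("training R is 1 for saturated consistent systems", {
  set.seed(18)
  X <- rand_mat(6, 5)   # N = 6 >= n_train - 1
  dg <- matrix(rnorm(5), 5, 1, dimnames = list(colnames(X), "A"))
  fit <- growth_model(X, dg)
  expect_equal(pooled_correlation(fitted(fit), dg), 1, tolerance = 1e-8)
})

test_that("pooled correlation matches the textbook formula and its edges", {
  set.seed(19)
  p <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("s", 1:5),
                                               c("A", "B")))
  o <- matrix(rnorm(10), 5, 2, dimnames = dimnames(p))
  pearson <- function(x, y)
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pooled_correlation(p, o), pearson(as.vector(p), as.vector(o)),
               tolerance = 1e-12)
  expect_equal(pooled_correlation(p, p), 1)
  expect_equal(pooled_correlation(p, 2 * mean(p) - p), -1)  # mirrored
  expect_error(pooled_correlation(p * 0, o), "zero variance")
  expect_error(pooled_correlation(p[1:2, 1, drop = FALSE],
                                  o[1:2, 1, drop = FALSE]), "3")
})

test_that("model methods print, summarize, simulate and serialize", {
  sim <- small_sim()
  fit <- growth_model(sim$X, sim$growth, genes = sim$truth$planted_genes)
  expect_output(print(fit), "pooled training R")
  s <- summary(fit)
  expect_length(s$per_stress_R, 11)
  expect_output(print(s), "per-stress")
  y <- simulate(fit, nsim = 2, seed = 1)
  expect_length(y, 2)
  expect_identical(dim(y[[1]]), dim(fit$fitted))
  expect_identical(simulate(fit, seed = 5), simulate(fit, seed = 5))
  d <- withr::local_tempdir()
  write_fit_json(fit, file.path(d, "fit.json"))
  back <- jsonlite::read_json(file.path(d, "fit.json"))
  expect_equal(back$S01$beta, unname(fit$beta["S01"]), tolerance = 1e-12)
  expect_equal(back$S03$alpha[[sim$truth$planted_genes[2]]],
               unname(fit$alpha["S03", 2]), tolerance = 1e-12)
})
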