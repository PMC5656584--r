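#' Per-stress linear model of growth-rate change
#'
#' Fits, for each stress condition k independently, the linear model
#' \deqn{\Delta g_j^k = \sum_{i=1}^{N} \alpha_i^k X_{ij} + \beta^k}
#' where \eqn{X_{ij}} is the standardized log10 expression change of
#' gene i in resistant strain j and \eqn{\Delta g_j^k} the change in
#' specific growth rate (1/h) of strain j versus the parent under
#' stress k.  Estimation is ordinary least squares via the singular
#' value decomposition; when the system is underdetermined (more genes
#' than training strains) the minimum-norm solution is returned, so the
#' overfitting regime at large N is reproduced rather than masked by
#' regularization.  Strains with a missing growth cell for a stress are
#' skipped for that stress.
#'
#' @param X standardized change matrix, genes x strains.
#' @param growth strains-by-stresses matrix of growth-rate changes
#'   (1/h); `NA` cells are permitted and skipped.
#' @param genes character vector of gene ids (rows of `X`) forming the
#'   shared gene set; may be empty for an intercept-only model.
#' @param strains training strains; default all strains common to `X`
#'   and `growth`.
#' @return an object of class `growth_model` with components `alpha`
#'   (stresses x genes coefficient matrix), `beta` (named per-stress
#'   intercepts, 1/h), `gene_set`, `stresses`, `strains`, `fitted` and
#'   `residuals` (strains x stresses matrices on the training data).
#' @seealso [predict.growth_model()], [pooled_correlation()]
#' @examples
#' X <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' dg <- t(X[1:2, ]) %*% cbind(A = c(2, -1), B = c(1, 1)) + 0.1
#' fit <- growth_model(X, dg, genes = c("g1", "g2"))
#' coef(fit)
#' @export
growth_model <- function(X, growth, genes = rownames(X),
                         strains = intersect(colnames(X), rownames(growth))) {
  genes <- as.character(genes)
  if (anyDuplicated(genes))
    stop("duplicated gene in gene set", call. = FALSE)
  missing_genes <- setdiff(genes, rownames(X))
  if (length(missing_genes))
    stop("gene not in X: ", missing_genes[1], call. = FALSE)
  missing_strains <- setdiff(strains, colnames(X))
  if (length(missing_strains))
    stop("strain not in X: ", missing_strains[1], call. = FALSE)
  growth <- growth[strains, , drop = FALSE]
  stresses <- colnames(growth)
  A_full <- cbind(`(Intercept)` = 1,
                  t(X[genes, strains, drop = FALSE]))
  alpha <- matrix(NA_real_, length(stresses), length(genes),
                  dimnames = list(stresses, genes))
  beta <- setNames(numeric(length(stresses)), stresses)
  fitted <- matrix(NA_real_, length(strains), length(stresses),
                   dimnames = list(strains, stresses))
  for (k in stresses) {
    ok <- which(!is.na(growth[, k]))
    if (!length(ok))
      stop("no training observation for stress ", k, call. = FALSE)
    cf <- min_norm_ols(A_full[ok, , drop = FALSE], growth[ok, k])
    beta[k] <- cf[1]
    alpha[k, ] <- cf[-1]
    fitted[ok, k] <- A_full[ok, , drop = FALSE] %*% cf
  }
  structure(list(alpha = alpha, beta = beta, gene_set = genes,
                 stresses = stresses, strains = strains,
                 fitted = fitted, residuals = growth - fitted,
                 observed = growth),
            class = "growth_model")
}

# Minimum-norm least squares via SVD.
min_norm_ols <- function(A, y) {
  s <- svd(A)
  tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  r <- sum(s$d > tol)
  if (r == 0) return(numeric(ncol(A)))
  drop(s$v[, seq_len(r), drop = FALSE] %*%
         ((t(s$u[, seq_len(r), drop = FALSE]) %*% y) / s$d[seq_len(r)]))
}

#' Predict growth-rate changes for new strains
#'
#' @param object a [growth_model()].
#' @param X standardized change matrix containing the model's gene set.
#' @param strains strains to predict; default all columns of `X`.
#' @param ... unused.
#' @return strains-by-stresses matrix of predicted growth changes (1/h).
#' @export
predict.growth_model <- function(object, X, strains = colnames(X), ...) {
  missing_genes <- setdiff(object$gene_set, rownames(X))
  if (length(missing_genes))
    stop("gene not in X: ", missing_genes[1], call. = FALSE)
  A <- cbind(1, t(X[object$gene_set, strains, drop = FALSE]))
  pred <- A %*% rbind(object$beta, t(object$alpha))
  dimnames(pred) <- list(strains, object$stresses)
  pred
}

#' @export
coef.growth_model <- function(object, ...)
  cbind(`(Intercept)` = object$beta, object$alpha)

#' @export
fitted.growth_model <- function(object, ...) object$fitted

#' @export
residuals.growth_model <- function(object, ...) object$residuals

#' @export
print.growth_model <- function(x, ...) {
  cat("Per-stress linear growth-change model\n")
  cat("  gene set (N):", length(x$gene_set), "\n")
  cat("  stresses:", length(x$stresses), " training strains:",
      length(x$strains), "\n")
  r <- pooled_correlation(x$fitted, x$observed)
  cat("  pooled training R:", format(r, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.growth_model <- function(object, ...) {
  per_stress <- vapply(object$stresses, function(k) {
    ok <- !is.na(object$observed[, k]) & !is.na(object$fitted[, k])
    if (sum(ok) < 3 || sd(object$observed[ok, k]) == 0 ||
        sd(object$fitted[ok, k]) == 0) return(NA_real_)
    cor(object$fitted[ok, k], object$observed[ok, k])
  }, numeric(1))
  out <- list(n_genes = length(object$gene_set),
              stresses = object$stresses,
              per_stress_R = per_stress,
              pooled_R = pooled_correlation(object$fitted, object$observed),
              residual_sd = sd(object$residuals[!is.na(object$residuals)]))
  class(out) <- "summary.growth_model"
  out
}

#' @export
print.summary.growth_model <- function(x, ...) {
  cat("Per-stress linear growth-change model (N =", x$n_genes, "genes)\n")
  cat("pooled training R:", format(x$pooled_R, digits = 4),
      " residual sd:", format(x$residual_sd, digits = 3), "1/h\n")
  cat("per-stress training R:\n")
  print(round(x$per_stress_R, 3))
  invisible(x)
}

#' @export
plot.growth_model <- function(x, ...) {
  obs <- as.vector(x$observed)
  fit <- as.vector(x$fitted)
  ok <- !is.na(obs) & !is.na(fit)
  plot(obs[ok], fit[ok], xlab = "observed growth change (1/h)",
       ylab = "fitted growth change (1/h)", ...)
  abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.growth_model <- function(object, nsim = 1, seed = NULL, X = NULL,
                                  noise_sd = NULL, ...) {
  local_seed(seed)
  if (is.null(X)) {
    mu <- object$fitted
  } else {
    mu <- predict(object, X)
  }
  if (is.null(noise_sd))
    noise_sd <- sd(object$residuals[!is.na(object$residuals)])
  lapply(seq_len(nsim), function(i)
    mu + matrix(rnorm(length(mu), 0, noise_sd), nrow(mu), ncol(mu),
                dimnames = dimnames(mu)))
}

#' Pooled Pearson correlation between predicted and observed growth
#'
#' Pearson correlation over all overlapping non-missing (strain, stress)
#' cells, pooled across stresses.  This is the scalar fitness used to
#' score gene sets during selection.
#'
#' @param pred,obs strains-by-stresses matrices sharing dimnames.
#' @return Pearson R in `[-1, 1]`.
#' @export
pooled_correlation <- function(pred, obs) {
  strains <- intersect(rownames(pred), rownames(obs))
  stresses <- intersect(colnames(pred), colnames(obs))
  p <- as.vector(pred[strains, stresses, drop = FALSE])
  o <- as.vector(obs[strains, stresses, drop = FALSE])
  ok <- !is.na(p) & !is.na(o)
  if (sum(ok) < 3)
    stop("need at least 3 overlapping cells", call. = FALSE)
  if (sd(p[ok]) == 0 || sd(o[ok]) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  cor(p[ok], o[ok])
}

#' Serialize a fit as JSON
#'
#' Layout: `{stress: {beta: x, alpha: {gene: x}}}`.
#'
#' @param object a [growth_model()].
#' @param path output path.
#' @export
write_fit_json <- function(object, path) {
  out <- lapply(object$stresses, function(k)
    list(beta = unname(object$beta[k]),
         alpha = as.list(setNames(object$alpha[k, ], object$gene_set))))
  names(out) <- object$stresses
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
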