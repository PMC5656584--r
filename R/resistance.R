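#' Cross-resistance / collateral-sensitivity matrix
#'
#' Differences in specific growth rate between each resistant strain and
#' the parent under every assayed stress.  Positive entries are
#' cross-resistance (the strain grows faster than the parent under that
#' stress), negative entries collateral sensitivity; a strain's entry
#' under its own evolution stress is its direct resistance gain.
#'
#' @param rates strains-by-stresses matrix of specific growth rates
#'   (1/h), including the parental row; `NA` cells propagate.
#' @param parent parental strain id (row of `rates`).
#' @return strains-by-stresses matrix of growth-rate differences, the
#'   parental row removed.
#' @export
cross_resistance_matrix <- function(rates, parent = PARENT_ID) {
  if (!parent %in% rownames(rates))
    stop("parental strain ", parent, " not in rates table", call. = FALSE)
  res <- rates[setdiff(rownames(rates), parent), , drop = FALSE]
  need <- colnames(res)[apply(!is.na(res), 2, any)]
  miss <- need[is.na(rates[parent, need])]
  if (length(miss))
    stop("missing parental rate for stress ", miss[1], call. = FALSE)
  sweep(res, 2, rates[parent, ], `-`)
}

#' Hierarchical clustering of expression changes
#'
#' Agglomerative clustering of strains by the similarity of their
#' overall expression changes.  The distance between two strains is
#' `1 - Pearson correlation` of their change vectors; linkage is
#' average (UPGMA) by default.  Strains evolved under the same stress
#' typically show the most similar expression changes and group
#' together.
#'
#' @param changes genes-by-strains matrix of (log) expression changes,
#'   no missing values.
#' @param method linkage passed to [stats::hclust()].
#' @return an object of class `hclust`.
#' @export
cluster_expression_changes <- function(changes, method = "average") {
  if (ncol(changes) < 2)
    stop("need at least 2 strains to cluster", call. = FALSE)
  if (anyNA(changes)) stop("missing values in change matrix", call. = FALSE)
  sds <- apply(changes, 2, sd)
  if (any(sds == 0))
    stop("constant change vector for strain ",
         colnames(changes)[which(sds == 0)[1]], call. = FALSE)
  d <- as.dist(1 - cor(changes))
  hclust(d, method = method)
}

#' Transcription-factor display panel
#'
#' Reporting helper for heatmap-style displays of regulator expression:
#' restricts a fold-change matrix to a user-supplied gene list (e.g.
#' transcription factors), keeps the `top_n` genes with the largest
#' variance of log fold-change across strains, and clips displayed
#' fold-changes to `clip` (default half to two-fold) so extreme values
#' do not dominate the colour scale.  Display only, not a statistic.
#'
#' @param changes genes-by-strains matrix of fold-changes (ratio scale).
#' @param genes character vector of genes to display (rows of `changes`).
#' @param top_n keep this many genes, ranked by variance of log change.
#' @param clip length-2 numeric display range on the ratio scale.
#' @return clipped fold-change matrix, rows ordered by decreasing
#'   variance.
#' @export
tf_panel <- function(changes, genes, top_n = 25, clip = c(0.5, 2)) {
  genes <- intersect(genes, rownames(changes))
  if (!length(genes)) stop("no listed gene found in matrix", call. = FALSE)
  m <- changes[genes, , drop = FALSE]
  v <- apply(log10(m), 1, var)
  keep <- head(order(v, decreasing = TRUE), top_n)
  m <- m[keep, , drop = FALSE]
  m[m < clip[1]] <- clip[1]
  m[m > clip[2]] <- clip[2]
  m
}

#' Correlation between mutant and resistant-strain growth changes
#'
#' Tests how far the growth-rate changes of single-mutation strains
#' reproduce the cross-resistance / collateral-sensitivity profile of
#' the evolved resistant strains they derive from.  Points are pooled
#' over all (pair, stress) cells, excluding each pair's evolution stress
#' (where the resistant strain was selected, so its direct gain is not
#' informative about side effects).  Reports the Pearson correlation, a
#' two-sided permutation p-value obtained by permuting which mutant is
#' paired with which resistant strain, and the analytic t-distribution
#' p-value for comparison.
#'
#' @param mutant_dg mutants-by-stresses growth-change matrix.
#' @param resistant_dg strains-by-stresses growth-change matrix.
#' @param pairing data frame with columns `mutant_id`, `resistant_id`,
#'   `evolution_stress`.
#' @param n_perm number of label permutations.
#' @param seed integer seed for the permutation draw.
#' @return list with `R`, `p_perm`, `p_t`, `n_points`.
#' @export
mutant_resistant_correlation <- function(mutant_dg, resistant_dg, pairing,
                                         n_perm = 10000, seed = NULL) {
  need <- c("mutant_id", "resistant_id", "evolution_stress")
  stopifnot(is.data.frame(pairing), all(need %in% names(pairing)))
  stresses <- intersect(colnames(mutant_dg), colnames(resistant_dg))
  pool <- function(mut_rows) {
    xs <- c(); ys <- c()
    for (i in seq_len(nrow(pairing))) {
      keep <- setdiff(stresses, pairing$evolution_stress[i])
      xs <- c(xs, mutant_dg[mut_rows[i], keep])
      ys <- c(ys, resistant_dg[pairing$resistant_id[i], keep])
    }
    ok <- !is.na(xs) & !is.na(ys)
    cbind(xs[ok], ys[ok])
  }
  pts <- pool(pairing$mutant_id)
  if (nrow(pts) < 3)
    stop("fewer than 3 paired points", call. = FALSE)
  R <- cor(pts[, 1], pts[, 2])
  p_t <- cor.test(pts[, 1], pts[, 2])$p.value
  local_seed(seed)
  n_pairs <- nrow(pairing)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    perm <- pairing$mutant_id[sample.int(n_pairs)]
    pp <- pool(perm)
    if (abs(cor(pp[, 1], pp[, 2])) >= abs(R)) exceed <- exceed + 1L
  }
  list(R = R, p_perm = (1 + exceed) / (n_perm + 1), p_t = p_t,
       n_points = nrow(pts))
}
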