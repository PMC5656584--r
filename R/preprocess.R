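#' Quantile-normalize an expression matrix
#'
#' Forces every sample's intensity distribution onto the common
#' reference distribution (the across-sample mean of sorted intensity
#' vectors), preserving within-sample rank order.  Tied values within a
#' sample receive the mean of the reference values over their rank span.
#' Backed by \code{limma::normalizeQuantiles(ties = TRUE)}.
#'
#' @param expr an [expression_set].
#' @return an [expression_set] with normalized intensities.
#' @export
quantile_normalize <- function(expr) {
  stopifnot(inherits(expr, "expression_set"))
  if (nrow(expr$values) == 0 || ncol(expr$values) == 0)
    stop("cannot quantile-normalize an empty matrix", call. = FALSE)
  v <- limma::normalizeQuantiles(expr$values, ties = TRUE)
  dimnames(v) <- dimnames(expr$values)
  expression_set(v, expr$meta)
}

#' Drop genes below the quantification floor
#'
#' Removes genes whose intensity is below `floor` (default 100 a.u.) in
#' every sample; a gene is kept as soon as one sample reaches the floor.
#' Idempotent, order-preserving.
#'
#' @param expr an [expression_set].
#' @param floor intensity floor, a.u.
#' @return a filtered [expression_set].
#' @export
filter_low_expression <- function(expr, floor = 100) {
  stopifnot(inherits(expr, "expression_set"), floor >= 0)
  keep <- apply(expr$values, 1, function(x) any(x >= floor))
  expression_set(expr$values[keep, , drop = FALSE], expr$meta)
}

#' Expression change of a resistant strain against the parent
#'
#' Per-gene ratio of the strain's expression to the parent's expression,
#' both assayed under the same stress condition; replicate intensities
#' are averaged (arithmetic mean) before taking the ratio.
#'
#' @param expr an [expression_set].
#' @param strain resistant strain id.
#' @param stress assay stress; defaults to the strain's evolution stress.
#' @param parent parental strain id.
#' @return named numeric vector of ratios, one per gene.
#' @export
expression_change <- function(expr, strain, stress = NULL,
                              parent = PARENT_ID) {
  stopifnot(inherits(expr, "expression_set"))
  m <- expr$meta
  if (is.null(stress)) {
    stress <- unique(m$evolution_stress[m$strain_id == strain])
    if (length(stress) != 1)
      stop("cannot infer assay stress for strain ", strain, call. = FALSE)
  }
  s_idx <- which(m$strain_id == strain & m$assay_stress == stress)
  p_idx <- which(m$strain_id == parent & m$assay_stress == stress)
  if (!length(s_idx))
    stop("no sample for strain ", strain, " under ", stress, call. = FALSE)
  if (!length(p_idx))
    stop("no parental sample under ", stress, call. = FALSE)
  num <- rowMeans(expr$values[, s_idx, drop = FALSE])
  den <- rowMeans(expr$values[, p_idx, drop = FALSE])
  zero <- names(den)[den == 0]
  if (length(zero))
    stop("zero parental intensity for gene ", zero[1], call. = FALSE)
  num / den
}

#' Reduce a change matrix to one representative gene per operon
#'
#' Operon members share transcriptional control, so their expression
#' changes are redundant for gene selection.  Within each operon the gene
#' with the highest mean intensity over all samples is retained; ties
#' break to the lexicographically smallest gene id.
#'
#' @param changes genes-by-strains matrix (any per-gene matrix).
#' @param operons operon map covering all genes in `changes`.
#' @param expr the [expression_set] whose intensities define "highest
#'   average expression" (typically the normalized, floor-filtered set).
#' @return the row-subset of `changes` with one gene per operon, in the
#'   original row order.
#' @export
operon_representatives <- function(changes, operons, expr) {
  operons <- validate_operon_map(operons)
  genes <- rownames(changes)
  missing_genes <- setdiff(genes, operons$gene_id)
  if (length(missing_genes))
    stop("gene absent from operon map: ", missing_genes[1], call. = FALSE)
  op <- operons$operon_id[match(genes, operons$gene_id)]
  avg <- rowMeans(expr$values[genes, , drop = FALSE])
  ord <- order(op, -avg, genes)   # per operon: highest mean, then smallest id
  rep_genes <- genes[ord][!duplicated(op[ord])]
  changes[genes %in% rep_genes, , drop = FALSE]
}

#' Drop genes whose expression change is nearly invariant
#'
#' Genes whose expression barely changes across strains carry mostly
#' measurement error.  The variance of the log10 change is computed
#' across the resistant strains together with the parent (whose change
#' is 0 by definition); genes below `threshold` are removed.
#'
#' @param log_changes genes-by-strains matrix of log10 changes.
#' @param threshold variance threshold in squared log10 units.
#' @param include_parent include the parent's zero change in the variance.
#' @return the row-subset of `log_changes` passing the filter.
#' @export
filter_by_variance <- function(log_changes, threshold = 0.01,
                               include_parent = TRUE) {
  stopifnot(threshold >= 0)
  v <- apply(log_changes, 1, function(x) {
    if (include_parent) x <- c(x, 0)
    var(x)
  })
  log_changes[v >= threshold, , drop = FALSE]
}

#' Standardize log10 expression changes per gene
#'
#' Centers and scales each gene's log10 change to zero mean and unit
#' variance across the resistant strains (population sd, divisor n),
#' yielding the matrix `X` that enters the linear growth model.
#'
#' @param log_changes genes-by-strains matrix of log10 changes.
#' @return standardized matrix of the same shape.
#' @export
standardize_changes <- function(log_changes) {
  mu <- rowMeans(log_changes)
  sdv <- sqrt(rowMeans((log_changes - mu)^2))
  zero <- which(sdv == 0)
  if (length(zero))
    stop("zero change variance for gene ", rownames(log_changes)[zero[1]],
         " (apply the variance filter first)", call. = FALSE)
  (log_changes - mu) / sdv
}

#' Full preprocessing pipeline: intensities to standardized changes
#'
#' Fixed stage order: quantile normalization, low-expression filter,
#' per-strain log10 expression change against the parent under the
#' strain's evolution stress, operon-representative reduction, variance
#' filter, per-gene standardization.  Deterministic.
#'
#' @param expr an [expression_set] including parental samples.
#' @param operons operon map covering the gene universe.
#' @param floor intensity floor (a.u.) for the low-expression filter.
#' @param var_threshold variance threshold (squared log10 units).
#' @param parent parental strain id.
#' @return list with `X` (standardized genes-by-strains matrix),
#'   `log_changes` (pre-standardization matrix on the retained genes),
#'   and `report` (genes retained after each stage).
#' @export
preprocess_expression <- function(expr, operons, floor = 100,
                                  var_threshold = 0.01,
                                  parent = PARENT_ID) {
  stopifnot(inherits(expr, "expression_set"))
  n0 <- nrow(expr$values)
  norm <- quantile_normalize(expr)
  kept <- filter_low_expression(norm, floor = floor)
  n1 <- nrow(kept$values)
  strains <- setdiff(unique(kept$meta$strain_id), parent)
  ratios <- vapply(strains,
                   function(s) expression_change(kept, s, parent = parent),
                   numeric(nrow(kept$values)))
  log_changes <- log10(ratios)
  rownames(log_changes) <- rownames(kept$values)
  log_changes <- operon_representatives(log_changes, operons, kept)
  n2 <- nrow(log_changes)
  log_changes <- filter_by_variance(log_changes, threshold = var_threshold)
  n3 <- nrow(log_changes)
  X <- standardize_changes(log_changes)
  list(X = X, log_changes = log_changes,
       report = c(input = n0, above_floor = n1, operon_representatives = n2,
                  variance_filtered = n3))
}
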