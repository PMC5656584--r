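#' Construct and validate an expression set
#'
#' An `expression_set` couples a gene-by-sample intensity matrix with
#' per-sample annotation.  Intensities are background-corrected,
#' nonnegative values in arbitrary units (a.u.).  The parental strain is
#' identified by the reserved strain id `"parent"` and must be assayed
#' under every stress that any resistant strain is assayed under, since
#' expression changes are ratios against the parent under the matching
#' stress.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids),
#'   samples in columns (colnames = sample ids); nonnegative, finite.
#' @param meta data frame with columns `sample_id`, `strain_id`,
#'   `evolution_stress`, `assay_stress`, `replicate`, one row per sample.
#' @return an object of class `expression_set`.
#' @export
expression_set <- function(values, meta) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and sample colnames", call. = FALSE)
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicated gene id: ", dup[1], call. = FALSE)
  dup <- colnames(values)[duplicated(colnames(values))]
  if (length(dup))
    stop("duplicated sample id: ", dup[1], call. = FALSE)
  bad <- which(!is.finite(values) | values < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite intensity at gene ", rownames(values)[bad[1, 1]],
         ", sample ", colnames(values)[bad[1, 2]], call. = FALSE)
  need <- c("sample_id", "strain_id", "evolution_stress", "assay_stress",
            "replicate")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("`meta` must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  miss <- setdiff(colnames(values), meta$sample_id)
  if (length(miss))
    stop("missing metadata for sample: ", miss[1], call. = FALSE)
  meta <- meta[match(colnames(values), meta$sample_id), need, drop = FALSE]
  rownames(meta) <- NULL
  structure(list(values = values, meta = meta), class = "expression_set")
}

#' @export
print.expression_set <- function(x, ...) {
  cat("expression_set:", nrow(x$values), "genes x", ncol(x$values),
      "samples\n")
  st <- setdiff(unique(x$meta$strain_id), PARENT_ID)
  cat("  strains:", length(st), "resistant +",
      if (PARENT_ID %in% x$meta$strain_id) "parent" else "NO PARENT", "\n")
  cat("  assay stresses:", paste(sort(unique(x$meta$assay_stress)),
                                 collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expression_set <- function(x) dim(x$values)

comment_header <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("crossres"))
  c(paste0("# crossres ", v),
    if (!is.null(seed)) paste0("# seed: ", seed))
}

write_tsv_matrix <- function(m, path, id_col, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(seed), con)
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

read_tsv_matrix <- function(path, sep = "\t") {
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read and write expression matrices
#'
#' Canonical on-disk layout: a TSV with genes in rows (first column
#' `gene_id`) and samples in columns, plus a sample-metadata TSV with
#' columns `sample_id`, `strain_id`, `evolution_stress`, `assay_stress`,
#' `replicate`.  Lines starting with `#` are provenance comments and are
#' skipped.  CSV input is accepted via `sep = ","`; the decimal
#' separator is always the point.
#'
#' @param path path of the intensity table.
#' @param meta_path path of the sample-metadata table.
#' @param sep field separator (`"\t"` by default, `","` for CSV).
#' @return [read_expression()] returns an [expression_set].
#' @export
read_expression <- function(path, meta_path, sep = "\t") {
  values <- read_tsv_matrix(path, sep = sep)
  meta <- utils::read.table(meta_path, header = TRUE, sep = sep,
                            comment.char = "#", check.names = FALSE,
                            stringsAsFactors = FALSE)
  expression_set(values, meta)
}

#' @rdname read_expression
#' @param x an [expression_set].
#' @param seed optional integer recorded in the file header for provenance.
#' @export
write_expression <- function(x, path, meta_path, seed = NULL) {
  stopifnot(inherits(x, "expression_set"))
  write_tsv_matrix(x$values, path, "gene_id", seed = seed)
  con <- file(meta_path, "w")
  on.exit(close(con))
  writeLines(comment_header(seed), con)
  write.table(x$meta, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

#' Read and write growth-rate and growth-change tables
#'
#' Growth tables are TSVs with strains in rows (first column `strain_id`)
#' and stresses in columns.  [read_growth_table()] reads specific growth
#' rates (1/h), which must be nonnegative where present; missing cells
#' are encoded as `NA`.  [read_growth_changes()] reads growth-rate
#' *changes* relative to the parent, which may be negative (collateral
#' sensitivity).
#'
#' @param path file path.
#' @param sep field separator.
#' @return numeric matrix, strains x stresses, possibly with `NA` cells.
#' @export
read_growth_table <- function(path, sep = "\t") {
  m <- read_tsv_matrix(path, sep = sep)
  bad <- which(!is.na(m) & (m < 0 | !is.finite(m)), arr.ind = TRUE)
  if (nrow(bad))
    stop("negative or non-finite growth rate for strain ",
         rownames(m)[bad[1, 1]], " under ", colnames(m)[bad[1, 2]],
         call. = FALSE)
  m
}

#' @rdname read_growth_table
#' @export
read_growth_changes <- function(path, sep = "\t") {
  m <- read_tsv_matrix(path, sep = sep)
  bad <- which(!is.na(m) & !is.finite(m), arr.ind = TRUE)
  if (nrow(bad))
    stop("non-finite growth change for strain ", rownames(m)[bad[1, 1]],
         call. = FALSE)
  m
}

#' @rdname read_growth_table
#' @param m strains-by-stresses numeric matrix with strain rownames.
#' @param seed optional integer recorded in the file header.
#' @export
write_growth_table <- function(m, path, seed = NULL) {
  write_tsv_matrix(m, path, "strain_id", seed = seed)
  invisible(m)
}

#' Read and write gene-to-operon maps
#'
#' Two-column TSV (`gene_id`, `operon_id`).  The map must be a total
#' function: each gene appears exactly once.
#'
#' @param path file path.
#' @return data frame with columns `gene_id` and `operon_id`.
#' @export
read_operon_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_operon_map(df)
}

#' @rdname read_operon_map
#' @param map data frame with columns `gene_id`, `operon_id`.
#' @param seed optional integer recorded in the file header.
#' @export
write_operon_map <- function(map, path, seed = NULL) {
  map <- validate_operon_map(map)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(comment_header(seed), con)
  write.table(map, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(map)
}

validate_operon_map <- function(map) {
  if (!is.data.frame(map) || !all(c("gene_id", "operon_id") %in% names(map)))
    stop("operon map needs columns gene_id and operon_id", call. = FALSE)
  dup <- map$gene_id[duplicated(map$gene_id)]
  if (length(dup))
    stop("gene assigned to more than one operon: ", dup[1], call. = FALSE)
  map[c("gene_id", "operon_id")]
}
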