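#' @keywords internal
"_PACKAGE"

# Shared validation helpers for the package's containers. Containers are plain
# numeric matrices carrying a class attribute (and, for Ct data, a sample
# metadata data frame), in the spirit of limma's "matrix plus annotation"
# objects but without S4 machinery.

assert_unique_ids <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop(sprintf("duplicate %s identifier(s): %s", what,
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  invisible(ids)
}

#' Construct a validated FPKM expression matrix
#'
#' Genes are rows, samples are columns. Values are FPKM (non-negative,
#' finite); at least two samples are required so that per-gene dispersion
#' statistics are defined.
#'
#' @param values Numeric matrix of FPKM, genes x samples.
#' @param gene_ids,sample_ids Unique identifiers; default to the dimnames of
#'   `values`.
#' @return A numeric matrix of class `expression_matrix` with gene ids as
#'   rownames and sample ids as colnames.
#' @examples
#' expression_matrix(matrix(1:6, 2, 3,
#'   dimnames = list(c("ACT", "TUB"), c("s1", "s2", "s3"))))
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  assert_unique_ids(gene_ids, "gene")
  assert_unique_ids(sample_ids, "sample")
  if (ncol(values) < 2L) {
    stop("an expression matrix needs at least 2 samples", call. = FALSE)
  }
  bad <- which(!is.finite(values) | values < 0)
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-finite or negative FPKM value at gene '%s', sample '%s'",
                 gene_ids[i[1L]], sample_ids[i[2L]]), call. = FALSE)
  }
  dimnames(values) <- list(gene_ids, sample_ids)
  class(values) <- c("expression_matrix", "matrix", "array")
  values
}

#' Construct a validated Ct matrix with sample metadata
#'
#' Quantification-cycle (Ct) values, genes x samples, with one metadata record
#' per sample column. Ct values must be finite and in (0, 45]; missing cells
#' are a hard error (the downstream stability statistics all assume complete
#' matrices).
#'
#' @param values Numeric matrix of Ct values, genes x samples.
#' @param sample_meta Data frame with columns `sample_id`, `group`,
#'   `condition` (one of `"treatment"`, `"control"`), `bio_rep` and
#'   `tech_rep` (positive integers), one row per sample column.
#' @param gene_ids,sample_ids Unique identifiers; default to the dimnames of
#'   `values`.
#' @return A numeric matrix of class `ct_matrix`; the metadata is stored in
#'   the `"sample_meta"` attribute (retrieve with [sample_meta()]).
#' @seealso [collapse_technical_replicates()]
#' @export
ct_matrix <- function(values, sample_meta, gene_ids = rownames(values),
                      sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(gene_ids) || is.null(sample_ids)) {
    stop("gene and sample identifiers are required", call. = FALSE)
  }
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(values) != length(gene_ids) || ncol(values) != length(sample_ids)) {
    stop("identifier lengths do not match matrix dimensions", call. = FALSE)
  }
  assert_unique_ids(gene_ids, "gene")
  assert_unique_ids(sample_ids, "sample")
  bad <- which(!is.finite(values) | values <= 0 | values > 45)
  if (length(bad) > 0L) {
    i <- arrayInd(bad[1L], dim(values))
    stop(sprintf(
      "Ct value %s at gene '%s', sample '%s' is outside (0, 45] or missing",
      format(values[bad[1L]]), gene_ids[i[1L]], sample_ids[i[2L]]),
      call. = FALSE)
  }
  sample_meta <- validate_sample_meta(sample_meta, sample_ids)
  dimnames(values) <- list(gene_ids, sample_ids)
  attr(values, "sample_meta") <- sample_meta
  class(values) <- c("ct_matrix", "matrix", "array")
  values
}

validate_sample_meta <- function(meta, sample_ids) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  needed <- c("sample_id", "group", "condition", "bio_rep", "tech_rep")
  missing_cols <- setdiff(needed, names(meta))
  if (length(missing_cols) > 0L) {
    stop(sprintf("sample metadata lacks column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  meta$sample_id <- as.character(meta$sample_id)
  assert_unique_ids(meta$sample_id, "metadata sample")
  absent <- setdiff(sample_ids, meta$sample_id)
  if (length(absent) > 0L) {
    stop(sprintf("sample(s) in the Ct table have no metadata record: %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  meta <- meta[match(sample_ids, meta$sample_id), needed, drop = FALSE]
  rownames(meta) <- NULL
  meta$group <- as.character(meta$group)
  meta$condition <- as.character(meta$condition)
  bad_cond <- setdiff(unique(meta$condition), c("treatment", "control"))
  if (length(bad_cond) > 0L) {
    stop(sprintf("condition label(s) must be 'treatment' or 'control', got: %s",
                 paste(bad_cond, collapse = ", ")), call. = FALSE)
  }
  meta$bio_rep <- as.integer(meta$bio_rep)
  meta$tech_rep <- as.integer(meta$tech_rep)
  if (anyNA(meta$bio_rep) || anyNA(meta$tech_rep) ||
      any(meta$bio_rep < 1L) || any(meta$tech_rep < 1L)) {
    stop("replicate indices must be integers >= 1", call. = FALSE)
  }
  meta
}

#' Sample metadata of a Ct matrix
#'
#' @param ct A [ct_matrix()].
#' @return Data frame with one row per sample column, in column order.
#' @export
sample_meta <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  attr(ct, "sample_meta")
}

# Strip container attributes down to a bare numeric matrix.
ct_values <- function(ct) {
  v <- unclass(ct)
  attr(v, "sample_meta") <- NULL
  v
}

#' Construct a dilution series for one primer pair
#'
#' Points are (log10 relative template amount, Ct), e.g. a 10-fold dilution
#' series has log10 amounts 0, -1, -2, ... with the most concentrated point
#' at 0. At least 3 points over at least 3 distinct dilutions are required to
#' fit a standard curve.
#'
#' @param gene_id Gene / primer-pair identifier.
#' @param log10_amount Numeric vector of log10 relative template amounts.
#' @param ct Numeric vector of Ct values, same length.
#' @return An object of class `dilution_series` (list with `gene_id` and a
#'   `points` data frame).
#' @export
dilution_series <- function(gene_id, log10_amount, ct) {
  gene_id <- as.character(gene_id)
  log10_amount <- as.numeric(log10_amount)
  ct <- as.numeric(ct)
  if (length(log10_amount) != length(ct)) {
    stop("log10_amount and ct must have the same length", call. = FALSE)
  }
  if (length(ct) < 3L || length(unique(log10_amount)) < 3L) {
    stop("a dilution series needs >= 3 points over >= 3 distinct dilutions",
         call. = FALSE)
  }
  if (any(!is.finite(ct)) || any(!is.finite(log10_amount))) {
    stop("dilution-series values must be finite", call. = FALSE)
  }
  structure(
    list(gene_id = gene_id,
         points = data.frame(log10_amount = log10_amount, ct = ct)),
    class = "dilution_series")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("FPKM expression matrix: %d genes x %d samples\n",
              nrow(x), ncol(x)))
  print(utils::head(unclass(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @export
print.ct_matrix <- function(x, ...) {
  meta <- sample_meta(x)
  cat(sprintf("Ct matrix: %d genes x %d samples (%d group(s))\n",
              nrow(x), ncol(x), length(unique(meta$group))))
  print(utils::head(ct_values(x)[, seq_len(min(6L, ncol(x))), drop = FALSE]))
  invisible(x)
}

#' @export
print.dilution_series <- function(x, ...) {
  cat(sprintf("Dilution series for '%s' (%d points)\n",
              x$gene_id, nrow(x$points)))
  print(x$points)
  invisible(x)
}
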