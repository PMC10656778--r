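# Delimited-table input/output. The delimiter is always explicit (comma by
# default): auto-detection is deliberately not attempted, because a silently
# mis-parsed Ct table is a worse failure mode than one extra argument.

read_delim_frame <- function(path, delimiter) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = delimiter,
                      check.names = FALSE, stringsAsFactors = FALSE,
                      quote = "\"", comment.char = ""),
    error = function(e) {
      stop(sprintf("file '%s' is empty or malformed: %s", path,
                   conditionMessage(e)), call. = FALSE)
    })
  if (ncol(df) < 2L || nrow(df) < 1L) {
    stop(sprintf("file '%s' must have an id column plus at least one data column",
                 path), call. = FALSE)
  }
  df
}

# First column = row ids, remaining columns numeric. Errors name the first
# offending cell.
delim_frame_to_matrix <- function(df, path) {
  ids <- as.character(df[[1L]])
  cols <- names(df)[-1L]
  values <- matrix(NA_real_, nrow(df), length(cols),
                   dimnames = list(NULL, cols))
  for (j in seq_along(cols)) {
    col <- df[[j + 1L]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad) > 0L) {
        stop(sprintf("non-numeric value '%s' at row '%s', column '%s' of '%s'",
                     col[bad[1L]], ids[bad[1L]], cols[j], path), call. = FALSE)
      }
      col <- num
    }
    values[, j] <- col
  }
  list(ids = ids, values = values)
}

#' Read an FPKM expression table
#'
#' The file must have a header row of sample ids and gene ids in the first
#' column; row and column order are preserved.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter (default comma; use `"\t"` for TSV).
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, delimiter = ",") {
  df <- read_delim_frame(path, delimiter)
  parsed <- delim_frame_to_matrix(df, path)
  expression_matrix(parsed$values, gene_ids = parsed$ids,
                    sample_ids = colnames(parsed$values))
}

#' Read a Ct table and its sample metadata
#'
#' The Ct table is formatted like an expression table (genes x samples); the
#' metadata table must have columns `sample_id`, `group`, `condition`,
#' `bio_rep`, `tech_rep` and cover every sample column.
#'
#' @param path Path to the Ct table.
#' @param meta_path Path to the sample metadata table.
#' @param delimiter Field delimiter for both files (default comma).
#' @return A [ct_matrix()].
#' @export
read_ct_table <- function(path, meta_path, delimiter = ",") {
  df <- read_delim_frame(path, delimiter)
  parsed <- delim_frame_to_matrix(df, path)
  if (!file.exists(meta_path)) {
    stop(sprintf("file not found: %s", meta_path), call. = FALSE)
  }
  meta <- utils::read.table(meta_path, header = TRUE, sep = delimiter,
                            check.names = FALSE, stringsAsFactors = FALSE)
  ct_matrix(parsed$values, sample_meta = meta, gene_ids = parsed$ids,
            sample_ids = colnames(parsed$values))
}

#' Average technical replicates of a Ct matrix
#'
#' Columns sharing the same (group, condition, biological replicate) key are
#' technical replicates of one biological sample; each cell of the collapsed
#' matrix is the arithmetic mean of the replicate Ct values. Averaging is done
#' on the Ct (log) scale, which is standard practice for qPCR replicates; no
#' linear-scale variant is offered. The operation is idempotent.
#'
#' @param ct A [ct_matrix()].
#' @return A [ct_matrix()] with one column per biological sample (the first
#'   replicate's sample id is kept) and `tech_rep` set to 1.
#' @export
collapse_technical_replicates <- function(ct) {
  stopifnot(inherits(ct, "ct_matrix"))
  meta <- sample_meta(ct)
  values <- ct_values(ct)
  key <- paste(meta$group, meta$condition, meta$bio_rep, sep = "\r")
  key <- factor(key, levels = unique(key))   # first-appearance order
  groups <- split(seq_along(key), key)
  collapsed <- vapply(groups, function(i) {
    rowMeans(values[, i, drop = FALSE])
  }, numeric(nrow(values)))
  if (nrow(values) == 1L) collapsed <- matrix(collapsed, nrow = 1L)
  first <- vapply(groups, `[`, integer(1L), 1L)
  new_meta <- meta[first, , drop = FALSE]
  new_meta$tech_rep <- 1L
  ct_matrix(collapsed, sample_meta = new_meta,
            gene_ids = rownames(values), sample_ids = meta$sample_id[first])
}

#' Write an expression or Ct matrix as delimited text
#'
#' Values are written at full precision (up to 15 significant digits), so any
#' matrix whose values have at most 6 fractional decimal digits round-trips
#' bit-for-bit through [read_expression_table()] / [read_ct_table()].
#'
#' @param x An [expression_matrix()] or [ct_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @return `path`, invisibly. For a `ct_matrix` the metadata is not written;
#'   use [write_sample_meta()].
#' @export
write_matrix_table <- function(x, path, delimiter = ",") {
  df <- data.frame(gene_id = rownames(x), unclass(x)[, , drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  attr(df, "sample_meta") <- NULL
  utils::write.table(df, path, sep = delimiter, row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write the sample metadata of a Ct matrix
#'
#' @param ct A [ct_matrix()].
#' @param path Output path.
#' @param delimiter Field delimiter (default comma).
#' @export
write_sample_meta <- function(ct, path, delimiter = ",") {
  utils::write.table(sample_meta(ct), path, sep = delimiter,
                     row.names = FALSE, col.names = TRUE, quote = FALSE)
  invisible(path)
}

#' Write a result table as CSV
#'
#' Numeric columns are rounded to `digits` fractional digits (default 4), the
#' package-wide reporting precision.
#'
#' @param df A data frame.
#' @param path Output path.
#' @param digits Fractional digits for numeric columns.
#' @export
write_report_csv <- function(df, path, digits = 4) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' Bundles the tunable settings of [run_pipeline()]: candidate-screening
#' thresholds, geNorm settings, the BestKeeper variant, the random seed and
#' the output directory. Defaults are the package's standard operating point
#' (MV > 30 FPKM, top 500 by SD, CV < 0.5, MFC < 6.3; geNorm pairwise-variation
#' guidance cutoff 0.15).
#'
#' @param mv_min Minimum mean FPKM (strict `>`).
#' @param top_n_sd Number of genes kept after ranking by SD ascending.
#' @param cv_max Maximum coefficient of variation (strict `<`).
#' @param mfc_max Maximum max/min fold change (strict `<`).
#' @param v_cutoff geNorm V(n/n+1) guidance threshold, in (0, 1); advisory
#'   only, never enforced.
#' @param bestkeeper_variant `"plain_sd"` or `"mad_geomean"`.
#' @param group_by Sample grouping fed to NormFinder: `"group"`,
#'   `"condition"` or `"none"`.
#' @param seed Integer random seed.
#' @param output_dir Output directory.
#' @param ... Further fields (input paths, simulation settings, normalization
#'   settings) understood by [run_pipeline()].
#' @return A list of class `run_config`.
#' @export
run_config <- function(mv_min = 30, top_n_sd = 500, cv_max = 0.5,
                       mfc_max = 6.3, v_cutoff = 0.15,
                       bestkeeper_variant = c("plain_sd", "mad_geomean"),
                       group_by = "group", seed = 1L,
                       output_dir = "refstab_out", ...) {
  cfg <- c(list(mv_min = mv_min, top_n_sd = top_n_sd, cv_max = cv_max,
                mfc_max = mfc_max, v_cutoff = v_cutoff,
                bestkeeper_variant = match.arg(bestkeeper_variant),
                group_by = group_by, seed = as.integer(seed),
                output_dir = output_dir),
           list(...))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  thr <- c("mv_min", "top_n_sd", "cv_max", "mfc_max")
  for (f in thr) {
    if (is.null(cfg[[f]]) || !is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      stop(sprintf("config threshold '%s' must be strictly positive", f),
           call. = FALSE)
    }
  }
  if (is.null(cfg$v_cutoff) || cfg$v_cutoff <= 0 || cfg$v_cutoff >= 1) {
    stop("config 'v_cutoff' must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$bestkeeper_variant)) cfg$bestkeeper_variant <- "plain_sd"
  if (is.null(cfg$group_by)) cfg$group_by <- "group"
  if (is.null(cfg$output_dir)) cfg$output_dir <- "refstab_out"
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from a YAML file
#'
#' A flat key-value document mirroring the arguments of [run_config()];
#' unknown keys are carried through to [run_pipeline()].
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  raw <- yaml::read_yaml(path)
  defaults <- run_config()
  for (f in names(defaults)) {
    if (is.null(raw[[f]])) raw[[f]] <- defaults[[f]]
  }
  validate_run_config(raw)
}
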