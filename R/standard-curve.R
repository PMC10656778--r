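# Standard-curve fitting and amplification efficiency. A 10-fold dilution
# series with perfect per-cycle doubling has slope magnitude
# 1/log10(2) = 3.3219 cycles per log10 dilution; the efficiency relation
# inverts the fitted slope:
#
#   E% = (10^(1 / |slope|) - 1) * 100

#' Amplification efficiency from a standard-curve slope
#'
#' @param slope_magnitude Positive slope magnitude of the standard curve, in
#'   Ct cycles per log10 dilution.
#' @return Efficiency in percent (100 = perfect doubling), unrounded; round
#'   to 2 decimal places at reporting time.
#' @examples
#' efficiency_from_slope(1 / log10(2))  # 100
#' efficiency_from_slope(3.3247)        # 99.88 to 2 d.p.
#' @export
efficiency_from_slope <- function(slope_magnitude) {
  if (!is.numeric(slope_magnitude) || any(!is.finite(slope_magnitude)) ||
      any(slope_magnitude <= 0)) {
    stop("slope magnitude must be a positive finite number", call. = FALSE)
  }
  (10^(1 / slope_magnitude) - 1) * 100
}

#' Fit a qPCR standard curve
#'
#' Ordinary least squares of Ct on log10 relative template amount. The slope
#' is reported as a positive magnitude, the regression coefficient is the
#' squared Pearson correlation of the points, and the amplification
#' efficiency comes from [efficiency_from_slope()].
#'
#' @param series A [dilution_series()] with at least 3 distinct dilutions.
#' @return A list of class `curve_fit` with fields `gene_id`, `slope`
#'   (positive magnitude), `intercept`, `r_squared` and `efficiency_pct`.
#' @export
fit_standard_curve <- function(series) {
  stopifnot(inherits(series, "dilution_series"))
  x <- series$points$log10_amount
  y <- series$points$ct
  if (length(unique(x)) < 3L) {
    stop("standard curve is rank-deficient: need >= 3 distinct dilutions",
         call. = FALSE)
  }
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  if (slope == 0 || stats::sd(y) == 0) {
    stop(sprintf("degenerate standard curve for '%s': Ct does not vary with dilution",
                 series$gene_id), call. = FALSE)
  }
  r2 <- stats::cor(x, y)^2
  structure(list(gene_id = series$gene_id,
                 slope = abs(slope),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = r2,
                 efficiency_pct = efficiency_from_slope(abs(slope))),
            class = "curve_fit")
}

#' @export
print.curve_fit <- function(x, ...) {
  cat(sprintf("Standard curve for '%s': slope %.4f, R2 %.4f, E = %.2f%%\n",
              x$gene_id, x$slope, x$r_squared, x$efficiency_pct))
  invisible(x)
}

#' Tabulate several curve fits
#'
#' @param fits A list of `curve_fit` objects (or a single one).
#' @return A data frame with one row per primer pair.
#' @export
curve_fit_table <- function(fits) {
  if (inherits(fits, "curve_fit")) fits <- list(fits)
  do.call(rbind, lapply(fits, function(f) {
    data.frame(gene_id = f$gene_id, slope = f$slope, intercept = f$intercept,
               r_squared = f$r_squared, efficiency_pct = f$efficiency_pct,
               stringsAsFactors = FALSE)
  }))
}
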