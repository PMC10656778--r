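#' Published standard-curve summary for 35 A. kteniophylla primer pairs
#'
#' Loads the bundled compendium of qRT-PCR standard-curve slopes, regression
#' coefficients and amplification efficiencies for the 29 candidate
#' reference-gene primer pairs and 6 anthocyanin-pathway target-gene primer
#' pairs of *Ardisia kteniophylla*. Useful as a desk-scale check that
#' [efficiency_from_slope()] reproduces each printed slope/efficiency pair.
#'
#' @return A data frame with columns `gene_id`, `role` (reference/target),
#'   `slope` (positive magnitude, cycles per log10 dilution), `r_squared`
#'   and `efficiency_pct`.
#' @examples
#' pc <- primer_curves()
#' all(abs(efficiency_from_slope(pc$slope) - pc$efficiency_pct) < 0.01)
#' @export
primer_curves <- function() {
  path <- system.file("extdata", "primer_curves.csv", package = "refstab",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
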