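#' RefFinder-style consensus ranking
#'
#' Combines the per-method ranks of two to four stability tables into an
#' unweighted geometric-mean score: for gene i with method ranks r_i1..r_iM,
#' `geomean_rank = (prod_m r_im)^(1/M)`. The final ranking ascends by the
#' geometric mean, with ties broken by gene id. Tied method ranks entering
#' the product are fractional (average) ranks, e.g. the geNorm final pair
#' enters as 1.5 and 1.5, which preserves rank-sum invariance under tie
#' splitting. The aggregation combines whatever stability tables it is
#' given and records their method labels; it does not claim bit-for-bit
#' compatibility with any particular web service.
#'
#' @param tables A list of 2 to 4 `stability_table` objects (a
#'   `genorm_result` may be passed directly; its table is extracted) covering
#'   identical gene sets.
#' @return A data frame of class `consensus_ranking` with one rank column
#'   per method, `geomean_rank` and `final_rank`, sorted by `final_rank`.
#' @examples
#' ct <- ct_matrix(rbind(A = c(20, 21, 22, 20.5), B = c(20.1, 21, 22.2, 20.4),
#'                       C = c(25, 20, 23, 21)),
#'                 sample_meta = data.frame(sample_id = paste0("s", 1:4),
#'                                          group = "g1", condition = "control",
#'                                          bio_rep = 1:4, tech_rep = 1),
#'                 sample_ids = paste0("s", 1:4))
#' aggregate_ranks(list(delta_ct_stability(ct), genorm_stability(ct)))
#' @export
aggregate_ranks <- function(tables) {
  if (inherits(tables, "stability_table") || inherits(tables, "genorm_result")) {
    tables <- list(tables)
  }
  tables <- lapply(tables, function(t) {
    if (inherits(t, "genorm_result")) t$table else t
  })
  if (length(tables) < 2L || length(tables) > 4L) {
    stop("aggregation needs between 2 and 4 stability tables", call. = FALSE)
  }
  if (!all(vapply(tables, inherits, logical(1L), "stability_table"))) {
    stop("all inputs must be stability tables", call. = FALSE)
  }
  genes <- sort(tables[[1L]]$gene_id)
  for (t in tables[-1L]) {
    other <- sort(t$gene_id)
    if (!identical(genes, other)) {
      diff <- c(setdiff(genes, other), setdiff(other, genes))
      stop(sprintf("stability tables cover different gene sets; symmetric difference: %s",
                   paste(sort(unique(diff)), collapse = ", ")), call. = FALSE)
    }
  }
  methods <- vapply(tables, stability_method, character(1L))
  methods <- make.unique(methods, sep = "_")
  ranks <- vapply(tables, function(t) t$rank[match(genes, t$gene_id)],
                  numeric(length(genes)))
  ranks <- matrix(ranks, nrow = length(genes),
                  dimnames = list(genes, paste0("rank_", methods)))
  geomean <- exp(rowMeans(log(ranks)))
  final_rank <- integer(length(genes))
  final_rank[order(geomean, genes)] <- seq_along(genes)
  out <- data.frame(gene_id = genes, ranks, geomean_rank = unname(geomean),
                    final_rank = final_rank, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  out <- out[order(out$final_rank), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "methods") <- methods
  class(out) <- c("consensus_ranking", "data.frame")
  out
}

#' @export
print.consensus_ranking <- function(x, ...) {
  cat(sprintf("Consensus ranking over %d methods (%s):\n",
              length(attr(x, "methods")),
              paste(attr(x, "methods"), collapse = ", ")))
  print.data.frame(x, digits = 4)
  invisible(x)
}
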