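#' Screen an FPKM matrix for candidate reference genes
#'
#' Computes, per gene, the mean FPKM (MV), the sample standard deviation (SD,
#' n - 1 denominator), the coefficient of variation (CV = SD / MV) and the
#' maximum fold change (MFC = max FPKM / min FPKM), then applies the
#' transcriptome-screening rule: keep genes with MV strictly above `mv_min`,
#' rank the survivors by SD ascending and keep the top `top_n_sd`, and of
#' those keep genes with CV strictly below `cv_max` and MFC strictly below
#' `mfc_max`. Genes containing any zero FPKM have an undefined MFC and never
#' pass. The returned table covers all genes, sorted by SD ascending.
#'
#' @param expr An [expression_matrix()].
#' @param mv_min Minimum mean FPKM (strict `>`; default 30).
#' @param top_n_sd How many of the lowest-SD genes to keep among those
#'   passing the MV filter (default 500).
#' @param cv_max CV upper bound (strict `<`; default 0.5).
#' @param mfc_max MFC upper bound (strict `<`; default 6.3).
#' @return A data frame of class `screening_stats` with columns `gene_id`,
#'   `mv`, `sd`, `cv`, `mfc`, `sd_rank` (rank by SD ascending over all genes,
#'   ties by gene id) and `passes`.
#' @examples
#' expr <- expression_matrix(rbind(ACT = c(50, 50, 50, 50),
#'                                 VAR = c(10, 20, 40, 80)),
#'                           sample_ids = paste0("s", 1:4))
#' screen_candidates(expr)
#' @export
screen_candidates <- function(expr, mv_min = 30, top_n_sd = 500,
                              cv_max = 0.5, mfc_max = 6.3) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr) < 2L) {
    stop("screening needs at least 2 samples per gene", call. = FALSE)
  }
  if (any(c(mv_min, top_n_sd, cv_max, mfc_max) <= 0)) {
    stop("screening thresholds must be strictly positive", call. = FALSE)
  }
  v <- unclass(expr)
  gene_id <- rownames(v)
  mv <- rowMeans(v)
  sdv <- apply(v, 1L, stats::sd)
  cv <- ifelse(mv > 0, sdv / mv, NA_real_)
  mn <- apply(v, 1L, min)
  mx <- apply(v, 1L, max)
  mfc <- ifelse(mn > 0, mx / mn, NA_real_)   # undefined with any zero FPKM

  sd_rank <- integer(length(mv))
  sd_rank[order(sdv, gene_id)] <- seq_along(sdv)

  # top-N rank is taken within the MV-passing subset (MV filter applied first)
  mv_pass <- mv > mv_min
  rank_in_subset <- rep(NA_integer_, length(mv))
  idx <- which(mv_pass)
  rank_in_subset[idx[order(sdv[idx], gene_id[idx])]] <- seq_along(idx)

  passes <- mv_pass &
    !is.na(rank_in_subset) & rank_in_subset <= top_n_sd &
    !is.na(cv) & cv < cv_max &
    !is.na(mfc) & mfc < mfc_max

  out <- data.frame(gene_id = gene_id, mv = mv, sd = sdv, cv = cv, mfc = mfc,
                    sd_rank = sd_rank, passes = passes,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$sd, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_stats", "data.frame")
  out
}
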