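# Four expression-stability statistics for candidate reference genes, all
# applied to a complete (replicate-collapsed) Ct matrix and all oriented the
# same way: lower statistic = more stable. Ties in any statistic are broken
# by gene id in lexicographic order so reports are deterministic.

make_stability_table <- function(method, gene_id, statistic, rank = NULL,
                                 extras = NULL) {
  if (is.null(rank)) {
    rank <- integer(length(statistic))
    rank[order(statistic, gene_id)] <- seq_along(statistic)
  }
  out <- data.frame(gene_id = gene_id, statistic = statistic, rank = rank,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(out$rank, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "method") <- method
  attr(out, "extras") <- extras
  class(out) <- c("stability_table", "data.frame")
  out
}

#' Method label of a stability table
#' @param x A `stability_table`.
#' @return One of `"delta_ct"`, `"bestkeeper"`, `"genorm"`, `"normfinder"`.
#' @export
stability_method <- function(x) attr(x, "method")

#' Method-specific payload of a stability table
#' @param x A `stability_table`.
#' @return A method-specific list or data frame (may be `NULL`).
#' @export
stability_extras <- function(x) attr(x, "extras")

#' @export
print.stability_table <- function(x, ...) {
  cat(sprintf("Stability table (%s), lower = more stable:\n",
              stability_method(x)))
  print.data.frame(x, digits = 4)
  invisible(x)
}

check_ct_input <- function(ct, min_genes, min_samples, method) {
  stopifnot(inherits(ct, "ct_matrix"))
  if (nrow(ct) < min_genes) {
    stop(sprintf("%s needs at least %d genes", method, min_genes),
         call. = FALSE)
  }
  if (ncol(ct) < min_samples) {
    stop(sprintf("%s needs at least %d samples", method, min_samples),
         call. = FALSE)
  }
  invisible(ct)
}

#' Comparative delta-Ct stability
#'
#' For every ordered gene pair (i, k) the per-sample difference
#' `Ct_i - Ct_k` is formed; a gene's statistic is the mean, over all other
#' genes k, of the sample standard deviation (n - 1 denominator) of those
#' differences. Because pairwise differences cancel any per-sample loading
#' offset, the statistic reflects how consistently a gene co-varies with the
#' rest of the panel.
#'
#' @param ct A complete [ct_matrix()] (collapse technical replicates first).
#' @return A `stability_table` with method `"delta_ct"`; the extras slot
#'   carries the full pairwise SD matrix.
#' @export
delta_ct_stability <- function(ct) {
  check_ct_input(ct, min_genes = 2L, min_samples = 3L, "the delta-Ct method")
  v <- ct_values(ct)
  n <- nrow(v)
  pair_sd <- matrix(0, n, n, dimnames = list(rownames(v), rownames(v)))
  for (i in seq_len(n - 1L)) {
    for (k in (i + 1L):n) {
      s <- stats::sd(v[i, ] - v[k, ])
      pair_sd[i, k] <- s
      pair_sd[k, i] <- s
    }
  }
  statistic <- rowSums(pair_sd) / (n - 1L)
  make_stability_table("delta_ct", rownames(v), unname(statistic),
                       extras = list(pairwise_sd = pair_sd))
}

#' BestKeeper descriptive stability
#'
#' Descriptive Ct dispersion per gene. Under the default `plain_sd` variant
#' the statistic is the sample standard deviation of the raw Ct values and
#' CV% = 100 * SD / mean Ct. Under `mad_geomean` the statistic is the mean
#' absolute deviation of Ct from the gene's geometric-mean Ct and
#' CV% = 100 * SD / geometric-mean Ct. Unlike the ratio-based methods,
#' BestKeeper operates on raw Ct and therefore does not cancel per-sample
#' loading offsets.
#'
#' @param ct A complete [ct_matrix()].
#' @param variant `"plain_sd"` (default) or `"mad_geomean"`.
#' @return A `stability_table` with method `"bestkeeper"`; the extras slot is
#'   a data frame with per-gene SD, CV% and a `"CV ± SD"` display label.
#' @export
bestkeeper_stability <- function(ct, variant = c("plain_sd", "mad_geomean")) {
  variant <- match.arg(variant)
  check_ct_input(ct, min_genes = 1L, min_samples = 2L, "BestKeeper")
  v <- ct_values(ct)
  if (variant == "plain_sd") {
    centre <- rowMeans(v)
    s <- apply(v, 1L, stats::sd)
  } else {
    if (any(v <= 0)) {
      stop("the mad_geomean variant requires strictly positive Ct values",
           call. = FALSE)
    }
    centre <- exp(rowMeans(log(v)))
    s <- rowMeans(abs(v - centre))
  }
  cv_pct <- 100 * s / centre
  extras <- data.frame(gene_id = rownames(v), sd = unname(s),
                       cv_pct = unname(cv_pct),
                       label = sprintf("%.2f ± %.2f", cv_pct, s),
                       stringsAsFactors = FALSE)
  make_stability_table("bestkeeper", rownames(v), unname(s), extras = extras)
}

# log2 relative quantities: logQ[i, j] = log2(E_i) * (min_j Ct[i, ] - Ct[i, j])
genorm_log_quantities <- function(v, efficiencies, gene_ids) {
  if (is.null(efficiencies)) {
    base <- rep(2, nrow(v))
  } else {
    if (is.data.frame(efficiencies)) {
      eff <- efficiencies$efficiency_pct
      names(eff) <- efficiencies$gene_id
      efficiencies <- eff
    }
    missing_eff <- setdiff(gene_ids, names(efficiencies))
    if (length(missing_eff) > 0L) {
      stop(sprintf("no amplification efficiency supplied for: %s",
                   paste(missing_eff, collapse = ", ")), call. = FALSE)
    }
    base <- 1 + efficiencies[gene_ids] / 100
  }
  log2(base) * (apply(v, 1L, min) - v)
}

#' geNorm M values for the full candidate set
#'
#' The average pairwise variation of each gene with all other candidates
#' (no iterative exclusion): `M_j = mean_k sd(log2(Q_j / Q_k))`.
#'
#' @inheritParams genorm_stability
#' @return Named numeric vector of M values, one per gene.
#' @export
genorm_m <- function(ct, efficiencies = NULL) {
  check_ct_input(ct, min_genes = 3L, min_samples = 2L, "geNorm")
  v <- ct_values(ct)
  logq <- genorm_log_quantities(v, efficiencies, rownames(v))
  m <- genorm_m_values(logq)
  names(m) <- rownames(v)
  m
}

genorm_m_values <- function(logq) {
  n <- nrow(logq)
  vjk <- matrix(0, n, n)
  for (j in seq_len(n - 1L)) {
    for (k in (j + 1L):n) {
      s <- stats::sd(logq[j, ] - logq[k, ])
      vjk[j, k] <- s
      vjk[k, j] <- s
    }
  }
  rowSums(vjk) / (n - 1L)
}

#' geNorm stability with iterative exclusion and pairwise variation
#'
#' Ct values are transformed to relative quantities
#' `Q = E^(minCt - Ct)` per gene (E = 2, perfect doubling, unless per-gene
#' efficiencies are supplied). A gene's M value is the mean, over all other
#' genes, of the standard deviation of the per-sample log2 expression ratio;
#' the gene with the largest M is removed and M values are recomputed until
#' two genes remain. The final pair is reported jointly (tied at rank 1.5).
#' The pairwise variation V(n/n+1) is the standard deviation of
#' `log2(NF_n / NF_(n+1))`, where NF_n is the per-sample geometric mean of
#' the n most stable genes' quantities; V values are advisory output
#' (commonly read against a 0.15 guidance threshold) and are never enforced.
#'
#' @param ct A complete [ct_matrix()] with at least 3 genes.
#' @param efficiencies Optional per-gene amplification efficiencies in
#'   percent: a named numeric vector or a [curve_fit_table()] data frame.
#'   Default uses E = 2 for every gene.
#' @param v_cutoff Guidance threshold for V(n/n+1) (default 0.15).
#' @return A list of class `genorm_result` with `table` (a
#'   `stability_table`, statistic = M at the step each gene was removed, the
#'   final pair at the terminal M), `removal_order`, `pairwise_variation`
#'   (data frame of n and V(n/n+1) for n = 2 .. n_genes - 1) and
#'   `recommended_n` (smallest n with V < `v_cutoff`, or `NA`).
#' @export
genorm_stability <- function(ct, efficiencies = NULL, v_cutoff = 0.15) {
  check_ct_input(ct, min_genes = 3L, min_samples = 2L, "geNorm")
  v <- ct_values(ct)
  gene_ids <- rownames(v)
  logq <- genorm_log_quantities(v, efficiencies, gene_ids)

  remaining <- gene_ids
  removal_order <- character(0)
  m_at_removal <- numeric(0)
  while (length(remaining) > 2L) {
    m <- genorm_m_values(logq[remaining, , drop = FALSE])
    worst_pool <- remaining[m == max(m)]
    worst <- worst_pool[order(worst_pool)][length(worst_pool)]
    removal_order <- c(removal_order, worst)
    m_at_removal <- c(m_at_removal, max(m))
    remaining <- setdiff(remaining, worst)
  }
  final_pair <- sort(remaining)
  terminal_m <- genorm_m_values(logq[final_pair, , drop = FALSE])[1L]

  statistic <- c(terminal_m, terminal_m, rev(m_at_removal))
  ids <- c(final_pair, rev(removal_order))
  rank <- c(1.5, 1.5, seq(3L, length.out = length(removal_order)))
  table <- make_stability_table("genorm", ids, statistic, rank = rank)

  ranked <- ids                       # most stable first
  n_genes <- length(ranked)
  vv <- numeric(0)
  if (n_genes >= 3L) {
    nf <- vapply(seq(2L, n_genes),
                 function(n) colMeans(logq[ranked[seq_len(n)], , drop = FALSE]),
                 numeric(ncol(logq)))    # log2 NF_n per sample, columns n=2..
    vv <- vapply(seq_len(n_genes - 2L), function(i) {
      stats::sd(nf[, i] - nf[, i + 1L])
    }, numeric(1L))
  }
  pairwise_variation <- data.frame(n = seq(2L, length.out = length(vv)),
                                   v = vv)
  rec <- pairwise_variation$n[pairwise_variation$v < v_cutoff]
  structure(list(table = table,
                 removal_order = removal_order,
                 m_at_removal = m_at_removal,
                 final_pair = final_pair,
                 pairwise_variation = pairwise_variation,
                 recommended_n = if (length(rec)) rec[1L] else NA_integer_,
                 v_cutoff = v_cutoff),
            class = "genorm_result")
}

#' @export
print.genorm_result <- function(x, ...) {
  print(x$table)
  cat(sprintf("Most stable pair: %s (terminal M = %.4f)\n",
              paste(x$final_pair, collapse = " & "), x$table$statistic[1L]))
  if (nrow(x$pairwise_variation) > 0L) {
    cat("Pairwise variation V(n/n+1):\n")
    print(x$pairwise_variation, digits = 4)
  }
  invisible(x)
}

#' NormFinder model-based stability
#'
#' Implements the model-based variance decomposition behind the NormFinder
#' stability value. Within each sample group the gene x sample Ct block is
#' double-centred (gene means, sample means and the grand mean removed); the
#' per-gene intra-group variance is estimated from the centred residuals with
#' the small-sample bias correction
#' `sigma2_ig = (z_ig - sum(z_g) / (I (I - 1))) * I / (I - 2)` where
#' `z_ig = sum_j r_igj^2 / (n_g - 1)` and I is the number of genes, truncated
#' below at zero. With two or more groups the inter-group deviation `d_ig`
#' (group gene mean minus gene grand mean, centred to sum to zero across
#' genes within each group) is shrunk by its sampling variance
#' `sigma2_ig / n_g` towards zero using the empirical between-group variance
#' `gamma2`, and the stability value is the average over groups of
#' `|d_shrunk| + sqrt(sigma2_ig / n_g)`. With a single group the stability
#' value is the intra-group standard deviation alone.
#'
#' @param ct A complete [ct_matrix()] with at least 3 genes.
#' @param group_by How to partition samples: `"group"` (default, the
#'   metadata group label), `"condition"` (treatment/control), or `"none"`
#'   for single-group mode.
#' @return A `stability_table` with method `"normfinder"`; the extras slot
#'   carries the per-group intra-group variances, inter-group deviations and
#'   the shrinkage variance `gamma2`.
#' @export
normfinder_stability <- function(ct, group_by = c("group", "condition", "none")) {
  group_by <- match.arg(group_by)
  check_ct_input(ct, min_genes = 3L, min_samples = 2L, "NormFinder")
  v <- ct_values(ct)
  meta <- sample_meta(ct)
  groups <- switch(group_by,
                   group = meta$group,
                   condition = meta$condition,
                   none = rep("all", ncol(v)))
  labels <- unique(groups)
  sizes <- table(factor(groups, levels = labels))
  if (length(labels) > 1L && any(sizes < 2L)) {
    stop(sprintf(
      "group(s) %s have a single sample; every group needs >= 2 samples (or use group_by = \"none\" for single-group mode)",
      paste(names(sizes)[sizes < 2L], collapse = ", ")), call. = FALSE)
  }
  i_genes <- nrow(v)
  g_n <- length(labels)
  sigma2 <- matrix(0, i_genes, g_n, dimnames = list(rownames(v), labels))
  gmean <- matrix(0, i_genes, g_n, dimnames = list(rownames(v), labels))
  for (g in seq_len(g_n)) {
    block <- v[, groups == labels[g], drop = FALSE]
    ng <- ncol(block)
    gmean[, g] <- rowMeans(block)
    r <- block - rowMeans(block)
    r <- sweep(r, 2L, colMeans(block)) + mean(block)
    if (ng > 1L) {
      z <- rowSums(r^2) / (ng - 1L)
      s2 <- (z - sum(z) / (i_genes * (i_genes - 1L))) * i_genes / (i_genes - 2L)
      sigma2[, g] <- pmax(s2, 0)
    }
  }
  if (g_n == 1L) {
    statistic <- sqrt(sigma2[, 1L])
    extras <- list(sigma2 = sigma2, d = NULL, gamma2 = NA_real_,
                   group_by = group_by)
    return(make_stability_table("normfinder", rownames(v),
                                unname(statistic), extras = extras))
  }
  d <- gmean - rowMeans(gmean)
  d <- sweep(d, 2L, colMeans(d))             # deviations sum to 0 across genes
  vard <- sweep(sigma2, 2L, as.numeric(sizes), "/")
  gamma2 <- max(0, sum(d^2) / ((i_genes - 1L) * (g_n - 1L)) - mean(vard))
  shrink <- ifelse(gamma2 + vard > 0, gamma2 / (gamma2 + vard), 0)
  d_shrunk <- d * shrink
  statistic <- rowMeans(abs(d_shrunk) + sqrt(vard))
  extras <- list(sigma2 = sigma2, d = d, d_shrunk = d_shrunk,
                 gamma2 = gamma2, group_by = group_by)
  make_stability_table("normfinder", rownames(v), unname(statistic),
                       extras = extras)
}
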