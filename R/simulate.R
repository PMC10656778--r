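# Seeded simulators with known ground truth. The Ct model is additive on the
# Ct (log2) scale:
#
#   Ct[i, g, j] = mu_i + beta[i, g] + phi[g, j] + eps[i, g, j]
#
# with beta ~ N(0, tau_i^2) drawn once per (gene, group) -- the instability a
# stability method should detect -- phi ~ N(0, lambda^2) drawn once per sample
# and shared by all genes (template-loading offsets, which ratio-based methods
# cancel and raw-Ct methods do not), and eps ~ N(0, sigma_eps^2) replicate
# noise.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Specify a Ct simulation
#'
#' @param mu Per-gene baseline Ct (cycles), each in \[15, 35\].
#' @param tau Per-gene group-effect SD (cycles); the planted instability
#'   magnitude, >= 0. Smaller tau = more stable.
#' @param n_groups Number of condition groups (>= 1).
#' @param n_bio_reps Biological replicates per group (>= 2).
#' @param loading_sd Per-sample loading-offset SD lambda (cycles), shared
#'   across genes. Default 1 cycle.
#' @param noise_sd Replicate noise SD sigma_eps (cycles). Default 0.2, a
#'   typical qPCR technical noise level.
#' @param seed Integer seed.
#' @param gene_ids,group_labels Optional identifiers.
#' @return A list of class `sim_spec`.
#' @export
sim_spec <- function(mu, tau, n_groups, n_bio_reps, loading_sd = 1,
                     noise_sd = 0.2, seed = 1L, gene_ids = NULL,
                     group_labels = NULL) {
  mu <- as.numeric(mu)
  tau <- as.numeric(tau)
  if (length(tau) == 1L) tau <- rep(tau, length(mu))
  if (length(mu) != length(tau)) {
    stop("mu and tau must have the same length", call. = FALSE)
  }
  if (any(mu < 15 | mu > 35)) {
    stop("baseline Ct values mu must lie in [15, 35]", call. = FALSE)
  }
  if (any(tau < 0) || loading_sd < 0 || noise_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (n_groups < 1L) stop("n_groups must be >= 1", call. = FALSE)
  if (n_bio_reps < 2L) stop("n_bio_reps must be >= 2", call. = FALSE)
  if (is.null(gene_ids)) gene_ids <- sprintf("gene%02d", seq_along(mu))
  if (is.null(group_labels)) group_labels <- sprintf("grp%02d", seq_len(n_groups))
  stopifnot(length(gene_ids) == length(mu), length(group_labels) == n_groups)
  structure(list(mu = mu, tau = tau, n_groups = as.integer(n_groups),
                 n_bio_reps = as.integer(n_bio_reps),
                 loading_sd = loading_sd, noise_sd = noise_sd,
                 seed = as.integer(seed), gene_ids = as.character(gene_ids),
                 group_labels = as.character(group_labels)),
            class = "sim_spec")
}

#' Simulate a Ct matrix with known stability ground truth
#'
#' Draws Ct values from the additive model described above; deterministic
#' given the spec's seed. The first group is labelled `condition = "control"`,
#' all others `"treatment"`, so the result can feed [ddct_single()] directly.
#'
#' @param spec A [sim_spec()].
#' @return A list with `ct` (a [ct_matrix()]) and `truth`, a data frame of
#'   gene ids and their tau values sorted most-stable first (ascending tau,
#'   ties by gene id).
#' @export
simulate_ct <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  n_genes <- length(spec$mu)
  n_samples <- spec$n_groups * spec$n_bio_reps
  with_seed(spec$seed, {
    beta <- matrix(stats::rnorm(n_genes * spec$n_groups, 0, spec$tau),
                   nrow = n_genes)           # tau recycles down rows
    phi <- stats::rnorm(n_samples, 0, spec$loading_sd)
    eps <- matrix(stats::rnorm(n_genes * n_samples, 0, spec$noise_sd),
                  nrow = n_genes)
  })
  grp_of_sample <- rep(seq_len(spec$n_groups), each = spec$n_bio_reps)
  values <- spec$mu + beta[, grp_of_sample, drop = FALSE] +
    matrix(phi, n_genes, n_samples, byrow = TRUE) + eps
  # keep values inside the container's (0, 45] admissible band
  values <- pmin(pmax(values, 1), 45)
  meta <- data.frame(
    sample_id = sprintf("%s_r%d", spec$group_labels[grp_of_sample],
                        rep(seq_len(spec$n_bio_reps), spec$n_groups)),
    group = spec$group_labels[grp_of_sample],
    condition = ifelse(grp_of_sample == 1L, "control", "treatment"),
    bio_rep = rep(seq_len(spec$n_bio_reps), spec$n_groups),
    tech_rep = 1L, stringsAsFactors = FALSE)
  ct <- ct_matrix(values, sample_meta = meta, gene_ids = spec$gene_ids,
                  sample_ids = meta$sample_id)
  ord <- order(spec$tau, spec$gene_ids)
  truth <- data.frame(gene_id = spec$gene_ids[ord], tau = spec$tau[ord],
                      stability_rank = seq_len(n_genes),
                      stringsAsFactors = FALSE)
  list(ct = ct, truth = truth)
}

#' Simulate an FPKM matrix with a planted stable gene set
#'
#' Stable genes are log-normal with mean expression in \[40, 150\] FPKM and
#' log-scale SD 0.1 (CV about 0.1, MFC well under 2 at realistic sample
#' sizes). Unstable genes are split between low-expression genes (mean in
#' \[1, 20\], failing the MV > 30 filter) and high-dispersion genes (mean in
#' \[40, 150\], log-scale SD 1.5, CV about 2.9, failing the CV and MFC
#' filters). The margins are wide enough that the standard screening
#' thresholds separate planted from non-planted genes.
#'
#' @param n_genes Total genes.
#' @param n_samples Samples (libraries).
#' @param n_stable Number of planted stable genes (<= `n_genes`).
#' @param seed Integer seed.
#' @return A list with `fpkm` (an [expression_matrix()]) and `stable_genes`
#'   (character vector of the planted gene ids).
#' @export
simulate_fpkm <- function(n_genes, n_samples, n_stable, seed = 1L) {
  if (n_stable > n_genes) stop("n_stable must be <= n_genes", call. = FALSE)
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  sample_ids <- sprintf("lib%02d", seq_len(n_samples))
  n_unstable <- n_genes - n_stable
  n_low <- n_unstable %/% 2L
  n_high <- n_unstable - n_low
  with_seed(seed, {
    kind <- sample(rep(c("stable", "low", "high"), c(n_stable, n_low, n_high)))
    m <- numeric(n_genes)
    sdlog <- numeric(n_genes)
    m[kind == "stable"] <- stats::runif(n_stable, 40, 150)
    sdlog[kind == "stable"] <- 0.1
    m[kind == "low"] <- stats::runif(n_low, 1, 20)
    sdlog[kind == "low"] <- 0.1
    m[kind == "high"] <- stats::runif(n_high, 40, 150)
    sdlog[kind == "high"] <- 1.5
    values <- m * exp(matrix(stats::rnorm(n_genes * n_samples, 0, sdlog),
                             nrow = n_genes))   # sdlog recycles down rows
  })
  fpkm <- expression_matrix(values, gene_ids = gene_ids,
                            sample_ids = sample_ids)
  list(fpkm = fpkm, stable_genes = gene_ids[kind == "stable"])
}

#' Simulate a dilution series for a known amplification efficiency
#'
#' Generates 10-fold dilution points `x = 0, -1, -2, ...` with
#' `Ct = intercept - slope * x + noise`, where
#' `slope = 1 / log10(1 + E / 100)` for true efficiency `E` percent. With
#' zero noise, [fit_standard_curve()] inverts the series exactly.
#'
#' @param gene_id Primer-pair identifier.
#' @param true_efficiency Amplification efficiency in percent, in (50, 150\].
#' @param intercept Ct of the undiluted point (cycles).
#' @param n_points Number of distinct dilutions (default 5).
#' @param noise_sd Gaussian Ct noise SD (cycles).
#' @param seed Integer seed.
#' @param n_replicates Technical replicates per dilution (default 2).
#' @return A [dilution_series()].
#' @export
simulate_dilution <- function(gene_id, true_efficiency, intercept = 22,
                              n_points = 5L, noise_sd = 0, seed = 1L,
                              n_replicates = 2L) {
  if (true_efficiency <= 50 || true_efficiency > 150) {
    stop("true_efficiency must lie in (50, 150]", call. = FALSE)
  }
  if (n_points < 3L) stop("n_points must be >= 3", call. = FALSE)
  slope <- 1 / log10(1 + true_efficiency / 100)
  x <- rep(-(seq_len(n_points) - 1), each = max(1L, n_replicates))
  ct <- with_seed(seed, intercept - slope * x +
                    stats::rnorm(length(x), 0, noise_sd))
  dilution_series(gene_id, log10_amount = x, ct = ct)
}
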