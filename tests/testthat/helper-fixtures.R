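# Fixture builders and brute-force oracles shared across the suite.

make_meta <- function(sample_id, group = "g1", condition = "control",
                      bio_rep = seq_along(sample_id), tech_rep = 1L) {
  data.frame(sample_id = sample_id, group = group, condition = condition,
             bio_rep = bio_rep, tech_rep = tech_rep,
             stringsAsFactors = FALSE)
}

make_ct <- function(values, group = "g1", condition = "control",
                    bio_rep = NULL, tech_rep = 1L) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("s", seq_len(ncol(values)))
  }
  if (is.null(bio_rep)) bio_rep <- seq_len(ncol(values))
  ct_matrix(values,
            sample_meta = make_meta(colnames(values), group = group,
                                    condition = condition, bio_rep = bio_rep,
                                    tech_rep = tech_rep))
}

# The 3-gene x 3-sample worked fixture: two perfectly co-varying genes and
# one flat gene.
worked_ct <- function() {
  make_ct(rbind(G1 = c(20, 21, 22), G2 = c(20, 21, 22), G3 = c(20, 20, 20)))
}

# Exhaustive pairwise brute force for the comparative delta-Ct statistic:
# mean over partners of the sample SD of the pairwise Ct difference. With
# E = 2 for every gene this same quantity is, in closed form, the geNorm M
# value, which gives an independent oracle for both methods.
oracle_pairwise_sd_mean <- function(v) {
  n <- nrow(v)
  vapply(seq_len(n), function(i) {
    mean(vapply(setdiff(seq_len(n), i), function(k) {
      d <- v[i, ] - v[k, ]
      sqrt(sum((d - mean(d))^2) / (length(d) - 1))
    }, numeric(1)))
  }, numeric(1))
}

# Ct matrices on a dyadic grid (multiples of 2^-6) with 8 samples, so that
# adding dyadic per-sample offsets and mean-centering are exact in IEEE
# doubles: the loading-invariance tests can assert bit identity.
dyadic_ct_pair <- function(n_genes = 6, n_samples = 8) {
  v <- matrix(round(runif(n_genes * n_samples, 16, 32) * 64) / 64,
              n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  off <- round(runif(n_samples, -3, 3) * 64) / 64
  list(base = make_ct(v), shifted = make_ct(sweep(v, 2, -off)))
}

# A random strict ranking (permutation) packaged as a stability table.
random_stability_table <- function(genes, method) {
  r <- sample(seq_along(genes))
  structure(data.frame(gene_id = genes, statistic = as.numeric(r), rank = r,
                       stringsAsFactors = FALSE),
            method = method, class = c("stability_table", "data.frame"))
}
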