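# Frozen outputs of an independent implementation of the model-based
# (NormFinder) variance decomposition, run once on the seeded fixtures below
# (synthetic oracle fixture; explicit-loop Python implementation of the same
# published equations, no shared code with the package).
NF_ORACLE_MULTI <- c(gene01 = 0.292901519494, gene02 = 0.170294641974,
                     gene03 = 0.261567584683, gene04 = 0.171039699434,
                     gene05 = 0.295908477202, gene06 = 0.318461944497,
                     gene07 = 0.665122492393, gene08 = 0.792736577922)
NF_ORACLE_SINGLE <- c(A = 0.081068241517, B = 0.112531910952,
                      C = 1.001433085100)

nf_multi_fixture <- function() {
  spec <- sim_spec(mu = seq(19, 29, length.out = 8),
                   tau = c(0.05, 0.1, 0.15, 0.2, 0.3, 0.5, 0.8, 1.2),
                   n_groups = 4, n_bio_reps = 6,
                   loading_sd = 1, noise_sd = 0.2, seed = 7)
  simulate_ct(spec)$ct
}

nf_single_fixture <- function() {
  set.seed(11)
  n <- 30
  phi <- rnorm(n, 0, 1)
  make_ct(rbind(A = 20 + phi + rnorm(n, 0, 0.1),
                B = 24 + phi + rnorm(n, 0, 0.1),
                C = 28 + phi + rnorm(n, 0, 1.0)),
          group = "all")
}

test_that("delta-Ct and geNorm M match the exhaustive pairwise brute force", {
  ct <- worked_ct()
  oracle <- oracle_pairwise_sd_mean(unclass(ct)[, ])
  expect_equal(oracle, c(0.5, 0.5, 1.0))

  dct <- delta_ct_stability(ct)
  expect_equal(dct$statistic[match(c("G1", "G2", "G3"), dct$gene_id)], oracle)
  expect_identical(dct$gene_id[dct$rank == 3], "G3")

  expect_equal(unname(genorm_m(ct)[c("G1", "G2", "G3")]), oracle)

  # random matrices too, not just the worked fixture
  set.seed(31)
  for (r in 1:5) {
    v <- matrix(runif(5 * 6, 18, 30), 5, 6,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:6)))
    ct_r <- make_ct(v)
    o <- oracle_pairwise_sd_mean(v)
    expect_equal(delta_ct_stability(ct_r)$statistic[
      match(rownames(v), delta_ct_stability(ct_r)$gene_id)], o,
      tolerance = 1e-12)
    expect_equal(unname(genorm_m(ct_r)[rownames(v)]), o, tolerance = 1e-12)
  }
})

test_that("perfectly co-varying genes score zero in delta-Ct", {
  ct <- make_ct(rbind(A = c(20, 21, 22, 23), B = c(20, 21, 22, 23),
                      C = c(20, 21, 22, 23)))
  expect_true(all(delta_ct_stability(ct)$statistic == 0))
  expect_error(delta_ct_stability(make_ct(rbind(A = c(20, 21, 22)))),
               "at least 2 genes")
})

test_that("BestKeeper variants follow their definitions and see loading shifts", {
  ct <- make_ct(rbind(FLAT = c(20, 20, 20), G = c(20, 21, 22),
                      H = c(25, 24, 26)))
  plain <- bestkeeper_stability(ct)
  expect_equal(plain$statistic[plain$gene_id == "FLAT"], 0)
  expect_equal(plain$statistic[plain$gene_id == "G"], 1)
  ex <- stability_extras(plain)
  expect_equal(ex$cv_pct[ex$gene_id == "G"], 100 / 21, tolerance = 1e-9)
  expect_match(ex$label[ex$gene_id == "G"], "4.76 ± 1.00")

  mad <- bestkeeper_stability(ct, variant = "mad_geomean")
  geo <- prod(c(20, 21, 22))^(1 / 3)
  expect_equal(mad$statistic[mad$gene_id == "G"],
               mean(abs(c(20, 21, 22) - geo)), tolerance = 1e-9)
  expect_equal(round(mad$statistic[mad$gene_id == "G"], 4), 0.672)

  # raw-Ct dispersion is NOT invariant under per-sample loading offsets
  v <- unclass(ct)[, ]
  shifted <- make_ct(sweep(v, 2, c(-2, 0, 2)))
  expect_false(isTRUE(all.equal(bestkeeper_stability(shifted)$statistic,
                                plain$statistic)))
})

test_that("geNorm excludes stepwise, ties the final pair, and reports V(n/n+1)", {
  ct <- worked_ct()
  g <- genorm_stability(ct)
  expect_identical(g$removal_order, "G3")
  expect_equal(g$m_at_removal, 1.0)
  expect_identical(g$final_pair, c("G1", "G2"))
  expect_equal(g$table$rank, c(1.5, 1.5, 3))
  # identical Ct vectors: the final pair's mutual variation is zero
  expect_equal(g$table$statistic[1:2], c(0, 0))
  expect_identical(g$pairwise_variation$n, 2L)

  expect_error(genorm_stability(make_ct(rbind(A = c(20, 21), B = c(20, 21)))),
               "at least 3 genes")

  # removing the least stable gene does not increase the survivors' mean M
  set.seed(13)
  v <- matrix(runif(6 * 8, 18, 30), 6, 8,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:8)))
  m_full <- genorm_m(make_ct(v))
  worst <- names(which.max(m_full))
  m_red <- genorm_m(make_ct(v[setdiff(rownames(v), worst), ]))
  expect_lte(mean(m_red), mean(m_full[setdiff(names(m_full), worst)]) + 1e-12)
})

test_that("geNorm accepts per-gene amplification efficiencies", {
  v <- rbind(G1 = c(20, 21, 22), G2 = c(20, 21.5, 23), G3 = c(20, 22, 24))
  colnames(v) <- paste0("s", 1:3)
  ct <- make_ct(v)
  eff <- c(G1 = 100, G2 = 100, G3 = 90)
  # independent evaluation of the definition: quantities Q_i = E_i^(min - Ct)
  base <- c(2, 2, 1.9)
  logq <- log2(base) * (apply(v, 1, min) - v)
  m_direct <- vapply(1:3, function(j) {
    mean(vapply(setdiff(1:3, j), function(k) sd(logq[j, ] - logq[k, ]),
                numeric(1)))
  }, numeric(1))
  m <- genorm_m(ct, efficiencies = eff)
  expect_equal(unname(m), m_direct, tolerance = 1e-12)
  # base 1.9 differs from the default base 2 result
  expect_false(isTRUE(all.equal(unname(m), unname(genorm_m(ct)))))
  expect_error(genorm_m(ct, efficiencies = c(G1 = 100)), "no amplification")
})

test_that("delta-Ct and geNorm are bit-identical under per-sample Ct offsets", {
  set.seed(99)
  for (r in 1:25) {
    p <- dyadic_ct_pair()
    expect_identical(delta_ct_stability(p$base)$statistic,
                     delta_ct_stability(p$shifted)$statistic)
    expect_identical(genorm_stability(p$base)$table$statistic,
                     genorm_stability(p$shifted)$table$statistic)
  }
})

test_that("all four methods are equivariant under gene relabelling", {
  set.seed(47)
  v <- matrix(runif(6 * 9, 18, 30), 6, 9,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:9)))
  meta_groups <- rep(c("A", "B", "C"), each = 3)
  ct <- make_ct(v, group = meta_groups, bio_rep = rep(1:3, 3))
  perm <- c(4, 1, 6, 2, 5, 3)
  vp <- v[perm, ]
  rownames(vp) <- rownames(v)[perm]
  ctp <- make_ct(vp, group = meta_groups, bio_rep = rep(1:3, 3))
  for (fun in list(delta_ct_stability, bestkeeper_stability,
                   function(x) genorm_stability(x)$table,
                   normfinder_stability)) {
    a <- fun(ct)
    b <- fun(ctp)
    expect_equal(b$statistic[match(a$gene_id, b$gene_id)], a$statistic,
                 tolerance = 1e-12)
  }
})

test_that("NormFinder matches the frozen synthetic oracle fixture to 1e-6", {
  t <- normfinder_stability(nf_multi_fixture())
  expect_equal(t$statistic[match(names(NF_ORACLE_MULTI), t$gene_id)],
               unname(NF_ORACLE_MULTI), tolerance = 1e-6)

  t1 <- normfinder_stability(nf_single_fixture(), group_by = "none")
  expect_equal(t1$statistic[match(names(NF_ORACLE_SINGLE), t1$gene_id)],
               unname(NF_ORACLE_SINGLE), tolerance = 1e-6)
  # the high-noise gene ranks last in single-group mode
  expect_identical(t1$gene_id[t1$rank == 3], "C")
})

test_that("NormFinder handles degenerate inputs as specified", {
  const <- make_ct(matrix(20, 3, 6, dimnames = list(paste0("g", 1:3),
                                                    paste0("s", 1:6))),
                   group = rep(c("A", "B"), each = 3), bio_rep = rep(1:3, 2))
  expect_true(all(normfinder_stability(const)$statistic == 0))

  lone <- make_ct(matrix(20 + runif(9), 3, 3,
                         dimnames = list(paste0("g", 1:3), paste0("s", 1:3))),
                  group = c("A", "A", "B"), bio_rep = c(1, 2, 1))
  expect_error(normfinder_stability(lone), "single sample.*single-group")
})

test_that("a strongly unstable planted gene ranks last in all four methods", {
  spec <- sim_spec(mu = rep(c(20, 22, 24, 26, 28), 2),
                   tau = c(rep(0.05, 9), 2.0), n_groups = 5, n_bio_reps = 3,
                   loading_sd = 1, noise_sd = 0.2, seed = 5)
  sim <- simulate_ct(spec)
  for (t in list(delta_ct_stability(sim$ct), bestkeeper_stability(sim$ct),
                 genorm_stability(sim$ct)$table,
                 normfinder_stability(sim$ct))) {
    expect_identical(t$gene_id[which.max(t$rank)], "gene10")
  }
})
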