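# Two groups (exp/ctl), one biological sample each, for the worked examples.
two_group_ct <- function(v) {
  make_ct(v, group = rep(c("exp", "ctl"), each = ncol(v) / 2),
          condition = rep(c("treatment", "control"), each = ncol(v) / 2),
          bio_rep = rep(seq_len(ncol(v) / 2), 2))
}

test_that("single-reference ddCt reproduces direct evaluation", {
  ct <- two_group_ct(rbind(tg = c(24, 26), ref = c(20, 21)))
  res <- ddct_single(ct, "tg", "ref", control_group = "ctl")
  exp_row <- res[res$sample_group == "exp", ]
  expect_equal(exp_row$delta_delta_ct, -1)   # 4 - 5
  expect_equal(exp_row$fold_change, 2)
  ctl_row <- res[res$sample_group == "ctl", ]
  expect_equal(ctl_row$delta_delta_ct, 0)    # control group is its own baseline
  expect_equal(ctl_row$fold_change, 1)

  # identical target and reference vectors: all folds are exactly 1
  ct_id <- two_group_ct(rbind(tg = c(24, 26), ref = c(24, 26)))
  expect_true(all(ddct_single(ct_id, "tg", "ref", "ctl")$fold_change == 1))

  expect_error(ddct_single(ct, "tg", "tg", "ctl"), "differ from the target")
  expect_error(ddct_single(ct, "tg", "ref", "nope"), "no samples")
})

test_that("dual-reference ddCt averages the per-reference terms", {
  ct <- two_group_ct(rbind(tg = c(24, 26), r1 = c(20, 21), r2 = c(22, 23)))
  res <- ddct_multi(ct, "tg", c("r1", "r2"), "ctl")
  exp_row <- res[res$sample_group == "exp", ]
  expect_equal(exp_row$delta_delta_ct, -1)   # (-1)/2 + (-1)/2
  expect_equal(exp_row$fold_change, 2)

  # duplicated reference reduces exactly to the single-reference result
  dup <- ddct_multi(ct, "tg", c("r1", "r1"), "ctl")
  single <- ddct_single(ct, "tg", "r1", "ctl")
  expect_identical(dup$delta_delta_ct, single$delta_delta_ct)
  expect_identical(dup$fold_change, single$fold_change)

  # per-reference folds 2 and 8 combine to their geometric mean 4
  ct2 <- two_group_ct(rbind(tg = c(24, 26), ra = c(20, 21), rb = c(23, 22)))
  fa <- ddct_single(ct2, "tg", "ra", "ctl")
  fb <- ddct_single(ct2, "tg", "rb", "ctl")
  both <- ddct_multi(ct2, "tg", c("ra", "rb"), "ctl")
  expect_equal(fa$fold_change[fa$sample_group == "exp"], 2)
  expect_equal(fb$fold_change[fb$sample_group == "exp"], 8)
  expect_equal(both$fold_change[both$sample_group == "exp"], 4)

  expect_error(ddct_multi(ct, "tg", character(0), "ctl"), "at least one")
})

test_that("fold changes cancel per-sample loading and ignore reference order", {
  set.seed(23)
  v <- matrix(runif(4 * 6, 20, 28), 4, 6,
              dimnames = list(c("tg", "r1", "r2", "r3"), paste0("s", 1:6)))
  ct <- make_ct(v, group = rep(c("exp", "ctl"), each = 3),
                condition = rep(c("treatment", "control"), each = 3),
                bio_rep = rep(1:3, 2))
  shifted <- make_ct(sweep(v, 2, c(3, 0, 0, 0, 0, 0), "+"),
                     group = rep(c("exp", "ctl"), each = 3),
                     condition = rep(c("treatment", "control"), each = 3),
                     bio_rep = rep(1:3, 2))
  a <- ddct_multi(ct, "tg", c("r1", "r2"), "ctl")
  b <- ddct_multi(shifted, "tg", c("r1", "r2"), "ctl")
  expect_equal(b$fold_change, a$fold_change, tolerance = 1e-12)

  swapped <- ddct_multi(ct, "tg", c("r2", "r1"), "ctl")
  expect_equal(swapped$delta_delta_ct, a$delta_delta_ct, tolerance = 1e-12)
})

test_that("expression profiles expose an unstable reference's group bias", {
  # identical references: every normalization scheme agrees exactly
  v <- rbind(tg = c(24, 25, 26, 27), r1 = c(20, 21, 20, 21),
             r2 = c(20, 21, 20, 21), bad = c(20, 21, 20, 21))
  ct <- make_ct(v, group = rep(c("A", "ctl"), each = 2),
                condition = rep(c("treatment", "control"), each = 2),
                bio_rep = rep(1:2, 2))
  prof <- expression_profile(ct, "tg", c("r1", "r2"), "bad", "ctl")
  folds_a <- prof$fold_change[prof$sample_group == "A"]
  expect_true(all(abs(folds_a - folds_a[1]) < 1e-12))

  # a reference carrying +2 cycles in group A distorts that group's folds
  # by exactly 2^2 = 4
  v2 <- v
  v2["bad", 1:2] <- v2["bad", 1:2] + 2
  ct2 <- make_ct(v2, group = rep(c("A", "ctl"), each = 2),
                 condition = rep(c("treatment", "control"), each = 2),
                 bio_rep = rep(1:2, 2))
  prof2 <- expression_profile(ct2, "tg", c("r1", "r2"), "bad", "ctl")
  stable_fold <- prof2$fold_change[prof2$scheme == "r1" &
                                     prof2$sample_group == "A"]
  bad_fold <- prof2$fold_change[prof2$scheme == "bad" &
                                  prof2$sample_group == "A"]
  expect_equal(bad_fold / stable_fold, 4, tolerance = 1e-12)

  # references differing only by technical noise: single vs combined
  # normalization agree within 2^(3 * sigma)
  set.seed(29)
  sigma <- 0.1
  v3 <- rbind(tg = runif(6, 24, 26), ra = 20 + rnorm(6, 0, sigma),
              rb = 20 + rnorm(6, 0, sigma))
  ct3 <- make_ct(v3, group = rep(c("A", "ctl"), each = 3),
                 condition = rep(c("treatment", "control"), each = 3),
                 bio_rep = rep(1:3, 2))
  pa <- ddct_single(ct3, "tg", "ra", "ctl")
  pc <- ddct_multi(ct3, "tg", c("ra", "rb"), "ctl")
  ratio <- pa$fold_change[pa$sample_group == "A"] /
    pc$fold_change[pc$sample_group == "A"]
  expect_lt(max(ratio, 1 / ratio), 2^(3 * sigma))
})
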