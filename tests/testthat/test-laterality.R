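test_that("left-right ratio handles symmetry, one-sidedness and 0/0", {
  expect_equal(lr_ratio(5, 5), 0.5)
  expect_equal(lr_ratio(10, 0), 0)
  expect_equal(lr_ratio(0, 10), 1)
  expect_true(is.na(lr_ratio(0, 0)))   # undefined, never coerced to 0.5
  expect_error(lr_ratio(-1, 2), "non-negative")
})

test_that("preference bins sit exactly at 0.33 and 0.67 with closed interior", {
  expect_equal(classify_preference(0.2), "left")
  expect_equal(classify_preference(0.5), "balanced")
  expect_equal(classify_preference(0.8), "right")
  expect_equal(classify_preference(c(0.33, 0.67)), c("balanced", "balanced"))
  expect_equal(classify_preference(0.3299999), "left")
  expect_equal(classify_preference(0.6700001), "right")
  expect_equal(classify_preference(NA_real_), "undefined")
  expect_error(classify_preference(1.2), "0, 1")
})

test_that("bias index is max-share and equals max(r, 1 - r)", {
  expect_equal(bias_index(3, 3), 0.5)
  expect_equal(bias_index(0, 7), 1)
  expect_equal(bias_index(1, 3), 0.75)
  expect_true(is.na(bias_index(0, 0)))
  set.seed(42)
  for (i in 1:200) {
    l <- rpois(1, 6); r <- rpois(1, 6)
    if (l + r == 0) next
    expect_equal(bias_index(l, r),
                 max(lr_ratio(l, r), 1 - lr_ratio(l, r)))
  }
})

test_that("ICC agrees with the aov mean-squares oracle on random matrices", {
  set.seed(7)
  for (i in 1:20) {
    m <- matrix(rnorm(18, sd = 2) + rep(rnorm(6, sd = 3), 3), nrow = 6)
    got <- icc_repeatability(m)
    ref <- aov_icc_oracle(m)
    expect_equal(got$f, ref$f, tolerance = 1e-10)
    expect_equal(got$kappa_consistency, ref$consistency, tolerance = 1e-10)
    expect_equal(got$kappa_agreement, ref$agreement, tolerance = 1e-10)
    expect_equal(got$df1, 5L)
    expect_equal(got$df2, 10L)
    expect_equal(got$p_value, pf(got$f, 5, 10, lower.tail = FALSE))
  }
})

test_that("ICC finds perfect repeatability and a null of ~0", {
  m <- matrix(rep(c(1, 5, 9, 13), 3), nrow = 4)   # identical repeats
  got <- icc_repeatability(m)
  expect_equal(got$kappa, 1)
  expect_equal(got$kappa_agreement, 1)
  # independent repeats per subject: kappa ~ 0 at large n
  set.seed(11)
  m0 <- matrix(rnorm(300 * 3), nrow = 300)
  expect_lt(abs(icc_repeatability(m0)$kappa), 0.1)
  expect_error(icc_repeatability(matrix(c(1, NA, 2, 3), 2)), "missing")
  expect_error(icc_repeatability(matrix(1:3, ncol = 1)), "at least 2")
})

test_that("icc_from_f matches the consistency identity and is monotone", {
  expect_equal(icc_from_f(4.5, 3), 3.5 / 6.5)
  expect_equal(icc_from_f(1, 3), 0)
  expect_equal(icc_from_f(0.5, 3), 0)      # clipped at 0 for reporting
  fs <- c(1.01, 2, 5, 20, 1e6)
  expect_true(all(diff(icc_from_f(fs, 3)) > 0))
  expect_equal(icc_from_f(1e9, 3), 1, tolerance = 1e-8)
  expect_error(icc_from_f(-1, 3), "positive")
  expect_error(icc_from_f(2, 1), "at least 2")
})

test_that("kappa labels follow the agreement-strength bins", {
  expect_equal(interpret_kappa(c(0.085, 0.39, 0.54, 0.7, 0.9)),
               c("none", "fair", "moderate", "substantial", "almost perfect"))
  expect_equal(interpret_kappa(c(0.2, 0.4, 0.6, 0.8)),
               c("fair", "moderate", "substantial", "almost perfect"))
  expect_equal(interpret_kappa(0), "none")
  expect_error(interpret_kappa(1.5), "exceed")
})

test_that("Kendall tau matches pair counting, including ties", {
  expect_equal(kendall_correlation(1:3, c(2, 4, 6))$tau, 1)
  expect_equal(kendall_correlation(1:3, c(3, 2, 1))$tau, -1)
  set.seed(19)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    x <- sample(1:5, n, replace = TRUE)      # ties likely
    y <- sample(1:5, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_correlation(x, y)$tau, tau_b_oracle(x, y),
                 tolerance = 1e-12)
  }
  expect_message(res <- kendall_correlation(rep(1, 5), 1:5), "constant")
  expect_true(is.na(res$tau))
  expect_error(kendall_correlation(1:3, 1:4), "unequal")
})

test_that("exact Kendall p-values equal full permutation enumeration", {
  set.seed(23)
  for (n in 4:6) {
    for (i in 1:4) {
      x <- sample(seq_len(n) * 10)
      y <- sample(seq_len(n) * 10)
      got <- kendall_correlation(x, y)
      expect_equal(got$p_value, tau_perm_p_oracle(x, y), tolerance = 1e-12)
    }
  }
})

test_that("fasting deltas difference matched fish and fail on unmatched ids", {
  bef <- data.frame(fish_id = c("f1", "f2"), noa_total = c(4, 7),
                    dir_total_s = c(10, 20))
  aft <- data.frame(fish_id = c("f2", "f1"), noa_total = c(7, 10),
                    dir_total_s = c(20, 5))
  d <- fasting_delta(bef, aft)
  expect_equal(d$delta_noa_total, c(6, 0))
  expect_equal(d$delta_dir_total_s, c(-5, 0))
  expect_error(fasting_delta(bef, aft[1, ]), "f1")
})

test_that("simulated sensory-behavior coupling is recovered as negative tau", {
  # cohort where the fasting NOA change is constructed to fall with left SN count
  set.seed(31)
  n <- 24
  sn_left <- rpois(n, 15)
  delta <- -2 * sn_left + rnorm(n, sd = 6)
  kt <- kendall_correlation(sn_left, delta)
  expect_lt(kt$tau, -0.4)
  expect_lt(kt$p_value, 0.01)
})

test_that("paired Wilcoxon with Holm reproduces the step-down by hand", {
  # all-positive distinct shifts: smallest attainable two-sided p for n = 6
  b <- c(1, 2, 3, 4, 5, 6); a <- b + seq(0.5, 3, by = 0.5)
  res <- paired_wilcoxon_holm(list(shift = list(before = b, after = a)))
  expect_equal(res$p_value, 2 / 2^6, tolerance = 1e-12)
  expect_equal(res$p_holm, res$p_value)    # single-test family
  # Holm on p = (0.01, 0.04) -> (0.02, 0.04); engineered via exact wilcoxon
  # is awkward, so check the step-down against p.adjust on the family scale
  fam <- list(
    t1 = list(before = c(1, 2, 3, 4, 5, 6, 7), after = c(1, 2, 3, 4, 5, 6, 7) + 1),
    t2 = list(before = c(1, 2, 3, 4, 5, 6, 7), after = c(2, 1, 4, 3, 6, 5, 9))
  )
  res2 <- paired_wilcoxon_holm(fam)
  expect_equal(res2$p_holm, p.adjust(res2$p_value, "holm"))
  expect_true(all(res2$p_holm >= res2$p_value))
  # all-zero differences are undefined, reported as NA
  res3 <- paired_wilcoxon_holm(list(null = list(before = b, after = b)))
  expect_true(is.na(res3$v_statistic))
  expect_error(paired_wilcoxon_holm(list(list(before = 1, after = 2))),
               "named")
})

test_that("Holm adjustment of the pair (0.01, 0.04) is (0.02, 0.04)", {
  expect_equal(p.adjust(c(0.01, 0.04), "holm"), c(0.02, 0.04))
})

test_that("laterality records derive ratios, bias and preference with covariates", {
  sums <- data.frame(fish_id = c("a", "b", "c"),
                     noa_left = c(2, 0, 0), noa_right = c(6, 0, 2),
                     dir_left_s = c(3, 0, 1), dir_right_s = c(1, 0, 1))
  sens <- data.frame(fish_id = c("a", "b", "c"), sn_left = c(10, 12, 8),
                     sn_right = c(11, 9, 8))
  rec <- laterality_records(sums, sens)
  expect_equal(rec$lr_noa_ratio, c(0.75, NA, 1))
  expect_equal(rec$bias_index_noa, c(0.75, NA, 1))
  expect_equal(rec$lr_dir_ratio, c(0.25, NA, 0.5))
  expect_equal(rec$preference, c("right", "undefined", "right"))
  expect_equal(rec$sn_left, c(10, 12, 8))
  bad <- sens; bad$sn_left[1] <- -2
  expect_error(laterality_records(sums, bad), "non-negative")
})
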