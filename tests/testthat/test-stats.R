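test_that("roi summaries handle exact, empty and single-voxel regions", {
  q <- list(t1 = array(c(rep(209, 10), rep(380, 6)), c(4, 2, 2)))
  m_nac <- array(c(rep(TRUE, 10), rep(FALSE, 6)), c(4, 2, 2))
  m_wml <- array(c(rep(FALSE, 10), rep(TRUE, 6)), c(4, 2, 2))
  m_one <- array(FALSE, c(4, 2, 2)); m_one[1, 1, 1] <- TRUE
  m_empty <- array(FALSE, c(4, 2, 2))
  s <- roi_summaries(q, list(nac = m_nac, wml = m_wml, one = m_one,
                             none = m_empty))
  expect_equal(s$mean[s$tissue == "nac"], 209)
  expect_equal(s$mean[s$tissue == "wml"], 380)
  expect_equal(s$sd[s$tissue == "one"], 0)     # n = 1 flagged with sd 0
  expect_identical(s$n[s$tissue == "one"], 1L)
  expect_identical(s$n[s$tissue == "none"], 0L)  # reported, not dropped
  expect_true(is.na(s$mean[s$tissue == "none"]))
})

test_that("group comparison matches hand-computed pooled t on a toy split", {
  a <- c(1, 2, 3); b <- c(2, 4, 6)
  # pooled two-sample t computed by explicit arithmetic
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  p_hand <- 2 * pt(-abs(t_hand), df = 4)
  g <- group_compare(a, b, n_comparisons = 5)
  expect_equal(g$t, t_hand, tolerance = 1e-12)
  expect_equal(g$p_raw, p_hand, tolerance = 1e-12)
  expect_equal(g$p_corrected, min(1, 5 * p_hand), tolerance = 1e-12)
  # identical groups: t = 0, p = 1, not significant
  same <- group_compare(c(5, 5, 5), c(5, 5, 5))
  expect_equal(same$t, 0)
  expect_equal(same$p_corrected, 1)
  expect_false(same$significant)
})

test_that("Student and Welch p-values agree with an exhaustive permutation oracle", {
  set.seed(14)
  for (rep in 1:3) {
    x <- round(rnorm(5, 10, 2), 2)
    y <- round(rnorm(5, 11, 3), 2)
    pooled <- c(x, y)
    splits <- utils::combn(10, 5)
    for (var_equal in c(TRUE, FALSE)) {
      tstat <- function(a, b) {
        unname(t.test(a, b, var.equal = var_equal)$statistic)
      }
      t_obs <- abs(tstat(x, y))
      t_perm <- apply(splits, 2, function(ix)
        abs(tstat(pooled[ix], pooled[-ix])))
      p_perm <- mean(t_perm >= t_obs - 1e-12)
      g <- group_compare(x, y, n_comparisons = 1, var_equal = var_equal)
      expect_lt(abs(g$p_raw - p_perm), 0.12)   # type-I calibration agreement
    }
  }
})

test_that("Bonferroni correction is monotone and capped", {
  set.seed(5)
  for (rep in 1:10) {
    g <- group_compare(rnorm(8), rnorm(8), n_comparisons = 5)
    expect_gte(g$p_corrected, g$p_raw)
    expect_lte(g$p_corrected, 1)
  }
})

test_that("cortical lesion vs NAC T2 groups separate decisively", {
  set.seed(100)
  g <- group_compare(rnorm(500, 91, 22), rnorm(500, 64, 11))
  expect_lt(g$p_corrected, 0.001)
  expect_true(g$significant)
})

test_that("correlations behave under monotone transforms and anticorrelation", {
  x <- c(1, 2, 3, 4, 5, 6)
  y <- exp(x)                       # monotone non-linear
  co <- correlate(y, x)
  expect_equal(co$spearman_rho, 1)
  expect_lt(co$pearson_r, 1)
  co2 <- correlate(-2 * x + 3, x)   # anti-correlated linear
  expect_equal(co2$pearson_r, -1, tolerance = 1e-12)
  expect_equal(co2$spearman_rho, -1)
  # Spearman invariance under strictly monotone transforms of either side
  set.seed(6)
  a <- rnorm(50); b <- a + rnorm(50)
  rho0 <- correlate(a, b)$spearman_rho
  expect_equal(correlate(exp(a), b)$spearman_rho, rho0, tolerance = 1e-12)
  expect_equal(correlate(a, b^3)$spearman_rho, rho0, tolerance = 1e-12)
  expect_false(correlate(rep(1, 5), 1:5)$defined)   # zero variance flagged
})

test_that("normalized histograms sum to one and flag overflow", {
  h <- normalized_histogram(c(1, 1.5, 2, 7, -3), seq(0, 5, by = 1))
  expect_equal(sum(h$frequencies) + h$underflow + h$overflow, 1,
               tolerance = 1e-9)
  expect_equal(h$underflow, 0.2)
  expect_equal(h$overflow, 0.2)
  one_bin <- normalized_histogram(rep(2.5, 10), c(0, 1, 2, 3))
  expect_equal(one_bin$frequencies, c(0, 0, 1))
  expect_error(normalized_histogram(1:5, c(1, 1, 2)), "strictly increasing")
})

test_that("phantom cortex reproduces the rank-dominant T1-myelin association", {
  sp <- small_spec()
  rep_ <- run_pipeline(sp)
  co <- rep_$correlations$t1
  expect_lt(co$pearson_r, 0)                       # longer T1, less myelin
  expect_lt(co$spearman_rho, 0)
  expect_gte(abs(co$spearman_rho), abs(co$pearson_r))  # rate-linear coupling
  expect_lt(rep_$correlations$t2$pearson_r, 0)
  expect_lt(rep_$correlations$m0$pearson_r, 0)
  expect_gt(rep_$correlations$mtr$pearson_r, 0)
})

test_that("CL and NAC histograms overlap substantially on the default phantom", {
  sp <- small_spec()
  rep_ <- run_pipeline(sp)
  for (p in c("t1", "t2", "mtr")) {
    h <- rep_$histograms[[p]]
    expect_gt(histogram_overlap(h$cl, h$nac), 0)
    expect_equal(sum(h$whole_cortex$frequencies) + h$whole_cortex$underflow +
                   h$whole_cortex$overflow, 1, tolerance = 1e-9)
  }
})
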