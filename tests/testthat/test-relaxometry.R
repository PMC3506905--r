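test_that("double-angle B1 recovery is exact for a range of fields", {
  for (db1 in c(0.8, 1.0, 1.2)) {
    b1 <- structure(array(db1, c(3, 3, 3)), class = "b1_map")
    dam <- simulate_dam_pair(b1)
    fit <- compute_b1(dam$s1, dam$s2)
    expect_true(all(fit$valid))
    expect_equal(fit$b1, unclass(b1), tolerance = 1e-9)
  }
  # degenerate ratio r = 1 (theta -> 0) has no valid root and is flagged
  s1 <- signal_volume(array(100, c(2, 2, 2)), acq_params("SPGR", 2000, 15, 20))
  s2 <- signal_volume(array(100, c(2, 2, 2)), acq_params("SPGR", 2000, 15, 40))
  fit <- compute_b1(s1, s2)
  expect_true(all(!fit$valid))
  expect_true(all(is.na(fit$b1)))
})

test_that("noiseless DESPOT1 recovers every tissue row exactly", {
  tab <- tissue_table_default()
  for (row in c("nac", "cl", "nawm", "wm_lesion")) {
    t1 <- tab[row, "t1_mean"]; m0 <- tab[row, "m0_mean"]
    m <- uniform_maps(t1, tab[row, "t2_mean"], m0, 0)
    sa <- simulate_spgr(m, acq_params("SPGR", 7.7, 3.35, 4), 1)
    sb <- simulate_spgr(m, acq_params("SPGR", 7.7, 3.35, 22), 1)
    fit <- fit_despot1(sa, sb, 1)
    expect_true(all(fit$valid))
    expect_lt(max(abs(fit$t1 - t1) / t1), 1e-6)
    expect_lt(max(abs(fit$m0 - m0) / m0), 1e-6)
  }
  expect_error(fit_despot1(sa, sa, 1), "distinct flip angles")
})

test_that("ignoring the B1 field biases T1, monotonically in |error|", {
  m <- uniform_maps(209, 64, 3797, 0.0747)
  bias <- sapply(c(-0.2, -0.1, 0, 0.1, 0.2), function(eps) {
    b1 <- structure(array(1 + eps, c(4, 4, 4)), class = "b1_map")
    sa <- simulate_spgr(m, acq_params("SPGR", 7.7, 3.35, 4), b1)
    sb <- simulate_spgr(m, acq_params("SPGR", 7.7, 3.35, 22), b1)
    corrected <- fit_despot1(sa, sb, unclass(b1))
    expect_lt(abs(corrected$t1[1] - 209) / 209, 1e-9)
    abs(fit_despot1(sa, sb, 1)$t1[1] - 209)   # fit at nominal flips
  })
  expect_equal(bias[3], 0, tolerance = 1e-9)
  expect_true(all(diff(bias[3:5]) > 0))
  expect_true(all(diff(bias[1:3]) < 0))
})

test_that("noiseless DESPOT2 recovers T2 exactly and flags the T2->Inf edge", {
  tab <- tissue_table_default()
  for (row in c("wm_lesion", "nac")) {
    t1 <- tab[row, "t1_mean"]; t2 <- tab[row, "t2_mean"]
    m <- uniform_maps(t1, t2, tab[row, "m0_mean"], 0)
    sa <- simulate_bssfp(m, acq_params("bSSFP", 7.7, 3.84, 20), 1)
    sb <- simulate_bssfp(m, acq_params("bSSFP", 7.7, 3.84, 70), 1)
    fit <- fit_despot2(sa, sb, 1, array(t1, c(4, 4, 4)))
    expect_true(all(fit$valid))
    expect_lt(max(abs(fit$t2 - t2) / t2), 1e-6)
  }
  # slope m = E1 maps to E2 = 1 (infinite T2): invalid, not clamped
  t1 <- 200; tr <- 7.7; e1 <- exp(-tr / t1)
  a1 <- 20 * pi / 180; a2 <- 70 * pi / 180
  # choose S so that Y = E1 X + b exactly (S/sin(a) = E1 S/tan(a) + b)
  pick_s <- function(a, b = 50) b * sin(a) / (1 - e1 * cos(a))
  s1v <- pick_s(a1); s2v <- pick_s(a2)
  sa <- signal_volume(array(s1v, c(2, 2, 2)), acq_params("bSSFP", tr, 3.84, 20))
  sb <- signal_volume(array(s2v, c(2, 2, 2)), acq_params("bSSFP", tr, 3.84, 70))
  fit <- fit_despot2(sa, sb, 1, array(t1, c(2, 2, 2)))
  expect_true(all(!fit$valid))
  expect_true(all(is.na(fit$t2)))
})

test_that("MTR is the percent saturation-induced signal drop", {
  s0 <- signal_volume(array(1000, c(3, 3, 3)), acq_params("SPGR", 25, 4.09, 25))
  same <- compute_mtr(s0, s0)
  expect_true(all(same$mtr == 0))
  sat <- signal_volume(array(1000 * (1 - 0.1282), c(3, 3, 3)),
                       acq_params("SPGR_MT", 25, 4.09, 25, TRUE))
  expect_equal(compute_mtr(s0, sat)$mtr[1], 12.82, tolerance = 1e-9)
  zero <- signal_volume(array(0, c(3, 3, 3)),
                        acq_params("SPGR_MT", 25, 4.09, 25, TRUE))
  expect_true(all(compute_mtr(s0, zero)$mtr == 100))
  expect_true(all(!compute_mtr(zero, s0)$valid))   # S0 = 0 flagged invalid
})

test_that("banding exclusion covers injected defects and tracks counts", {
  sp <- noiseless_spec(grid_shape = c(48, 48, 48), seed = 5)
  lab <- build_geometry(sp)
  maps <- assign_tissue_parameters(lab, sp)
  brain <- lab$data != label_codes()[["formalin"]]
  mk <- function(defect = NULL) {
    sa <- simulate_bssfp(maps, acq_params("bSSFP", 7.7, 3.84, 20), 1, brain,
                         defect_region = defect)
    sb <- simulate_bssfp(maps, acq_params("bSSFP", 7.7, 3.84, 70), 1, brain,
                         defect_region = defect)
    fit_despot2(sa, sb, 1, maps$t1, mask = brain)
  }
  clean <- mk()
  excl0 <- banding_exclusion_mask(clean, NULL, mask = brain)
  expect_identical(sum(excl0), 0L)   # noiseless phantom: nothing excluded
  defect <- array(FALSE, dim(lab$data))
  defect[20:26, 20:26, 20:26] <- brain[20:26, 20:26, 20:26]
  withdef <- mk(defect)
  excl <- banding_exclusion_mask(withdef, defect, mask = brain)
  expect_true(all(excl[defect]))     # exclusion mask contains the defect
  # downstream voxel counts drop by exactly the excluded count
  n_all <- sum(brain)
  expect_identical(sum(brain & !excl), n_all - sum(excl))
})

test_that("T1 error stays small at moderate SNR and NaNs never leak", {
  n <- 24
  m <- uniform_maps(209, 64, 3797, 0.0747, n = n)
  sa <- simulate_spgr(m, acq_params("SPGR", 7.7, 3.35, 4), 1)
  sb <- simulate_spgr(m, acq_params("SPGR", 7.7, 3.35, 22), 1)
  sigma <- mean(sa$data) / 50          # SNR 50 on the weaker SPGR volume
  fit <- fit_despot1(add_rician_noise(sa, sigma, 21),
                     add_rician_noise(sb, sigma, 22), 1)
  err <- abs(fit$t1 - 209) / 209
  expect_lt(median(err, na.rm = TRUE), 0.05)
  # every non-finite fit value is captured by the validity mask
  expect_true(all(is.finite(fit$t1[fit$valid])))
  expect_true(all(is.na(fit$t1[!fit$valid])))
})
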