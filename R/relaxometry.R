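#' Compute the B1 transmit field from a double-angle pair
#'
#' For each voxel the ratio r = S2/S1 = cos(2 theta)/cos(theta) (theta the
#' actual preparation flip) gives the quadratic 2 c^2 - r c - 1 = 0 in
#' c = cos(theta); the root in (0, 1) is c = (r + sqrt(r^2 + 8)) / 4, and
#' dB1 = theta / nominal. Voxels where no valid root exists (r >= 1, i.e.
#' theta outside (0, 90) degrees, or nonpositive S1) are flagged invalid,
#' never filled.
#'
#' @param s1,s2 [signal_volume()]s of the alpha and 2 alpha acquisitions.
#' @param nominal_deg Nominal preparation flip angle, degrees (default 20).
#' @param mask Optional logical array restricting the computation.
#' @return List with `b1` (numeric array, `NA` where invalid) and `valid`
#'   (logical array).
#' @export
compute_b1 <- function(s1, s2, nominal_deg = 20, mask = NULL) {
  a <- s1$data
  b <- s2$data
  if (is.null(mask)) mask <- a > 0
  valid <- mask & a > 0 & is.finite(a) & is.finite(b)
  r <- array(NA_real_, dim = dim(a))
  r[valid] <- b[valid] / a[valid]
  cth <- (r + sqrt(r^2 + 8)) / 4
  valid <- valid & !is.na(cth) & cth > 0 & cth < 1
  theta <- suppressWarnings(acos(cth))
  b1 <- array(NA_real_, dim = dim(a))
  b1[valid] <- theta[valid] / (nominal_deg * pi / 180)
  list(b1 = b1, valid = valid)
}

#' Two-point DESPOT1 fit: T1 and M0 from an SPGR pair
#'
#' Linearizes the SPGR equation as Y = E1 X + M0 (1 - E1) with
#' Y = S/sin(ae), X = S/tan(ae) and effective flips ae = dB1 x nominal.
#' From the two flip angles, slope = (Y2 - Y1)/(X2 - X1), T1 =
#' -TR / log(slope) and M0 = (Y1 - slope X1) / (1 - slope). Voxels with
#' slope outside (0, 1) are flagged invalid, never clamped (clamping would
#' bias the group statistics).
#'
#' @param sa,sb [signal_volume()]s at the two flip angles (shared TR).
#' @param b1 B1 correction: array/`b1_map` of dB1 factors, or scalar 1 to
#'   fit at nominal flips.
#' @param mask Optional logical array restricting the fit.
#' @return List with `t1` (ms), `m0` (r.u.), `valid` (logical array).
#' @export
fit_despot1 <- function(sa, sb, b1 = 1, mask = NULL) {
  if (sa$acquisition$flip_deg == sb$acquisition$flip_deg)
    stop("DESPOT1 requires two distinct flip angles")
  if (sa$acquisition$TR != sb$acquisition$TR)
    stop("DESPOT1 requires a shared TR")
  tr <- sa$acquisition$TR
  b1a <- if (inherits(b1, "b1_map")) unclass(b1) else b1
  a1 <- b1a * sa$acquisition$flip_deg * pi / 180
  a2 <- b1a * sb$acquisition$flip_deg * pi / 180
  y1 <- sa$data / sin(a1); x1 <- sa$data / tan(a1)
  y2 <- sb$data / sin(a2); x2 <- sb$data / tan(a2)
  slope <- (y2 - y1) / (x2 - x1)
  if (is.null(mask)) mask <- sa$data > 0 | sb$data > 0
  if (length(b1a) > 1) mask <- mask & is.finite(b1a)
  valid <- mask & is.finite(slope) & slope > 0 & slope < 1
  t1 <- m0 <- array(NA_real_, dim = dim(sa$data))
  t1[valid] <- -tr / log(slope[valid])
  m0[valid] <- (y1[valid] - slope[valid] * x1[valid]) / (1 - slope[valid])
  valid <- valid & is.finite(t1) & is.finite(m0)
  t1[!valid] <- NA_real_; m0[!valid] <- NA_real_
  list(t1 = t1, m0 = m0, valid = valid)
}

#' Two-point DESPOT2 fit: T2 from a bSSFP pair given T1
#'
#' With Y = S/sin(ae), X = S/tan(ae), the on-resonance bSSFP signal is
#' linear, Y = m X + b, with slope m = (E1 - E2)/(1 - E1 E2). Inverting,
#' E2 = (E1 - m)/(1 - m E1) and T2 = -TR / log(E2). Voxels with E2 outside
#' (0, 1) (including the m = E1 infinite-T2 boundary) or missing T1 are
#' flagged invalid.
#'
#' @param sa,sb [signal_volume()]s at the two bSSFP flip angles (shared TR).
#' @param b1 B1 correction factor(s).
#' @param t1 T1 map in ms (e.g. from [fit_despot1()]).
#' @param mask Optional logical array restricting the fit.
#' @return List with `t2` (ms) and `valid`.
#' @export
fit_despot2 <- function(sa, sb, b1 = 1, t1, mask = NULL) {
  if (sa$acquisition$flip_deg == sb$acquisition$flip_deg)
    stop("DESPOT2 requires two distinct flip angles")
  tr <- sa$acquisition$TR
  b1a <- if (inherits(b1, "b1_map")) unclass(b1) else b1
  a1 <- b1a * sa$acquisition$flip_deg * pi / 180
  a2 <- b1a * sb$acquisition$flip_deg * pi / 180
  y1 <- sa$data / sin(a1); x1 <- sa$data / tan(a1)
  y2 <- sb$data / sin(a2); x2 <- sb$data / tan(a2)
  m <- (y2 - y1) / (x2 - x1)
  if (is.null(mask)) mask <- sa$data > 0 | sb$data > 0
  e1 <- exp(-tr / t1)
  valid <- mask & is.finite(m) & is.finite(e1)
  e2 <- (e1 - m) / (1 - m * e1)
  valid <- valid & is.finite(e2) & e2 > 0 & e2 < 1
  t2 <- array(NA_real_, dim = dim(sa$data))
  t2[valid] <- -tr / log(e2[valid])
  valid <- valid & is.finite(t2)
  t2[!valid] <- NA_real_
  list(t2 = t2, valid = valid)
}

#' Magnetization transfer ratio map
#'
#' MTR = (S0 - Ssat) / S0 x 100 per voxel, the percentage signal decrease
#' caused by the MT saturation pulse. Voxels with S0 <= 0 are flagged
#' invalid.
#'
#' @param s0 Unsaturated [signal_volume()].
#' @param ssat Saturated [signal_volume()].
#' @param mask Optional logical array.
#' @return List with `mtr` (percent) and `valid`.
#' @export
compute_mtr <- function(s0, ssat, mask = NULL) {
  a <- s0$data
  b <- ssat$data
  if (is.null(mask)) mask <- array(TRUE, dim = dim(a))
  valid <- mask & a > 0 & is.finite(a) & is.finite(b)
  mtr <- array(NA_real_, dim = dim(a))
  mtr[valid] <- (a[valid] - b[valid]) / a[valid] * 100
  list(mtr = mtr, valid = valid)
}

#' Banding exclusion mask for the T2 map
#'
#' Voxels whose bSSFP signals are inconsistent with the on-resonance
#' two-point model — i.e. where the DESPOT2 fit is invalid (slope maps to
#' E2 outside (0, 1)) — are excluded from all downstream statistics,
#' together with any injected defect region recorded in the acquisition
#' metadata. With exactly two flip angles the two-point model is exactly
#' determined, so fit validity is the residual rule.
#'
#' @param t2fit Result of [fit_despot2()].
#' @param defect_region Optional logical array of injected banding defects
#'   (e.g. `sa$defect_region` from [simulate_bssfp()]).
#' @param mask Optional logical array of voxels under study; exclusions are
#'   reported within it.
#' @return Logical array: `TRUE` = excluded.
#' @export
banding_exclusion_mask <- function(t2fit, defect_region = NULL, mask = NULL) {
  excl <- !t2fit$valid
  if (!is.null(defect_region)) excl <- excl | defect_region
  if (!is.null(mask)) excl <- excl & mask
  excl
}
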