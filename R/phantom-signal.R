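#' Acquisition parameter record
#'
#' @param sequence `"SPGR"`, `"bSSFP"` or `"SPGR_MT"`.
#' @param TR Repetition time, ms.
#' @param TE Echo time, ms (must be < TR; not used by the steady-state
#'   magnitude models but carried as metadata).
#' @param flip_deg Nominal flip angle, degrees, in (0, 180).
#' @param mt_saturation Whether the off-resonance MT saturation pulse is on.
#' @return An `acq_params` list.
#' @export
acq_params <- function(sequence = c("SPGR", "bSSFP", "SPGR_MT"), TR, TE,
                       flip_deg, mt_saturation = FALSE) {
  sequence <- match.arg(sequence)
  stopifnot(flip_deg > 0, flip_deg < 180, TE < TR, TR > 0)
  structure(list(sequence = sequence, TR = TR, TE = TE, flip_deg = flip_deg,
                 mt_saturation = isTRUE(mt_saturation)), class = "acq_params")
}

#' Signal volume container
#' @param data Non-negative numeric 3D array of magnitude values (r.u.).
#' @param acquisition The [acq_params()] used.
#' @param noise_sigma Rician sigma applied (0 = noiseless).
#' @param defect_region Optional logical array flagging voxels carrying an
#'   injected off-resonance banding defect (bSSFP only).
#' @return A `signal_volume` object.
#' @export
signal_volume <- function(data, acquisition, noise_sigma = 0,
                          defect_region = NULL) {
  structure(list(data = data, acquisition = acquisition,
                 noise_sigma = noise_sigma, defect_region = defect_region),
            class = "signal_volume")
}

#' Generate a smooth B1 transmit field
#'
#' A low-order (quadratic) polynomial in the centered world coordinates,
#' centered at 1.0 and rescaled so its range is contained in
#' `[1 - amplitude, 1 + amplitude]`. Coefficients are drawn from the spec
#' seed, so the field is smooth and reproducible.
#'
#' @param spec A [phantom_spec()] (uses `grid_shape`, `voxel_size`,
#'   `b1_amplitude`, `seed`).
#' @return Numeric 3D array of multiplicative flip-angle factors (class
#'   `b1_map`), strictly positive.
#' @export
generate_b1_field <- function(spec) {
  gs <- spec$grid_shape
  if (spec$b1_amplitude == 0)
    return(structure(array(1, dim = gs), class = "b1_map"))
  set.seed(spec$seed + 3L)
  cf <- runif(9, -1, 1)
  co <- .centered_coords(gs, spec$voxel_size)
  half <- pmax(vapply(co, function(v) max(abs(v)), 0), 1e-9)
  x <- co[[1]][slice.index(array(0L, gs), 1)] / half[1]
  y <- co[[2]][slice.index(array(0L, gs), 2)] / half[2]
  z <- co[[3]][slice.index(array(0L, gs), 3)] / half[3]
  p <- cf[1] * x + cf[2] * y + cf[3] * z + cf[4] * x * y + cf[5] * x * z +
    cf[6] * y * z + cf[7] * x^2 + cf[8] * y^2 + cf[9] * z^2
  p <- p - mean(range(p))              # center the range on zero
  p <- p / max(abs(p))                 # normalize to [-1, 1]
  structure(array(1 + spec$b1_amplitude * p, dim = gs), class = "b1_map")
}

#' Simulate a spoiled gradient echo (SPGR) acquisition
#'
#' Steady-state SPGR magnitude per voxel,
#' S = M0 sin(ae) (1 - E1) / (1 - cos(ae) E1), with effective flip
#' ae = dB1 x nominal flip and E1 = exp(-TR/T1). With `mt_saturation` on,
#' the signal is attenuated by (1 - delta), the semi-quantitative MT model
#' in which delta is the saturation fraction (MTR/100).
#'
#' @param maps Ground-truth [parameter_maps()].
#' @param acq [acq_params()] with `sequence = "SPGR"` or `"SPGR_MT"`.
#' @param b1 B1 field from [generate_b1_field()] (or scalar 1 for nominal).
#' @param mask Optional logical array; voxels outside get signal 0.
#' @return A [signal_volume()].
#' @export
simulate_spgr <- function(maps, acq, b1 = 1, mask = NULL) {
  stopifnot(acq$sequence %in% c("SPGR", "SPGR_MT"))
  t1 <- maps$t1
  if (is.null(mask)) mask <- !is.na(t1)
  if (any(t1[mask] <= 0, na.rm = TRUE))
    stop("nonpositive T1 inside the simulation mask")
  ae <- (if (inherits(b1, "b1_map")) unclass(b1) else b1) *
    acq$flip_deg * pi / 180
  e1 <- exp(-acq$TR / t1)
  s <- maps$m0 * sin(ae) * (1 - e1) / (1 - cos(ae) * e1)
  if (acq$mt_saturation) s <- s * (1 - maps$delta)
  s[!mask | is.na(s)] <- 0
  signal_volume(s, acq)
}

#' Simulate a balanced SSFP acquisition (on-resonance ideal model)
#'
#' S = M0 sin(ae) (1 - E1) / (1 - E1 E2 - (E1 - E2) cos(ae)), with
#' E2 = exp(-TR/T2). Off-resonance banding can be injected as a
#' multiplicative defect over a configured region; the region is recorded in
#' the volume metadata so the downstream exclusion mask can be validated.
#'
#' @param maps Ground-truth [parameter_maps()].
#' @param acq [acq_params()] with `sequence = "bSSFP"`.
#' @param b1 B1 field or scalar.
#' @param mask Optional simulation mask.
#' @param defect_region Optional logical array of voxels to corrupt.
#' @param defect_gain Multiplicative signal defect inside the region
#'   (default 0.15, a deep band).
#' @return A [signal_volume()] with `defect_region` metadata.
#' @export
simulate_bssfp <- function(maps, acq, b1 = 1, mask = NULL,
                           defect_region = NULL, defect_gain = 0.15) {
  stopifnot(acq$sequence == "bSSFP")
  t1 <- maps$t1
  t2 <- maps$t2
  if (is.null(mask)) mask <- !is.na(t1) & !is.na(t2)
  if (any(t2[mask] >= t1[mask], na.rm = TRUE))
    stop("T2 >= T1 inside the simulation mask")
  ae <- (if (inherits(b1, "b1_map")) unclass(b1) else b1) *
    acq$flip_deg * pi / 180
  e1 <- exp(-acq$TR / t1)
  e2 <- exp(-acq$TR / t2)
  s <- maps$m0 * sin(ae) * (1 - e1) / (1 - e1 * e2 - (e1 - e2) * cos(ae))
  if (!is.null(defect_region)) s[defect_region] <- s[defect_region] * defect_gain
  s[!mask | is.na(s)] <- 0
  signal_volume(s, acq, defect_region = defect_region)
}

#' Simulate the magnetization transfer SPGR pair
#'
#' Two proton-density-weighted SPGR volumes at 25 degrees, TE 4.09 ms,
#' TR 25 ms: the first without and the second with the MT saturation pulse,
#' modeled as a multiplicative attenuation (1 - delta).
#'
#' @param maps Ground-truth [parameter_maps()].
#' @param b1 B1 field or scalar.
#' @param mask Optional simulation mask.
#' @return List of two [signal_volume()]s: `s0` (unsaturated), `ssat`.
#' @export
simulate_mt_pair <- function(maps, b1 = 1, mask = NULL) {
  a0 <- acq_params("SPGR", TR = 25, TE = 4.09, flip_deg = 25,
                   mt_saturation = FALSE)
  asat <- acq_params("SPGR_MT", TR = 25, TE = 4.09, flip_deg = 25,
                     mt_saturation = TRUE)
  list(s0 = simulate_spgr(maps, a0, b1, mask),
       ssat = simulate_spgr(maps, asat, b1, mask))
}

#' Simulate the double-angle B1 mapping pair
#'
#' Magnetization-prepared acquisitions whose prepared magnitudes are
#' proportional to cos(dB1 a) and cos(2 dB1 a) with a common spatial
#' proportionality factor, so the ratio S2/S1 depends only on the transmit
#' field.
#'
#' @param b1 B1 field (3D array or `b1_map`).
#' @param prep_flip_deg Nominal preparation flip a, degrees (default 20).
#' @param scale Common proportionality factor (scalar or array; cancels in
#'   the ratio).
#' @return List of two [signal_volume()]s `s1`, `s2`.
#' @export
simulate_dam_pair <- function(b1, prep_flip_deg = 20, scale = 1000) {
  b1a <- if (inherits(b1, "b1_map")) unclass(b1) else b1
  a <- prep_flip_deg * pi / 180
  if (any(b1a * 2 * a >= pi / 2))
    stop("double-angle precondition violated: dB1 * 2a reaches 90 degrees ",
         "at ", sum(b1a * 2 * a >= pi / 2), " voxel(s)")
  acq1 <- acq_params("SPGR", TR = 2000, TE = 15, flip_deg = prep_flip_deg)
  acq2 <- acq_params("SPGR", TR = 2000, TE = 15, flip_deg = 2 * prep_flip_deg)
  list(s1 = signal_volume(scale * cos(b1a * a), acq1),
       s2 = signal_volume(scale * cos(2 * b1a * a), acq2))
}

#' Add Rician noise to a magnitude volume
#'
#' S' = sqrt((S + n1)^2 + n2^2) with n1, n2 independent N(0, sigma^2) per
#' voxel — the magnitude-image noise model. Multi-repetition signal averaging
#' is folded into a single effective sigma.
#'
#' @param signal A [signal_volume()].
#' @param sigma Noise sigma, same relative units as the signal.
#' @param seed Integer seed (bit-reproducible output).
#' @return A [signal_volume()] with updated data and `noise_sigma`.
#' @export
add_rician_noise <- function(signal, sigma, seed) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(signal)
  set.seed(seed)
  s <- signal$data
  n <- length(s)
  s2 <- sqrt((s + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
  signal_volume(array(s2, dim = dim(s)), signal$acquisition,
                noise_sigma = sigma, defect_region = signal$defect_region)
}
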