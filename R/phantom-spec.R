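#' Default tissue parameter table for the fixed-hemisphere phantom
#'
#' Mean and standard deviation of T1 (ms), T2 (ms), relative proton density M0
#' (r.u.), MT saturation fraction delta (dimensionless, = MTR/100) and myelin
#' content (% area) for each phantom tissue class. The four pathology rows
#' (normal-appearing cortex, cortical lesion, normal-appearing white matter,
#' white matter lesion) carry the values measured on fixed post-mortem MS
#' tissue at 3 T; the formalin row is a generator choice describing the
#' embedding fluid (long relaxation times, negligible MT effect, no myelin),
#' and subcortical grey matter is parameterized like normal-appearing cortex.
#'
#' @return A data.frame with one row per tissue class (`tissue` column:
#'   `"nac"`, `"cl"`, `"nawm"`, `"wm_lesion"`, `"formalin"`,
#'   `"subcortical_gm"`) and columns `<param>_mean` / `<param>_sd` for
#'   `t1`, `t2`, `m0`, `delta`, `myelin`.
#' @export
#' @examples
#' tissue_table_default()
tissue_table_default <- function() {
  tab <- data.frame(
    tissue      = c("nac", "cl", "nawm", "wm_lesion", "formalin", "subcortical_gm"),
    t1_mean     = c(209, 236, 196, 380, 2200, 209),
    t1_sd       = c(27, 26, 18, 88, 0, 27),
    t2_mean     = c(64, 91, 56, 121, 800, 64),
    t2_sd       = c(11, 22, 13, 27, 0, 11),
    m0_mean     = c(3797, 3835, 3467, 4005, 4400, 3797),
    m0_sd       = c(114, 86, 88, 111, 0, 114),
    delta_mean  = c(0.0747, 0.0709, 0.1282, 0.0616, 0.002, 0.0747),
    delta_sd    = c(0.0126, 0.0109, 0.0090, 0.0279, 0, 0.0126),
    myelin_mean = c(7.96, 1.96, 74.18, 27.55, 0, 7.96),
    myelin_sd   = c(6.69, 2.55, 4.70, 14.32, 0, 6.69),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$tissue
  tab
}

#' Integer label codes used in phantom label volumes
#' @return Named integer vector mapping tissue class names to label codes.
#' @export
label_codes <- function() {
  c(formalin = 0L, wm = 1L, cortex = 2L, subcortical_gm = 3L,
    cortical_lesion = 4L, wm_lesion = 5L)
}

#' Specify a lesion to implant in the phantom
#'
#' @param kind `"subpial_typeIII"` (tangential demyelination of the
#'   superficial cortical laminae, seeded at the pial surface) or
#'   `"wm_focal"` (ellipsoidal lesion inside white matter).
#' @param center Approximate lesion center, 0-based voxel coordinates
#'   (length 3). For subpial lesions the nearest pial cortex voxel is used
#'   as the seed.
#' @param tangential_radius Lesion radius in mm (tangential extent for
#'   subpial lesions, ellipsoid semi-axis for focal WM lesions).
#' @param depth_fraction Fraction of cortical depth demyelinated, in (0, 1];
#'   subpial lesions only.
#' @param target_tissue_row Row of the tissue table supplying the lesion
#'   parameters (default `"cl"` for subpial, `"wm_lesion"` for focal).
#' @return A `lesion_spec` list.
#' @export
lesion_spec <- function(kind = c("subpial_typeIII", "wm_focal"), center,
                        tangential_radius, depth_fraction = 0.5,
                        target_tissue_row = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 3, tangential_radius > 0)
  if (kind == "subpial_typeIII") {
    if (!(depth_fraction > 0 && depth_fraction <= 1))
      stop("depth_fraction must be in (0, 1]")
  }
  if (is.null(target_tissue_row))
    target_tissue_row <- if (kind == "subpial_typeIII") "cl" else "wm_lesion"
  structure(list(kind = kind, center = as.numeric(center),
                 tangential_radius = tangential_radius,
                 depth_fraction = depth_fraction,
                 target_tissue_row = target_tissue_row),
            class = "lesion_spec")
}

#' Default lesion set for the phantom
#'
#' Two type III subpial lesions extending tangentially along the pial
#' surface over about half the cortical depth, plus one focal white matter
#' lesion, sized so each tissue row receives at least several hundred voxels
#' at the default 0.35 mm grid.
#'
#' @param grid_shape Phantom grid dimensions (used to place lesions relative
#'   to the volume center).
#' @return List of [lesion_spec()] objects.
#' @export
default_lesions <- function(grid_shape = c(128, 128, 128)) {
  c0 <- (grid_shape - 1) / 2
  list(
    lesion_spec("subpial_typeIII",
                center = c0 + c(0.45, 0.10, 0.10) * grid_shape,
                tangential_radius = 6, depth_fraction = 0.5),
    lesion_spec("subpial_typeIII",
                center = c0 + c(-0.30, -0.35, 0.05) * grid_shape,
                tangential_radius = 5, depth_fraction = 0.6),
    lesion_spec("wm_focal",
                center = c0 + c(0.12, -0.08, 0) * grid_shape,
                tangential_radius = 3)
  )
}

#' Build a phantom specification
#'
#' Describes the synthetic fixed hemisphere: grid, voxel size, per-tissue
#' parameter distributions, lesions, B1 transmit field amplitude and Rician
#' noise level. All downstream stochastic operations are reproducible given
#' `seed`.
#'
#' @param grid_shape Voxel counts per axis (default 128^3).
#' @param voxel_size Isotropic voxel size in mm (default 0.35).
#' @param tissue_table Per-tissue parameter table; see [tissue_table_default()].
#' @param lesion_specs List of [lesion_spec()]; default [default_lesions()].
#' @param cortical_thickness_vox Cortical shell thickness in voxels (6-10).
#' @param b1_amplitude Peak fractional deviation of the transmit field from
#'   nominal (e.g. 0.2 means actual flip in [0.8, 1.2] x nominal).
#' @param noise_sigma Rician noise sigma in the same relative units as the
#'   simulated signals (M0 ~ 3500-4000 r.u. gives signals of order 250-900
#'   r.u.; the default 2 r.u. describes a heavily-averaged acquisition).
#' @param laminar_jitter SD of the per-voxel jitter added to fractional depth
#'   before the laminar myelin gradient is standardized to the
#'   normal-appearing-cortex mean/SD; 0 gives a purely depth-determined
#'   gradient.
#' @param laminar_shape `"linear"` or `"sigmoid"` myelin-vs-depth profile.
#' @param seed Integer seed governing every stochastic stage.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 128), voxel_size = 0.35,
                         tissue_table = tissue_table_default(),
                         lesion_specs = default_lesions(grid_shape),
                         cortical_thickness_vox = 8,
                         b1_amplitude = 0.2, noise_sigma = 2,
                         laminar_jitter = 0.15,
                         laminar_shape = c("linear", "sigmoid"),
                         seed = 1L) {
  laminar_shape <- match.arg(laminar_shape)
  if (length(grid_shape) == 1) grid_shape <- rep(grid_shape, 3)
  stopifnot(length(grid_shape) == 3, voxel_size > 0, noise_sigma >= 0,
            b1_amplitude >= 0, b1_amplitude <= 0.5,
            cortical_thickness_vox >= 4)
  with(tissue_table, {
    if (any(t1_mean <= 0) || any(t2_mean <= 0))
      stop("relaxation times must be positive")
    if (any(t2_mean > t1_mean)) stop("T2 must not exceed T1 for any tissue")
    if (any(delta_mean < 0 | delta_mean > 1))
      stop("saturation fraction must lie in [0, 1]")
    if (any(myelin_mean < 0 | myelin_mean > 100))
      stop("myelin content must lie in [0, 100]")
  })
  structure(list(grid_shape = as.integer(grid_shape), voxel_size = voxel_size,
                 tissue_table = tissue_table, lesion_specs = lesion_specs,
                 cortical_thickness_vox = cortical_thickness_vox,
                 b1_amplitude = b1_amplitude, noise_sigma = noise_sigma,
                 laminar_jitter = laminar_jitter, laminar_shape = laminar_shape,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Fully deterministic phantom specification
#'
#' Convenience wrapper that zeroes every source of spread: tissue SDs, the
#' laminar myelin gradient jitter and amplitude, and the Rician noise sigma.
#' Every voxel of a tissue then sits exactly at its table mean, which is the
#' regime in which the closed-form acquisition models invert exactly and the
#' pipeline report must reproduce the configured means to numerical
#' precision.
#'
#' @param ... Passed to [phantom_spec()].
#' @return A `phantom_spec` with all variability switched off.
#' @export
noiseless_spec <- function(...) {
  sp <- phantom_spec(...)
  sd_cols <- grep("_sd$", names(sp$tissue_table))
  sp$tissue_table[, sd_cols] <- 0
  sp$noise_sigma <- 0
  sp$laminar_jitter <- 0
  sp$deterministic <- TRUE
  sp
}
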