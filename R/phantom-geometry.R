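#' @title Label volume container
#' @description Integer 3D array of tissue labels (see [label_codes()]) with
#'   voxel size (mm) attached. Coordinates are 0-based voxel indices, axis
#'   order (x, y, z); world position = index * voxel_size.
#' @param data Integer 3D array.
#' @param voxel_size Voxel edge length in mm.
#' @return A `label_volume` object.
#' @export
label_volume <- function(data, voxel_size) {
  stopifnot(length(dim(data)) == 3, voxel_size > 0)
  structure(list(data = data, voxel_size = voxel_size), class = "label_volume")
}

#' @export
print.label_volume <- function(x, ...) {
  cat("label_volume:", paste(dim(x$data), collapse = " x "),
      "voxels @", x$voxel_size, "mm\n")
  print(table(factor(x$data, levels = label_codes(),
                     labels = names(label_codes()))))
  invisible(x)
}

# voxel-center world coordinates (mm) relative to the grid center, per axis
.centered_coords <- function(grid_shape, voxel_size) {
  lapply(grid_shape, function(n) (seq_len(n) - 1 - (n - 1) / 2) * voxel_size)
}

#' Build the folded-hemisphere phantom geometry
#'
#' A white matter core wrapped by a cortical shell of configured thickness,
#' with a sinusoidal radial perturbation of the pial and WM surfaces creating
#' gyri and sulci, all immersed in formalin. A small central sphere is
#' labeled subcortical grey matter. The perturbation phases are drawn from
#' the spec seed, so the volume is deterministic given (spec, seed).
#'
#' @param spec A [phantom_spec()].
#' @return A [label_volume()].
#' @export
build_geometry <- function(spec) {
  gs <- spec$grid_shape
  if (any(gs < 32)) stop("grid_shape must be at least 32 voxels per axis")
  vs <- spec$voxel_size
  th_mm <- spec$cortical_thickness_vox * vs
  half_extent <- min(gs) * vs / 2
  amp <- min(2.2, 0.12 * half_extent)             # gyral fold amplitude, mm
  r_pial0 <- half_extent - 1.5 * amp - 2 * vs     # mean pial radius, mm
  if (r_pial0 - 1.5 * amp - th_mm < 4 * vs)
    stop("grid too small to contain the cortical shell: ",
         "increase grid_shape or reduce cortical_thickness_vox")

  set.seed(spec$seed)
  ph <- runif(4, 0, 2 * pi)

  co <- .centered_coords(gs, vs)
  x <- co[[1]][slice.index(array(0L, gs), 1)]
  y <- co[[2]][slice.index(array(0L, gs), 2)]
  z <- co[[3]][slice.index(array(0L, gs), 3)]
  r <- sqrt(x^2 + y^2 + z^2)
  theta <- acos(ifelse(r > 0, z / pmax(r, 1e-12), 1))
  phi <- atan2(y, x)

  # radial perturbation shared by pial and WM surfaces (constant thickness)
  pert <- amp * (sin(3 * phi + ph[1]) * sin(2 * theta + ph[2]) +
                   0.5 * sin(5 * phi + ph[3]) * sin(3 * theta + ph[4]))
  r_pial <- r_pial0 + pert
  r_wm <- r_pial - th_mm

  lab <- array(label_codes()[["formalin"]], dim = gs)
  lab[r < r_pial] <- label_codes()[["cortex"]]
  lab[r < r_wm] <- label_codes()[["wm"]]
  r_sub <- min(4, 0.5 * (r_pial0 - 1.5 * amp - th_mm))
  lab[r < r_sub] <- label_codes()[["subcortical_gm"]]
  label_volume(lab, vs)
}
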