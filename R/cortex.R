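#' Exact Euclidean distance transform of a 3D mask
#'
#' Distance (mm) from every voxel to the nearest `TRUE` voxel of `mask`,
#' computed with the separable lower-envelope algorithm under anisotropic
#' voxel spacing. Voxels inside the mask get distance 0; if the mask is
#' empty all distances are `Inf`.
#'
#' @param mask Logical 3D array.
#' @param voxel_size Voxel spacing in mm, length 1 (isotropic) or 3.
#' @return Numeric 3D array of distances in mm.
#' @export
distance_transform <- function(mask, voxel_size = 1) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3)
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  d <- .edt3d_cpp(mask, dim(mask), as.numeric(voxel_size))
  array(d, dim = dim(mask))
}

# shift a 3D array by one voxel along an axis, filling with `fill`
.shift3 <- function(a, axis, by, fill) {
  out <- array(fill, dim = dim(a))
  n <- dim(a)[axis]
  src <- if (by > 0) 1:(n - 1) else 2:n
  dst <- if (by > 0) 2:n else 1:(n - 1)
  idx_src <- idx_dst <- rep(list(quote(expr = )), 3)
  idx_src[[axis]] <- src
  idx_dst[[axis]] <- dst
  out_call <- as.call(c(list(quote(`[<-`), quote(out)), idx_dst,
                        as.call(c(list(quote(`[`), quote(a)), idx_src))))
  eval(out_call)
}

#' Erode a 3D binary mask with the 6-connectivity kernel
#'
#' A voxel is retained iff it and all six face neighbours are inside the
#' mask; volume boundaries count as outside. One application removes exactly
#' the face-boundary layer of the mask (0.35 mm at the default grid).
#'
#' @param mask Logical 3D array.
#' @param iterations Number of erosion passes (default 1).
#' @return Logical 3D array, always a subset of `mask`.
#' @export
erode_mask_6conn <- function(mask, iterations = 1L) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3, iterations >= 0)
  for (i in seq_len(iterations)) {
    out <- mask
    for (axis in 1:3) {
      out <- out & .shift3(mask, axis, +1L, FALSE) &
        .shift3(mask, axis, -1L, FALSE)
    }
    mask <- out
  }
  mask
}

#' Fractional cortical depth field
#'
#' For every voxel of the cortical ribbon (cortex plus cortical lesions,
#' which remain part of the ribbon), the fractional depth
#' d = Dp / (Dp + Dw), where Dp is the Euclidean distance to the nearest
#' non-brain (formalin) voxel and Dw the distance to the nearest white
#' matter voxel. d = 0 at the pial boundary, 1 at the WM boundary.
#' Subcortical grey matter and WM lesions count as white matter for the
#' purpose of the WM boundary.
#'
#' @param labels A [label_volume()].
#' @return Numeric 3D array with depth in [0, 1] on ribbon voxels and `NA`
#'   elsewhere, with attribute `ribbon` (the logical ribbon mask).
#' @export
depth_field <- function(labels) {
  lc <- label_codes()
  lab <- labels$data
  ribbon <- lab == lc[["cortex"]] | lab == lc[["cortical_lesion"]]
  pial_src <- lab == lc[["formalin"]]
  wm_src <- lab == lc[["wm"]] | lab == lc[["subcortical_gm"]] |
    lab == lc[["wm_lesion"]]
  if (!any(pial_src))
    stop("cortical ribbon has no formalin (pial) boundary")
  if (!any(wm_src))
    stop("cortical ribbon has no white matter boundary")
  dp <- distance_transform(pial_src, labels$voxel_size)
  dw <- distance_transform(wm_src, labels$voxel_size)
  d <- array(NA_real_, dim = dim(lab))
  d[ribbon] <- dp[ribbon] / (dp[ribbon] + dw[ribbon])
  attr(d, "ribbon") <- ribbon
  d
}

#' Sample a quantitative map at a fixed cortical depth
#'
#' Collects map values at ribbon voxels whose fractional depth lies within
#' `band` of `fraction`, enabling depth-resolved laminar summaries.
#'
#' @param qmap Numeric 3D array (a quantitative map on the phantom grid).
#' @param depth Depth field from [depth_field()].
#' @param fraction Target fractional depth in (0, 1).
#' @param band Half-width of the depth band (default 0.05).
#' @param mask Optional logical array restricting the sample (e.g. a lesion
#'   footprint or validity mask).
#' @return List with `values`, a per-voxel `table` (x, y, z 0-based, depth,
#'   value), and `mean`, `sd`, `n`. Empty bands return `n = 0`, not an error.
#' @export
sample_at_depth <- function(qmap, depth, fraction, band = 0.05, mask = NULL) {
  stopifnot(fraction > 0, fraction < 1, band > 0)
  sel <- !is.na(depth) & abs(depth - fraction) <= band & is.finite(qmap)
  if (!is.null(mask)) sel <- sel & mask
  idx <- which(sel, arr.ind = TRUE)
  vals <- qmap[sel]
  list(values = vals,
       table = data.frame(x = idx[, 1] - 1L, y = idx[, 2] - 1L,
                          z = idx[, 3] - 1L, depth = depth[sel], value = vals),
       mean = if (length(vals)) mean(vals) else NA_real_,
       sd = if (length(vals) > 1) sd(vals) else NA_real_,
       n = length(vals))
}
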