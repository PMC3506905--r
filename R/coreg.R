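#' 2D affine transform
#' @param A 2x2 linear part.
#' @param t Length-2 translation, mm.
#' @return An `affine2d` object.
#' @export
affine2d <- function(A, t = c(0, 0)) {
  A <- matrix(as.numeric(A), 2, 2)
  if (abs(det(A)) < 1e-12) stop("affine linear part is singular")
  structure(list(A = A, t = as.numeric(t)), class = "affine2d")
}

#' Apply an affine to 2D point coordinates
#' @param tr An [affine2d()].
#' @param pts n x 2 matrix of (x, y) in mm.
#' @return n x 2 matrix of transformed points.
#' @export
affine_points <- function(tr, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  sweep(pts %*% t(tr$A), 2, tr$t, `+`)
}

#' Invert a 2D affine
#' @param tr An [affine2d()].
#' @return The inverse [affine2d()].
#' @export
affine_invert <- function(tr) {
  Ai <- solve(tr$A)
  affine2d(Ai, -as.numeric(Ai %*% tr$t))
}

#' Fit a 2D affine transform to tag-point pairs by least squares
#'
#' Minimizes the sum of squared target-side residuals over the 6 affine
#' parameters; with exactly 3 non-collinear pairs the transform
#' interpolates (residual 0).
#'
#' @param tags Data frame or matrix with columns `x_src`, `y_src`, `x_dst`,
#'   `y_dst` (mm), n >= 3 rows.
#' @return An [affine2d()] with attributes `rms_residual` (mm) and
#'   `residuals` (n x 2).
#' @export
fit_affine_tags <- function(tags) {
  tags <- as.data.frame(tags)
  stopifnot(all(c("x_src", "y_src", "x_dst", "y_dst") %in% names(tags)))
  n <- nrow(tags)
  if (n < 3) stop("at least 3 tag-point pairs are required")
  X <- cbind(tags$x_src, tags$y_src, 1)
  if (qr(X)$rank < 3)
    stop("degenerate tag points: source points are collinear")
  Y <- cbind(tags$x_dst, tags$y_dst)
  beta <- qr.solve(X, Y)                       # 3 x 2: rows ax, ay, t
  tr <- affine2d(t(beta[1:2, ]), beta[3, ])
  res <- Y - X %*% beta
  attr(tr, "rms_residual") <- sqrt(mean(res^2))
  attr(tr, "residuals") <- res
  tr
}

#' Resample a 2D image through an affine transform
#'
#' Inverse-mapping resampler: each target pixel center (mm) is pulled back
#' through the inverse transform and sampled from the source image —
#' nearest-neighbour for label images (no label mixing), bilinear for
#' continuous maps. Out-of-grid samples get `background`.
#'
#' @param img Source matrix.
#' @param tr [affine2d()] mapping source mm coordinates to target mm.
#' @param target_dim Target grid dimensions (rows, cols); default source dim.
#' @param pixel_size Pixel size in mm (source and target; default 1).
#' @param interpolation `"nearest"` or `"linear"`.
#' @param background Fill value outside the source grid (default `NA`;
#'   use 0 for label images).
#' @return Resampled matrix of dimension `target_dim`.
#' @export
apply_affine <- function(img, tr, target_dim = dim(img), pixel_size = 1,
                         interpolation = c("linear", "nearest"),
                         background = NA_real_) {
  interpolation <- match.arg(interpolation)
  inv <- affine_invert(tr)
  # target pixel centers in mm (0-based index * pixel_size)
  gx <- (seq_len(target_dim[1]) - 1) * pixel_size
  gy <- (seq_len(target_dim[2]) - 1) * pixel_size
  pts <- cbind(rep(gx, times = target_dim[2]),
               rep(gy, each = target_dim[1]))
  src <- affine_points(inv, pts)
  sx <- src[, 1] / pixel_size + 1   # fractional source index
  sy <- src[, 2] / pixel_size + 1
  out <- rep(background, nrow(src))
  if (interpolation == "nearest") {
    ix <- round(sx); iy <- round(sy)
    ok <- ix >= 1 & ix <= nrow(img) & iy >= 1 & iy <= ncol(img)
    out[ok] <- img[cbind(ix[ok], iy[ok])]
  } else {
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    ok <- x0 >= 1 & x0 + 1 <= nrow(img) & y0 >= 1 & y0 + 1 <= ncol(img)
    i00 <- cbind(x0[ok], y0[ok]); i10 <- cbind(x0[ok] + 1, y0[ok])
    i01 <- cbind(x0[ok], y0[ok] + 1); i11 <- cbind(x0[ok] + 1, y0[ok] + 1)
    out[ok] <- img[i00] * (1 - fx[ok]) * (1 - fy[ok]) +
      img[i10] * fx[ok] * (1 - fy[ok]) +
      img[i01] * (1 - fx[ok]) * fy[ok] +
      img[i11] * fx[ok] * fy[ok]
  }
  matrix(out, target_dim[1], target_dim[2])
}

#' Extract a coronal plane from a volumetric map
#'
#' Returns one plane of any volume on the MR grid with its world
#' coordinates (mm, world = 0-based index x voxel_size), mirroring the
#' coronal slab geometry used for histology matching.
#'
#' @param volume Numeric or integer 3D array.
#' @param plane_index 1-based index along `axis`.
#' @param axis Axis normal to the plane (default 2, the y/coronal axis).
#' @param voxel_size Voxel size in mm for the world coordinates.
#' @return Matrix with attributes `world_x`, `world_y` (mm coordinates of
#'   the in-plane axes), `axis` and `plane_index`.
#' @export
extract_slab_plane <- function(volume, plane_index, axis = 2, voxel_size = 1) {
  stopifnot(length(dim(volume)) == 3, axis %in% 1:3)
  if (plane_index < 1 || plane_index > dim(volume)[axis])
    stop("plane_index ", plane_index, " out of range for axis ", axis,
         " of extent ", dim(volume)[axis])
  idx <- rep(list(quote(expr = )), 3)
  idx[[axis]] <- plane_index
  pl <- do.call(`[`, c(list(volume), idx, list(drop = TRUE)))
  in_plane <- setdiff(1:3, axis)
  attr(pl, "world_x") <- (seq_len(dim(volume)[in_plane[1]]) - 1) * voxel_size
  attr(pl, "world_y") <- (seq_len(dim(volume)[in_plane[2]]) - 1) * voxel_size
  attr(pl, "axis") <- axis
  attr(pl, "plane_index") <- plane_index
  pl
}

#' Serialize an affine transform to JSON (row-major 2x3 matrix, mm)
#' @param tr An [affine2d()].
#' @param path Output path.
#' @export
write_affine_json <- function(tr, path) {
  m <- cbind(tr$A, tr$t)
  jsonlite::write_json(list(matrix_2x3_row_major = as.vector(t(m)),
                            units = "mm"),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read tag points from CSV (columns x_src, y_src, x_dst, y_dst in mm)
#' @param path CSV path.
#' @return Data frame of tag-point pairs.
#' @export
read_tag_points <- function(path) utils::read.csv(path)
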