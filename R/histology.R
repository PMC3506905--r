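#' Segment myelin fibers from a chromogen-stained slide
#'
#' Classifies a pixel as myelin when the normalized red-versus-blue contrast
#' (R - B) / max(R + B, 1) exceeds the threshold `tau`, exploiting the color
#' separation between the red-brown AEC chromogen and the light blue
#' counterstain. The ratio rule is invariant to uniform brightness scaling.
#'
#' @param slide RGB array (rows x cols x 3), either 8-bit values in 0-255 or
#'   normalized values in [0, 1] (auto-detected and rescaled to 0-255).
#' @param tau Contrast threshold (default 0.08).
#' @return Logical matrix: `TRUE` = myelin pixel.
#' @export
segment_myelin <- function(slide, tau = 0.08) {
  if (length(dim(slide)) != 3 || dim(slide)[3] < 3)
    stop("slide must be an RGB raster (rows x cols x 3); ",
         "grayscale input has no chromogen/counterstain color contrast")
  if (max(slide, na.rm = TRUE) <= 1) slide <- slide * 255
  r <- slide[, , 1]
  b <- slide[, , 3]
  (r - b) / pmax(r + b, 1) > tau
}

#' Down-sample a binary myelin map into an MR-resolution content map
#'
#' Each output value is 100 x the mean of its `factor` x `factor` input
#' block (percent area covered by myelin). On divisible grids the global
#' myelin fraction is preserved exactly. Non-divisible grids are padded and
#' the padded (partial) blocks are masked `NA`, excluded from statistics
#' rather than partially averaged.
#'
#' @param binary Logical (or 0/1 numeric) matrix from [segment_myelin()].
#' @param factor Integer down-sampling factor >= 1.
#' @return Numeric matrix of myelin content in percent, with attribute
#'   `masked` (logical matrix of padded blocks).
#' @export
myelin_content_map <- function(binary, factor) {
  stopifnot(length(dim(binary)) == 2)
  factor <- as.integer(factor)
  if (factor < 1) stop("down-sampling factor must be >= 1")
  b <- binary * 1
  nr <- nrow(b); nc <- ncol(b)
  nro <- ceiling(nr / factor); nco <- ceiling(nc / factor)
  padded <- array(NA_real_, dim = c(nro * factor, nco * factor))
  padded[1:nr, 1:nc] <- b
  blocks <- array(padded, dim = c(factor, nro, factor, nco))
  content <- 100 * apply(blocks, c(2, 4), mean)   # NA where block is partial
  masked <- is.na(content)
  attr(content, "masked") <- masked
  content
}

#' Read an RGB slide image from PNG (or TIFF)
#' @param path File path; `.png` read via the png package, `.tif`/`.tiff`
#'   via the tiff package when available.
#' @return RGB array with values in [0, 1].
#' @export
read_slide <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::readPNG(path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to read TIFF slides")
    tiff::readTIFF(path)
  } else stop("unsupported slide format: ", path)
}

#' Write an RGB slide image
#' @param slide RGB array in 0-255 or [0, 1].
#' @param path Output path (`.png` or `.tif`/`.tiff`).
#' @export
write_slide <- function(slide, path) {
  if (max(slide, na.rm = TRUE) > 1) slide <- slide / 255
  slide <- pmin(pmax(slide, 0), 1)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(slide, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the tiff package is required to write TIFF slides")
    tiff::writeTIFF(slide, path)
  } else stop("unsupported slide format: ", path)
  invisible(path)
}
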