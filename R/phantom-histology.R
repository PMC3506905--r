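#' Render a synthetic chromogen-stained histology slide
#'
#' Paints each MR-resolution block of a myelin content map with short,
#' randomly oriented fiber strokes in the red-brown of an AEC chromogen over
#' a light blue counterstain background, at `upsample_factor` times finer
#' resolution. Strokes accumulate until the painted-pixel fraction of the
#' block matches its target content exactly at pixel quantization (error
#' < 1 pixel per block, i.e. < 1/upsample_factor^2). Per-pixel color jitter
#' is bounded so the red-minus-blue sign that the segmentation rule relies
#' on is preserved.
#'
#' @param content2d Numeric matrix of target myelin content, percent (`NA`
#'   blocks are rendered as pure background).
#' @param upsample_factor Integer >= 4: histology pixels per MR voxel edge
#'   (default 10, i.e. 35 um synthetic pixels for a 0.35 mm grid).
#' @param seed Integer seed.
#' @param fiber_rgb,background_rgb Base colors, 8-bit RGB.
#' @param jitter SD of the per-pixel Gaussian color jitter (8-bit units).
#' @return RGB array (rows x cols x 3, 0-255) with attributes
#'   `painted_fraction` (realized per-block fraction, percent) and
#'   `upsample_factor`.
#' @export
render_histology_slide <- function(content2d, upsample_factor = 10, seed = 1L,
                                   fiber_rgb = c(165, 70, 50),
                                   background_rgb = c(173, 205, 232),
                                   jitter = 10) {
  f <- as.integer(upsample_factor)
  if (f < 4) stop("upsample_factor must be at least 4")
  if (any(content2d > 100, na.rm = TRUE))
    stop("target myelin content exceeds 100%")
  nr <- nrow(content2d); nc <- ncol(content2d)
  set.seed(seed)
  fiber <- matrix(FALSE, nr * f, nc * f)
  realized <- matrix(0, nr, nc)

  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      tgt <- content2d[i, j]
      if (is.na(tgt) || tgt <= 0) next
      n_t <- round(tgt / 100 * f * f)
      if (n_t == 0) next
      blk <- matrix(FALSE, f, f)
      if (n_t >= f * f) {
        blk[] <- TRUE
      } else {
        while (sum(blk) < n_t) {
          u <- runif(1, 0.5, f + 0.5)
          v <- runif(1, 0.5, f + 0.5)
          ang <- runif(1, 0, pi)
          len <- runif(1, 0.5 * f, 1.2 * f)
          tt <- seq(-len / 2, len / 2, by = 0.4)
          px <- round(u + tt * cos(ang))
          py <- round(v + tt * sin(ang))
          ok <- px >= 1 & px <= f & py >= 1 & py <= f
          new_idx <- unique(cbind(px[ok], py[ok])[!blk[cbind(px[ok], py[ok])], ,
                                                  drop = FALSE])
          if (nrow(new_idx) == 0) next
          need <- n_t - sum(blk)
          if (nrow(new_idx) > need)
            new_idx <- new_idx[sample.int(nrow(new_idx), need), , drop = FALSE]
          blk[new_idx] <- TRUE
        }
      }
      fiber[(i - 1) * f + seq_len(f), (j - 1) * f + seq_len(f)] <- blk
      realized[i, j] <- 100 * sum(blk) / (f * f)
    }
  }

  npix <- length(fiber)
  slide <- array(0, dim = c(dim(fiber), 3))
  for (ch in 1:3) {
    base <- ifelse(fiber, fiber_rgb[ch], background_rgb[ch])
    slide[, , ch] <- pmin(pmax(base + rnorm(npix, 0, jitter), 0), 255)
  }
  # bounded jitter must preserve the chromogen/counterstain R-B contrast sign
  rch <- slide[, , 1]; bch <- slide[, , 3]
  bch[fiber] <- pmin(bch[fiber], rch[fiber] - 15)
  bch[!fiber] <- pmax(bch[!fiber], rch[!fiber] + 15)
  slide[, , 3] <- pmin(pmax(bch, 0), 255)

  attr(slide, "painted_fraction") <- realized
  attr(slide, "upsample_factor") <- f
  slide
}
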