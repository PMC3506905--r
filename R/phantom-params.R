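#' Two-point calibration of the myelin-to-parameter couplings
#'
#' Within the cortical ribbon the quantitative parameters are driven by
#' myelin content m (% area) through couplings that are linear in relaxation
#' RATE: 1/T1 = a1 + k1 m, 1/T2 = a2 + k2 m, delta = a3 + k3 m,
#' M0 = a4 - k4 m. The (a, k) pairs are calibrated so that m equal to the
#' cortical-lesion myelin mean maps exactly onto the cortical-lesion row of
#' the tissue table and m equal to the normal-appearing-cortex mean maps
#' onto the NAC row. Linearity in rate makes the time-versus-content
#' relation hyperbolic: relaxation times rise steeply as myelin tends to
#' zero.
#'
#' @param tissue_table Tissue table with `nac` and `cl` rows; see
#'   [tissue_table_default()].
#' @return List with intercepts `a1..a4` and slopes `k1..k4` (all slopes
#'   positive by construction or an error is raised).
#' @export
myelin_coupling <- function(tissue_table = tissue_table_default()) {
  nac <- tissue_table["nac", ]
  cl <- tissue_table["cl", ]
  dm <- nac$myelin_mean - cl$myelin_mean
  if (dm == 0) stop("calibration rows have identical myelin means")
  k1 <- (1 / nac$t1_mean - 1 / cl$t1_mean) / dm
  k2 <- (1 / nac$t2_mean - 1 / cl$t2_mean) / dm
  k3 <- (nac$delta_mean - cl$delta_mean) / dm
  k4 <- (cl$m0_mean - nac$m0_mean) / dm
  ks <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4)
  if (any(ks <= 0))
    stop("non-monotone myelin coupling: slopes must be positive, got ",
         paste(sprintf("%s=%.3g", names(ks), ks), collapse = ", "))
  list(a1 = 1 / nac$t1_mean - k1 * nac$myelin_mean,
       a2 = 1 / nac$t2_mean - k2 * nac$myelin_mean,
       a3 = nac$delta_mean - k3 * nac$myelin_mean,
       a4 = nac$m0_mean + k4 * nac$myelin_mean,
       k1 = k1, k2 = k2, k3 = k3, k4 = k4)
}

#' Map myelin content to quantitative parameters through the couplings
#'
#' @param m Myelin content, % area.
#' @param coupling Output of [myelin_coupling()].
#' @return List of vectors `t1`, `t2` (ms), `m0` (r.u.), `delta`.
#' @export
coupling_apply <- function(m, coupling) {
  list(t1 = 1 / (coupling$a1 + coupling$k1 * m),
       t2 = 1 / (coupling$a2 + coupling$k2 * m),
       m0 = coupling$a4 - coupling$k4 * m,
       delta = coupling$a3 + coupling$k3 * m)
}

#' Parameter maps container
#' @param t1,t2,m0,delta,myelin Numeric 3D arrays on the label grid.
#' @param voxel_size Voxel size in mm.
#' @return A `parameter_maps` object.
#' @export
parameter_maps <- function(t1, t2, m0, delta, myelin, voxel_size) {
  structure(list(t1 = t1, t2 = t2, m0 = m0, delta = delta, myelin = myelin,
                 voxel_size = voxel_size), class = "parameter_maps")
}

# Gaussian draw clamped (winsorized) to a valid range; sd = 0 gives the mean
.draw_clamped <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  x <- if (sd > 0) rnorm(n, mean, sd) else rep(mean, n)
  pmin(pmax(x, lo), hi)
}

#' Assign ground-truth tissue parameters to a phantom label volume
#'
#' Formalin, white matter, subcortical grey matter and WM-lesion voxels draw
#' T1, T2, M0, delta and myelin independently from their tissue-table rows
#' (Gaussian, clamped to valid ranges, T2 kept strictly below T1). Cortical
#' voxels instead receive myelin from a pial-to-WM laminar gradient
#' (superficial laminae least myelinated), standardized so the cortex-wide
#' mean and SD equal the NAC row, and their T1/T2/M0/delta follow from the
#' rate-linear couplings of [myelin_coupling()].
#'
#' @param labels A [label_volume()].
#' @param spec The [phantom_spec()].
#' @param depth Optional precomputed [depth_field()]; computed if missing.
#' @param seed Seed for the parameter draws (default derived from the spec).
#' @return A [parameter_maps()] object.
#' @export
assign_tissue_parameters <- function(labels, spec, depth = NULL,
                                     seed = spec$seed + 1L) {
  tab <- spec$tissue_table
  lc <- label_codes()
  lab <- labels$data
  dims <- dim(lab)
  t1 <- t2 <- m0 <- delta <- myelin <- array(NA_real_, dim = dims)
  set.seed(seed)

  draw_row <- function(mask, row) {
    n <- sum(mask)
    if (n == 0) return(invisible(NULL))
    r <- tab[row, ]
    t1v <- .draw_clamped(n, r$t1_mean, r$t1_sd, lo = 1e-3)
    t2v <- pmin(.draw_clamped(n, r$t2_mean, r$t2_sd, lo = 1e-3), 0.999 * t1v)
    t1[mask] <<- t1v
    t2[mask] <<- t2v
    m0[mask] <<- .draw_clamped(n, r$m0_mean, r$m0_sd, lo = 1e-6)
    delta[mask] <<- .draw_clamped(n, r$delta_mean, r$delta_sd, 0, 1)
    myelin[mask] <<- .draw_clamped(n, r$myelin_mean, r$myelin_sd, 0, 100)
  }
  draw_row(lab == lc[["formalin"]], "formalin")
  draw_row(lab == lc[["wm"]], "nawm")
  draw_row(lab == lc[["subcortical_gm"]], "subcortical_gm")
  draw_row(lab == lc[["wm_lesion"]], "wm_lesion")

  ctx <- lab == lc[["cortex"]]
  if (any(ctx)) {
    if (is.null(depth)) depth <- depth_field(labels)
    d <- depth[ctx]
    g <- switch(spec$laminar_shape,
                linear = d,
                sigmoid = stats::plogis((d - 0.5) / 0.15))
    if (spec$laminar_jitter > 0)
      g <- g + rnorm(length(g), 0, spec$laminar_jitter)
    r <- tab["nac", ]
    if (r$myelin_sd > 0 && sd(g) > 0) {
      m <- r$myelin_mean + r$myelin_sd * (g - mean(g)) / sd(g)
    } else {
      m <- rep(r$myelin_mean, length(g))
    }
    m <- pmin(pmax(m, 0), 100)
    cp <- coupling_apply(m, myelin_coupling(tab))
    myelin[ctx] <- m
    t1[ctx] <- cp$t1
    t2[ctx] <- pmin(cp$t2, 0.999 * cp$t1)
    m0[ctx] <- cp$m0
    delta[ctx] <- pmin(pmax(cp$delta, 0), 1)
  }
  # cortical-lesion voxels present at assignment time follow the CL row
  cl_mask <- lab == lc[["cortical_lesion"]]
  if (any(cl_mask)) {
    r <- tab["cl", ]
    m <- .draw_clamped(sum(cl_mask), r$myelin_mean, r$myelin_sd, 0, 100)
    cp <- coupling_apply(m, myelin_coupling(tab))
    myelin[cl_mask] <- m
    t1[cl_mask] <- cp$t1
    t2[cl_mask] <- pmin(cp$t2, 0.999 * cp$t1)
    m0[cl_mask] <- cp$m0
    delta[cl_mask] <- pmin(pmax(cp$delta, 0), 1)
  }
  parameter_maps(t1, t2, m0, delta, myelin, labels$voxel_size)
}

# face-adjacency of `mask_a` voxels to `mask_b` voxels
.adjacent_to <- function(mask_a, mask_b) {
  adj <- array(FALSE, dim = dim(mask_a))
  for (axis in 1:3) {
    adj <- adj | .shift3(mask_b, axis, +1L, FALSE) |
      .shift3(mask_b, axis, -1L, FALSE)
  }
  mask_a & adj
}

#' Implant lesions into a phantom
#'
#' Type III subpial lesions relabel cortical voxels lying within
#' `tangential_radius` (mm) of a pial seed point and shallower than
#' `depth_fraction` of the cortical depth; their myelin is drawn from the
#' cortical-lesion distribution and the other parameters follow through the
#' myelin couplings. Focal WM lesions relabel a spherical region of white
#' matter and redraw all parameters independently from the WM-lesion row
#' (WM lesions do not obey the cortical monotone coupling).
#'
#' @param labels A [label_volume()].
#' @param maps The [parameter_maps()] to update.
#' @param spec The [phantom_spec()] carrying `lesion_specs`.
#' @param depth Optional precomputed [depth_field()] of `labels`.
#' @param seed Seed for the lesion parameter draws.
#' @return List with updated `labels`, `maps`, and `lesion_masks` (one
#'   logical array per lesion, in spec order).
#' @export
implant_lesions <- function(labels, maps, spec, depth = NULL,
                            seed = spec$seed + 2L) {
  lc <- label_codes()
  lab <- labels$data
  vs <- labels$voxel_size
  tab <- spec$tissue_table
  if (is.null(depth)) depth <- depth_field(labels)
  co <- lapply(dim(lab), function(n) (seq_len(n) - 1) * vs)
  set.seed(seed)
  lesion_masks <- vector("list", length(spec$lesion_specs))

  for (i in seq_along(spec$lesion_specs)) {
    ls <- spec$lesion_specs[[i]]
    ctr_mm <- ls$center * vs
    if (ls$kind == "subpial_typeIII") {
      ctx <- lab == lc[["cortex"]]
      pial <- .adjacent_to(ctx, lab == lc[["formalin"]])
      if (!any(pial)) stop("no pial boundary to seed subpial lesion ", i)
      idx <- which(pial, arr.ind = TRUE)
      pos <- sweep(idx - 1, 2, vs, `*`)
      d2 <- rowSums(sweep(pos, 2, ctr_mm, `-`)^2)
      if (min(d2) > (ls$tangential_radius + 2)^2)
        stop("subpial lesion ", i, " center is not in cortex ",
             "(nearest pial voxel ", round(sqrt(min(d2)), 1), " mm away)")
      seed_mm <- pos[which.min(d2), ]
      dist2 <- (co[[1]][slice.index(lab, 1)] - seed_mm[1])^2 +
        (co[[2]][slice.index(lab, 2)] - seed_mm[2])^2 +
        (co[[3]][slice.index(lab, 3)] - seed_mm[3])^2
      sel <- ctx & dist2 <= ls$tangential_radius^2 &
        !is.na(depth) & depth < ls$depth_fraction
      if (any(sel)) {
        lab[sel] <- lc[["cortical_lesion"]]
        r <- tab[ls$target_tissue_row, ]
        m <- .draw_clamped(sum(sel), r$myelin_mean, r$myelin_sd, 0, 100)
        cp <- coupling_apply(m, myelin_coupling(tab))
        maps$myelin[sel] <- m
        maps$t1[sel] <- cp$t1
        maps$t2[sel] <- pmin(cp$t2, 0.999 * cp$t1)
        maps$m0[sel] <- cp$m0
        maps$delta[sel] <- pmin(pmax(cp$delta, 0), 1)
      }
      lesion_masks[[i]] <- sel
    } else { # wm_focal
      wm <- lab == lc[["wm"]]
      ci <- round(ls$center) + 1
      in_wm <- wm[ci[1], ci[2], ci[3]]
      if (!in_wm) {
        # snap to nearest WM voxel if the center is marginally off
        idx <- which(wm, arr.ind = TRUE)
        pos <- sweep(idx - 1, 2, vs, `*`)
        d2 <- rowSums(sweep(pos, 2, ctr_mm, `-`)^2)
        if (min(d2) > 2^2)
          stop("wm_focal lesion ", i, " center is not in white matter")
        ctr_mm <- pos[which.min(d2), ]
      }
      dist2 <- (co[[1]][slice.index(lab, 1)] - ctr_mm[1])^2 +
        (co[[2]][slice.index(lab, 2)] - ctr_mm[2])^2 +
        (co[[3]][slice.index(lab, 3)] - ctr_mm[3])^2
      sel <- wm & dist2 <= ls$tangential_radius^2
      if (any(sel)) {
        lab[sel] <- lc[["wm_lesion"]]
        r <- tab[ls$target_tissue_row, ]
        n <- sum(sel)
        t1v <- .draw_clamped(n, r$t1_mean, r$t1_sd, lo = 1e-3)
        maps$t1[sel] <- t1v
        maps$t2[sel] <- pmin(.draw_clamped(n, r$t2_mean, r$t2_sd, lo = 1e-3),
                             0.999 * t1v)
        maps$m0[sel] <- .draw_clamped(n, r$m0_mean, r$m0_sd, lo = 1e-6)
        maps$delta[sel] <- .draw_clamped(n, r$delta_mean, r$delta_sd, 0, 1)
        maps$myelin[sel] <- .draw_clamped(n, r$myelin_mean, r$myelin_sd, 0, 100)
      }
      lesion_masks[[i]] <- sel
    }
  }
  labels$data <- lab
  list(labels = labels, maps = maps, lesion_masks = lesion_masks)
}
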