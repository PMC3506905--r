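#' Write a 3D map as NIfTI-1 with voxel size in the header
#'
#' Coordinate convention: 0-based voxel indices, axis order (x, y, z),
#' world position = index x voxel_size (mm).
#'
#' @param arr Numeric or integer 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param voxel_size Voxel edge length(s), mm.
#' @export
write_map_nifti <- function(arr, path, voxel_size) {
  if (length(voxel_size) == 1) voxel_size <- rep(voxel_size, 3)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Build a phantom specification from a YAML config file
#'
#' Recognized keys mirror the [phantom_spec()] arguments; `lesions` is a
#' list of records with `kind`, `center`, `tangential_radius`,
#' `depth_fraction`.
#'
#' @param path YAML file path.
#' @return A [phantom_spec()].
#' @export
phantom_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        c("grid_shape", "voxel_size", "cortical_thickness_vox",
                          "b1_amplitude", "noise_sigma", "laminar_jitter",
                          "laminar_shape", "seed"))]
  if (!is.null(cfg$lesions))
    args$lesion_specs <- lapply(cfg$lesions, function(l)
      do.call(lesion_spec, l))
  do.call(phantom_spec, args)
}

# generate the full synthetic dataset: geometry, truth maps, acquisitions
.generate_phantom_data <- function(spec, banding_defect = NULL) {
  labels <- build_geometry(spec)
  depth0 <- depth_field(labels)
  maps <- assign_tissue_parameters(labels, spec, depth = depth0)
  imp <- implant_lesions(labels, maps, spec, depth = depth0)
  labels <- imp$labels
  maps <- imp$maps
  # depth is invariant to cortex<->lesion relabeling (ribbon unchanged) and
  # wm_lesion still counts as WM boundary, so depth0 remains valid
  b1 <- generate_b1_field(spec)
  brain <- labels$data != label_codes()[["formalin"]]

  defect <- NULL
  if (!is.null(banding_defect)) {
    if (is.logical(banding_defect)) {
      defect <- banding_defect
    } else {
      co <- lapply(dim(labels$data),
                   function(n) (seq_len(n) - 1) * labels$voxel_size)
      ctr <- banding_defect$center * labels$voxel_size
      d2 <- (co[[1]][slice.index(labels$data, 1)] - ctr[1])^2 +
        (co[[2]][slice.index(labels$data, 2)] - ctr[2])^2 +
        (co[[3]][slice.index(labels$data, 3)] - ctr[3])^2
      defect <- d2 <= banding_defect$radius^2 & brain
    }
  }

  spgr_a <- simulate_spgr(maps, acq_params("SPGR", 7.7, 3.35, 4), b1, brain)
  spgr_b <- simulate_spgr(maps, acq_params("SPGR", 7.7, 3.35, 22), b1, brain)
  ssfp_a <- simulate_bssfp(maps, acq_params("bSSFP", 7.7, 3.84, 20), b1,
                           brain, defect_region = defect)
  ssfp_b <- simulate_bssfp(maps, acq_params("bSSFP", 7.7, 3.84, 70), b1,
                           brain, defect_region = defect)
  mt <- simulate_mt_pair(maps, b1, brain)
  dam <- simulate_dam_pair(b1)

  sig <- spec$noise_sigma
  if (sig > 0) {
    s0 <- spec$seed
    spgr_a <- add_rician_noise(spgr_a, sig, s0 + 11L)
    spgr_b <- add_rician_noise(spgr_b, sig, s0 + 12L)
    ssfp_a <- add_rician_noise(ssfp_a, sig, s0 + 13L)
    ssfp_b <- add_rician_noise(ssfp_b, sig, s0 + 14L)
    mt$s0 <- add_rician_noise(mt$s0, sig, s0 + 15L)
    mt$ssat <- add_rician_noise(mt$ssat, sig, s0 + 16L)
    dam$s1 <- add_rician_noise(dam$s1, sig, s0 + 17L)
    dam$s2 <- add_rician_noise(dam$s2, sig, s0 + 18L)
  }
  list(labels = labels, maps = maps, depth = depth0, b1 = b1, brain = brain,
       spgr = list(a = spgr_a, b = spgr_b),
       bssfp = list(a = ssfp_a, b = ssfp_b),
       mt = mt, dam = dam, defect = defect,
       lesion_masks = imp$lesion_masks)
}

#' Run the full phantom-to-statistics pipeline
#'
#' Generates the synthetic hemisphere, forward-simulates the four
#' acquisitions, inverts them to quantitative maps with B1 correction,
#' applies the banding exclusion and the 6-connectivity cortical-mask
#' erosion, computes per-tissue summaries, Bonferroni-corrected group
#' tests (cortical lesion vs normal-appearing cortex, WM lesion vs
#' normal-appearing WM), voxel-wise Pearson/Spearman correlations of each
#' qMR parameter with myelin content over the eroded cortical ribbon,
#' normalized histograms, laminar depth-resolved T1 summaries, and a
#' histology round-trip check (rendered slide, segmented and down-sampled
#' back to MR resolution). Deterministic given `spec$seed`.
#'
#' @param spec A [phantom_spec()] (or [noiseless_spec()]).
#' @param out_dir Optional output directory; when given, quantitative maps,
#'   labels, depth field, CSV tables, the report JSON and a provenance
#'   manifest are written there.
#' @param depth_fractions Cortical depths to sample (default 0.25/0.5/0.75).
#' @param depth_band Depth band half-width (default 0.05).
#' @param n_bins Histogram bin count (default 64, uniform over the pooled
#'   1st-99th percentile range, recorded in the report).
#' @param banding_defect Optional injected bSSFP banding defect: a logical
#'   array or `list(center = <voxel>, radius = <mm>)`.
#' @param histology_factor Slide upsampling factor (default 10).
#' @param histology_crop Maximum in-plane extent (MR voxels) of the rendered
#'   slide region (default 40, a desk-scale tissue block).
#' @return A `stats_report` list; see the elements documented in the fields
#'   of the returned object.
#' @export
run_pipeline <- function(spec, out_dir = NULL,
                         depth_fractions = c(0.25, 0.5, 0.75),
                         depth_band = 0.05, n_bins = 64,
                         banding_defect = NULL,
                         histology_factor = 10, histology_crop = 40) {
  lc <- label_codes()
  dat <- .generate_phantom_data(spec, banding_defect)
  labels <- dat$labels; maps <- dat$maps

  b1fit <- compute_b1(dat$dam$s1, dat$dam$s2, nominal_deg = 20,
                      mask = dat$brain)
  d1 <- fit_despot1(dat$spgr$a, dat$spgr$b, b1fit$b1, mask = dat$brain)
  d2 <- fit_despot2(dat$bssfp$a, dat$bssfp$b, b1fit$b1, d1$t1,
                    mask = dat$brain)
  mtr <- compute_mtr(dat$mt$s0, dat$mt$ssat, mask = dat$brain)
  banding <- banding_exclusion_mask(d2, dat$defect, mask = dat$brain)

  ribbon <- labels$data == lc[["cortex"]] |
    labels$data == lc[["cortical_lesion"]]
  eroded <- erode_mask_6conn(ribbon)
  valid <- d1$valid & d2$valid & mtr$valid & b1fit$valid & !banding

  roi <- list(
    nac = labels$data == lc[["cortex"]] & eroded & valid,
    cl = labels$data == lc[["cortical_lesion"]] & eroded & valid,
    nawm = labels$data == lc[["wm"]] & valid,
    wm_lesion = labels$data == lc[["wm_lesion"]] & valid)

  qmaps <- list(t1 = d1$t1, t2 = d2$t2, m0 = d1$m0, mtr = mtr$mtr,
                myelin = maps$myelin)
  summaries <- roi_summaries(qmaps, roi)

  tests <- list()
  for (p in names(qmaps)) {
    tests[[paste0("cl_vs_nac_", p)]] <-
      group_compare(qmaps[[p]][roi$cl], qmaps[[p]][roi$nac])
    tests[[paste0("wmlesion_vs_nawm_", p)]] <-
      group_compare(qmaps[[p]][roi$wm_lesion], qmaps[[p]][roi$nawm])
  }

  ribbon_roi <- roi$nac | roi$cl
  correlations <- lapply(qmaps[c("t1", "t2", "m0", "mtr")], function(q)
    correlate(q[ribbon_roi], maps$myelin[ribbon_roi]))

  histograms <- list()
  for (p in names(qmaps)) {
    pooled <- qmaps[[p]][ribbon_roi]
    pooled <- pooled[is.finite(pooled)]
    if (length(unique(pooled)) < 2) next   # degenerate deterministic map
    edges <- histogram_edges(pooled, n_bins)
    histograms[[p]] <- list(
      bin_edges = edges,
      cl = normalized_histogram(qmaps[[p]][roi$cl], edges),
      nac = normalized_histogram(qmaps[[p]][roi$nac], edges),
      whole_cortex = normalized_histogram(pooled, edges))
  }

  depth_summary <- do.call(rbind, lapply(depth_fractions, function(fr) {
    s <- sample_at_depth(d1$t1, dat$depth, fr, depth_band, mask = ribbon_roi)
    data.frame(depth_fraction = fr, parameter = "t1",
               mean = s$mean, sd = s$sd, n = s$n)
  }))

  histology <- .histology_roundtrip(dat, spec, histology_factor,
                                    histology_crop)

  counts <- list(
    brain_voxels = sum(dat$brain),
    ribbon_voxels = sum(ribbon),
    erosion_losses = sum(ribbon) - sum(eroded),
    banding_excluded = sum(banding & eroded & ribbon),
    invalid_fit = sum(dat$brain & !(d1$valid & d2$valid & mtr$valid &
                                      b1fit$valid)),
    roi_n = vapply(roi, sum, 0L))

  report <- structure(list(
    summaries = summaries, tests = tests, correlations = correlations,
    histograms = histograms, depth_summary = depth_summary,
    histology = histology, counts = counts,
    config = list(grid_shape = spec$grid_shape, voxel_size = spec$voxel_size,
                  noise_sigma = spec$noise_sigma,
                  b1_amplitude = spec$b1_amplitude, seed = spec$seed,
                  n_bins = n_bins, depth_fractions = depth_fractions),
    version = as.character(packageVersion("cortexqmr"))),
    class = "stats_report")

  if (!is.null(out_dir)) {
    .write_pipeline_outputs(out_dir, dat, d1, d2, mtr, b1fit, banding,
                            report, spec)
  }
  report
}

# render a slide from one coronal plane of the ground-truth myelin map,
# segment it back and compare block content against the truth
.histology_roundtrip <- function(dat, spec, factor, crop) {
  lc <- label_codes()
  ribbon <- dat$labels$data == lc[["cortex"]] |
    dat$labels$data == lc[["cortical_lesion"]]
  # coronal plane with the most ribbon voxels (through the lesions if any)
  footprint <- if (length(dat$lesion_masks) &&
                   any(vapply(dat$lesion_masks, any, TRUE)))
    Reduce(`|`, dat$lesion_masks) & ribbon else ribbon
  per_plane <- apply(footprint, 2, sum)
  plane <- which.max(per_plane)
  truth <- extract_slab_plane(dat$maps$myelin, plane, axis = 2,
                              voxel_size = dat$labels$voxel_size)
  rib_pl <- extract_slab_plane(ribbon, plane, axis = 2)
  content <- ifelse(rib_pl, truth, NA_real_)
  # crop to a tissue-block-sized window around the richest ribbon region
  rs <- which(rowSums(rib_pl) > 0); cs <- which(colSums(rib_pl) > 0)
  if (length(rs) == 0) return(list(plane = plane, n_blocks = 0L))
  r0 <- max(min(rs), round(mean(range(rs))) - crop %/% 2)
  c0 <- max(min(cs), round(mean(range(cs))) - crop %/% 2)
  rr <- r0:min(r0 + crop - 1, nrow(content))
  cc <- c0:min(c0 + crop - 1, ncol(content))
  content <- content[rr, cc, drop = FALSE]

  slide <- render_histology_slide(content, upsample_factor = factor,
                                  seed = spec$seed + 20L)
  seg <- segment_myelin(slide)
  recovered <- myelin_content_map(seg, factor)
  ok <- !is.na(content)
  list(plane = plane, crop_rows = range(rr), crop_cols = range(cc),
       n_blocks = sum(ok),
       mean_truth = mean(content[ok]),
       mean_recovered = mean(recovered[ok]),
       mean_abs_error = mean(abs(recovered[ok] - content[ok])),
       slide = slide, recovered = recovered, truth = content)
}

.write_pipeline_outputs <- function(out_dir, dat, d1, d2, mtr, b1fit,
                                    banding, report, spec) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- dat$labels$voxel_size
  files <- character()
  wr <- function(arr, name) {
    p <- file.path(out_dir, name)
    write_map_nifti(arr, p, vs)
    files <<- c(files, p)
  }
  wr(dat$labels$data, "labels.nii.gz")
  wr(dat$maps$myelin, "myelin_truth.nii.gz")
  wr(replace(d1$t1, is.na(d1$t1), 0), "t1.nii.gz")
  wr(replace(d2$t2, is.na(d2$t2), 0), "t2.nii.gz")
  wr(replace(d1$m0, is.na(d1$m0), 0), "m0.nii.gz")
  wr(replace(mtr$mtr, is.na(mtr$mtr), 0), "mtr.nii.gz")
  wr(replace(b1fit$b1, is.na(b1fit$b1), 0), "b1.nii.gz")
  wr(replace(dat$depth, is.na(dat$depth), -1), "depth.nii.gz")
  wr(banding * 1L, "banding_exclusion.nii.gz")

  write.csv(report$summaries, file.path(out_dir, "summaries.csv"),
            row.names = FALSE)
  write.csv(report$depth_summary, file.path(out_dir, "depth_summary.csv"),
            row.names = FALSE)
  files <- c(files, file.path(out_dir, c("summaries.csv",
                                         "depth_summary.csv")))
  if (!is.null(report$histology$slide)) {
    sp <- file.path(out_dir, "slide.png")
    write_slide(report$histology$slide, sp)
    files <- c(files, sp)
  }
  rep_json <- report
  rep_json$histology$slide <- NULL       # raster goes to PNG, not JSON
  rep_json$histology$recovered <- NULL
  rep_json$histology$truth <- NULL
  jsonlite::write_json(rep_json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       dataframe = "rows")
  manifest <- list(files = basename(files), seed = spec$seed,
                   config = report$config, version = report$version)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.stats_report <- function(x, ...) {
  cat("Phantom pipeline report (seed", x$config$seed, ",",
      paste(x$config$grid_shape, collapse = "x"), "voxels)\n\n")
  cat("Per-tissue summaries:\n")
  print(x$summaries, row.names = FALSE)
  cat("\nCL vs NAC (Bonferroni-corrected p):\n")
  for (p in c("t1", "t2", "m0", "mtr", "myelin")) {
    tst <- x$tests[[paste0("cl_vs_nac_", p)]]
    cat(sprintf("  %-7s t = %8.2f  p = %.3g %s\n", p, tst$t,
                tst$p_corrected, if (tst$significant) "*" else ""))
  }
  cat("\nCorrelations with myelin content (eroded cortical ribbon):\n")
  for (p in names(x$correlations)) {
    co <- x$correlations[[p]]
    cat(sprintf("  %-5s r = %6.3f  rho = %6.3f (n = %d)\n", p,
                co$pearson_r, co$spearman_rho, co$n))
  }
  invisible(x)
}
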