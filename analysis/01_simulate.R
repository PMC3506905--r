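#!/usr/bin/env Rscript
# Build the synthetic fixed hemisphere and forward-simulate the four
# quantitative acquisitions (SPGR pair, bSSFP pair, MT pair, double-angle
# B1 pair) with Rician noise. Writes the label volume, ground-truth
# parameter maps, B1 field and all signal volumes under results/01_simulate/.

suppressPackageStartupMessages(library(cortexqmr))

out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec(seed = 1)   # default 128^3 grid, 0.35 mm, Table-row tissues
lab <- build_geometry(spec)
cat("Phantom geometry:\n"); print(lab)

depth <- depth_field(lab)
maps <- assign_tissue_parameters(lab, spec, depth = depth)
imp <- implant_lesions(lab, maps, spec, depth = depth)
lab <- imp$labels; maps <- imp$maps
cat("\nAfter lesion implantation:\n"); print(lab)

b1 <- generate_b1_field(spec)
brain <- lab$data != label_codes()[["formalin"]]
cat(sprintf("\nB1 field range: [%.3f, %.3f]\n", min(b1), max(b1)))

acqs <- list(
  spgr_fa04 = list(sim = function() simulate_spgr(
    maps, acq_params("SPGR", 7.7, 3.35, 4), b1, brain), seed = 11L),
  spgr_fa22 = list(sim = function() simulate_spgr(
    maps, acq_params("SPGR", 7.7, 3.35, 22), b1, brain), seed = 12L),
  bssfp_fa20 = list(sim = function() simulate_bssfp(
    maps, acq_params("bSSFP", 7.7, 3.84, 20), b1, brain), seed = 13L),
  bssfp_fa70 = list(sim = function() simulate_bssfp(
    maps, acq_params("bSSFP", 7.7, 3.84, 70), b1, brain), seed = 14L))
mt <- simulate_mt_pair(maps, b1, brain)
dam <- simulate_dam_pair(b1)
acqs$mt_s0 <- list(vol = mt$s0, seed = 15L)
acqs$mt_ssat <- list(vol = mt$ssat, seed = 16L)
acqs$dam_s1 <- list(vol = dam$s1, seed = 17L)
acqs$dam_s2 <- list(vol = dam$s2, seed = 18L)

meta <- list()
for (nm in names(acqs)) {
  v <- if (!is.null(acqs[[nm]]$vol)) acqs[[nm]]$vol else acqs[[nm]]$sim()
  v <- add_rician_noise(v, spec$noise_sigma, spec$seed + acqs[[nm]]$seed)
  write_map_nifti(v$data, file.path(out, paste0(nm, ".nii.gz")),
                  spec$voxel_size)
  meta[[nm]] <- c(v$acquisition[c("sequence", "TR", "TE", "flip_deg",
                                  "mt_saturation")],
                  noise_sigma = v$noise_sigma)
}
jsonlite::write_json(meta, file.path(out, "acquisitions.json"),
                     auto_unbox = TRUE, digits = NA)

write_map_nifti(lab$data, file.path(out, "labels.nii.gz"), spec$voxel_size)
write_map_nifti(unclass(b1), file.path(out, "b1_truth.nii.gz"),
                spec$voxel_size)
for (p in c("t1", "t2", "m0", "delta", "myelin"))
  write_map_nifti(maps[[p]], file.path(out, paste0("truth_", p, ".nii.gz")),
                  spec$voxel_size)

cat("\nWrote", length(meta), "signal volumes plus ground truth to", out, "\n")
cat("Acquisition metadata: results/01_simulate/acquisitions.json\n")
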