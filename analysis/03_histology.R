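#!/usr/bin/env Rscript
# Synthetic histology: render a chromogen-stained slide from one coronal
# plane of the ground-truth myelin map, segment the fibers back out,
# down-sample to MR resolution, and register a deliberately perturbed copy
# back with a tag-point affine. Writes the slide, content maps and the
# recovered transform under results/03_histology/.

suppressPackageStartupMessages(library(cortexqmr))

ind <- "results/01_simulate"
out <- "results/03_histology"
if (!file.exists(file.path(ind, "labels.nii.gz")))
  stop("run analysis/01_simulate.R first")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

labels <- RNifti::readNifti(file.path(ind, "labels.nii.gz"))
vs <- RNifti::pixdim(labels)[1]
lab <- array(as.integer(labels), dim = dim(labels))
myelin <- array(as.numeric(RNifti::readNifti(
  file.path(ind, "truth_myelin.nii.gz"))), dim = dim(labels))
lc <- label_codes()
ribbon <- lab == lc[["cortex"]] | lab == lc[["cortical_lesion"]]

# coronal plane with the largest cortical-lesion footprint
cl_per_plane <- apply(lab == lc[["cortical_lesion"]], 2, sum)
plane <- which.max(cl_per_plane)
cat(sprintf("Using coronal plane %d (%d lesion voxels in plane)\n",
            plane, cl_per_plane[plane]))

truth <- extract_slab_plane(myelin, plane, axis = 2, voxel_size = vs)
rib <- extract_slab_plane(ribbon, plane, axis = 2)
content <- ifelse(rib, truth, NA_real_)
# crop to a 40-voxel tissue block around the ribbon
rs <- range(which(rowSums(rib) > 0)); cs <- range(which(colSums(rib) > 0))
rr <- max(1, round(mean(rs)) - 20):min(nrow(content), round(mean(rs)) + 19)
cc <- max(1, round(mean(cs)) - 20):min(ncol(content), round(mean(cs)) + 19)
content <- content[rr, cc]

slide <- render_histology_slide(content, upsample_factor = 10, seed = 21)
write_slide(slide, file.path(out, "slide.png"))
seg <- segment_myelin(slide)
recovered <- myelin_content_map(seg, 10)
ok <- !is.na(content)
cat(sprintf("Round trip over %d blocks: truth %.2f%%, recovered %.2f%%, mean abs err %.3f points\n",
            sum(ok), mean(content[ok]), mean(recovered[ok]),
            mean(abs(recovered[ok] - content[ok]))))
write.csv(data.frame(truth = content[ok], recovered = recovered[ok]),
          file.path(out, "content_roundtrip.csv"), row.names = FALSE)

# tag-point affine: perturb the slide frame by a known transform and recover
true_tr <- affine2d(matrix(c(cos(0.15), sin(0.15), -sin(0.15), cos(0.15)),
                           2, 2) * 1.05, c(3.2, -1.8))
set.seed(22)
src <- cbind(runif(6, 0, nrow(content) * vs), runif(6, 0, ncol(content) * vs))
dst <- affine_points(true_tr, src)
fit <- fit_affine_tags(data.frame(x_src = src[, 1], y_src = src[, 2],
                                  x_dst = dst[, 1], y_dst = dst[, 2]))
cat(sprintf("Affine recovery RMS residual: %.2e mm (max matrix error %.2e)\n",
            attr(fit, "rms_residual"), max(abs(fit$A - true_tr$A))))
write_affine_json(fit, file.path(out, "slide_to_mr_affine.json"))
cat("Wrote slide.png, content_roundtrip.csv and the affine JSON to", out, "\n")
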