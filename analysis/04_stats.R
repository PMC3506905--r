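#!/usr/bin/env Rscript
# End-to-end statistical analysis on the default phantom: per-tissue
# summaries, Bonferroni-corrected group tests (cortical lesions vs
# normal-appearing cortex, WM lesions vs NAWM), correlations of every qMR
# parameter with myelin content, normalized histograms, and depth-resolved
# laminar T1. Writes the full report bundle under results/04_stats/.

suppressPackageStartupMessages(library(cortexqmr))

out <- "results/04_stats"
spec <- phantom_spec(seed = 1)
report <- run_pipeline(spec, out_dir = out)

print(report)

cat("\nLaminar T1 (eroded cortical ribbon):\n")
print(report$depth_summary, row.names = FALSE, digits = 5)

cat(sprintf("\nHistology round trip: %d blocks, mean abs error %.3f points\n",
            report$histology$n_blocks, report$histology$mean_abs_error))
cat(sprintf("Voxel audit: %d brain, %d ribbon, %d lost to erosion, %d banding-excluded, %d invalid fits\n",
            report$counts$brain_voxels, report$counts$ribbon_voxels,
            report$counts$erosion_losses, report$counts$banding_excluded,
            report$counts$invalid_fit))

# headline contrast: percent T2 increase in cortical lesions over NAC
s <- report$summaries
t2cl <- s$mean[s$tissue == "cl" & s$parameter == "t2"]
t2nac <- s$mean[s$tissue == "nac" & s$parameter == "t2"]
cat(sprintf("\nCortical-lesion T2 exceeds NAC T2 by %.1f%%\n",
            100 * (t2cl - t2nac) / t2nac))
cat("\nReport bundle written to", out, "\n")
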