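#!/usr/bin/env Rscript
# The core perivascular anchoring analysis on the simulated vessel FOV:
# dsDNA-median tile normalisation, composite-channel vessel segmentation,
# one-pixel step rings from -14 (lumen) to +14 (parenchyma) around every
# vessel, overlap exclusion, per-step marker means aggregated across
# vessels (sqrt transform, 95% CIs), z-normalised heatmap rows and
# per-channel peak steps compared against the generative radial layout.
# Because blur + Otsu + closing place the segmented boundary a few pixels
# outside the generative one, absolute peak steps shift inward by that
# amount while the radial ordering is preserved -- the quantity the
# analysis is read for.

suppressPackageStartupMessages(library(exmtools))
sim_dir <- "scratch/sim"
if (!dir.exists(sim_dir)) stop("run analysis/01_simulate.R first")
dir.create("results", showWarnings = FALSE)

img <- read_fov(file.path(sim_dir, "fov_vessels"))
truth <- unlist(jsonlite::read_json(file.path(sim_dir,
                                              "vessel_truth.json")))

norm <- normalize_tile_by_dsdna(cap_percentile(img), "dsDNA")

# vessel objects from the standard vessel composite (boundary marker plus
# lumen-filling leakage marker), as when no external feature mask is given
comp <- composite(norm, c("GLUT1", "Fibrinogen"))
seg <- segment_features(comp, segmentation_params(blur_sigma_px = 2,
                                                  threshold = "otsu",
                                                  min_size_px = 100,
                                                  closing_radius_px = 3))
message(sprintf("segmented %d vessel features", length(mask_labels(seg))))

pv <- profile_vessels(norm, seg, k_min = -14, k_max = 14, se = "disc")
ap <- aggregate_profiles(pv, transform = "sqrt")
hp <- heatmap_and_peaks(ap)
write_table_csv(as.data.frame(ap), "results/anchor_profile.csv")
write_table_csv(hp$peaks, "results/anchor_peaks.csv")

# ordering comparison uses the localised (thin) layers; broad fillers like
# Fibrinogen/dsDNA have flat per-step plateaus with no meaningful peak
thin <- c("SAA", "GLUT1", "CollagenIV", "GlnSyn")
markers <- intersect(thin, hp$peaks$variable)
peaks <- hp$peaks$peak_step[match(markers, hp$peaks$variable)]
cmp <- data.frame(marker = markers, true_offset = truth[markers],
                  peak_step = peaks)
print(cmp)
message(sprintf(
  "radial ordering recovered with Kendall tau = %.2f over %d vessels",
  cor(cmp$true_offset, cmp$peak_step, method = "kendall"),
  length(pv$records)))
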