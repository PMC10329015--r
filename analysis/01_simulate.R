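#!/usr/bin/env Rscript
# Simulate the synthetic inputs every downstream analysis consumes: a
# multi-vessel brain-like phantom with four markers at known signed radial
# offsets around each vessel, and a nuclear cell field for the
# expansion-fold analyses. Images are written as standard FOV directories
# (one grayscale TIFF per channel + panel.csv + fov.json) so the readers
# are exercised too. Ion counts are Poisson; geometry is the ground truth.

suppressPackageStartupMessages(library(exmtools))
set.seed(1)
sim_dir <- "scratch/sim"
dir.create(sim_dir, recursive = TRUE, showWarnings = FALSE)

# --- vessel phantom: 36 vessels on a jittered grid ------------------------
layers <- list(
  list(marker = "SAA", offset_px = -10, thickness_px = 2, amplitude = 50),
  list(marker = "GLUT1", offset_px = 0, thickness_px = 2, amplitude = 50),
  list(marker = "CollagenIV", offset_px = 3, thickness_px = 2,
       amplitude = 50),
  list(marker = "GlnSyn", offset_px = 8, thickness_px = 2, amplitude = 50),
  list(marker = "dsDNA", offset_px = -4, thickness_px = 6, amplitude = 30),
  # lumen-filling leakage marker; fills the object for segmentation
  list(marker = "Fibrinogen", offset_px = -8, thickness_px = 16,
       amplitude = 25))
g <- expand.grid(r = seq(60, 360, by = 60), c = seq(60, 360, by = 60))
vessels <- lapply(seq_len(nrow(g)), function(i)
  list(center = c(g$r[i], g$c[i]) + runif(2, -6, 6),
       lumen_radius_px = 12, wall_thickness_px = 4))
sp <- phantom_spec(420, 420, vessels = vessels, layers = layers,
                   background_rate = 1, pixel_size_um = 0.39,
                   expansion_fold = 3.7, seed = 2)
ph <- make_vessel_phantom(sp, poisson = TRUE)
write_fov(ph$image, file.path(sim_dir, "fov_vessels"))
write_mask(ph$mask, file.path(sim_dir, "vessel_mask.tiff"))
jsonlite::write_json(as.list(ph$truth),
                     file.path(sim_dir, "vessel_truth.json"),
                     auto_unbox = TRUE)
message(sprintf("phantom: %d vessels, %d channels, %d x %d px",
                length(mask_labels(ph$mask)), length(ph$image$channels),
                nrow(ph$mask), ncol(ph$mask)))

# --- nuclear cell field for the fold analyses -----------------------------
cf <- make_cell_field(60, c(300, 300), mean_area_px = 120, area_cv = 0.25,
                      seed = 3)
write_fov(add_poisson_noise(cf$image, seed = 4),
          file.path(sim_dir, "fov_cells_pre"))
write_mask(cf$mask, file.path(sim_dir, "cell_mask_pre.tiff"))
post <- apply_scale(cf$image, 3.7, "linear")
write_fov(add_poisson_noise(post, seed = 5),
          file.path(sim_dir, "fov_cells_post"))
write_mask(apply_scale(cf$mask, 3.7, "nearest"),
           file.path(sim_dir, "cell_mask_post.tiff"))
message(sprintf("cell field: %d cells placed, scaled copy at fold 3.7",
                length(mask_labels(cf$mask))))
message("simulated inputs written under ", sim_dir)
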