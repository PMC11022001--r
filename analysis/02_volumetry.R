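#!/usr/bin/env Rscript
# Step 2 - image-domain volumetry: overlay each stimulated (C2) mask onto
# the baseline (C1), delimit the aneurysm with one world-frame cut plane,
# and measure the luminal volumes with the voxel and mesh estimators.
# Writes results/volumetry/volume_report.csv and the overlay transforms.

source("analysis/00_config.R")
cfg <- study_config(seed = 1L)
src <- file.path("results", "synthetic")
out <- results_dir("volumetry")
stopifnot(file.exists(file.path(src, "c1.nii.gz")))

c1 <- read_mask_nifti(file.path(src, "c1.nii.gz"), label = "C1")
# NIfTI stores spacing, not our world origin; recover it from the sidecar-
# free convention used at synthesis (phantom bbox) by re-deriving the mask
c1_ref <- phantom_mask(cfg$phantom, label = "C1")
c1$origin <- c1_ref$origin

plane <- region_delimitation(
  c(0, 0, cfg$phantom$parent_vessel_radius + cfg$phantom$voxel_size),
  c(0, 0, 1), side = 1)
write_region(plane, file.path(out, "plane.json"))

rows <- lapply(seq_along(cfg$flow_rates), function(k) {
  c2 <- read_mask_nifti(file.path(src, sprintf("c2_d%d.nii.gz", k)),
                        label = sprintf("C2-D%d", k))
  c2$origin <- c1$origin  # same synthesis grid
  tr <- register_overlay(c1, c2, exclude = plane, subsample = 8000)
  write_transform(tr, file.path(out, sprintf("overlay_d%d.json", k)))
  c2r <- transform_mask(c2, tr)
  v1 <- luminal_volume(c1, plane)
  v2 <- luminal_volume(c2r, plane)
  rep_k <- volume_report(v1, v2)
  mesh1 <- mesh_from_mask(c1)
  data.frame(flow_mlmin = cfg$flow_rates[k],
             v_c1_mm3 = rep_k$v_c1, v_c2_mm3 = rep_k$v_c2,
             dv_exp_mm3 = rep_k$delta_v, dv_exp_pct = rep_k$delta_v_pct,
             v_c1_mesh_mm3 = luminal_volume(mesh1, plane),
             overlay_dice = attr(tr, "dice"))
})
tab <- do.call(rbind, rows)
write.csv(tab, file.path(out, "volume_report.csv"), row.names = FALSE)

cat("voxel-domain aneurysm volumetry after overlay:\n")
print(tab, row.names = FALSE)
cat(sprintf("voxel vs mesh C1 estimator gap: %.2f%%\n",
            max(abs(tab$v_c1_mm3 - tab$v_c1_mesh_mm3) / tab$v_c1_mm3 * 100)))
cat("note: sub-voxel sac deformation makes the voxel-count volume change\n")
cat("quantization-limited at 0.25 mm; the identification step therefore\n")
cat("consumes the forward-sourced volume change (see methods vignette).\n")
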