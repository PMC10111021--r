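#!/usr/bin/env Rscript
# Label-volume clean-up and surface extraction, demonstrated on a corrupted
# segmentation: closing (5-voxel cube), ball median filter (5 voxels),
# largest connected component, iso-surfacing, Laplacian smoothing.
library(lvssm)

out <- "results/mask2mesh"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

mesh0 <- generate_lv_mesh(latent_params(bump_amplitudes = c(2, -1, 1.5, 0)))
v0 <- surface_and_volume(mesh0)$volume

lab <- voxelize(mesh0, spacing_mm = 0.8)
bad <- corrupt_label(lab, n_holes = 6, hole_diameter_vox = 3,
                     n_islands = 4, seed = 3)$label
write_nrrd(bad, file.path(out, "label_corrupted.nrrd"))

clean <- clean_label(bad)
write_nrrd(clean, file.path(out, "label_cleaned.nrrd"))

mesh1 <- extract_surface(clean, smooth_iterations = 20, relaxation = 0.1)
write_stl(mesh1, file.path(out, "surface_cleaned.stl"))
v1 <- surface_and_volume(mesh1)$volume

cat(sprintf("source mesh volume      %8.0f mm^3\n", v0))
cat(sprintf("corrupted label volume  %8.0f mm^3\n", label_volume(bad)))
cat(sprintf("cleaned label volume    %8.0f mm^3\n", label_volume(clean)))
cat(sprintf("re-meshed volume        %8.0f mm^3 (%.2f%% from source)\n",
            v1, 100 * (v1 - v0) / v0))
cat("outputs in", out, "\n")
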