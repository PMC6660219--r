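#!/usr/bin/env Rscript
# Density mapping on a synthetic foveal mosaic with known ground truth:
# generates a quasi-hexagonal mosaic with a radial falloff, maps its density
# with the 10-arcmin sliding window, finds the peak, and extracts annular
# (5-arcmin and 25-micron) and meridional profiles.

library(foveatopo)
dir.create("results", showWarnings = FALSE)

rmf <- rmf_from_biometry(biometry(23.5, 7.8, 3.6))$rmf_um_per_deg
profile <- density_profile(15000, r0_arcmin = 30, gamma = 1.2,
                           anisotropy = 1.15)
mosaic <- generate_mosaic(profile, extent_arcmin = 60, seed = 101, rmf = rmf)
cat(sprintf("Synthetic mosaic: %d cones over 60 x 60 arcmin (rmf %.1f um/deg)\n",
            length(mosaic$x_px), rmf))

map <- density_map(mosaic, step_px = 6)
peak <- find_peak(map)
cat(sprintf("Peak density: %.0f cones/deg^2 = %.0f cones/mm^2 at (%.1f, %.1f) arcmin\n",
            peak$d_ang, peak$d_lin, peak$location_arcmin[1],
            peak$location_arcmin[2]))
cat(sprintf("  (injected peak %.0f cones/deg^2 at (30.0, 30.0); recovery error %.1f%%)\n",
            profile$peak, 100 * (peak$d_ang / profile$peak - 1)))
# coarser grid for the exported table; the step-6 map above drives the peak
write_density_csv(density_map(mosaic, step_px = 24), "results/density_map.csv")

ann_arcmin <- annular_profile(mosaic, peak$location_arcmin, width = 5,
                              unit = "arcmin", max_eccentricity = 25)
ann_um <- annular_profile(mosaic, peak$location_arcmin, width = 25,
                          unit = "um", max_eccentricity = 125)
write.csv(ann_arcmin, "results/profile_annular_arcmin.csv", row.names = FALSE)
write.csv(ann_um, "results/profile_annular_um.csv", row.names = FALSE)
cat("Annular profile (5-arcmin rings, cones/deg^2):",
    paste(round(ann_arcmin$d_ang), collapse = " "), "\n")

for (ax in c("horizontal", "vertical")) {
  dp <- directional_profile(mosaic, peak$location_arcmin, ax,
                            step_arcmin = 2, max_eccentricity = 20)
  write.csv(dp, sprintf("results/profile_%s.csv", ax), row.names = FALSE)
}
h <- read.csv("results/profile_horizontal.csv")
v <- read.csv("results/profile_vertical.csv")
edge <- abs(h$position) >= 14
cat(sprintf("Meridional asymmetry at 14-20 arcmin: vertical/horizontal density ratio %.2f\n",
            mean(v$d_ang[edge]) / mean(h$d_ang[edge])))
cat("  (< 1 as injected: vertical falloff 1.15x steeper)\n")
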