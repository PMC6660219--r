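#!/usr/bin/env Rscript
# Spatial-vision estimates: hexagonal-packing Nyquist limits, cone spacing
# and approximate Snellen equivalents for every reference eye, at the density
# peak and at the PRL.

library(foveatopo)
dir.create("results", showWarnings = FALSE)

co <- table2_cohort()
co <- add_sampling_columns(co, "peak_density_deg2", prefix = "peak_")
co <- add_sampling_columns(co, "prl_density_deg2", prefix = "prl_")
co$prl_snellen_denom <- snellen_equivalent(co$prl_nyquist_cpd)
write.csv(co, "results/sampling_limits.csv", row.names = FALSE)

cat(sprintf("Nyquist limit at peak density: %.1f to %.2f cyc/deg (mean %.1f)\n",
            min(co$peak_nyquist_cpd), max(co$peak_nyquist_cpd),
            mean(co$peak_nyquist_cpd)))
cat(sprintf("Nyquist limit at PRL:          %.1f to %.1f cyc/deg (mean %.1f)\n",
            min(co$prl_nyquist_cpd), max(co$prl_nyquist_cpd),
            mean(co$prl_nyquist_cpd)))
cat(sprintf("Cone spacing at peak: %.2f to %.2f arcmin; at PRL: %.2f to %.2f arcmin\n",
            min(co$peak_spacing_arcmin), max(co$peak_spacing_arcmin),
            min(co$prl_spacing_arcmin), max(co$prl_spacing_arcmin)))
cat(sprintf("Approximate Snellen range at PRL: 20/%.1f to 20/%.1f\n",
            max(co$prl_snellen_denom), min(co$prl_snellen_denom)))
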