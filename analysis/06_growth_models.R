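#!/usr/bin/env Rscript
# Eye-growth model simulation: cohorts generated under each growth model
# carry their defining slope signatures, and the mixed regime tuned to the
# observed angular slope is recoverable from noisy 28-eye cohorts.

library(foveatopo)
dir.create("results", showWarnings = FALSE)

sig_row <- function(kind, regs)
  data.frame(model = kind,
             slope_angular = regs$peak_ang$slope,
             slope_linear = regs$peak_lin$slope)
sig <- do.call(rbind, lapply(
  c("global_expansion", "equatorial_stretching", "over_development"),
  function(k) {
    gm <- growth_model(k, gain = 0.05)
    sig_row(k, cohort_regressions(generate_cohort(gm, n_eyes = 28, seed = 201)))
  }))
write.csv(sig, "results/growth_model_signatures.csv", row.names = FALSE)
cat("Noiseless slope signatures (cones per deg^2 or mm^2, per mm of axial length):\n")
print(sig, row.names = FALSE)
cat("  global expansion: flat angular, falling linear; equatorial stretching:\n")
cat("  rising angular, flat linear; over-development: both rising.\n\n")

# parameter recovery in the mixed regime (~ +750 cones/deg^2 per mm)
gm <- growth_model("mixed", mix = 0.42)
n_rep <- 200
fits <- truths <- covered <- numeric(n_rep)
for (i in seq_len(n_rep)) {
  co <- generate_cohort(gm, n_eyes = 28, noise_sd = 0.08, seed = 300 + i)
  f <- ols_fit(co$axial_length_mm, co$peak_density_deg2)
  fits[i] <- f$slope
  truths[i] <- attr(co, "true_slope_ang")
  covered[i] <- f$ci_lower <= truths[i] && truths[i] <= f$ci_upper
}
rec <- data.frame(n_replicates = n_rep, n_eyes = 28, noise_sd = 0.08,
                  mean_true_slope = mean(truths),
                  mean_fitted_slope = mean(fits),
                  recovery_ratio = mean(fits / truths),
                  ci_coverage = mean(covered))
write.csv(rec, "results/growth_model_recovery.csv", row.names = FALSE)
cat(sprintf("Mixed-model recovery over %d noisy cohorts (n = 28 eyes, 8%% noise):\n",
            n_rep))
cat(sprintf("  injected angular slope ~%.0f, fitted mean %.0f (ratio %.3f)\n",
            mean(truths), mean(fits), mean(fits / truths)))
cat(sprintf("  95%% CI coverage of the injected slope: %.1f%%\n",
            100 * mean(covered)))
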