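#!/usr/bin/env Rscript
# Stage 5: report.
#
# Reads the stage-4 tables and summarizes the study: per-plaque PCS
# distributions (median, interquartile range, full range) against the
# homogeneous-model PCS, the homogeneous-vs-median deviation under both
# normalizations, the range-vs-homogeneous regression, and the highest
# Sobol main index per plaque. Also renders the two study figures
# (PCS distributions per plaque; PCS range vs homogeneous PCS).

library(plaqhet)

pcs <- read.csv("results/pcs.csv")
summ <- read.csv("results/pcs_summary.csv")
sens <- read.csv("results/sensitivity.csv")
corr <- jsonlite::read_json("results/correlation.json",
                            simplifyVector = TRUE)

dev_vs_median <- abs(summ$pcs_homogeneous - summ$pcs_median) /
  summ$pcs_median * 100
dev_vs_hom <- abs(summ$pcs_homogeneous - summ$pcs_median) /
  abs(summ$pcs_homogeneous) * 100
in_iqr <- summ$pcs_homogeneous >= summ$pcs_iqr_low &
  summ$pcs_homogeneous <= summ$pcs_iqr_high

message("Per-plaque PCS (kPa):")
for (i in seq_len(nrow(summ))) {
  message(sprintf(
    "  %s: homogeneous %6.1f | heterogeneous median %6.1f, IQR [%5.1f, %5.1f], range %5.1f (cap %3.0f um)",
    summ$plaque_id[i], summ$pcs_homogeneous[i], summ$pcs_median[i],
    summ$pcs_iqr_low[i], summ$pcs_iqr_high[i], summ$pcs_range[i],
    summ$min_cap_thickness_um[i]))
}
message(sprintf(
  "Homogeneous PCS within the heterogeneous IQR for %d of %d plaques",
  sum(in_iqr), nrow(summ)))
message(sprintf(
  "Mean |homogeneous - median| deviation: %.1f%% of the median (%.1f%% of the homogeneous value)",
  mean(dev_vs_median), mean(dev_vs_hom)))
message(sprintf(
  "PCS range vs homogeneous PCS: slope %.2f, R^2 = %.2f",
  corr$slope, corr$r_squared))
message(sprintf(
  "Highest main Sobol index per plaque: %.2f-%.2f (mean %.2f)",
  min(summ$highest_main_index, na.rm = TRUE),
  max(summ$highest_main_index, na.rm = TRUE),
  mean(summ$highest_main_index, na.rm = TRUE)))

dir.create("results/figures", showWarnings = FALSE, recursive = TRUE)

png("results/figures/pcs_distributions.png", 900, 600, res = 110)
het <- pcs[pcs$sample_index > 0, ]
boxplot(pcs_kPa ~ plaque_id, het, range = 0,
        xlab = "plaque", ylab = "PCS (kPa)",
        main = "PCS: heterogeneous distributions vs homogeneous models",
        border = "steelblue")
points(seq_len(nrow(summ)), summ$pcs_homogeneous, pch = 19)
legend("topleft", legend = c("heterogeneous (box: IQR, whiskers: range)",
                             "homogeneous model"),
       pch = c(NA, 19), lty = c(1, NA), col = c("steelblue", "black"),
       bty = "n")
dev.off()

png("results/figures/range_vs_homogeneous.png", 700, 600, res = 110)
plot(summ$pcs_homogeneous, summ$pcs_range, pch = 19,
     xlab = "homogeneous-model PCS (kPa)",
     ylab = "heterogeneous PCS range (kPa)",
     main = sprintf("R^2 = %.2f", corr$r_squared))
abline(corr$intercept, corr$slope, col = "grey40")
dev.off()

message("wrote results/figures/*.png")
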