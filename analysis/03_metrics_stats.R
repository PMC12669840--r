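#!/usr/bin/env Rscript
# Stage 3: univariate bill descriptors and the statistical battery.
#
# Computes arc length, arc:chord curvature, outer surface area, the
# distal-millimeter sharpness ratio, the dorsal included angle and centroid
# size per specimen; then tests sexual dimorphism with Procrustes ANOVA on
# the symmetric shape (sex, curvature and sharpness as predictors),
# Mann-Whitney U tests on each descriptor, and Spearman correlations among
# the sharpness measures and PC1.
#
# Outputs under results/stats/: metrics table, test summaries as JSON.

suppressPackageStartupMessages(library(billmorph))

pop <- readRDS("results/population/population.rds")
shape <- readRDS("results/shape/shape.rds")
out_dir <- "results/stats"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

metrics <- metrics_table(pop)
write.csv(metrics, file.path(out_dir, "bill_metrics.csv"), row.names = FALSE)

sex <- factor(metrics$sex)
seed <- 20260923L

anovas <- list(
  shape_by_sex = procrustes_anova(shape$symmetry$symmetric, sex,
                                  n_perm = 999, seed = seed),
  shape_by_curvature = procrustes_anova(shape$symmetry$symmetric,
                                        metrics$arc_chord_ratio,
                                        n_perm = 999, seed = seed + 1L),
  shape_by_sharpness = procrustes_anova(shape$symmetry$symmetric,
                                        metrics$sharpness_ratio,
                                        n_perm = 999, seed = seed + 2L),
  size_by_arc_length = procrustes_anova(shape$fit$centroid_sizes,
                                        metrics$arc_length,
                                        n_perm = 999, seed = seed + 3L),
  size_by_area = procrustes_anova(shape$fit$centroid_sizes,
                                  metrics$outer_surface_area,
                                  n_perm = 999, seed = seed + 4L))

mw <- lapply(c(curvature = "arc_chord_ratio", arc_length = "arc_length",
               sharpness = "sharpness_ratio", included_angle = "included_angle",
               surface_area = "outer_surface_area"), function(v)
  mann_whitney_u(metrics[[v]][sex == "M"], metrics[[v]][sex == "F"]))

rho <- list(
  sharpness_vs_angle = spearman_cor(metrics$sharpness_ratio,
                                    metrics$included_angle),
  pc1_vs_angle = spearman_cor(shape$space$scores[, 1],
                              metrics$included_angle),
  pc1_vs_sharpness = spearman_cor(shape$space$scores[, 1],
                                  metrics$sharpness_ratio))

strip <- function(x) lapply(x, function(e) unclass(e)[c("r_squared", "f_stat",
                                                        "p_value")])
jsonlite::write_json(list(
  procrustes_anova = strip(anovas),
  mann_whitney = mw, spearman = rho), file.path(out_dir, "tests.json"),
  auto_unbox = TRUE, digits = NA, force = TRUE)

cat(sprintf("sex on shape: R2 = %.3f, p = %.4g\n",
            anovas$shape_by_sex$r_squared, anovas$shape_by_sex$p_value))
for (nm in names(mw))
  cat(sprintf("Mann-Whitney %-14s W = %4.0f  p = %.4g\n",
              nm, mw[[nm]]$statistic, mw[[nm]]$p_value))
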