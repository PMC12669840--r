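#' Configuration for a full synthetic study run
#'
#' Bundles every stage's parameters with explicit seeds so a run is
#' reproducible bit-for-bit.
#'
#' @param population A [population_spec()].
#' @param landmark_n Points per contour in the landmark protocol.
#' @param anova_perms Permutations for Procrustes ANOVA.
#' @param seed Study seed (statistics stages); the population carries its
#'   own seed.
#' @param exclude_shape Specimen ids excluded from shape/surface analyses
#'   (emulates damaged specimens; exercises unbalanced designs).
#' @param surface_res `list(n_s, n_phi)` surface mesh resolution.
#' @param volume_res `list(n_s, n_phi, n_core, n_shell)` volume mesh
#'   resolution for the FE pair.
#' @param fe_order Element order for FE runs.
#' @param F_A_mN,F_B_unscaled_mN Stabbing forces, mN.
#' @param materials FE materials.
#' @param buckling Compute buckling factors in FE comparisons.
#' @return A `study_config` list.
#' @export
study_config <- function(population = population_spec(),
                         landmark_n = 60L, anova_perms = 999L, seed = 1L,
                         exclude_shape = character(0),
                         surface_res = list(n_s = 120L, n_phi = 32L),
                         volume_res = list(n_s = 20L, n_phi = 12L,
                                           n_core = 2L, n_shell = 1L),
                         fe_order = 2L, F_A_mN = 200, F_B_unscaled_mN = 125,
                         materials = bill_materials(), buckling = TRUE) {
  structure(list(population = population, landmark_n = as.integer(landmark_n),
                 anova_perms = as.integer(anova_perms),
                 seed = as.integer(seed), exclude_shape = exclude_shape,
                 surface_res = surface_res, volume_res = volume_res,
                 fe_order = fe_order, F_A_mN = F_A_mN,
                 F_B_unscaled_mN = F_B_unscaled_mN, materials = materials,
                 buckling = buckling),
            class = "study_config")
}

#' Select the PC1-extreme specimen pair
#'
#' Returns the specimens with the minimum and maximum score on the first
#' principal component of the shape space — the pair spanning the dominant
#' axis of shape variation, used for the FE comparison. Ties are broken by
#' specimen id (lexicographic).
#'
#' @param scores_pc1 Numeric PC1 scores.
#' @param groups Group label (sex) per specimen; at least two groups
#'   required.
#' @param ids Specimen ids.
#' @return List with `low` and `high` ids, plus their groups.
#' @export
select_extremes <- function(scores_pc1, groups, ids) {
  if (length(unique(groups)) < 2L)
    stop("need specimens from at least two groups")
  ord <- order(scores_pc1, ids)
  low <- ord[1]; high <- ord[length(ord)]
  list(low = ids[low], high = ids[high],
       low_group = groups[low], high_group = groups[high])
}

#' Run the full synthetic dimorphism study
#'
#' Executes every stage in order: population generation, landmarking, GPA
#' with sliding semilandmarks, bilateral symmetry decomposition, PCA of the
#' symmetric component, univariate bill metrics, the statistical battery
#' (Procrustes ANOVAs, Mann-Whitney tests, Spearman correlations), selection
#' of the PC1-extreme pair, volume meshing of that pair, and the scaled and
#' unscaled comparative FE protocols at both load angles. Rerunning with the
#' same config reproduces all stochastic outputs exactly.
#'
#' @param config A [study_config()].
#' @param verbose Print stage progress.
#' @return A `study_report` list with per-stage results.
#' @export
run_study <- function(config = study_config(), verbose = FALSE) {
  say <- function(...) if (verbose) message(...)
  stage <- "population"
  result <- tryCatch({
    say("generating population")
    pop <- sample_population(config$population,
                             n_s = config$surface_res$n_s,
                             n_phi = config$surface_res$n_phi)
    pop_shape <- pop[!(names(pop) %in% config$exclude_shape)]

    stage <- "landmarks"
    say("landmarking")
    configs <- lapply(pop_shape, specimen_configuration,
                      n = config$landmark_n)

    stage <- "gpa"
    say("Procrustes superimposition")
    fit <- generalized_procrustes(configs)
    sym <- bilateral_symmetry(fit)
    space <- shape_pca(sym$symmetric)

    stage <- "metrics"
    say("bill metrics")
    metrics <- metrics_table(pop)
    metrics_shape <- metrics[!(metrics$id %in% config$exclude_shape), ]

    stage <- "stats"
    say("statistics")
    sex_shape <- factor(vapply(pop_shape, function(s) s$sex, ""))
    anova_sex <- procrustes_anova(sym$symmetric, sex_shape,
                                  n_perm = config$anova_perms,
                                  seed = config$seed)
    anova_curv <- procrustes_anova(sym$symmetric,
                                   metrics_shape$arc_chord_ratio,
                                   n_perm = config$anova_perms,
                                   seed = config$seed + 1L)
    anova_sharp <- procrustes_anova(sym$symmetric,
                                    metrics_shape$sharpness_ratio,
                                    n_perm = config$anova_perms,
                                    seed = config$seed + 2L)
    cs <- fit$centroid_sizes
    anova_cs_arc <- procrustes_anova(cs, metrics_shape$arc_length,
                                     n_perm = config$anova_perms,
                                     seed = config$seed + 3L)
    anova_cs_area <- procrustes_anova(cs, metrics_shape$outer_surface_area,
                                      n_perm = config$anova_perms,
                                      seed = config$seed + 4L)
    mw <- function(var) {
      mann_whitney_u(metrics[[var]][metrics$sex == "M"],
                     metrics[[var]][metrics$sex == "F"])
    }
    mw_tests <- list(arc_chord_ratio = mw("arc_chord_ratio"),
                     arc_length = mw("arc_length"),
                     sharpness_ratio = mw("sharpness_ratio"),
                     included_angle = mw("included_angle"),
                     outer_surface_area = mw("outer_surface_area"))
    spearman_tests <- list(
      sharpness_vs_angle = spearman_cor(metrics$sharpness_ratio,
                                        metrics$included_angle),
      pc1_vs_angle = spearman_cor(
        space$scores[, 1],
        metrics_shape$included_angle),
      pc1_vs_sharpness = spearman_cor(
        space$scores[, 1],
        metrics_shape$sharpness_ratio))

    stage <- "extremes"
    ids_shape <- names(pop_shape)
    ext <- select_extremes(space$scores[, 1], as.character(sex_shape),
                           ids_shape)
    # reference = the female of the pair when the extremes span the sexes
    pair <- c(ext$low, ext$high)
    sexes <- c(ext$low_group, ext$high_group)
    ref_id <- if ("F" %in% sexes) pair[sexes == "F"][1] else pair[1]
    tgt_id <- setdiff(pair, ref_id)[1]

    stage <- "volume meshing"
    say("volume meshing extreme pair: ", ref_id, " vs ", tgt_id)
    vr <- config$volume_res
    spec_A <- generate_volume(pop[[ref_id]],
                              n_s = vr$n_s, n_phi = vr$n_phi,
                              n_core = vr$n_core, n_shell = vr$n_shell)
    spec_B <- generate_volume(pop[[tgt_id]],
                              n_s = vr$n_s, n_phi = vr$n_phi,
                              n_core = vr$n_core, n_shell = vr$n_shell)

    stage <- "fea"
    say("comparative FE")
    fe_scaled <- run_comparison(spec_A, spec_B, mode = "scaled",
                                F_A_mN = config$F_A_mN,
                                materials = config$materials,
                                order = config$fe_order,
                                buckling = config$buckling)
    fe_unscaled <- run_comparison(spec_A, spec_B, mode = "unscaled",
                                  F_A_mN = config$F_A_mN,
                                  F_B_unscaled_mN = config$F_B_unscaled_mN,
                                  materials = config$materials,
                                  order = config$fe_order,
                                  buckling = config$buckling)

    list(config = config, population = pop, fit = fit, symmetry = sym,
         shape_space = space, metrics = metrics,
         anova = list(sex = anova_sex, curvature = anova_curv,
                      sharpness = anova_sharp, size_arc = anova_cs_arc,
                      size_area = anova_cs_area),
         mann_whitney = mw_tests, spearman = spearman_tests,
         extremes = ext, reference_id = ref_id, target_id = tgt_id,
         fe_scaled = fe_scaled, fe_unscaled = fe_unscaled)
  }, error = function(e) {
    stop("study failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  structure(result, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("Synthetic bill dimorphism study\n")
  cat(sprintf("  specimens: %d (%d in shape analysis)\n",
              length(x$population), dim(x$fit$aligned)[1]))
  cat(sprintf("  PC1 %.1f%%, PC2 %.1f%% of symmetric shape variation\n",
              x$shape_space$pct_variance[1], x$shape_space$pct_variance[2]))
  cat(sprintf("  sex effect: R2 = %.2f, p = %.4g\n",
              x$anova$sex$r_squared, x$anova$sex$p_value))
  cat(sprintf("  FE pair: %s (ref) vs %s\n", x$reference_id, x$target_id))
  cat("  scaled FE percentage differences (target vs reference):\n")
  print(x$fe_scaled$table[, c("metric", "pct_difference", "load_mode")],
        digits = 3)
  invisible(x)
}
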