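#' Scale a load to an equal force:surface-area ratio
#'
#' Comparative FE protocol: the force applied to the target model B is chosen
#' so that F_B / SA_B = F_A / SA_A, removing size differences from stress
#' comparisons.
#'
#' @param F_A Reference force, mN.
#' @param SA_A,SA_B Reference and target model surface areas, mm^2 (the full
#'   closed-model boundary area, not the morphometric outer selection).
#' @return Target force F_B, mN (full precision; round for reporting).
#' @export
scale_force <- function(F_A, SA_A, SA_B) {
  if (F_A <= 0) stop("reference force must be > 0")
  if (SA_A <= 0 || SA_B <= 0) stop("surface areas must be > 0")
  F_A * SA_B / SA_A
}

#' Adjust strain energy to an equal force:volume ratio
#'
#' Strain energies of differently sized models are not directly comparable;
#' the target model's energy is adjusted to the reference's force:volume
#' regime via `U_B' = U_B (F_A / F_B)^2 (V_B / V_A)^(1/3)`. Under linear
#' elasticity this maps geometrically similar models to identical adjusted
#' energies, and reduces to the identity when forces and volumes agree.
#'
#' @param U_B Computed strain energy of the target model, mJ.
#' @param F_A,F_B Reference and target forces (any common unit).
#' @param V_A,V_B Reference and target model volumes, mm^3.
#' @return Adjusted strain energy U_B', mJ.
#' @export
adjust_strain_energy <- function(U_B, F_A, F_B, V_A, V_B) {
  if (F_A <= 0 || F_B <= 0) stop("forces must be > 0")
  if (V_A <= 0 || V_B <= 0) stop("volumes must be > 0")
  U_B * (F_A / F_B)^2 * (V_B / V_A)^(1 / 3)
}

#' Percentage differences between two performance summaries
#'
#' Reports `100 * (value_B - value_A) / value_A` per metric — the target
#' (male) relative to the reference (female).
#'
#' @param summary_A,summary_B Named lists/vectors with identical metric
#'   names (e.g. `peak_vm_98`, `mwam_vm`, `strain_energy`,
#'   `buckling_load_factor`).
#' @return Named numeric vector of percentage differences.
#' @export
compare_performance <- function(summary_A, summary_B) {
  a <- unlist(summary_A); b <- unlist(summary_B)
  common <- intersect(names(a), names(b))
  if (length(common) == 0L) stop("no common metrics")
  a <- a[common]; b <- b[common]
  keep <- !is.na(a) & !is.na(b)
  if (any(a[keep] == 0)) stop("zero reference value in metric(s): ",
                              paste(common[keep][a[keep] == 0], collapse = ", "))
  out <- rep(NA_real_, length(common)); names(out) <- common
  out[keep] <- 100 * (b[keep] - a[keep]) / a[keep]
  out
}

# One specimen's full performance summary under one load mode.
performance_summary <- function(model, specimen, load_mode, force_mN,
                                buckling = TRUE) {
  bc <- make_bc(specimen, load_mode = load_mode, total_force_mN = force_mN)
  sol <- solve_static(model, bc)
  vs <- vm_summaries(sol)
  blf <- if (buckling) buckling_load_factor(model, bc, sol)$load_factor
         else NA_real_
  list(peak_vm_98 = vs$peak_vm_98, mwam_vm = vs$mwam_vm,
       strain_energy = sol$strain_energy, buckling_load_factor = blf,
       applied_force_mN = force_mN, load_mode = load_mode)
}

#' Run the comparative finite-element protocol on a specimen pair
#'
#' Reference model A and target model B are solved under both stabbing load
#' angles. In `unscaled` mode the empirical puncture forces are applied
#' (200 mN to the reference, 125 mN to the target by default); in `scaled`
#' mode the target force is set by [scale_force()] to an equal
#' force:surface-area ratio and the target's strain energy is adjusted by
#' [adjust_strain_energy()] to the equal force:volume regime.
#'
#' @param specimen_A,specimen_B Aligned `bill_specimen`s with volume meshes
#'   (A is the reference).
#' @param mode `"scaled"` or `"unscaled"`.
#' @param load_modes Load angles to run.
#' @param F_A_mN Reference force, mN.
#' @param F_B_unscaled_mN Target force in unscaled mode, mN.
#' @param materials Materials per region (see [fe_model()]).
#' @param order Element order.
#' @param buckling Also compute buckling load factors.
#' @return A `scaling_comparison`: forces, areas, volumes, per-angle
#'   summaries for both models, percentage differences, and a tidy `table`.
#' @export
run_comparison <- function(specimen_A, specimen_B,
                           mode = c("scaled", "unscaled"),
                           load_modes = c("horizontal", "parallel"),
                           F_A_mN = 200, F_B_unscaled_mN = 125,
                           materials = bill_materials(), order = 2L,
                           buckling = TRUE) {
  mode <- match.arg(mode)
  if (is.null(specimen_A$volume_mesh) || is.null(specimen_B$volume_mesh))
    stop("both specimens need volume meshes")
  SA_A <- tet_boundary_area(specimen_A$volume_mesh)
  SA_B <- tet_boundary_area(specimen_B$volume_mesh)
  V_A <- sum(tet_volumes(specimen_A$volume_mesh))
  V_B <- sum(tet_volumes(specimen_B$volume_mesh))
  F_B <- if (mode == "scaled") scale_force(F_A_mN, SA_A, SA_B)
         else F_B_unscaled_mN
  model_A <- fe_model(specimen_A$volume_mesh, materials, order)
  model_B <- fe_model(specimen_B$volume_mesh, materials, order)
  summaries <- list(); pct <- list(); rows <- list()
  for (lm in load_modes) {
    sA <- performance_summary(model_A, specimen_A, lm, F_A_mN, buckling)
    sB <- performance_summary(model_B, specimen_B, lm, F_B, buckling)
    if (mode == "scaled") {
      sB$strain_energy_raw <- sB$strain_energy
      sB$strain_energy <- adjust_strain_energy(sB$strain_energy,
                                               F_A_mN, F_B, V_A, V_B)
    }
    metrics <- c("peak_vm_98", "mwam_vm", "strain_energy",
                 "buckling_load_factor")
    pd <- compare_performance(sA[metrics], sB[metrics])
    summaries[[lm]] <- list(A = sA, B = sB)
    pct[[lm]] <- pd
    rows[[lm]] <- data.frame(metric = metrics,
                             value_A = unlist(sA[metrics]),
                             value_B = unlist(sB[metrics]),
                             pct_difference = pd,
                             load_mode = lm, scaling_mode = mode,
                             row.names = NULL)
  }
  structure(list(reference_id = specimen_A$id, target_id = specimen_B$id,
                 mode = mode, F_A = F_A_mN, F_B = F_B,
                 SA_A = SA_A, SA_B = SA_B, V_A = V_A, V_B = V_B,
                 summaries = summaries, pct_differences = pct,
                 table = do.call(rbind, rows)),
            class = "scaling_comparison")
}

#' @export
print.scaling_comparison <- function(x, ...) {
  cat(sprintf("Comparative FE (%s): %s (ref, %g mN) vs %s (%.0f mN)\n",
              x$mode, x$reference_id, x$F_A, x$target_id, round(x$F_B)))
  cat(sprintf("  SA: %.3f / %.3f mm^2;  V: %.3f / %.3f mm^3\n",
              x$SA_A, x$SA_B, x$V_A, x$V_B))
  print(x$table, digits = 4)
  invisible(x)
}
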