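#' Parametric description of a maxillary bill
#'
#' Holds the geometric parameters of the synthetic bill family: the culmen is a
#' planar circular arc of length `arc_length` with curvature given by the
#' arc:chord ratio, and a tapering, bilaterally symmetric cross-section
#' (dorsal half-ellipse over a shallow ventral face) is swept along it. A thin
#' keratin shell (rhamphotheca) of constant thickness wraps a bone core.
#'
#' @param arc_length Culmen arc length from tip to the proximal end of the
#'   exposed culmen, mm.
#' @param arc_chord_ratio Arc length divided by chord length; 1 is a straight
#'   bill, larger is curvier. Must be >= 1.
#' @param base_height Cross-section height at the bill base, mm.
#' @param base_width Cross-section width at the bill base, mm.
#' @param taper_exponent Exponent p of the taper law `(s/L)^p` controlling how
#'   fast the cross-section shrinks toward the tip; larger p gives a sharper,
#'   more needle-like tip. Must be > 0.
#' @param shell_thickness Rhamphotheca shell thickness, mm. Must be smaller
#'   than half the smaller base dimension.
#' @param tip_truncation Length of bill removed at the apex so the mesh has no
#'   singular point, mm (>= 0).
#' @return An object of class `bill_params` (a named list).
#' @export
bill_params <- function(arc_length = 40, arc_chord_ratio = 1.07,
                        base_height = 3, base_width = 4,
                        taper_exponent = 1.1, shell_thickness = 0.15,
                        tip_truncation = 0.05) {
  p <- structure(list(
    arc_length = arc_length, arc_chord_ratio = arc_chord_ratio,
    base_height = base_height, base_width = base_width,
    taper_exponent = taper_exponent, shell_thickness = shell_thickness,
    tip_truncation = tip_truncation
  ), class = "bill_params")
  validate_bill_params(p)
  p
}

#' Validate bill parameters
#'
#' @param p A `bill_params` object or named list with the same fields.
#' @return `p` invisibly; errors if any invariant is violated.
#' @export
validate_bill_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("arc_length", "arc_chord_ratio", "base_height", "base_width",
              "taper_exponent", "shell_thickness", "tip_truncation")) {
    if (!num1(p[[f]])) stop("bill_params field '", f, "' must be a finite number")
  }
  if (p$arc_length <= 0) stop("arc_length must be > 0")
  if (p$arc_chord_ratio < 1) stop("arc_chord_ratio must be >= 1 (no real arc)")
  if (p$base_height <= 0 || p$base_width <= 0) stop("base dimensions must be > 0")
  if (p$taper_exponent <= 0) stop("taper_exponent must be > 0")
  if (p$shell_thickness <= 0) stop("shell_thickness must be > 0")
  if (p$shell_thickness >= min(p$base_height, p$base_width) / 2)
    stop("shell_thickness must be < min(base_height, base_width)/2")
  if (p$tip_truncation < 0) stop("tip_truncation must be >= 0")
  if (p$tip_truncation >= p$arc_length / 4)
    stop("tip_truncation too large relative to arc_length")
  invisible(p)
}

#' @export
print.bill_params <- function(x, ...) {
  cat("Parametric bill:",
      sprintf("arc %g mm, arc:chord %g, base %g x %g mm,", x$arc_length,
              x$arc_chord_ratio, x$base_width, x$base_height),
      sprintf("taper %g, shell %g mm, tip truncation %g mm\n",
              x$taper_exponent, x$shell_thickness, x$tip_truncation))
  invisible(x)
}

#' Default female / male group-mean bill parameters
#'
#' Group means for the dimorphic synthetic population: males straighter
#' (lower arc:chord), longer, with sharper tips (higher taper exponent) and
#' slightly larger cross-sections, mirroring the direction of dimorphism in
#' large lekking hermit hummingbirds. Magnitudes are plausible for a ~40 mm
#' hermit bill; cross-sectional dimensions and shell thickness are
#' non-biological calibrations (no published data for the species).
#'
#' @return A `bill_params` object.
#' @export
female_bill_params <- function() {
  bill_params(arc_length = 39, arc_chord_ratio = 1.100, base_height = 3.0,
              base_width = 4.0, taper_exponent = 0.50, shell_thickness = 0.15,
              tip_truncation = 0.05)
}

#' @rdname female_bill_params
#' @export
male_bill_params <- function() {
  bill_params(arc_length = 42, arc_chord_ratio = 1.035, base_height = 3.4,
              base_width = 4.5, taper_exponent = 0.65, shell_thickness = 0.15,
              tip_truncation = 0.05)
}

#' Specification of a two-sex synthetic population
#'
#' @param n_per_group Specimens per sex (>= 2).
#' @param female_mean,male_mean Group-mean `bill_params`.
#' @param noise_sd Named numeric vector of per-parameter Gaussian standard
#'   deviations (missing entries default to 0). Names as in `bill_params`.
#' @param landmark_jitter_sd Isotropic Gaussian noise added to contour points
#'   after generation, mm.
#' @param seed Integer RNG seed for the population.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_per_group = 8,
                            female_mean = female_bill_params(),
                            male_mean = male_bill_params(),
                            noise_sd = default_noise_sd(),
                            landmark_jitter_sd = 0.02,
                            seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (any(noise_sd < 0)) stop("noise_sd must be >= 0 elementwise")
  if (landmark_jitter_sd < 0) stop("landmark_jitter_sd must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group),
                 female_mean = female_mean, male_mean = male_mean,
                 noise_sd = noise_sd,
                 landmark_jitter_sd = landmark_jitter_sd,
                 seed = as.integer(seed)),
            class = "population_spec")
}

#' Default per-parameter noise standard deviations
#'
#' Individual variation within a sex, roughly 2% coefficients of variation;
#' shell thickness and tip truncation are held fixed across individuals.
#'
#' @return Named numeric vector.
#' @export
default_noise_sd <- function() {
  c(arc_length = 0.8, arc_chord_ratio = 0.012, base_height = 0.08,
    base_width = 0.08, taper_exponent = 0.03, shell_thickness = 0,
    tip_truncation = 0)
}

# Deterministic per-specimen substream: derived from the population seed by a
# counter so that adding specimens does not perturb earlier draws.
specimen_seed <- function(seed, counter) {
  as.integer((as.numeric(seed) * 2654435L + 7919 * counter) %% 2147483647)
}

#' Draw one set of bill parameters around a group mean
#'
#' Gaussian perturbation of each parameter with truncation to validity:
#' invalid draws are rejected and redrawn, up to `max_retry` times.
#'
#' @param mean_params Group-mean `bill_params`.
#' @param noise_sd Named sd vector (see [population_spec()]).
#' @param max_retry Redraw cap for invalid parameter sets.
#' @return A valid `bill_params` draw.
#' @export
sample_bill_params <- function(mean_params, noise_sd = default_noise_sd(),
                               max_retry = 100L) {
  fields <- names(unclass(mean_params))
  sd_of <- function(f) if (f %in% names(noise_sd)) noise_sd[[f]] else 0
  for (try in seq_len(max_retry)) {
    draw <- mean_params
    for (f in fields) draw[[f]] <- mean_params[[f]] + stats::rnorm(1, 0, sd_of(f))
    ok <- tryCatch({ validate_bill_params(draw); TRUE },
                   error = function(e) FALSE)
    if (ok) return(draw)
  }
  stop("could not draw valid bill parameters in ", max_retry, " attempts")
}

#' Generate a synthetic two-sex bill population
#'
#' Draws per-specimen parameters around each sex's group mean (deterministic
#' given `spec$seed`; per-specimen substreams are derived by counter), builds
#' each specimen's surface mesh and labeled contour curves, and applies
#' isotropic landmark jitter to the contours. Ground-truth parameters are
#' stored with every specimen.
#'
#' @param spec A [population_spec()].
#' @param make_surface If `FALSE`, skip the triangulated surface and generate
#'   contours only (fast path for statistical calibration studies).
#' @param n_s,n_phi Surface mesh resolution passed to [generate_surface()].
#' @param n_contour Points per analytic contour curve.
#' @return List of `bill_specimen` objects (female specimens first).
#' @export
sample_population <- function(spec, make_surface = TRUE,
                              n_s = 120L, n_phi = 32L, n_contour = 120L) {
  stopifnot(inherits(spec, "population_spec"))
  out <- vector("list", 2L * spec$n_per_group)
  groups <- list(F = spec$female_mean, M = spec$male_mean)
  idx <- 0L
  for (sex in c("F", "M")) {
    for (j in seq_len(spec$n_per_group)) {
      idx <- idx + 1L
      counter <- if (sex == "F") j else 10000L + j
      set.seed(specimen_seed(spec$seed, counter))
      params <- sample_bill_params(groups[[sex]], spec$noise_sd)
      sp <- if (make_surface) {
        generate_surface(params, n_s = n_s, n_phi = n_phi,
                         n_contour = n_contour)
      } else {
        contour_only_specimen(params, n_contour = n_contour)
      }
      sp$id <- sprintf("%s%02d", sex, j)
      sp$sex <- sex
      sp$truth <- params
      if (spec$landmark_jitter_sd > 0)
        sp$contours <- jitter_contours(sp$contours, spec$landmark_jitter_sd)
      out[[idx]] <- sp
    }
  }
  names(out) <- vapply(out, function(s) s$id, "")
  out
}

# Shared-tip-preserving isotropic jitter: the tip point receives one common
# draw across the three curves so the shared-endpoint invariant survives.
jitter_contours <- function(contours, sd) {
  tip_jit <- stats::rnorm(3, 0, sd)
  for (nm in names(contours)) {
    pts <- contours[[nm]]
    jit <- matrix(stats::rnorm(length(pts), 0, sd), ncol = 3)
    jit[1, ] <- tip_jit
    contours[[nm]] <- pts + jit
  }
  contours
}
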