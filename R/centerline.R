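#' Subtended angle of a circular arc from its arc:chord ratio
#'
#' For a circular arc subtending angle `theta`, arc:chord = theta / (2
#' sin(theta/2)), which increases monotonically on (0, 2*pi). The inverse is
#' found by root bracketing; a ratio of 1 maps to the straight-line limit
#' theta = 0.
#'
#' @param ratio Arc:chord ratio (>= 1).
#' @return Subtended angle in radians.
#' @export
arc_angle_from_ratio <- function(ratio) {
  if (ratio < 1) stop("arc_chord_ratio must be >= 1 (no real arc)")
  if (ratio < 1 + 1e-12) return(0)
  f <- function(th) th / (2 * sin(th / 2)) - ratio
  stats::uniroot(f, c(1e-9, 2 * pi - 1e-9), tol = 1e-14)$root
}

# Closed-form evaluation of the culmen arc at arc-length positions s.
# The arc lies in the sagittal (x-z) plane, chord along +x, tip at the
# origin, bulging dorsally (+z). Returns points, unit tangents (pointing
# proximally, i.e. tip -> base) and in-plane unit normals (dorsal).
centerline_eval <- function(params, s) {
  L <- params$arc_length
  theta <- arc_angle_from_ratio(params$arc_chord_ratio)
  n <- length(s)
  if (theta == 0) {
    pts <- cbind(s, 0, 0)
    tan <- matrix(rep(c(1, 0, 0), each = n), ncol = 3)
    nor <- matrix(rep(c(0, 0, 1), each = n), ncol = 3)
  } else {
    R <- L / theta
    chord <- 2 * R * sin(theta / 2)
    phi <- -theta / 2 + theta * s / L
    pts <- cbind(chord / 2 + R * sin(phi), 0, R * cos(phi) - R * cos(theta / 2))
    tan <- cbind(cos(phi), 0, -sin(phi))
    nor <- cbind(sin(phi), 0, cos(phi))
  }
  colnames(pts) <- colnames(tan) <- colnames(nor) <- c("x", "y", "z")
  list(points = pts, tangent = tan, normal = nor, theta = theta)
}

#' Generate the culmen centerline of a parametric bill
#'
#' The centerline is the planar circular arc (the unique planar curve with a
#' prescribed arc:chord ratio) realizing `params$arc_length` and
#' `params$arc_chord_ratio`, laid in the sagittal x-z plane with the chord on
#' the x-axis and the tip at the origin.
#'
#' @param params A [bill_params()] object.
#' @param n Number of points (equally spaced in arc length).
#' @return An `n x 3` matrix of points, mm.
#' @export
generate_centerline <- function(params, n = 200L) {
  validate_bill_params(params)
  s <- seq(0, params$arc_length, length.out = n)
  centerline_eval(params, s)$points
}

# Taper scale factor at arc positions s: cross-section dimensions shrink
# toward the tip as (s/L)^p.
taper_scale <- function(params, s) {
  (s / params$arc_length)^params$taper_exponent
}

# Cross-section boundary radius about the section's star center, as a
# function of the polar angle phi in the local (lateral y, dorsal n) plane.
# Dorsal half-ellipse (semi-axes width/2, dorsal_frac*height) over a shallow
# ventral half-ellipse; the slope break at phi = 0, pi gives well-defined
# tomial edges, the dorsal apex at phi = pi/2 is the culmen.
section_radius <- function(phi, width, height, dorsal_frac = 0.82) {
  a <- width / 2
  b <- ifelse(sin(phi) >= 0, dorsal_frac * height, (1 - dorsal_frac) * height)
  a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
}

# Local in-section coordinates (lateral, dorsal) of the boundary at angle phi,
# expressed relative to the culmen point (the sweep follows the culmen, so the
# dorsal apex sits on the centerline). For a full equi-angular grid the
# coordinates are symmetrized exactly (phi <-> pi - phi), so bilateral mirror
# symmetry of generated meshes holds to the last bit, not just to rounding.
section_local_coords <- function(phi, width, height, dorsal_frac = 0.82) {
  r <- section_radius(phi, width, height, dorsal_frac)
  out <- cbind(lat = r * cos(phi), dor = r * sin(phi) - dorsal_frac * height)
  n <- length(phi)
  if (n %% 4L == 0L && max(abs(phi - 2 * pi * (seq_len(n) - 1L) / n)) < 1e-12) {
    j <- seq_len(n)
    jm <- ((n / 2L - (j - 1L)) %% n) + 1L       # index of pi - phi_j
    right <- which(out[, "lat"] > 0)            # canonical half
    out[jm[right], "lat"] <- -out[right, "lat"]
    out[jm[right], "dor"] <- out[right, "dor"]
    out[abs(out[, "lat"]) < 1e-12 * width, "lat"] <- 0
  }
  out
}
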