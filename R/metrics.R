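#' Arc length, chord length and arc:chord curvature of a contour
#'
#' Arc is the cumulative polyline length from tip to the proximal end; chord
#' is the straight distance between the endpoints; their ratio is the
#' standard arc:chord curvature measure (1 = straight, larger = curvier).
#'
#' @param curve `n x 3` matrix of ordered culmen points, tip-first.
#' @return List with `arc_length`, `chord_length`, `arc_chord_ratio`.
#' @export
arc_chord <- function(curve) {
  if (nrow(curve) < 2L) stop("curve needs at least 2 points")
  arc <- sum(sqrt(rowSums(diff(curve)^2)))
  chord <- sqrt(sum((curve[nrow(curve), ] - curve[1, ])^2))
  if (chord < 1e-12) stop("zero chord length")
  list(arc_length = arc, chord_length = chord, arc_chord_ratio = arc / chord)
}

#' Outer surface area of the maxilla
#'
#' Sum of triangle areas over the outer (lateral) selection of the surface
#' mesh, tip to the proximal end of the exposed culmen — the morphometric
#' selection, distinct from the closed-model boundary area used in force
#' scaling.
#'
#' @param specimen A `bill_specimen` with a surface mesh, or a `tri_mesh`.
#' @param faces Optional explicit face selection (indices); by default the
#'   faces labeled `"lateral"` when labels exist, else all faces.
#' @return Area, mm^2.
#' @export
outer_surface_area <- function(specimen, faces = NULL) {
  mesh <- if (inherits(specimen, "bill_specimen")) specimen$surface_mesh
          else specimen
  if (is.null(mesh)) stop("specimen has no surface mesh")
  if (is.null(faces)) {
    faces <- if (!is.null(mesh$face_label)) which(mesh$face_label == "lateral")
             else seq_len(nrow(mesh$faces))
  }
  if (length(faces) == 0L) stop("empty face selection")
  surface_area(mesh, faces)
}

#' Surface-area sharpness ratio of the bill tip
#'
#' The outer surface area of the distal-most millimeter of the bill (A1) is
#' divided by that of the second-most distal millimeter (A2) and subtracted
#' from 1; larger values indicate sharper bills. Distal millimeters are
#' measured as slabs along the aligned longitudinal axis from the stored tip
#' point; triangles straddling the slab planes are clipped exactly.
#'
#' @param specimen A `bill_specimen` (aligned frame assumed) or a `tri_mesh`.
#' @param tip Tip point (defaults to the specimen's stored tip point).
#' @param axis Unit longitudinal direction pointing proximally (default +x).
#' @param faces Optional face selection, as in [outer_surface_area()].
#' @return List with `area_distal_mm` (A1), `area_second_mm` (A2),
#'   `sharpness_ratio`.
#' @export
sharpness_ratio <- function(specimen, tip = NULL, axis = c(1, 0, 0),
                            faces = NULL) {
  mesh <- if (inherits(specimen, "bill_specimen")) specimen$surface_mesh
          else specimen
  if (is.null(mesh)) stop("specimen has no surface mesh")
  if (is.null(tip)) {
    tip <- if (inherits(specimen, "bill_specimen")) specimen$tip_point
           else stop("tip point required for a bare mesh")
  }
  if (is.null(faces)) {
    faces <- if (!is.null(mesh$face_label)) which(mesh$face_label == "lateral")
             else seq_len(nrow(mesh$faces))
  }
  axis <- axis / sqrt(sum(axis^2))
  v <- sweep(mesh$vertices, 2, tip)
  xcoord <- as.vector(v %*% axis)
  f <- mesh$faces[faces, , drop = FALSE]
  a1 <- clipped_area(v, f, xcoord, 0, 1)
  a2 <- clipped_area(v, f, xcoord, 1, 2)
  if (a2 <= 0) stop("no surface in the second distal millimeter (A2 = 0)")
  list(area_distal_mm = a1, area_second_mm = a2,
       sharpness_ratio = 1 - a1 / a2)
}

# Exact area of the triangle set clipped to the slab x0 <= x < x1 of the
# scalar field `xcoord` (per-vertex). Triangles are split at the slab planes
# (Sutherland-Hodgman in the scalar coordinate); planar polygon areas are
# accumulated by fanning.
clipped_area <- function(verts, faces, xcoord, x0, x1) {
  fx <- matrix(xcoord[faces], nrow(faces), 3)
  fmin <- pmin(fx[, 1], fx[, 2], fx[, 3])
  fmax <- pmax(fx[, 1], fx[, 2], fx[, 3])
  inside <- fmin >= x0 & fmax <= x1
  cand <- which(!inside & fmin < x1 & fmax > x0)
  area <- if (any(inside)) {
    surface_area(list(vertices = verts, faces = faces[inside, , drop = FALSE]))
  } else 0
  for (t in cand) {
    poly <- verts[faces[t, ], , drop = FALSE]
    px <- fx[t, ]
    clip <- clip_polygon_halfspace(poly, px, x0, keep_above = TRUE)
    clip <- clip_polygon_halfspace(clip$poly, clip$x, x1, keep_above = FALSE)
    area <- area + polygon_area(clip$poly)
  }
  area
}

clip_polygon_halfspace <- function(poly, x, threshold, keep_above) {
  n <- nrow(poly)
  if (n == 0L) return(list(poly = poly, x = x))
  keep <- if (keep_above) x >= threshold else x <= threshold
  outp <- list(); outx <- numeric(0)
  for (i in seq_len(n)) {
    j <- i %% n + 1L
    if (keep[i]) { outp[[length(outp) + 1L]] <- poly[i, ]; outx <- c(outx, x[i]) }
    if (keep[i] != keep[j]) {
      tpar <- (threshold - x[i]) / (x[j] - x[i])
      outp[[length(outp) + 1L]] <- poly[i, ] + tpar * (poly[j, ] - poly[i, ])
      outx <- c(outx, threshold)
    }
  }
  list(poly = do.call(rbind, outp), x = outx)
}

polygon_area <- function(poly) {
  if (is.null(poly) || nrow(poly) < 3L) return(0)
  a <- 0
  for (i in 2:(nrow(poly) - 1L)) {
    e1 <- poly[i, ] - poly[1, ]
    e2 <- poly[i + 1L, ] - poly[1, ]
    cr <- c(e1[2] * e2[3] - e1[3] * e2[2],
            e1[3] * e2[1] - e1[1] * e2[3],
            e1[1] * e2[2] - e1[2] * e2[1])
    a <- a + sqrt(sum(cr^2)) / 2
  }
  a
}

#' Included angle of the bill tip in dorsal view
#'
#' The mesh silhouette is projected on the dorsal (x-y) plane; the silhouette
#' half-width at `at` mm from the tip forms an isoceles triangle whose apex
#' angle, `2 atan(half_width / at)`, is reported in degrees. Lower angles
#' indicate sharper bills.
#'
#' @param specimen A `bill_specimen` (aligned frame) or a `tri_mesh`.
#' @param tip Tip point (defaults to the stored tip point).
#' @param at Distance of the triangle base from the tip, mm (default 0.5).
#' @return Angle in degrees.
#' @export
included_angle <- function(specimen, tip = NULL, at = 0.5) {
  mesh <- if (inherits(specimen, "bill_specimen")) specimen$surface_mesh
          else specimen
  if (is.null(mesh)) stop("specimen has no surface mesh")
  if (is.null(tip)) {
    tip <- if (inherits(specimen, "bill_specimen")) specimen$tip_point
           else stop("tip point required for a bare mesh")
  }
  v <- sweep(mesh$vertices, 2, tip)
  f <- mesh$faces
  x <- v[, 1]
  # all mesh edges crossing the plane x = at
  ea <- c(f[, 1], f[, 2], f[, 3]); eb <- c(f[, 2], f[, 3], f[, 1])
  cross <- (x[ea] - at) * (x[eb] - at) < 0
  hw <- 0
  if (any(cross)) {
    i <- ea[cross]; j <- eb[cross]
    tpar <- (at - x[i]) / (x[j] - x[i])
    y <- v[i, 2] + tpar * (v[j, 2] - v[i, 2])
    hw <- max(abs(y))
  }
  on_plane <- abs(x - at) < 1e-12
  if (any(on_plane)) hw <- max(hw, max(abs(v[on_plane, 2])))
  if (hw <= 0) {
    warning("zero silhouette width at ", at, " mm: degenerate tip")
    return(0)
  }
  2 * atan(hw / at) * 180 / pi
}

#' All univariate bill descriptors of a specimen
#'
#' Computes arc length, chord, arc:chord curvature (from the culmen contour
#' resampled to `n_culmen` points), outer surface area, the two distal-
#' millimeter areas with the sharpness ratio, included angle, and centroid
#' size of the landmark configuration. The specimen is aligned to the
#' measurement frame first.
#'
#' @param specimen A `bill_specimen` with surface mesh and contours.
#' @param n_culmen Culmen resampling count for the curvature measures.
#' @param realign Re-align the specimen via [align_to_axis()] first.
#' @return One-row `data.frame` of metrics.
#' @export
bill_metrics <- function(specimen, n_culmen = 60L, realign = TRUE) {
  if (realign) specimen <- align_to_axis(specimen)
  culmen <- resample_curve(specimen$contours$culmen, n_culmen)
  ac <- arc_chord(culmen)
  out <- data.frame(id = specimen$id %||% NA_character_,
                    sex = specimen$sex %||% NA_character_,
                    arc_length = ac$arc_length, chord_length = ac$chord_length,
                    arc_chord_ratio = ac$arc_chord_ratio,
                    stringsAsFactors = FALSE)
  if (!is.null(specimen$surface_mesh)) {
    sr <- sharpness_ratio(specimen)
    out$outer_surface_area <- outer_surface_area(specimen)
    out$area_distal_mm <- sr$area_distal_mm
    out$area_second_mm <- sr$area_second_mm
    out$sharpness_ratio <- sr$sharpness_ratio
    out$included_angle <- included_angle(specimen)
  }
  cfg <- specimen_configuration(specimen, n = n_culmen)
  out$centroid_size <- centroid_size(cfg)
  out
}

#' Metrics table for a list of specimens
#'
#' @param specimens List of `bill_specimen` objects.
#' @param ... Passed to [bill_metrics()].
#' @return `data.frame`, one row per specimen.
#' @export
metrics_table <- function(specimens, ...) {
  do.call(rbind, lapply(specimens, bill_metrics, ...))
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a
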