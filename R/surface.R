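#' Generate a synthetic bill surface with labeled contours
#'
#' Sweeps the tapering bilaterally symmetric cross-section along the culmen
#' arc and triangulates it into a closed (watertight) surface. The apex is
#' truncated at `params$tip_truncation` and both ends are capped. The three
#' contour polylines (culmen, left and right tomium) are evaluated
#' analytically on the parametric surface, tip-first, all sharing the bill-tip
#' point exactly.
#'
#' @param params A [bill_params()] object.
#' @param n_s Number of sweep stations along the arc (graded toward the tip).
#' @param n_phi Number of angular samples around the cross-section; must be a
#'   multiple of 4 so the culmen and both tomia lie on mesh vertices.
#' @param n_contour Points per contour polyline.
#' @param grade Grading exponent for the sweep stations (>1 refines the tip).
#' @param dorsal_frac Fraction of the section height above the tomial plane.
#' @return A `bill_specimen` with fields `surface_mesh` (vertices, faces,
#'   face_label in lateral/tip_cap/base_cap), `contours`, `tip_point`,
#'   `tip_tangent`, `base_point`, `base_normal`.
#' @export
generate_surface <- function(params, n_s = 120L, n_phi = 32L,
                             n_contour = 120L, grade = 1.4,
                             dorsal_frac = 0.82) {
  validate_bill_params(params)
  if (n_phi %% 4L != 0L) stop("n_phi must be a multiple of 4")
  if (n_s < 3L) stop("n_s must be >= 3")
  L <- params$arc_length
  # sweep stations: the first at a small standoff, the exact apex closed by a
  # triangle fan (the conical apex is only singular for volume meshing, so
  # the surface keeps it and all tip metrics are truncation-independent)
  s1 <- max(params$tip_truncation, 1e-4 * L)
  sgrid <- s1 + (L - s1) * seq(0, 1, length.out = n_s)^grade
  ce <- centerline_eval(params, sgrid)
  apex <- centerline_eval(params, 0)
  g <- taper_scale(params, sgrid)
  if (any(g <= 0)) stop("degenerate cross-section: non-positive taper scale")
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  loc <- section_local_coords(phi, params$base_width, params$base_height,
                              dorsal_frac)
  # vertex grid: v(i, j) = (i-1)*n_phi + j, row-major over sweep stations
  A <- g %o% loc[, "dor"]                      # dorsal offsets (n_s x n_phi)
  Vx <- matrix(ce$points[, 1], n_s, n_phi) + A * ce$normal[, 1]
  Vy <- g %o% loc[, "lat"]
  Vz <- matrix(ce$points[, 3], n_s, n_phi) + A * ce$normal[, 3]
  verts <- cbind(as.vector(t(Vx)), as.vector(t(Vy)), as.vector(t(Vz)))
  bd <- dorsal_frac * params$base_height
  base_center <- ce$points[n_s, ] - bd * g[n_s] * ce$normal[n_s, ]
  verts <- rbind(verts, apex$points[1, ], base_center)
  id_apex <- n_s * n_phi + 1L
  id_basec <- n_s * n_phi + 2L

  vid <- function(i, j) (i - 1L) * n_phi + j
  i <- rep(seq_len(n_s - 1L), each = n_phi)
  j <- rep(seq_len(n_phi), times = n_s - 1L)
  jp <- j %% n_phi + 1L
  a <- vid(i, j); b <- vid(i + 1L, j); cc <- vid(i + 1L, jp); d <- vid(i, jp)
  lateral <- rbind(cbind(a, cc, b), cbind(a, d, cc))
  jj <- seq_len(n_phi); jjp <- jj %% n_phi + 1L
  apex_fan <- cbind(id_apex, vid(1L, jjp), vid(1L, jj))
  base_cap <- cbind(id_basec, vid(n_s, jj), vid(n_s, jjp))
  faces <- rbind(lateral, apex_fan, base_cap)
  label <- c(rep("lateral", nrow(lateral) + n_phi), rep("base_cap", n_phi))
  mesh <- structure(list(vertices = verts, faces = faces, face_label = label),
                    class = "tri_mesh")
  if (mesh_signed_volume(mesh) < 0) {  # enforce outward orientation
    mesh$faces <- mesh$faces[, c(1L, 3L, 2L)]
  }

  contours <- analytic_contours(params, n_contour, grade, dorsal_frac)
  structure(list(id = NA_character_, sex = NA_character_,
                 surface_mesh = mesh, contours = contours,
                 volume_mesh = NULL, truth = NULL,
                 tip_point = apex$points[1, ],
                 tip_tangent = apex$tangent[1, ],
                 base_point = ce$points[n_s, ],
                 base_normal = ce$tangent[n_s, ]),
            class = "bill_specimen")
}

# Analytic contour curves on the parametric surface, tip-first. All three
# curves start at the exact apex (s = 0), where the cross-section collapses
# to a point, so the shared-tip invariant holds by construction.
analytic_contours <- function(params, n_contour, grade = 1.4,
                              dorsal_frac = 0.82) {
  L <- params$arc_length
  s <- L * seq(0, 1, length.out = n_contour)^grade
  ce <- centerline_eval(params, s)
  g <- taper_scale(params, s)
  a <- params$base_width / 2
  bd <- dorsal_frac * params$base_height
  offset_curve <- function(sign_y) {
    ce$points + cbind(0, sign_y * a * g, 0) - (bd * g) * ce$normal
  }
  list(culmen = ce$points,
       left_tomium = offset_curve(+1),
       right_tomium = offset_curve(-1))
}

#' Contour-only synthetic specimen (no surface mesh)
#'
#' Fast path used by statistical calibration studies that only need landmark
#' curves, not triangulated geometry.
#'
#' @param params A [bill_params()] object.
#' @param n_contour Points per contour.
#' @return A `bill_specimen` with `surface_mesh = NULL`.
#' @export
contour_only_specimen <- function(params, n_contour = 120L) {
  validate_bill_params(params)
  L <- params$arc_length
  ce <- centerline_eval(params, c(0, L))
  structure(list(id = NA_character_, sex = NA_character_, surface_mesh = NULL,
                 contours = analytic_contours(params, n_contour),
                 volume_mesh = NULL, truth = NULL,
                 tip_point = ce$points[1, ], tip_tangent = ce$tangent[1, ],
                 base_point = ce$points[2, ], base_normal = ce$tangent[2, ]),
            class = "bill_specimen")
}

#' @export
print.bill_specimen <- function(x, ...) {
  cat("Bill specimen", x$id, "sex:", x$sex, "\n")
  if (!is.null(x$surface_mesh))
    cat("  surface:", nrow(x$surface_mesh$vertices), "vertices,",
        nrow(x$surface_mesh$faces), "faces\n")
  if (!is.null(x$volume_mesh))
    cat("  volume:", nrow(x$volume_mesh$nodes), "nodes,",
        nrow(x$volume_mesh$elems), "tets\n")
  invisible(x)
}

#' Total area of (a subset of) a triangle mesh
#'
#' @param mesh A `tri_mesh`.
#' @param faces Optional integer vector of face indices; default all faces.
#' @return Area in mm^2.
#' @export
surface_area <- function(mesh, faces = NULL) {
  f <- if (is.null(faces)) mesh$faces else mesh$faces[faces, , drop = FALSE]
  if (nrow(f) == 0L) stop("empty face selection")
  v <- mesh$vertices
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2]
  cy <- e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3]
  cz <- e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  sum(sqrt(cx^2 + cy^2 + cz^2)) / 2
}

#' Signed volume enclosed by a closed triangle mesh
#'
#' Positive when faces are consistently oriented outward.
#'
#' @param mesh A `tri_mesh`.
#' @return Volume in mm^3.
#' @export
mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

#' Watertightness check for a triangle mesh
#'
#' A closed, consistently oriented 2-manifold has every undirected edge shared
#' by exactly two faces and every directed edge used exactly once.
#'
#' @param mesh A `tri_mesh`.
#' @return Logical.
#' @export
is_watertight <- function(mesh) {
  f <- mesh$faces
  from <- c(f[, 1], f[, 2], f[, 3])
  to <- c(f[, 2], f[, 3], f[, 1])
  n <- nrow(mesh$vertices)
  directed <- (from - 1) * n + to
  if (anyDuplicated(directed) > 0L) return(FALSE)
  undirected <- (pmin(from, to) - 1) * n + pmax(from, to)
  all(table(undirected) == 2L)
}

#' Apply a rigid (or similarity) transform to a specimen
#'
#' @param specimen A `bill_specimen`.
#' @param rotation 3x3 rotation matrix (applied as `x %*% t(R)`).
#' @param translation Length-3 shift, applied after rotation and scaling.
#' @param scale Scalar scale factor.
#' @return The transformed specimen.
#' @export
transform_specimen <- function(specimen, rotation = diag(3),
                               translation = c(0, 0, 0), scale = 1) {
  tf_pts <- function(p) sweep(scale * (p %*% t(rotation)), 2, translation, "+")
  tf_vec <- function(v) as.vector(rotation %*% v)
  if (!is.null(specimen$surface_mesh))
    specimen$surface_mesh$vertices <- tf_pts(specimen$surface_mesh$vertices)
  if (!is.null(specimen$volume_mesh))
    specimen$volume_mesh$nodes <- tf_pts(specimen$volume_mesh$nodes)
  specimen$contours <- lapply(specimen$contours, tf_pts)
  specimen$tip_point <- as.vector(tf_pts(matrix(specimen$tip_point, 1)))
  specimen$base_point <- as.vector(tf_pts(matrix(specimen$base_point, 1)))
  specimen$tip_tangent <- tf_vec(specimen$tip_tangent)
  specimen$base_normal <- tf_vec(specimen$base_normal)
  specimen
}
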