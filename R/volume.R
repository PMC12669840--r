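#' Tetrahedral two-region volume mesh of a synthetic bill
#'
#' Builds a structured tetrahedral mesh of the parametric bill solid directly
#' from its stored ground-truth parameters: a polar cross-section template
#' (center fan plus radial rings) is swept along the culmen arc, prisms are
#' split into tetrahedra with a globally consistent (min-vertex-index)
#' diagonal rule, and elements are labeled `shell` (rhamphotheca) or `core`
#' (bone). The shell/core interface is conforming: interface nodes are shared
#' by both regions, realizing bonded contact. Shell thickness is measured
#' radially in the cross-section plane; near the tip, where the section is
#' thinner than the shell, the core is kept at a minimum radial fraction of
#' the section so every element retains positive volume (there the "core"
#' label persists as a thin kernel rather than vanishing).
#'
#' @param specimen A synthetic `bill_specimen` carrying `truth` parameters.
#' @param shell_thickness Shell thickness, mm; defaults to the specimen's
#'   ground-truth value.
#' @param n_s Sweep stations (graded toward the tip).
#' @param n_phi Angular samples (multiple of 4).
#' @param n_core,n_shell Radial element layers in core and shell.
#' @param grade Sweep grading exponent.
#' @param min_core_frac Minimum core radius as a fraction of the local
#'   section radius.
#' @param dorsal_frac Fraction of section height above the tomial plane.
#' @return The specimen with `volume_mesh` set: a `tet_mesh` list with
#'   `nodes` (n x 3, mm), `elems` (m x 4, 1-based), `region` (integer,
#'   1 = shell, 2 = core).
#' @export
generate_volume <- function(specimen, shell_thickness = NULL,
                            n_s = 20L, n_phi = 12L, n_core = 2L, n_shell = 1L,
                            grade = 2.6, min_core_frac = 0.25,
                            dorsal_frac = 0.82) {
  if (is.null(specimen$truth))
    stop("volume meshing requires a synthetic specimen with stored truth parameters")
  params <- specimen$truth
  t <- if (is.null(shell_thickness)) params$shell_thickness else shell_thickness
  if (t <= 0) stop("shell_thickness must be > 0")
  if (t >= min(params$base_height, params$base_width) / 2)
    stop("shell thicker than local half-thickness at the base")
  if (n_phi %% 4L != 0L) stop("n_phi must be a multiple of 4")

  L <- params$arc_length
  t0 <- max(params$tip_truncation, 1e-4 * L)
  sgrid <- t0 + (L - t0) * seq(0, 1, length.out = n_s)^grade
  ce <- centerline_eval(params, sgrid)
  g <- taper_scale(params, sgrid)
  phi <- 2 * pi * (seq_len(n_phi) - 1L) / n_phi
  Rb_tmpl <- section_radius(phi, params$base_width, params$base_height,
                            dorsal_frac)
  bd <- dorsal_frac * params$base_height
  K <- n_core + n_shell
  n2 <- 1L + K * n_phi                       # template nodes per station

  # node positions, station-major: node id = (i-1)*n2 + template id
  nodes <- matrix(0, n_s * n2, 3)
  for (i in seq_len(n_s)) {
    Rb <- g[i] * Rb_tmpl                     # physical boundary radius per phi
    Rc <- pmax(Rb - t, min_core_frac * Rb)   # physical core radius per phi
    radii <- matrix(0, K, n_phi)
    for (k in seq_len(n_core)) radii[k, ] <- (k / n_core) * Rc
    for (k in seq_len(n_shell)) radii[n_core + k, ] <- Rc + (k / n_shell) * (Rb - Rc)
    ctr_local <- c(0, -bd * g[i])            # star center in (lat, dor)
    # template id layout: 1 = center, then ring k node j = 1 + (k-1)*n_phi + j
    lat2 <- c(ctr_local[1], ctr_local[1] + as.vector(t(radii) * rep(cos(phi), times = K)))
    dor2 <- c(ctr_local[2], ctr_local[2] + as.vector(t(radii) * rep(sin(phi), times = K)))
    pts <- matrix(ce$points[i, ], n2, 3, byrow = TRUE) +
      outer(lat2, c(0, 1, 0)) + outer(dor2, ce$normal[i, ])
    nodes[(i - 1L) * n2 + seq_len(n2), ] <- pts
  }

  tmpl <- section_template(n_phi, n_core, n_shell)
  elems_region <- extrude_template(tmpl, n_s, n2)
  elems <- fix_tet_orientation(nodes, elems_region$elems)
  mesh <- structure(list(nodes = nodes, elems = elems,
                         region = elems_region$region,
                         n_station = n_s, nodes_per_station = n2),
                    class = "tet_mesh")
  vols <- tet_volumes(mesh)
  if (any(vols <= 0))
    stop("tetrahedralization failure: non-positive volume in elements ",
         paste(utils::head(which(vols <= 0), 5), collapse = ", "))
  specimen$volume_mesh <- mesh
  # the mesh lives in the parametric frame; refresh the tip/base metadata so
  # boundary conditions and the mesh agree (re-align the specimen afterwards
  # if an aligned frame is needed)
  specimen$tip_point <- ce$points[1, ]
  specimen$tip_tangent <- ce$tangent[1, ]
  specimen$base_point <- ce$points[n_s, ]
  specimen$base_normal <- ce$tangent[n_s, ]
  specimen
}

# 2D cross-section template: triangles (rows of template node ids) and region
# per triangle (1 = shell, 2 = core). Ring 0 is the single center node.
section_template <- function(n_phi, n_core, n_shell) {
  K <- n_core + n_shell
  ring_id <- function(k, j) 1L + (k - 1L) * n_phi + (j - 1L) %% n_phi + 1L
  tris <- list(); region <- integer(0)
  j <- seq_len(n_phi)
  tris[[1]] <- cbind(1L, ring_id(1L, j), ring_id(1L, j + 1L))
  region <- c(region, rep(2L, n_phi))
  for (k in seq_len(K - 1L)) {
    a <- ring_id(k, j); b <- ring_id(k + 1L, j)
    cc <- ring_id(k + 1L, j + 1L); d <- ring_id(k, j + 1L)
    tris[[length(tris) + 1L]] <- rbind(cbind(a, b, cc), cbind(a, cc, d))
    reg <- if (k + 1L <= n_core) 2L else 1L
    region <- c(region, rep(reg, 2L * n_phi))
  }
  list(tris = do.call(rbind, tris), region = region)
}

# Extrude 2D triangles through n_s - 1 slabs; each prism is split into three
# tets using the ascending-template-id rule, which makes face diagonals agree
# between neighboring prisms (each quad face's diagonal rises from its
# smaller-indexed bottom vertex).
extrude_template <- function(tmpl, n_s, n2) {
  tri <- t(apply(tmpl$tris, 1L, sort))
  n_tri <- nrow(tri)
  elems <- vector("list", n_s - 1L)
  for (i in seq_len(n_s - 1L)) {
    off_b <- (i - 1L) * n2; off_t <- i * n2
    A <- off_b + tri[, 1]; B <- off_b + tri[, 2]; C <- off_b + tri[, 3]
    Ap <- off_t + tri[, 1]; Bp <- off_t + tri[, 2]; Cp <- off_t + tri[, 3]
    elems[[i]] <- rbind(cbind(A, B, C, Cp),
                        cbind(A, B, Cp, Bp),
                        cbind(A, Ap, Bp, Cp))
  }
  list(elems = do.call(rbind, elems),
       region = rep(rep(tmpl$region, 3L), times = n_s - 1L))
}

fix_tet_orientation <- function(nodes, elems) {
  v <- signed_tet_volumes(nodes, elems)
  neg <- v < 0
  if (any(neg)) elems[neg, c(1L, 2L)] <- elems[neg, c(2L, 1L)]
  elems
}

signed_tet_volumes <- function(nodes, elems) {
  a <- nodes[elems[, 2], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  b <- nodes[elems[, 3], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  d <- nodes[elems[, 4], , drop = FALSE] - nodes[elems[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
   a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
   a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
}

#' Element volumes of a tetrahedral mesh
#'
#' @param mesh A `tet_mesh` (corner connectivity is used for 10-node meshes).
#' @return Numeric vector of volumes, mm^3.
#' @export
tet_volumes <- function(mesh) {
  signed_tet_volumes(mesh$nodes, mesh$elems[, 1:4, drop = FALSE])
}

#' Uniform 1:8 refinement of a tetrahedral mesh
#'
#' Each tetrahedron is octasected through its edge midpoints (four corner
#' tets plus four from the central octahedron, split along a fixed diagonal).
#' The polyhedral geometry is preserved exactly, so comparing solutions on
#' the original and refined meshes isolates finite-element discretization
#' error from geometry approximation.
#'
#' @param mesh A `tet_mesh` with 4-column `elems`.
#' @return The refined `tet_mesh` (region labels inherited).
#' @export
refine_tets <- function(mesh) {
  el <- mesh$elems
  if (ncol(el) != 4L) stop("expected a 4-node tetrahedral mesh")
  m10 <- tet4_to_tet10(mesh)
  el10 <- m10$elems
  # midside columns 5..10 follow edges (1-2, 2-3, 3-1, 1-4, 2-4, 3-4)
  v1 <- el10[, 1]; v2 <- el10[, 2]; v3 <- el10[, 3]; v4 <- el10[, 4]
  m12 <- el10[, 5]; m23 <- el10[, 6]; m13 <- el10[, 7]
  m14 <- el10[, 8]; m24 <- el10[, 9]; m34 <- el10[, 10]
  elems <- rbind(cbind(v1, m12, m13, m14),
                 cbind(v2, m12, m23, m24),
                 cbind(v3, m13, m23, m34),
                 cbind(v4, m14, m24, m34),
                 cbind(m13, m24, m12, m23),
                 cbind(m13, m24, m23, m34),
                 cbind(m13, m24, m34, m14),
                 cbind(m13, m24, m14, m12))
  elems <- fix_tet_orientation(m10$nodes, elems)
  structure(list(nodes = m10$nodes, elems = elems,
                 region = rep(mesh$region, 8L)), class = "tet_mesh")
}

#' Convert a 4-node tetrahedral mesh to 10-node (quadratic) elements
#'
#' Midside nodes are inserted at the midpoints of the six element edges in
#' the order (1-2, 2-3, 3-1, 1-4, 2-4, 3-4); elements stay straight-sided so
#' the Jacobian remains affine.
#'
#' @param mesh A `tet_mesh` with 4-column `elems`.
#' @return A `tet_mesh` with 10-column `elems` and augmented `nodes`.
#' @export
tet4_to_tet10 <- function(mesh) {
  el <- mesh$elems
  if (ncol(el) != 4L) stop("expected a 4-node tetrahedral mesh")
  edge_def <- rbind(c(1, 2), c(2, 3), c(3, 1), c(1, 4), c(2, 4), c(3, 4))
  m <- nrow(el)
  ea <- as.vector(el[, edge_def[, 1]])
  eb <- as.vector(el[, edge_def[, 2]])
  lo <- pmin(ea, eb); hi <- pmax(ea, eb)
  key <- paste(lo, hi)
  uniq <- !duplicated(key)
  mid_id <- match(key, key[uniq])
  n0 <- nrow(mesh$nodes)
  mids <- (mesh$nodes[lo[uniq], , drop = FALSE] +
           mesh$nodes[hi[uniq], , drop = FALSE]) / 2
  mesh$nodes <- rbind(mesh$nodes, mids)
  mesh$elems <- cbind(el, matrix(n0 + mid_id, m, 6L))
  mesh
}

#' Boundary faces of a tetrahedral mesh
#'
#' @param mesh A `tet_mesh`.
#' @return Integer matrix (k x 3) of corner-node triangles appearing in
#'   exactly one element.
#' @export
tet_boundary_faces <- function(mesh) {
  el <- mesh$elems[, 1:4, drop = FALSE]
  faces <- rbind(el[, c(1, 3, 2)], el[, c(1, 2, 4)],
                 el[, c(2, 3, 4)], el[, c(1, 4, 3)])
  lo <- pmin(faces[, 1], faces[, 2], faces[, 3])
  hi <- pmax(faces[, 1], faces[, 2], faces[, 3])
  mid <- faces[, 1] + faces[, 2] + faces[, 3] - lo - hi
  key <- paste(lo, mid, hi)
  counts <- table(key)
  faces[counts[key] == 1L, , drop = FALSE]
}

#' Surface area of the boundary of a tetrahedral mesh
#'
#' The area of the full closed boundary (the "entire model" surface used by
#' the comparative force-scaling rule, as distinct from the morphometric
#' outer-maxilla selection).
#'
#' @param mesh A `tet_mesh`.
#' @return Area, mm^2.
#' @export
tet_boundary_area <- function(mesh) {
  f <- tet_boundary_faces(mesh)
  surface_area(list(vertices = mesh$nodes, faces = f), NULL)
}
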