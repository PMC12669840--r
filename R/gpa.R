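#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of all points from their
#' centroid; the standard geometric-morphometric size measure.
#'
#' @param coords A `k x 3` coordinate matrix (or a `landmark_config`).
#' @return Centroid size, mm.
#' @export
centroid_size <- function(coords) {
  if (inherits(coords, "landmark_config")) coords <- coords$coords
  ctr <- colMeans(coords)
  sqrt(sum(sweep(coords, 2, ctr)^2))
}

# Proper orthogonal rotation R minimizing ||A R - B||_F (A rotated onto B).
opa_rotation <- function(A, B) {
  sv <- svd(crossprod(A, B))
  d <- sign(det(sv$u %*% t(sv$v)))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Full Procrustes distance between two configurations
#'
#' Both configurations are centered, scaled to unit centroid size and
#' optimally rotated (proper rotations only) before the root-summed-squared
#' difference is taken.
#'
#' @param A,B `k x 3` coordinate matrices in correspondence.
#' @return Non-negative distance.
#' @export
procrustes_distance <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  sqrt(sum((A %*% opa_rotation(A, B) - B)^2))
}

# Unit tangent directions of the sliding semilandmarks, by central differences
# of within-curve neighbors (one-sided at the ends of the sliding range, where
# a neighbor is a fixed endpoint).
semilandmark_tangents <- function(coords, structure) {
  semi <- structure$semi_idx
  p <- structure$curve$prev[semi]
  q <- structure$curve$nxt[semi]
  tg <- coords[q, , drop = FALSE] - coords[p, , drop = FALSE]
  len <- sqrt(rowSums(tg^2))
  list(tangent = tg / pmax(len, 1e-300), degenerate = len < 1e-12)
}

#' Slide semilandmarks toward a consensus along their tangents
#'
#' Each semilandmark is displaced along its tangent line by the scalar that
#' minimizes its squared distance to the corresponding consensus point (the
#' projection of the residual onto the tangent, i.e. the Procrustes-distance
#' criterion restricted to tangent lines). Displacements are capped at the
#' local inter-neighbor spacing to prevent curve fold-over. With
#' `reproject = TRUE`, slid points are then projected back onto the original
#' piecewise-linear curve so they remain on it.
#'
#' @param coords `k x 3` configuration.
#' @param consensus `k x 3` reference shape.
#' @param structure A `landmark_config` (its `coords` are ignored) supplying
#'   `semi_idx` and curve neighbors.
#' @param reproject Re-project slid points onto the pre-slide polyline.
#' @return The updated `k x 3` matrix.
#' @export
slide_semilandmarks <- function(coords, consensus, structure,
                                reproject = TRUE) {
  semi <- structure$semi_idx
  tg <- semilandmark_tangents(coords, structure)
  if (any(tg$degenerate))
    warning("zero-length tangent: ", sum(tg$degenerate),
            " semilandmark(s) held fixed this iteration")
  resid <- consensus[semi, , drop = FALSE] - coords[semi, , drop = FALSE]
  disp <- rowSums(resid * tg$tangent)
  p <- structure$curve$prev[semi]; q <- structure$curve$nxt[semi]
  cap <- pmin(sqrt(rowSums((coords[semi, , drop = FALSE] -
                            coords[p, , drop = FALSE])^2)),
              sqrt(rowSums((coords[semi, , drop = FALSE] -
                            coords[q, , drop = FALSE])^2)))
  disp <- pmax(pmin(disp, cap), -cap)
  disp[tg$degenerate] <- 0
  # never move past the consensus projection, and never increase the distance
  new_semi <- coords[semi, , drop = FALSE] + disp * tg$tangent
  out <- coords
  out[semi, ] <- new_semi
  if (reproject) out <- reproject_to_curves(out, coords, structure)
  out
}

# Project each semilandmark of `coords` onto the polyline formed by the
# reference configuration's curve points (per curve, in stored order).
reproject_to_curves <- function(coords, reference, structure) {
  for (lab in unique(structure$curve$label)) {
    on_curve <- which(structure$curve$label == lab)
    # curve traversal order: stored row order within each block, with the
    # tip (index 1) prepended for the tomia
    rows <- if (lab == "culmen") on_curve else c(1L, on_curve)
    poly <- reference[rows, , drop = FALSE]
    for (i in intersect(on_curve, structure$semi_idx)) {
      coords[i, ] <- project_point_polyline(coords[i, ], poly)
    }
  }
  coords
}

project_point_polyline <- function(pt, poly) {
  a <- poly[-nrow(poly), , drop = FALSE]
  b <- poly[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  tpar <- pmin(pmax(rowSums(sweep(a, 2, pt, function(x, y) y - x) * ab) /
                    pmax(len2, 1e-300), 0), 1)
  proj <- a + tpar * ab
  d2 <- rowSums(sweep(proj, 2, pt)^2)
  proj[which.min(d2), ]
}

#' Generalized Procrustes analysis with sliding semilandmarks
#'
#' Removes position, scale and orientation: configurations are centered,
#' scaled to unit centroid size and rotated (proper rotations only) to the
#' running consensus; semilandmarks slide toward the consensus between
#' superimposition passes; the consensus is re-estimated until it changes by
#' less than `tol` or `max_outer` iterations are reached. The converged fit
#' is put in a canonical orientation (consensus principal axes) so the result
#' is invariant to arbitrary rigid motions and scalings of the inputs.
#'
#' @param configs List of `landmark_config` objects sharing one structure.
#' @param slide Enable semilandmark sliding.
#' @param tol Consensus convergence tolerance (Frobenius norm).
#' @param max_outer Maximum outer iterations.
#' @param reproject Passed to [slide_semilandmarks()].
#' @return A `procrustes_fit`: `aligned` (n x k x 3 array), `consensus`
#'   (k x 3, unit centroid size), `centroid_sizes` (mm), `n_iterations`,
#'   `converged`, `rss_trace`, and the shared `structure`.
#' @export
generalized_procrustes <- function(configs, slide = TRUE, tol = 1e-8,
                                   max_outer = 10L, reproject = TRUE) {
  n <- length(configs)
  if (n < 2L) stop("need at least 2 configurations")
  k <- nrow(configs[[1]]$coords)
  for (cfg in configs) if (nrow(cfg$coords) != k)
    stop("configurations have mismatched numbers of landmarks")
  structure_ <- configs[[1]]
  X <- array(0, c(n, k, 3))
  sizes <- numeric(n)
  for (i in seq_len(n)) {
    ci <- configs[[i]]$coords
    ci <- sweep(ci, 2, colMeans(ci))
    sizes[i] <- sqrt(sum(ci^2))
    if (sizes[i] < 1e-12) stop("configuration ", i, " has zero centroid size")
    X[i, , ] <- ci / sizes[i]
  }
  consensus <- X[1, , ]
  consensus <- consensus / sqrt(sum(consensus^2))
  rss_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  for (outer in seq_len(max_outer)) {
    iter <- outer
    for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% opa_rotation(X[i, , ], consensus)
    if (slide && length(structure_$semi_idx) > 0L) {
      for (i in seq_len(n)) {
        xi <- slide_semilandmarks(X[i, , ], consensus, structure_, reproject)
        xi <- sweep(xi, 2, colMeans(xi))
        X[i, , ] <- xi / sqrt(sum(xi^2))
      }
      for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% opa_rotation(X[i, , ], consensus)
    }
    new_consensus <- apply(X, c(2, 3), mean)
    new_consensus <- sweep(new_consensus, 2, colMeans(new_consensus))
    new_consensus <- new_consensus / sqrt(sum(new_consensus^2))
    rss_trace <- c(rss_trace, sum(sweep(X, c(2, 3), new_consensus)^2))
    delta <- sqrt(sum((new_consensus - consensus)^2))
    consensus <- new_consensus
    if (delta < tol) { converged <- TRUE; break }
  }
  # canonical orientation: consensus principal axes, sign-fixed
  rot <- principal_axes(consensus)
  for (i in seq_len(n)) X[i, , ] <- X[i, , ] %*% rot
  consensus <- consensus %*% rot
  structure(list(aligned = X, consensus = consensus, centroid_sizes = sizes,
                 n_iterations = iter, converged = converged,
                 rss_trace = rss_trace, structure = structure_),
            class = "procrustes_fit")
}

# Rotation to principal axes with an intrinsic sign convention: axes ordered
# by decreasing variance; each axis sign is fixed by the third moment
# (skewness) of the shape along it, which is rotation-equivariant and hence
# independent of the input frame. An axis with (near-)zero skewness — the
# lateral axis of a bilaterally symmetric shape — is completed by the
# right-handed cross product of the determined axes.
principal_axes <- function(coords) {
  cc <- sweep(coords, 2, colMeans(coords))
  V <- eigen(crossprod(cc), symmetric = TRUE)$vectors
  A <- cc %*% V
  skew <- colSums(A^3) / pmax(colSums(A^2), 1e-300)^1.5
  s <- ifelse(abs(skew) > 1e-6, sign(skew), 0)
  for (j in which(s < 0)) V[, j] <- -V[, j]
  cross3 <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                             a[3] * b[1] - a[1] * b[3],
                             a[1] * b[2] - a[2] * b[1])
  und <- which(s == 0)
  if (length(und) == 0L) {
    if (det(V) < 0) { j <- which.min(abs(skew)); V[, j] <- -V[, j] }
  } else if (length(und) == 1L) {
    j <- und
    oth <- setdiff(1:3, j)
    # cyclic order so the completed triad is right-handed
    V[, j] <- if (j == 1L) cross3(V[, 2], V[, 3])
              else if (j == 2L) cross3(V[, 3], V[, 1])
              else cross3(V[, 1], V[, 2])
  } else {
    # fully symmetric shape: fall back to a fixed entry-sign rule
    for (j in und) if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
    if (det(V) < 0) V[, und[length(und)]] <- -V[, und[length(und)]]
  }
  V
}

#' Bilateral (object) symmetry decomposition
#'
#' For each aligned configuration the mirrored copy (reflection of the
#' left-right axis followed by the left/right relabeling) is Procrustes-
#' superimposed on the original; their average is the symmetric component and
#' the residual the asymmetric component.
#'
#' @param fit A `procrustes_fit` (or an n x k x 3 array with `structure`
#'   supplied).
#' @param structure A `landmark_config` supplying the `pair` involution and
#'   midline set; defaults to the fit's structure.
#' @return A `symmetry_decomposition`: arrays `symmetric` and `asymmetric`
#'   with `symmetric + asymmetric` reconstructing the aligned coordinates.
#' @export
bilateral_symmetry <- function(fit, structure = NULL) {
  if (inherits(fit, "procrustes_fit")) {
    X <- fit$aligned
    if (is.null(structure)) structure <- fit$structure
  } else X <- fit
  if (is.null(structure)) stop("a landmark structure with pairing is required")
  pair <- structure$pair
  k <- dim(X)[2]
  unpaired <- which(is.na(pair))
  if (!all(unpaired %in% structure$midline_idx))
    stop("unpaired non-midline points are not allowed")
  perm <- ifelse(is.na(pair), seq_len(k), pair)
  if (!all(perm[perm] == seq_len(k))) stop("pairing is not an involution")
  n <- dim(X)[1]
  sym <- asym <- array(0, dim(X))
  for (i in seq_len(n)) {
    x <- X[i, , ]
    m <- x[perm, , drop = FALSE]
    m[, 2] <- -m[, 2]                      # mirror across the sagittal plane
    m <- sweep(m, 2, colMeans(m))
    m <- m %*% opa_rotation(m, x)
    sym[i, , ] <- (x + m) / 2
    asym[i, , ] <- x - sym[i, , ]
  }
  structure(list(symmetric = sym, asymmetric = asym),
            class = "symmetry_decomposition")
}

#' Principal component analysis of shape coordinates
#'
#' Eigendecomposition of the covariance of mean-centered flattened
#' coordinates. Components are ordered by decreasing variance; each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param coords An n x k x 3 array (e.g. the symmetric component) or an
#'   n x p matrix.
#' @return A `shape_space`: `scores` (n x n_pc), `eigenvalues`,
#'   `pct_variance` (sums to 100 over nonzero components), `loadings`
#'   (orthonormal columns), `center`.
#' @export
shape_pca <- function(coords) {
  Y <- if (length(dim(coords)) == 3L) flatten_coords(coords) else as.matrix(coords)
  n <- nrow(Y)
  if (n < 2L) stop("need at least 2 specimens")
  ctr <- colMeans(Y)
  Yc <- sweep(Y, 2, ctr)
  sv <- svd(Yc, nu = 0)
  keep <- sv$d > max(sv$d) * 1e-10
  d <- sv$d[keep]
  V <- sv$v[, keep, drop = FALSE]
  for (j in seq_len(ncol(V))) {
    if (V[which.max(abs(V[, j])), j] < 0) V[, j] <- -V[, j]
  }
  scores <- Yc %*% V
  eig <- d^2 / (n - 1)
  structure(list(scores = scores, eigenvalues = eig,
                 pct_variance = 100 * eig / sum(eig),
                 loadings = V, center = ctr),
            class = "shape_space")
}

#' Flatten an n x k x 3 coordinate array to an n x 3k matrix
#'
#' Coordinates are interleaved per landmark (x1, y1, z1, x2, ...).
#'
#' @param X n x k x 3 array.
#' @return n x 3k matrix.
#' @export
flatten_coords <- function(X) {
  n <- dim(X)[1]; k <- dim(X)[2]
  out <- matrix(0, n, 3 * k)
  for (d in 1:3) out[, seq(d, 3 * k, by = 3)] <- X[, , d]
  out
}
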