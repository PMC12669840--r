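#' Isotropic linear-elastic material
#'
#' @param young_modulus Young's modulus, MPa (> 0).
#' @param poisson_ratio Poisson's ratio in [0, 0.5).
#' @return A `material` list.
#' @export
material <- function(young_modulus, poisson_ratio = 0.4) {
  if (young_modulus <= 0) stop("Young's modulus must be > 0")
  if (poisson_ratio < 0 || poisson_ratio >= 0.5)
    stop("Poisson's ratio must be in [0, 0.5)")
  structure(list(young_modulus = young_modulus,
                 poisson_ratio = poisson_ratio), class = "material")
}

#' Default bill materials
#'
#' Keratin rhamphotheca shell (1700 MPa) over a bone core (7300 MPa), both
#' with Poisson's ratio 0.4 — standard values for bird bill tissue.
#'
#' @return Named list of [material()] objects for regions `shell` and `core`.
#' @export
bill_materials <- function() {
  list(shell = material(1700, 0.4), core = material(7300, 0.4))
}

#' Assemble a finite-element model from a labeled tetrahedral mesh
#'
#' Builds the global stiffness operator for isotropic linear elasticity on
#' 4-node or 10-node (default) straight-sided tetrahedra. Region labels map
#' elements to materials; bonded shell-core contact is realized by the shared
#' interface nodes of the conforming mesh.
#'
#' @param mesh A `tet_mesh` with 4-column `elems` and integer `region`
#'   (1 = shell, 2 = core), or a single-region mesh with `region` omitted.
#' @param materials Named list of [material()] per region (`shell`, `core`),
#'   or a single `material` applied to all elements.
#' @param order Element order: 2 for quadratic 10-node tets (default),
#'   1 for linear 4-node tets (fast tests, reduced accuracy).
#' @return An `fe_model`: `mesh` (possibly quadratic), `K` (sparse symmetric
#'   stiffness, N/mm), `E`, `nu` per element, `volumes` (mm^3), `n_dof`.
#' @export
fe_model <- function(mesh, materials = bill_materials(), order = 2L) {
  stopifnot(inherits(mesh, "tet_mesh") || is.list(mesh))
  if (!order %in% c(1L, 2L)) stop("order must be 1 or 2")
  if (order == 2L && ncol(mesh$elems) == 4L) mesh <- tet4_to_tet10(mesh)
  m <- nrow(mesh$elems)
  if (inherits(materials, "material"))
    materials <- list(shell = materials, core = materials)
  region <- mesh$region
  if (is.null(region)) region <- rep(2L, m)
  E <- ifelse(region == 1L, materials$shell$young_modulus,
              materials$core$young_modulus)
  nu <- ifelse(region == 1L, materials$shell$poisson_ratio,
               materials$core$poisson_ratio)
  trip <- fea_assemble_stiffness(mesh$nodes, mesh$elems, E, nu)
  n_dof <- 3L * nrow(mesh$nodes)
  K <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$v,
                            dims = c(n_dof, n_dof), symmetric = TRUE)
  structure(list(mesh = mesh, K = K, E = E, nu = nu,
                 volumes = trip$volumes, n_dof = n_dof),
            class = "fe_model")
}

#' Boundary conditions for the stabbing simulation
#'
#' Fixes all degrees of freedom on the proximal cut plane (the bill's
#' attachment to the head) and applies the total stabbing force over the
#' nodes within the distal millimeter of the tip, shared equally. In
#' `horizontal` mode the force acts along +x (the chord direction, pointing
#' proximally into the bill); in `parallel` mode along the centerline tangent
#' at the tip, pointing proximally.
#'
#' @param specimen A `bill_specimen` with a volume mesh, in the aligned frame
#'   (tip at the origin, chord along +x).
#' @param load_mode `"horizontal"` or `"parallel"`.
#' @param total_force_mN Total applied force, mN (converted to N
#'   internally).
#' @param load_extent Distance from the tip over which load nodes are
#'   selected, mm.
#' @param weighting `"area"` (default) shares the total force across load
#'   nodes in proportion to their tributary boundary surface area,
#'   approximating a uniform traction over the loaded patch; `"equal"` gives
#'   every load node the same share. Equal shares on a tip-graded mesh
#'   concentrate force on the finest apex elements, whose local compliance
#'   can dominate the response, so area weighting is the default for bill
#'   geometries.
#' @param plane_tol Tolerance for base-plane node detection, mm.
#' @return A `boundary_conditions` list: `fixed_nodes`, `load_nodes`,
#'   `load_weights` (sum to 1), `direction` (unit), `total_force` (N),
#'   `load_mode`.
#' @export
make_bc <- function(specimen, load_mode = c("horizontal", "parallel"),
                    total_force_mN = 200, load_extent = 1,
                    weighting = c("area", "equal"), plane_tol = 1e-6) {
  load_mode <- match.arg(load_mode)
  weighting <- match.arg(weighting)
  mesh <- specimen$volume_mesh
  if (is.null(mesh)) stop("specimen has no volume mesh")
  if (total_force_mN <= 0) stop("total force must be > 0")
  nodes <- mesh$nodes
  rel <- sweep(nodes, 2, specimen$base_point)
  fixed <- which(abs(rel %*% specimen$base_normal) < plane_tol)
  tip_rel <- sweep(nodes, 2, specimen$tip_point)
  axis <- c(1, 0, 0)
  xdist <- as.vector(tip_rel %*% axis)
  load <- which(xdist <= load_extent)
  load <- setdiff(load, fixed)
  if (length(fixed) == 0L) stop("empty fixed node set: base plane not found")
  if (length(load) == 0L) stop("empty load node set at the tip")
  weights <- rep(1 / length(load), length(load))
  if (weighting == "area") {
    bf <- tet_boundary_faces(mesh)
    fc <- (xdist[bf[, 1]] + xdist[bf[, 2]] + xdist[bf[, 3]]) / 3
    bf <- bf[fc <= load_extent, , drop = FALSE]
    if (nrow(bf) > 0L) {
      e1 <- nodes[bf[, 2], , drop = FALSE] - nodes[bf[, 1], , drop = FALSE]
      e2 <- nodes[bf[, 3], , drop = FALSE] - nodes[bf[, 1], , drop = FALSE]
      ar <- sqrt((e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2])^2 +
                 (e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3])^2 +
                 (e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])^2) / 2
      w <- numeric(nrow(nodes))
      for (c in 1:3) {
        acc <- tapply(ar / 3, bf[, c], sum)
        w[as.integer(names(acc))] <- w[as.integer(names(acc))] + acc
      }
      wl <- w[load]
      if (sum(wl) > 0) weights <- wl / sum(wl)
    }
  }
  dirn <- if (load_mode == "horizontal") c(1, 0, 0) else specimen$tip_tangent
  dirn <- unname(dirn / sqrt(sum(dirn^2)))
  total_N <- total_force_mN / 1000
  structure(list(fixed_nodes = fixed, load_nodes = load,
                 load_weights = weights, direction = dirn,
                 total_force = total_N, load_mode = load_mode,
                 weighting = weighting), class = "boundary_conditions")
}

#' Solve the linear-static problem
#'
#' Solves `K u = f` with the fixed set eliminated and the total force shared
#' equally over the load nodes. Element stresses are recovered at centroids;
#' the strain energy is the work of the applied loads, `u' f / 2`.
#'
#' @param model An [fe_model()].
#' @param bc A [make_bc()] result, or a list with `fixed_nodes`,
#'   `load_nodes`, `direction`, `total_force` (N).
#' @return An `fe_solution`: `displacements` (n x 3, mm),
#'   `element_stress` (m x 6, MPa), `element_vm_stress` (MPa),
#'   `element_volumes` (mm^3), `strain_energy` (mJ), `u`, `f`, `free_dof`,
#'   `chol` (cached factor).
#' @export
solve_static <- function(model, bc) {
  n_dof <- model$n_dof
  fixed_dof <- as.vector(outer(c(-2L, -1L, 0L), 3L * bc$fixed_nodes, "+"))
  free <- setdiff(seq_len(n_dof), fixed_dof)
  if (length(free) == n_dof)
    stop("under-constrained system: no fixed degrees of freedom")
  f <- numeric(n_dof)
  w <- bc$load_weights
  if (is.null(w)) w <- rep(1 / length(bc$load_nodes), length(bc$load_nodes))
  for (d in 1:3)
    f[3L * (bc$load_nodes - 1L) + d] <- bc$total_force * w * bc$direction[d]
  Kff <- model$K[free, free]
  ch <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE, super = TRUE)
  uf <- as.vector(Matrix::solve(ch, f[free], system = "A"))
  u <- numeric(n_dof)
  u[free] <- uf
  stress <- fea_element_stress(model$mesh$nodes, model$mesh$elems,
                               model$E, model$nu, u)
  structure(list(displacements = matrix(u, ncol = 3, byrow = TRUE),
                 element_stress = stress[, 1:6, drop = FALSE],
                 element_vm_stress = stress[, 7],
                 element_volumes = model$volumes,
                 strain_energy = 0.5 * sum(u * f),
                 u = u, f = f, free_dof = free, chol = ch),
            class = "fe_solution")
}

#' Von Mises stress summaries
#'
#' The peak is the 98th percentile of element von Mises stresses (linear
#' interpolation between order statistics), discarding the top 2% as likely
#' numerical singularities; the mesh-weighted arithmetic mean (MWAM) weights
#' each element by its volume.
#'
#' @param solution An `fe_solution`.
#' @return List with `peak_vm_98` and `mwam_vm`, MPa.
#' @export
vm_summaries <- function(solution) {
  vm <- solution$element_vm_stress
  if (length(vm) == 0L) stop("no elements")
  list(peak_vm_98 = unname(stats::quantile(vm, 0.98, type = 7)),
       mwam_vm = sum(vm * solution$element_volumes) /
         sum(solution$element_volumes))
}

#' Eigenvalue buckling load factor
#'
#' Assembles the geometric (stress) stiffness from the static pre-solution
#' and finds the smallest positive load multiplier `lambda` solving
#' `(K + lambda Kg(u0)) phi = 0`, via Lanczos iteration on the symmetric
#' whitened pencil (largest positive eigenvalue of `-K^{-1} Kg`).
#' `lambda` times the applied load is the predicted critical load; higher
#' values mean greater buckling resistance.
#'
#' @param model An [fe_model()].
#' @param bc Boundary conditions used for the pre-solution.
#' @param solution Optional cached [solve_static()] result for `(model, bc)`.
#' @param n_lanczos Number of Lanczos vectors.
#' @param seed Seed for the start vector.
#' @return List with `load_factor` (NA if no compressive instability under
#'   this load direction), `critical_force` (N), `n_lanczos`.
#' @export
buckling_load_factor <- function(model, bc, solution = NULL,
                                 n_lanczos = 80L, seed = 1L) {
  if (is.null(solution)) solution <- solve_static(model, bc)
  trip <- fea_assemble_geometric(model$mesh$nodes, model$mesh$elems,
                                 model$E, model$nu, solution$u)
  n_dof <- model$n_dof
  Kg <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$v,
                             dims = c(n_dof, n_dof), symmetric = TRUE)
  free <- solution$free_dof
  Kgf <- Kg[free, free]
  ch <- solution$chol
  # symmetric operator L^-1 P (-Kg) P' L^-T with K = P' L L' P
  op <- function(x) {
    t1 <- Matrix::solve(ch, x, system = "Lt")
    t2 <- Matrix::solve(ch, t1, system = "Pt")
    t3 <- -(Kgf %*% t2)
    t4 <- Matrix::solve(ch, t3, system = "P")
    as.vector(Matrix::solve(ch, t4, system = "L"))
  }
  mu <- lanczos_extreme(op, length(free), n_lanczos, seed)
  if (!is.finite(mu) || mu <= 0) {
    return(list(load_factor = NA_real_, critical_force = NA_real_,
                n_lanczos = n_lanczos,
                message = "no compressive instability under this load direction"))
  }
  list(load_factor = 1 / mu, critical_force = bc$total_force / mu,
       n_lanczos = n_lanczos)
}

# Largest eigenvalue of a symmetric operator by Lanczos iteration with full
# reorthogonalization; returns the largest (signed) Ritz value.
lanczos_extreme <- function(op, n, m = 80L, seed = 1L) {
  set.seed(as.integer(seed))
  m <- min(m, n)
  V <- matrix(0, n, m)
  alpha <- beta <- numeric(m)
  v <- stats::rnorm(n)
  v <- v / sqrt(sum(v^2))
  V[, 1] <- v
  w <- op(v)
  alpha[1] <- sum(w * v)
  w <- w - alpha[1] * v
  for (j in 2:m) {
    w <- w - V[, 1:(j - 1), drop = FALSE] %*%
      crossprod(V[, 1:(j - 1), drop = FALSE], w)  # reorthogonalize
    beta[j] <- sqrt(sum(w^2))
    if (beta[j] < 1e-13) { m <- j - 1L; break }
    v <- as.vector(w) / beta[j]
    V[, j] <- v
    w <- op(v)
    alpha[j] <- sum(w * v)
    w <- w - alpha[j] * v - beta[j] * V[, j - 1]
  }
  Tm <- diag(alpha[1:m], nrow = m)
  if (m > 1) {
    for (j in 2:m) { Tm[j - 1, j] <- beta[j]; Tm[j, j - 1] <- beta[j] }
  }
  max(eigen(Tm, symmetric = TRUE, only.values = TRUE)$values)
}

#' Structured tetrahedral box mesh
#'
#' A rectangular block split into a structured grid of cubes, each divided
#' into six tetrahedra around the main diagonal (globally conforming).
#' Standard validation geometry for cantilever-beam and column-buckling
#' checks.
#'
#' @param lx,ly,lz Box dimensions, mm.
#' @param nx,ny,nz Cells per direction.
#' @return A single-region `tet_mesh`.
#' @export
mesh_box <- function(lx, ly, lz, nx, ny, nz) {
  xs <- seq(0, lx, length.out = nx + 1L)
  ys <- seq(0, ly, length.out = ny + 1L)
  zs <- seq(0, lz, length.out = nz + 1L)
  nid <- function(i, j, k) {
    (k - 1L) * (nx + 1L) * (ny + 1L) + (j - 1L) * (nx + 1L) + i
  }
  nodes <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dimnames(nodes) <- NULL
  cells <- expand.grid(i = seq_len(nx), j = seq_len(ny), k = seq_len(nz))
  c000 <- nid(cells$i, cells$j, cells$k)
  c100 <- nid(cells$i + 1L, cells$j, cells$k)
  c010 <- nid(cells$i, cells$j + 1L, cells$k)
  c110 <- nid(cells$i + 1L, cells$j + 1L, cells$k)
  c001 <- nid(cells$i, cells$j, cells$k + 1L)
  c101 <- nid(cells$i + 1L, cells$j, cells$k + 1L)
  c011 <- nid(cells$i, cells$j + 1L, cells$k + 1L)
  c111 <- nid(cells$i + 1L, cells$j + 1L, cells$k + 1L)
  elems <- rbind(cbind(c000, c100, c110, c111),
                 cbind(c000, c110, c010, c111),
                 cbind(c000, c010, c011, c111),
                 cbind(c000, c011, c001, c111),
                 cbind(c000, c001, c101, c111),
                 cbind(c000, c101, c100, c111))
  elems <- fix_tet_orientation(nodes, elems)
  structure(list(nodes = nodes, elems = elems,
                 region = rep(2L, nrow(elems))), class = "tet_mesh")
}
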