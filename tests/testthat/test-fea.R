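# small shared fixtures: a coarse beam and a coarse bill FE model
beam_fixture <- function(order = 2L, nx = 30, E = 1000, nu = 0.3) {
  mesh <- mesh_box(20, 1, 1, nx, 2, 2)
  model <- fe_model(mesh, material(E, nu), order = order)
  nodes <- model$mesh$nodes
  list(model = model,
       fixed = which(abs(nodes[, 1]) < 1e-9),
       tip = which(abs(nodes[, 1] - 20) < 1e-9))
}

test_that("the stiffness operator is elastic, symmetric and translation-free", {
  bf <- beam_fixture(order = 1L, nx = 6)
  K <- bf$model$K
  n <- nrow(bf$model$mesh$nodes)
  # rigid-body translation lies in the null space
  for (d in 1:3) {
    tr <- rep(0, 3 * n); tr[seq(d, 3 * n, 3)] <- 1
    expect_lt(max(abs(K %*% tr)) / max(abs(K)), 1e-10)
  }
  # doubling E doubles the operator
  K2 <- fe_model(mesh_box(20, 1, 1, 6, 2, 2), material(2000, 0.3),
                 order = 1L)$K
  expect_lt(max(abs(K2 - 2 * K)) / max(abs(K)), 1e-12)
  expect_equal(as.matrix(K), t(as.matrix(K)), tolerance = 1e-12)

  expect_error(material(-1), "Young")
  expect_error(material(100, 0.5), "Poisson")
})

test_that("a single tetrahedron matches a hand-assembled stiffness matrix", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  elems <- matrix(1:4, 1)
  E <- 100; nu <- 0.25
  mdl <- fe_model(list(nodes = nodes, elems = elems, region = 2L),
                  material(E, nu), order = 1L)
  # independent assembly: constant-strain tet, V * B' D B
  grads <- rbind(c(-1, -1, -1), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    g <- grads[a, ]; c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- g[1]; B[2, c0 + 2] <- g[2]; B[3, c0 + 3] <- g[3]
    B[4, c0 + 1] <- g[2]; B[4, c0 + 2] <- g[1]
    B[5, c0 + 2] <- g[3]; B[5, c0 + 3] <- g[2]
    B[6, c0 + 1] <- g[3]; B[6, c0 + 3] <- g[1]
  }
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu)); mu <- E / (2 * (1 + nu))
  D <- diag(c(rep(0, 3), rep(mu, 3)))
  D[1:3, 1:3] <- lam; diag(D)[1:3] <- lam + 2 * mu
  Ke <- (1 / 6) * t(B) %*% D %*% B
  expect_equal(as.matrix(mdl$K), Ke, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("static solutions satisfy work balance and linear scaling", {
  bf <- beam_fixture(nx = 12)
  bc <- list(fixed_nodes = bf$fixed, load_nodes = bf$tip,
             direction = c(0, 0, 1), total_force = 0.01)
  sol <- solve_static(bf$model, bc)
  # work balance: 0.5 u'Ku = 0.5 u'f
  internal <- 0.5 * as.numeric(sol$u %*% (bf$model$K %*% sol$u))
  expect_lt(abs(internal - sol$strain_energy) / sol$strain_energy, 1e-8)

  # zero load
  bc0 <- bc; bc0$total_force <- 0
  sol0 <- solve_static(bf$model, bc0)
  expect_equal(max(abs(sol0$u)), 0)
  expect_equal(sol0$strain_energy, 0)
  expect_equal(max(sol0$element_vm_stress), 0)

  # linearity: scaling the force by c scales u and stress by c, energy by c^2
  bc3 <- bc; bc3$total_force <- 0.03
  sol3 <- solve_static(bf$model, bc3)
  expect_lt(max(abs(sol3$u - 3 * sol$u)) / max(abs(sol$u)), 1e-8)
  expect_lt(max(abs(sol3$element_vm_stress - 3 * sol$element_vm_stress)) /
              max(sol$element_vm_stress), 1e-8)
  expect_lt(abs(sol3$strain_energy - 9 * sol$strain_energy) /
              sol$strain_energy, 1e-8)

  expect_error(solve_static(bf$model, list(fixed_nodes = integer(0),
                                           load_nodes = bf$tip,
                                           direction = c(0, 0, 1),
                                           total_force = 1)),
               "under-constrained")
})

test_that("a slender cantilever reproduces Euler-Bernoulli tip deflection", {
  bf <- beam_fixture(nx = 40)
  Fz <- 0.01; L <- 20; E <- 1000; I <- 1 / 12
  bc <- list(fixed_nodes = bf$fixed, load_nodes = bf$tip,
             direction = c(0, 0, 1), total_force = Fz)
  sol <- solve_static(bf$model, bc)
  tip_def <- mean(sol$displacements[bf$tip, 3])
  expect_lt(abs(tip_def - Fz * L^3 / (3 * E * I)) / (Fz * L^3 / (3 * E * I)),
            0.05)
})

test_that("stress summaries follow their definitions", {
  sol <- structure(list(element_vm_stress = c(1, 2, 3),
                        element_volumes = c(1, 1, 2)), class = "fe_solution")
  vs <- vm_summaries(sol)
  expect_equal(vs$mwam_vm, 2.25)

  sol2 <- structure(list(element_vm_stress = 1:100,
                         element_volumes = rep(1, 100)),
                    class = "fe_solution")
  expect_equal(vm_summaries(sol2)$peak_vm_98, 98.02)

  solu <- structure(list(element_vm_stress = rep(7, 10),
                         element_volumes = runif(10)), class = "fe_solution")
  expect_equal(vm_summaries(solu)$peak_vm_98, 7)
  expect_equal(vm_summaries(solu)$mwam_vm, 7)
})

test_that("eigenvalue buckling matches the Euler column and scales with load", {
  bf <- beam_fixture(nx = 40)
  bc <- list(fixed_nodes = bf$fixed, load_nodes = bf$tip,
             direction = c(-1, 0, 0), total_force = 1)
  sol <- solve_static(bf$model, bc)
  bl <- buckling_load_factor(bf$model, bc, sol)
  Pcr <- pi^2 * 1000 * (1 / 12) / (4 * 20^2)
  expect_lt(abs(bl$critical_force - Pcr) / Pcr, 0.10)

  # halving the applied load doubles lambda (Kg linear in the load)
  bc_half <- bc; bc_half$total_force <- 0.5
  bl_half <- buckling_load_factor(bf$model, bc_half)
  expect_equal(bl_half$load_factor, 2 * bl$load_factor, tolerance = 1e-4)
  expect_equal(bl_half$critical_force, bl$critical_force, tolerance = 1e-4)

  # tension: no instability anywhere near the compressive critical load
  bc_t <- bc; bc_t$direction <- c(1, 0, 0)
  bl_t <- buckling_load_factor(bf$model, bc_t)
  expect_true(is.na(bl_t$load_factor) ||
                bl_t$load_factor > 100 * bl$load_factor)
})

test_that("bill boundary conditions select base plane and tip millimeter", {
  p <- female_bill_params()
  sp <- contour_only_specimen(p); sp$truth <- p
  sp <- generate_volume(sp, n_s = 18, n_phi = 12)
  bc <- make_bc(sp, "horizontal", total_force_mN = 200)
  nodes <- sp$volume_mesh$nodes
  expect_gt(length(bc$fixed_nodes), 0)
  expect_gt(length(bc$load_nodes), 0)
  expect_length(intersect(bc$fixed_nodes, bc$load_nodes), 0)
  expect_true(all(nodes[bc$load_nodes, 1] - sp$tip_point[1] <= 1 + 1e-9))
  expect_equal(sum(bc$load_weights), 1, tolerance = 1e-12)
  expect_equal(bc$total_force, 0.2)      # 200 mN -> 0.2 N

  # force vector assembles to the requested resultant
  mdl <- fe_model(sp$volume_mesh, bill_materials(), order = 1L)
  sol <- solve_static(mdl, bc)
  expect_equal(sum(sol$f[seq(1, length(sol$f), 3)]), 0.2, tolerance = 1e-12)

  # the two load angles differ by the tangent-chord angle at the (truncated)
  # tip station of the volume mesh: |phi(t0)| = theta/2 - theta * t0 / L
  bc_par <- make_bc(sp, "parallel", total_force_mN = 200)
  got <- acos(sum(bc$direction * bc_par$direction))
  theta <- arc_angle_from_ratio(p$arc_chord_ratio)
  t0 <- max(p$tip_truncation, 1e-4 * p$arc_length)
  expect_equal(got, theta / 2 - theta * t0 / p$arc_length, tolerance = 1e-9)

  # a straight bill makes the two directions coincide
  p0 <- bill_params(arc_chord_ratio = 1)
  sp0 <- contour_only_specimen(p0); sp0$truth <- p0
  sp0 <- generate_volume(sp0, n_s = 14, n_phi = 12)
  b1 <- make_bc(sp0, "horizontal"); b2 <- make_bc(sp0, "parallel")
  expect_equal(b1$direction, b2$direction, tolerance = 1e-12)
})

test_that("strain energy is stable under one uniform mesh refinement", {
  # octasection preserves the polyhedral geometry exactly, isolating the
  # finite-element discretization error
  p <- female_bill_params()
  sp <- contour_only_specimen(p); sp$truth <- p
  sp <- generate_volume(sp)               # default mesh resolution
  base <- sp$volume_mesh
  refined <- refine_tets(base)
  expect_equal(sum(tet_volumes(refined)), sum(tet_volumes(base)),
               tolerance = 1e-12)
  energies <- vapply(list(base, refined), function(msh) {
    s <- sp; s$volume_mesh <- msh
    mdl <- fe_model(msh, bill_materials(), order = 2L)
    solve_static(mdl, make_bc(s, "horizontal", 200))$strain_energy
  }, 0)
  expect_lt(abs(diff(energies)) / energies[1], 0.02)
})
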