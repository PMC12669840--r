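test_that("centerline realizes the requested arc:chord geometry", {
  # degenerate arc: straight segment along x
  p <- bill_params(arc_length = 40, arc_chord_ratio = 1)
  cl <- generate_centerline(p, n = 101)
  expect_equal(cl[, 2], rep(0, 101))
  expect_equal(cl[, 3], rep(0, 101))
  expect_equal(max(cl[, 1]), 40)
  expect_equal(sum(sqrt(rowSums(diff(cl)^2))), 40, tolerance = 1e-12)

  # semicircular arc: ratio pi/2 by closed form
  p2 <- bill_params(arc_length = 40, arc_chord_ratio = pi / 2)
  expect_equal(arc_angle_from_ratio(pi / 2), pi, tolerance = 1e-8)
  cl2 <- generate_centerline(p2, n = 2001)
  ac <- arc_chord(cl2)
  expect_equal(ac$arc_chord_ratio, pi / 2, tolerance = 1e-5)

  # quarter circle recovered from its ratio by an independent bisection oracle
  target <- pi / (2 * sqrt(2))
  expect_equal(oracle_arc_angle(target), pi / 2, tolerance = 1e-9)
  expect_equal(arc_angle_from_ratio(target), pi / 2, tolerance = 1e-9)

  expect_error(bill_params(arc_chord_ratio = 0.98), "arc_chord_ratio")
})

test_that("surface meshes are watertight, mirror-symmetric and match quadrature area", {
  p <- female_bill_params()
  sp <- generate_surface(p, n_s = 160, n_phi = 48)
  mesh <- sp$surface_mesh
  expect_true(is_watertight(mesh))
  expect_gt(mesh_signed_volume(mesh), 0)

  # exact sagittal mirror symmetry: reflecting y maps the vertex set to itself
  v <- mesh$vertices
  refl <- v; refl[, 2] <- -refl[, 2]
  key <- function(m) {
    m[abs(m) < 1e-15] <- 0          # collapse signed zeros
    paste(sprintf("%.12f", m[, 1]), sprintf("%.12f", m[, 2]),
          sprintf("%.12f", m[, 3]))
  }
  expect_setequal(key(refl), key(v))

  # contours share the tip point and lie tip-first
  tips <- vapply(sp$contours, function(cc) cc[1, ], numeric(3))
  expect_equal(max(abs(tips - tips[, 1])), 0)

  # lateral area against the independent Simpson quadrature oracle
  area_mesh <- outer_surface_area(sp)
  area_oracle <- oracle_bill_area(p, 1e-4)
  expect_lt(abs(area_mesh - area_oracle) / area_oracle, 0.005)

  expect_error(generate_surface(p, n_phi = 30), "multiple of 4")
})

test_that("volume meshes partition the solid into valid labeled regions", {
  p <- female_bill_params()
  sp <- generate_surface(p, n_s = 60, n_phi = 16)
  sp$truth <- p
  sp <- generate_volume(sp, n_s = 40, n_phi = 48, n_core = 2, n_shell = 1)
  vm <- sp$volume_mesh
  vols <- tet_volumes(vm)
  expect_true(all(vols > 0))
  expect_setequal(unique(vm$region), c(1L, 2L))

  # tet volumes partition the enclosed volume of the mesh's own boundary
  bnd <- tet_boundary_faces(vm)
  enclosed <- mesh_signed_volume(list(vertices = vm$nodes, faces = bnd))
  expect_equal(sum(vols), abs(enclosed), tolerance = 1e-3)

  # region volumes against the curved-sweep quadrature oracle
  t0 <- max(p$tip_truncation, 1e-4 * p$arc_length)
  v_tot_oracle <- oracle_bill_volume(p, t0)
  v_core_oracle <- oracle_bill_volume(p, t0, core_only = TRUE)
  expect_lt(abs(sum(vols) - v_tot_oracle) / v_tot_oracle, 0.02)
  expect_lt(abs(sum(vols[vm$region == 2L]) - v_core_oracle) / v_core_oracle,
            0.02)

  # vanishing shell: core volume approaches the total
  p_thin <- bill_params(arc_length = 39, arc_chord_ratio = 1.1,
                        base_height = 3, base_width = 4,
                        taper_exponent = 0.55, shell_thickness = 0.02)
  sp2 <- contour_only_specimen(p_thin)
  sp2$truth <- p_thin
  sp2 <- generate_volume(sp2, n_s = 26, n_phi = 16)
  v2 <- tet_volumes(sp2$volume_mesh)
  expect_gt(sum(v2[sp2$volume_mesh$region == 2L]) / sum(v2), 0.95)

  expect_error(generate_volume(sp, shell_thickness = 2),
               "thicker than local half-thickness")
})

test_that("population sampling is deterministic with recoverable group structure", {
  spec <- population_spec(n_per_group = 3, seed = 42)
  popA <- sample_population(spec, make_surface = FALSE)
  popB <- sample_population(spec, make_surface = FALSE)
  expect_identical(lapply(popA, function(s) s$truth),
                   lapply(popB, function(s) s$truth))
  expect_identical(popA[["F02"]]$contours, popB[["F02"]]$contours)

  # zero noise and jitter: identical specimens within a group
  spec0 <- population_spec(n_per_group = 3, seed = 1,
                           noise_sd = default_noise_sd() * 0,
                           landmark_jitter_sd = 0)
  pop0 <- sample_population(spec0, make_surface = FALSE)
  expect_equal(pop0[["F01"]]$contours, pop0[["F03"]]$contours)
  expect_equal(pop0[["F01"]]$truth, female_bill_params())

  # Monte-Carlo mean recovery: sampled arc:chord mean within 3 SE
  set.seed(99)
  n <- 200
  draws <- replicate(n, sample_bill_params(male_bill_params())$arc_chord_ratio)
  se <- default_noise_sd()[["arc_chord_ratio"]] / sqrt(n)
  expect_lt(abs(mean(draws) - male_bill_params()$arc_chord_ratio), 3 * se)

  # invalid draws are redrawn and capped
  set.seed(1)
  bad_sd <- default_noise_sd()
  bad_sd["shell_thickness"] <- 1e4    # valid shell window hit with P ~ 1e-4
  expect_error(sample_bill_params(female_bill_params(), bad_sd,
                                  max_retry = 5L), "could not draw")
})
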