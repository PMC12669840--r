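test_that("arc:chord ratio matches closed forms", {
  straight <- cbind(seq(0, 10, length.out = 40), 0, 0)
  expect_equal(arc_chord(straight)$arc_chord_ratio, 1, tolerance = 1e-12)

  th <- seq(0, pi, length.out = 4001)          # semicircle: ratio pi/2
  semi <- cbind(5 * (1 - cos(th)), 0, 5 * sin(th))
  expect_equal(arc_chord(semi)$arc_chord_ratio, pi / 2, tolerance = 1e-5)

  th4 <- seq(0, pi / 2, length.out = 4001)     # quarter circle: pi/(2 sqrt 2)
  quarter <- cbind(5 * sin(th4), 0, 5 * (1 - cos(th4)))
  oracle <- (pi / 2) / (2 * sin(pi / 4))
  expect_equal(arc_chord(quarter)$arc_chord_ratio, oracle, tolerance = 1e-5)
  expect_equal(oracle, pi / (2 * sqrt(2)), tolerance = 1e-12)

  expect_error(arc_chord(rbind(c(0, 0, 0), c(0, 0, 0))), "zero chord")
})

test_that("surface area sums triangle areas and is rigid-motion invariant", {
  unit_square <- list(vertices = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0),
                                       c(0, 1, 0)),
                      faces = rbind(c(1, 2, 3), c(1, 3, 4)))
  expect_equal(surface_area(unit_square), 1, tolerance = 1e-14)

  set.seed(3)
  R <- random_rotation()
  moved <- unit_square
  moved$vertices <- sweep(unit_square$vertices %*% t(R), 2, c(4, 5, -2), "+")
  expect_equal(surface_area(moved), surface_area(unit_square),
               tolerance = 1e-10)
  expect_error(surface_area(unit_square, integer(0)), "empty")
})

test_that("sharpness ratio recovers cone and cylinder closed forms", {
  # right circular cone, apex at the tip: frustum areas give A1/A2 = 1/3
  cone <- make_cone_mesh()
  sr <- sharpness_ratio(cone, tip = c(0, 0, 0))
  expect_equal(sr$sharpness_ratio, 2 / 3, tolerance = 1e-3)
  expect_equal(sr$area_distal_mm / sr$area_second_mm, 1 / 3, tolerance = 1e-3)

  # untapered cylinder: A1 = A2, ratio 0
  cyl <- make_cylinder_mesh()
  expect_equal(sharpness_ratio(cyl, tip = c(0, 0, 0))$sharpness_ratio, 0,
               tolerance = 1e-9)

  # orientation contract: measuring from the wrong end differs on a cone
  sr_rev <- sharpness_ratio(cone, tip = c(4, 0, 0), axis = c(-1, 0, 0))
  expect_gt(abs(sr_rev$sharpness_ratio - sr$sharpness_ratio), 0.1)

  expect_error(sharpness_ratio(cone, tip = c(10, 0, 0)), "A2 = 0")
})

test_that("included angle reads the dorsal silhouette", {
  # silhouette half-width 0.5 mm at 0.5 mm from the tip: 90 degrees
  cone45 <- make_revolution_mesh(function(x) x, 3)
  expect_equal(included_angle(cone45, tip = c(0, 0, 0)), 90, tolerance = 1e-6)

  # cone with 15-degree dorsal half-angle: included angle 30 degrees
  cone15 <- make_cone_mesh(15)
  expect_equal(included_angle(cone15, tip = c(0, 0, 0)), 30, tolerance = 1e-6)

  # half-width 0.1 mm: 2 atan(0.2) in degrees
  thin <- make_revolution_mesh(function(x) 0.2 * x, 3)
  expect_equal(included_angle(thin, tip = c(0, 0, 0)),
               2 * atan(0.2) * 180 / pi, tolerance = 1e-6)
})

test_that("metrics recover synthetic ground truth and respond to taper", {
  for (p in list(female_bill_params(), male_bill_params())) {
    sp <- generate_surface(p)
    sp$truth <- p; sp$id <- "X"; sp$sex <- "F"
    m <- bill_metrics(sp)
    expect_lt(abs(m$arc_length - p$arc_length) / p$arc_length, 0.01)
    expect_lt(abs(m$arc_chord_ratio - p$arc_chord_ratio) / p$arc_chord_ratio,
              0.01)
    # outer area against the quadrature oracle
    oracle <- oracle_bill_area(p, 1e-4, ns = 161, nphi = 129)
    expect_lt(abs(m$outer_surface_area - oracle) / oracle, 0.01)
  }

  # sharpness increases monotonically with the taper exponent
  sharp <- vapply(c(0.45, 0.6, 0.8, 1.0), function(pe) {
    p <- bill_params(taper_exponent = pe)
    sharpness_ratio(generate_surface(p))$sharpness_ratio
  }, 0)
  expect_true(all(diff(sharp) > 0))

  # metrics invariant under rigid motion of the specimen (via realignment)
  p <- female_bill_params()
  sp <- generate_surface(p); sp$truth <- p; sp$id <- "Y"; sp$sex <- "F"
  set.seed(10)
  moved <- transform_specimen(sp, random_rotation(), c(8, -3, 12))
  m0 <- bill_metrics(sp)
  m1 <- bill_metrics(moved)
  for (col in c("arc_length", "arc_chord_ratio", "outer_surface_area",
                "sharpness_ratio", "included_angle", "centroid_size"))
    expect_equal(m1[[col]], m0[[col]], tolerance = 1e-6)
})

test_that("tip truncation does not bias the metrics at the 1% level", {
  base <- bill_params(tip_truncation = 0.02)
  more <- bill_params(tip_truncation = 0.1)
  m0 <- bill_metrics({s <- generate_surface(base); s$truth <- base; s})
  m1 <- bill_metrics({s <- generate_surface(more); s$truth <- more; s})
  expect_lt(abs(m1$arc_chord_ratio - m0$arc_chord_ratio) / m0$arc_chord_ratio,
            0.01)
  expect_lt(abs(m1$sharpness_ratio - m0$sharpness_ratio) /
              abs(m0$sharpness_ratio), 0.01)
  expect_lt(abs(m1$outer_surface_area - m0$outer_surface_area) /
              m0$outer_surface_area, 0.01)
})
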