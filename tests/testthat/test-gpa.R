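random_config <- function(k = 12, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  matrix(stats::rnorm(3 * k), k, 3)
}

test_that("centroid size matches its definition and scales linearly", {
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1), 0)
  expect_equal(centroid_size(sq), sqrt(2))
  set.seed(4)
  for (i in 1:10) {
    x <- random_config(15)
    brute <- sqrt(sum(apply(x, 1, function(p) sum((p - colMeans(x))^2))))
    expect_equal(centroid_size(x), brute, tolerance = 1e-12)
    expect_equal(centroid_size(2.7 * x), 2.7 * centroid_size(x),
                 tolerance = 1e-12)
  }
})

test_that("Procrustes superimposition removes similarity transforms exactly", {
  pop <- tiny_population(n = 3, seed = 21)
  cfgA <- specimen_configuration(pop[[1]], n = 20)
  set.seed(8)
  cfgB <- cfgA
  cfgB$coords <- sweep(1.7 * cfgA$coords %*% t(random_rotation()), 2,
                       c(3, -1, 2), "+")
  expect_lt(procrustes_distance(cfgA$coords, cfgB$coords), 1e-9)

  fit <- generalized_procrustes(list(cfgA, cfgB), slide = FALSE)
  expect_lt(sqrt(sum((fit$aligned[1, , ] - fit$aligned[2, , ])^2)), 1e-9)

  # n identical configurations: consensus equals each aligned copy
  fit3 <- generalized_procrustes(list(cfgA, cfgA, cfgA), slide = FALSE)
  for (i in 1:3)
    expect_lt(max(abs(fit3$aligned[i, , ] - fit3$consensus)), 1e-9)

  # aligned configurations have centroid 0 and unit centroid size
  for (i in 1:2) {
    expect_equal(colMeans(fit$aligned[i, , ]), rep(0, 3), tolerance = 1e-10)
    expect_equal(sqrt(sum(fit$aligned[i, , ]^2)), 1, tolerance = 1e-8)
  }
  expect_equal(fit$consensus, apply(fit$aligned, c(2, 3), mean),
               tolerance = 1e-9)

  expect_error(generalized_procrustes(list(cfgA)), "at least 2")
})

test_that("a 3-point toy case matches the closed-form Procrustes oracle", {
  set.seed(5)
  A <- random_config(3)
  B <- random_config(3)
  oa <- oracle_opa(A, B)
  # package route: rotate A onto B after centering/scaling
  A1 <- sweep(A, 2, colMeans(A)); A1 <- A1 / sqrt(sum(A1^2))
  B1 <- sweep(B, 2, colMeans(B)); B1 <- B1 / sqrt(sum(B1^2))
  R <- billmorph:::opa_rotation(A1, B1)
  expect_lt(max(abs(A1 %*% R - oa$aligned)), 1e-9)
  expect_equal(sqrt(sum((A1 %*% R - B1)^2)), oa$distance, tolerance = 1e-9)
})

test_that("semilandmark sliding projects onto tangents and never increases misfit", {
  pop <- tiny_population(n = 2, seed = 31)
  cfg <- specimen_configuration(pop[[1]], n = 15)
  coords <- cfg$coords

  # consensus on the tangent line: the point lands exactly on it
  semi <- cfg$semi_idx[3]
  tg <- coords[cfg$curve$nxt[semi], ] - coords[cfg$curve$prev[semi], ]
  tg <- tg / sqrt(sum(tg^2))
  cons <- coords
  step <- 0.3 * min(sqrt(sum((coords[semi, ] - coords[cfg$curve$prev[semi], ])^2)),
                    sqrt(sum((coords[semi, ] - coords[cfg$curve$nxt[semi], ])^2)))
  cons[semi, ] <- coords[semi, ] + step * tg
  slid <- slide_semilandmarks(coords, cons, cfg, reproject = FALSE)
  expect_equal(slid[semi, ], cons[semi, ], tolerance = 1e-10)

  # residual orthogonal to the tangent: no displacement
  ortho <- c(-tg[2], tg[1], 0); ortho <- ortho / sqrt(sum(ortho^2))
  cons2 <- coords
  cons2[semi, ] <- coords[semi, ] + 0.05 * ortho
  slid2 <- slide_semilandmarks(coords, cons2, cfg, reproject = FALSE)
  expect_equal(slid2[semi, ], coords[semi, ], tolerance = 1e-10)

  # monotonicity: sliding does not increase summed squared misfit
  set.seed(12)
  for (rep in 1:100) {
    jit <- coords + matrix(stats::rnorm(length(coords), 0, 0.05), ncol = 3)
    cons3 <- coords + matrix(stats::rnorm(length(coords), 0, 0.05), ncol = 3)
    before <- sum((jit[cfg$semi_idx, ] - cons3[cfg$semi_idx, ])^2)
    slid3 <- slide_semilandmarks(jit, cons3, cfg, reproject = FALSE)
    after <- sum((slid3[cfg$semi_idx, ] - cons3[cfg$semi_idx, ])^2)
    expect_lte(after, before + 1e-12)
  }
})

test_that("GPA output is invariant to arbitrary input similarity transforms", {
  pop <- tiny_population(n = 3, seed = 17)
  cfgs <- lapply(pop, specimen_configuration, n = 25)
  fit <- generalized_procrustes(cfgs)
  set.seed(23)
  moved <- lapply(pop, function(s) {
    transform_specimen(s, random_rotation(), stats::rnorm(3, 0, 10),
                       exp(stats::rnorm(1)))
  })
  fit2 <- generalized_procrustes(lapply(moved, specimen_configuration, n = 25))
  expect_lt(max(abs(fit$aligned - fit2$aligned)), 1e-8)

  # residual sum of squares is non-increasing across outer iterations
  expect_true(all(diff(fit$rss_trace) <= 1e-10))
})

test_that("bilateral symmetry decomposition isolates asymmetry", {
  pop <- sample_population(population_spec(n_per_group = 2, seed = 3,
                                           landmark_jitter_sd = 0),
                           make_surface = FALSE)
  cfgs <- lapply(pop, specimen_configuration, n = 20)
  fit <- generalized_procrustes(cfgs, slide = FALSE)
  dec <- bilateral_symmetry(fit)

  # perfectly symmetric configurations: zero asymmetric component
  expect_lt(max(abs(dec$asymmetric)), 1e-10)
  # decomposition reconstructs the aligned coordinates
  expect_equal(dec$symmetric + dec$asymmetric, fit$aligned, tolerance = 1e-12)

  # symmetric component is a fixed point of the mirror-relabel map
  cfg <- fit$structure
  perm <- ifelse(is.na(cfg$pair), seq_along(cfg$pair), cfg$pair)
  s1 <- dec$symmetric[1, , ]
  m <- s1[perm, ]; m[, 2] <- -m[, 2]
  m <- m %*% billmorph:::opa_rotation(sweep(m, 2, colMeans(m)), s1)
  expect_lt(max(abs(m - s1)), 1e-9)

  # a planted left-only displacement splits evenly between components
  delta <- 0.004
  cfgs2 <- cfgs
  lef <- which(cfgs2[[1]]$curve$label == "left_tomium")[5]
  cfgs2[[1]]$coords[lef, 3] <- cfgs2[[1]]$coords[lef, 3] + delta
  fit2 <- generalized_procrustes(cfgs2, slide = FALSE)
  dec2 <- bilateral_symmetry(fit2)
  scale1 <- centroid_size(cfgs2[[1]]$coords)   # aligned shapes are unit-size
  asym_mag <- sqrt(sum(dec2$asymmetric[1, , ]^2)) * scale1
  # the displaced point and its mirror partner each carry ~ delta/2
  expect_equal(asym_mag, delta / sqrt(2), tolerance = 0.05)
})

test_that("shape PCA spans the variation with orthonormal sign-fixed axes", {
  # data varying along a single direction: PC1 explains everything
  set.seed(6)
  base <- random_config(10)
  dir <- matrix(stats::rnorm(30), 10, 3)
  X <- array(0, c(8, 10, 3))
  for (i in 1:8) X[i, , ] <- base + stats::rnorm(1, 0, 0.3) * dir
  ss <- shape_pca(X)
  expect_equal(ss$pct_variance[1], 100, tolerance = 1e-8)
  expect_equal(sum(ss$pct_variance), 100, tolerance = 1e-6)
  expect_true(all(ss$eigenvalues >= 0))

  # reconstruction from scores and loadings
  Y <- flatten_coords(X)
  rec <- sweep(ss$scores %*% t(ss$loadings), 2, ss$center, "+")
  expect_lt(max(abs(rec - Y)), 1e-9)
  # orthonormal loadings
  expect_equal(crossprod(ss$loadings), diag(ncol(ss$loadings)),
               tolerance = 1e-10)

  # planted dominant mode: PC1 recovers the injected direction
  set.seed(9)
  X2 <- array(0, c(20, 10, 3))
  for (i in 1:20) {
    X2[i, , ] <- base + (if (i <= 10) -1 else 1) * 0.5 * dir +
      matrix(stats::rnorm(30, 0, 0.02), 10, 3)
  }
  ss2 <- shape_pca(X2)
  v <- as.vector(flatten_coords(array(dir, c(1, 10, 3))))
  r <- abs(stats::cor(ss2$loadings[, 1], v))
  expect_gt(r, 0.99)
})
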