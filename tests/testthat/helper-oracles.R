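# Independent oracles used across the suite. Each re-derives its quantity
# from first principles (closed forms, bisection, quadrature, enumeration)
# without calling the code paths it checks.

# Invert the arc:chord relation ratio = theta / (2 sin(theta/2)) by plain
# bisection on (0, 2*pi).
oracle_arc_angle <- function(ratio, tol = 1e-12) {
  f <- function(th) th / (2 * sin(th / 2)) - ratio
  lo <- 1e-9; hi <- 2 * pi - 1e-9
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# Independent evaluation of the parametric bill surface (same design
# formulas, written out directly): culmen-following circular-arc sweep of
# the half-ellipse-pair section scaled by (s/L)^p.
oracle_bill_point <- function(params, s, phi, dorsal_frac = 0.82) {
  L <- params$arc_length
  theta <- if (params$arc_chord_ratio <= 1 + 1e-12) 0 else
    oracle_arc_angle(params$arc_chord_ratio)
  if (theta == 0) {
    C <- c(s, 0, 0); nor <- c(0, 0, 1)
  } else {
    R <- L / theta
    chord <- 2 * R * sin(theta / 2)
    ang <- -theta / 2 + theta * s / L
    C <- c(chord / 2 + R * sin(ang), 0, R * cos(ang) - R * cos(theta / 2))
    nor <- c(sin(ang), 0, cos(ang))
  }
  a <- params$base_width / 2
  bd <- dorsal_frac * params$base_height
  bv <- (1 - dorsal_frac) * params$base_height
  b <- if (sin(phi) >= 0) bd else bv
  r <- a * b / sqrt((b * cos(phi))^2 + (a * sin(phi))^2)
  g <- (s / L)^params$taper_exponent
  C + g * r * cos(phi) * c(0, 1, 0) + g * (r * sin(phi) - bd) * nor
}

# Lateral surface area of the parametric bill over s in [s0, L] by composite
# Simpson quadrature of |dP/ds x dP/dphi| (partials by central differences).
oracle_bill_area <- function(params, s0, ns = 301, nphi = 257) {
  L <- params$arc_length
  svals <- seq(s0, L, length.out = ns)
  pvals <- seq(0, 2 * pi, length.out = nphi)
  hs <- 1e-5; hp <- 1e-5
  integrand <- matrix(0, ns, nphi)
  for (i in seq_len(ns)) {
    for (j in seq_len(nphi)) {
      dPs <- (oracle_bill_point(params, svals[i] + hs, pvals[j]) -
              oracle_bill_point(params, svals[i] - hs, pvals[j])) / (2 * hs)
      dPp <- (oracle_bill_point(params, svals[i], pvals[j] + hp) -
              oracle_bill_point(params, svals[i], pvals[j] - hp)) / (2 * hp)
      cr <- c(dPs[2] * dPp[3] - dPs[3] * dPp[2],
              dPs[3] * dPp[1] - dPs[1] * dPp[3],
              dPs[1] * dPp[2] - dPs[2] * dPp[1])
      integrand[i, j] <- sqrt(sum(cr^2))
    }
  }
  simpson_w <- function(n) {
    w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1; w / 3
  }
  ws <- simpson_w(ns) * (svals[2] - svals[1])
  wp <- simpson_w(nphi) * (pvals[2] - pvals[1])
  as.numeric(t(ws) %*% integrand %*% wp)
}

# Solid volume of the parametric bill over s in [s0, L]: cross-section areas
# with the curved-sweep metric factor (1 + d/R), d the local dorsal offset
# from the culmen arc.
oracle_bill_volume <- function(params, s0, core_only = FALSE,
                               min_core_frac = 0.25, dorsal_frac = 0.82,
                               ns = 241, nphi = 241) {
  L <- params$arc_length
  theta <- if (params$arc_chord_ratio <= 1 + 1e-12) 0 else
    oracle_arc_angle(params$arc_chord_ratio)
  R <- if (theta == 0) Inf else L / theta
  a <- params$base_width / 2
  bd <- dorsal_frac * params$base_height
  bv <- (1 - dorsal_frac) * params$base_height
  t <- params$shell_thickness
  svals <- seq(s0, L, length.out = ns)
  pvals <- seq(0, 2 * pi, length.out = nphi)
  b <- ifelse(sin(pvals) >= 0, bd, bv)
  rb <- a * b / sqrt((b * cos(pvals))^2 + (a * sin(pvals))^2)
  simpson_w <- function(n) {
    w <- rep(c(2, 4), length.out = n); w[1] <- 1; w[n] <- 1; w / 3
  }
  ws <- simpson_w(ns) * (svals[2] - svals[1])
  wp <- simpson_w(nphi) * (pvals[2] - pvals[1])
  total <- 0
  for (i in seq_len(ns)) {
    g <- (svals[i] / L)^params$taper_exponent
    rphys <- g * rb
    if (core_only) rphys <- pmax(rphys - t, min_core_frac * rphys)
    # area element in polar coords about the star center, with the sweep
    # metric factor 1 + d/R, d = rho sin(phi) - bd * g (dorsal offset)
    # integrate rho from 0 to rphys: int rho (1 + (rho sin phi - bd g)/R) drho
    term <- rphys^2 / 2 * (1 - bd * g / R) + rphys^3 * sin(pvals) / (3 * R)
    total <- total + ws[i] * sum(wp * term)
  }
  total
}

# Closed-form ordinary Procrustes alignment of A onto B (centered, unit
# size, SVD rotation with the proper-rotation correction).
oracle_opa <- function(A, B) {
  A <- sweep(A, 2, colMeans(A)); A <- A / sqrt(sum(A^2))
  B <- sweep(B, 2, colMeans(B)); B <- B / sqrt(sum(B^2))
  sv <- svd(t(A) %*% B)
  R <- sv$u %*% t(sv$v)
  if (det(R) < 0) {
    u <- sv$u; u[, 3] <- -u[, 3]
    R <- u %*% t(sv$v)
  }
  list(aligned = A %*% R, target = B,
       distance = sqrt(sum((A %*% R - B)^2)))
}

# Exhaustive-permutation p-value for a single-factor multivariate ANOVA on
# response Y (rows exchangeable): enumerates every row permutation.
oracle_perm_anova_p <- function(Y, groups) {
  n <- nrow(Y)
  stopifnot(n <= 8)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(Yc^2)
  fstat <- function(Ymat) {
    sse <- 0
    for (gl in unique(groups)) {
      idx <- which(groups == gl)
      m <- colMeans(Ymat[idx, , drop = FALSE])
      sse <- sse + length(idx) * sum(m^2)
    }
    df1 <- length(unique(groups)) - 1
    df2 <- n - length(unique(groups))
    (sse / df1) / ((ss_tot - sse) / df2)
  }
  perms <- gtools_permutations(n)
  obs <- fstat(Yc)
  mean(apply(perms, 1, function(p) fstat(Yc[p, , drop = FALSE])) >= obs - 1e-12)
}

# all permutations of 1..n (small n only)
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- gtools_permutations(n - 1)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (i in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- setdiff(seq_len(n), i)[sub[r, ]]
      out[row, ] <- c(i, rest)
      row <- row + 1L
    }
  }
  out
}

# Random proper rotation matrix.
random_rotation <- function() {
  R <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}
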