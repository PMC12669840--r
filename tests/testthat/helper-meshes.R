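# Simple closed surfaces of revolution used as analytic test geometries.
make_revolution_mesh <- function(radius_fun, L, nx = 80, nphi = 48,
                                 closed = TRUE) {
  xs <- seq(0, L, length.out = nx)
  phi <- 2 * pi * (0:(nphi - 1)) / nphi
  verts <- do.call(rbind, lapply(seq_along(xs), function(i) {
    r <- max(radius_fun(xs[i]), 1e-9)
    cbind(xs[i], r * cos(phi), r * sin(phi))
  }))
  vid <- function(i, j) (i - 1) * nphi + j
  i <- rep(1:(nx - 1), each = nphi)
  j <- rep(1:nphi, nx - 1)
  jp <- j %% nphi + 1
  faces <- rbind(cbind(vid(i, j), vid(i + 1, j), vid(i + 1, jp)),
                 cbind(vid(i, j), vid(i + 1, jp), vid(i, jp)))
  if (closed) {
    c0 <- nrow(verts) + 1; c1 <- nrow(verts) + 2
    verts <- rbind(verts, c(0, 0, 0), c(L, 0, 0))
    jj <- 1:nphi; jjp <- jj %% nphi + 1
    faces <- rbind(faces, cbind(c0, vid(1, jjp), vid(1, jj)),
                   cbind(c1, vid(nx, jj), vid(nx, jjp)))
  }
  list(vertices = verts, faces = faces)
}

make_cone_mesh <- function(half_angle_deg = 26.5650511770780,
                           L = 4, nx = 120, nphi = 64) {
  k <- tan(half_angle_deg * pi / 180)
  make_revolution_mesh(function(x) k * x, L, nx, nphi)
}

make_cylinder_mesh <- function(r = 1, L = 4, nx = 60, nphi = 48,
                               closed = FALSE) {
  # open by default: the lateral (outer) surface is what sharpness measures
  make_revolution_mesh(function(x) r, L, nx, nphi, closed = closed)
}

# small dimorphic study population shared by several tests
tiny_population <- function(n = 4, seed = 11, surface = FALSE) {
  sample_population(population_spec(n_per_group = n, seed = seed),
                    make_surface = surface, n_s = 60L, n_phi = 16L,
                    n_contour = 60L)
}
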