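# Analytic fixture meshes built in code (no binary fixtures).

cube_mesh <- function(side = 1) {
  v <- as.matrix(expand.grid(c(0, side), c(0, side), c(0, side)))
  colnames(v) <- NULL
  # 12 triangles, outward oriented
  f <- rbind(
    c(1, 3, 2), c(2, 3, 4),     # z = 0
    c(5, 6, 7), c(6, 8, 7),     # z = side
    c(1, 2, 5), c(2, 6, 5),     # y = 0
    c(3, 7, 4), c(4, 7, 8),     # y = side
    c(1, 5, 3), c(3, 5, 7),     # x = 0
    c(2, 4, 6), c(4, 8, 6))     # x = side
  triangle_surface(v, f)
}

# Geodesic sphere by subdividing an icosahedron and reprojecting.
sphere_mesh <- function(radius = 10, subdivisions = 3, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  s <- triangle_surface(v, f, clean = FALSE)
  for (i in seq_len(subdivisions)) s <- vesselssm:::subdivide_midpoint(s)
  vv <- s$vertices
  vv <- vv / vesselssm:::rownorm(vv) * radius
  s$vertices <- sweep(vv, 2L, -center)
  s
}

# Open cylinder (tube) along z from 0 to L, optional radius profile r(z).
tube_mesh <- function(radius = 10, length = 100, n_theta = 24, n_z = 40,
                      radius_fun = NULL) {
  z <- seq(0, length, length.out = n_z + 1L)
  th <- seq(0, 2 * pi, length.out = n_theta + 1L)[-(n_theta + 1L)]
  r <- if (is.null(radius_fun)) rep(radius, length(z)) else radius_fun(z)
  v <- do.call(rbind, lapply(seq_along(z), function(i)
    cbind(r[i] * cos(th), r[i] * sin(th), z[i])))
  f <- NULL
  idx <- function(i, j) (i - 1L) * n_theta + ((j - 1L) %% n_theta) + 1L
  for (i in seq_len(n_z)) {
    for (j in seq_len(n_theta)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cpt <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      f <- rbind(f, c(a, b, d), c(a, d, cpt))
    }
  }
  triangle_surface(v, f)
}

# Half-torus tube: centreline is a semicircle of radius R in the x-z plane.
half_torus_mesh <- function(R = 50, r = 8, n_u = 40, n_v = 16) {
  u <- seq(0, pi, length.out = n_u + 1L)
  th <- seq(0, 2 * pi, length.out = n_v + 1L)[-(n_v + 1L)]
  v <- do.call(rbind, lapply(seq_along(u), function(i) {
    cu <- c(R * cos(u[i]), 0, R * sin(u[i]))
    e1 <- c(cos(u[i]), 0, sin(u[i]))
    e2 <- c(0, 1, 0)
    cbind(cu[1] + r * (cos(th) * e1[1] + sin(th) * e2[1]),
          cu[2] + r * (cos(th) * e1[2] + sin(th) * e2[2]),
          cu[3] + r * (cos(th) * e1[3] + sin(th) * e2[3]))
  }))
  f <- NULL
  idx <- function(i, j) (i - 1L) * n_v + ((j - 1L) %% n_v) + 1L
  for (i in seq_len(n_u)) {
    for (j in seq_len(n_v)) {
      a <- idx(i, j); b <- idx(i, j + 1L); cpt <- idx(i + 1L, j); d <- idx(i + 1L, j + 1L)
      f <- rbind(f, c(a, b, d), c(a, d, cpt))
    }
  }
  triangle_surface(v, f)
}

random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}
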