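# Independent brute-force oracle: explicit double loop over face pairs.
brute_currents_inner <- function(a, b) {
  acc <- 0
  for (f in seq_len(nrow(a$centers))) {
    for (g in seq_len(nrow(b$centers))) {
      d2 <- sum((a$centers[f, ] - b$centers[g, ])^2)
      acc <- acc + exp(-d2 / a$lambda_w^2) * sum(a$normals[f, ] * b$normals[g, ])
    }
  }
  acc
}

test_that("currents representation has analytic centers and normals", {
  tri <- triangle_surface(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)),
                          rbind(c(1, 2, 3)), clean = FALSE)
  cr <- to_currents(tri, 5)
  expect_equal(as.vector(cr$centers), c(1 / 3, 1 / 3, 0))
  expect_equal(as.vector(cr$normals), c(0, 0, 0.5))
  # |normal| equals the triangle area
  expect_equal(vesselssm:::rownorm(cr$normals), 0.5)
  # reversing orientation negates the normals
  tri2 <- triangle_surface(tri$vertices, rbind(c(1, 3, 2)), clean = FALSE)
  expect_equal(to_currents(tri2, 5)$normals, -cr$normals)
  # closed, consistently oriented mesh: total current vanishes
  cb <- cube_mesh(2)
  tot <- colSums(to_currents(cb, 5)$normals)
  expect_lt(sqrt(sum(tot^2)), 1e-6 * surface_measures(cb)$area)
})

test_that("currents inner products follow the Gaussian-kernel formulas", {
  tri <- triangle_surface(rbind(c(0, 0, 0), c(2, 0, 0), c(0, 2, 0)),
                          rbind(c(1, 2, 3)), clean = FALSE)
  a <- to_currents(tri, 4)
  expect_equal(currents_inner(a, a), 2^2)         # area 2, zero distance
  # identical parallel triangle shifted by d: exp(-d^2/lambda^2) * area^2
  trib <- tri
  trib$vertices[, 3] <- 3
  b <- to_currents(trib, 4)
  expect_equal(currents_inner(a, b), exp(-9 / 16) * 4)
  # orientation flip: <s, -s> = -||s||^2
  flip <- triangle_surface(tri$vertices, rbind(c(1, 3, 2)), clean = FALSE)
  expect_equal(currents_inner(a, to_currents(flip, 4)), -currents_inner(a, a))
  # kernel-width mismatch errors
  expect_error(currents_inner(a, to_currents(tri, 7)), "mismatch")
})

test_that("currents distance is a distance and shrinks as lambda_w grows", {
  sp <- sphere_mesh(8, 2)
  a <- to_currents(sp, 10)
  expect_lt(currents_distance2(a, a), 1e-9 * currents_inner(a, a))
  # monotone growth with translation 0 -> 5 -> 10 mm
  d_at <- function(dx) {
    sp2 <- apply_rigid(sp, diag(3), c(dx, 0, 0))
    currents_distance2(a, to_currents(sp2, 10))
  }
  d <- vapply(c(0, 5, 10), d_at, numeric(1))
  expect_true(all(diff(d) > 0))
  # lambda_w -> infinity: total currents of closed meshes vanish
  big <- to_currents(sp, 1e6)
  sp3 <- apply_rigid(sp, diag(3), c(4, 0, 0))
  expect_lt(currents_distance2(big, to_currents(sp3, 1e6)),
            1e-6 * currents_inner(big, big))
})

test_that("accelerated inner product matches the brute-force double sum", {
  set.seed(1)
  sp <- sphere_mesh(8, 2)                       # 320 faces
  tube <- tube_mesh(6, 30, n_theta = 10, n_z = 10)
  a <- to_currents(sp, 12)
  b <- to_currents(tube, 12)
  for (pair in list(list(a, a), list(a, b), list(b, b))) {
    got <- currents_inner(pair[[1]], pair[[2]])
    want <- brute_currents_inner(pair[[1]], pair[[2]])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("currents Gram matrices are PSD and rigid-invariant", {
  set.seed(2)
  shapes <- list(sphere_mesh(8, 1), sphere_mesh(10, 1),
                 tube_mesh(6, 30, n_theta = 8, n_z = 6), cube_mesh(10))
  G <- currents_gram(shapes, 12)
  expect_equal(G, t(G))
  ev <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev >= -1e-8 * sum(diag(G))))
  # simultaneous rigid motion of both shapes preserves the inner product
  R <- random_rotation()
  t_ <- rnorm(3, sd = 20)
  ip0 <- currents_inner(to_currents(shapes[[1]], 12), to_currents(shapes[[3]], 12))
  ip1 <- currents_inner(to_currents(apply_rigid(shapes[[1]], R, t_), 12),
                        to_currents(apply_rigid(shapes[[3]], R, t_), 12))
  expect_equal(ip1, ip0, tolerance = 1e-8)
})

test_that("refining the mesh barely changes the current norm at coarse lambda_w", {
  sp <- sphere_mesh(8, 1)
  # pure midpoint subdivision: the piecewise-linear surface is unchanged
  fine <- vesselssm:::subdivide_midpoint(sp)
  n0 <- currents_inner(to_currents(sp, 25), to_currents(sp, 25))
  n1 <- currents_inner(to_currents(fine, 25), to_currents(fine, 25))
  expect_lt(abs(n1 - n0) / n0, 0.01)
})
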