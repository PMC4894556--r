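test_that("centreline of a straight cylinder is the axis", {
  cy <- tube_mesh(10, 100, n_theta = 24, n_z = 40)
  cl <- extract_centreline(cy)
  expect_lt(max(sqrt(rowSums(cl$points[, 1:2]^2))), 0.2)
  cd <- centreline_descriptors(cl)
  expect_equal(cd$L_CL, 100, tolerance = 0.02)
  expect_equal(cd$To_CL, 0, tolerance = 0.01)
  expect_lt(cd$C_med, 0.001)
  # closed mesh: non-tubular error
  expect_error(extract_centreline(sphere_mesh(10, 2)), "non-tubular")
})

test_that("centreline of a half-torus has the analytic arc length", {
  ht <- half_torus_mesh(50, 8)
  cl <- extract_centreline(ht)
  cd <- centreline_descriptors(cl)
  expect_equal(cd$L_CL, pi * 50, tolerance = 0.02)
})

test_that("centreline descriptors match closed-form circle geometry", {
  # analytic straight segment
  straight <- structure(list(points = cbind(seq(0, 100, 2), 0, 0)),
                        class = "centreline")
  cd0 <- centreline_descriptors(straight)
  expect_equal(cd0$L_CL, 100)
  expect_equal(cd0$To_CL, 0)
  expect_equal(cd0$C_med, 0)
  # analytic semicircle of radius 50
  th <- seq(0, pi, length.out = 120)
  semi <- structure(list(points = cbind(50 * cos(th), 50 * sin(th), 0)),
                    class = "centreline")
  cd <- centreline_descriptors(semi)
  expect_equal(cd$L_CL, 50 * pi, tolerance = 0.01)
  expect_equal(cd$To_CL, pi / 2 - 1, tolerance = 0.01)
  expect_equal(cd$C_med, 0.02, tolerance = 0.02)
  # similarity scaling: lengths double, curvature halves, tortuosity fixed
  semi2 <- structure(list(points = semi$points * 2), class = "centreline")
  cd2 <- centreline_descriptors(semi2)
  expect_equal(cd2$L_CL, 2 * cd$L_CL)
  expect_equal(cd2$C_med, cd$C_med / 2)
  expect_equal(cd2$To_CL, cd$To_CL)
  expect_error(centreline_descriptors(structure(
    list(points = cbind(c(0, 1, 0), c(0, 1, 0), 0)), class = "centreline")),
    "oincident")
})

test_that("equivalent-area diameters track constant, narrowed and tapered tubes", {
  cy <- tube_mesh(10, 100, n_theta = 24, n_z = 40)
  cl <- extract_centreline(cy)
  d <- suppressWarnings(diameters(cy, cl))
  expect_equal(d$D_max, 20, tolerance = 0.02)
  expect_equal(d$D_min, 20, tolerance = 0.02)
  expect_equal(d$D_med, 20, tolerance = 0.02)
  # Gaussian narrowing to 60 % radius at mid-length
  nar <- tube_mesh(10, 100, n_theta = 24, n_z = 50,
                   radius_fun = function(z)
                     10 * (1 - 0.4 * exp(-(z - 50)^2 / (2 * 6^2))))
  cln <- extract_centreline(nar)
  dn <- suppressWarnings(diameters(nar, cln))
  expect_equal(dn$D_min, 12, tolerance = 0.03)
  imin <- which.min(dn$profile$diameter)
  expect_equal(dn$profile$arc_fraction[imin], 0.5, tolerance = 0.05)
  # linear taper 20 -> 10 mm: mid-level diameter ~ 15 mm
  tap <- tube_mesh(10, 100, n_theta = 24, n_z = 40,
                   radius_fun = function(z) 10 - 0.05 * z)
  clt <- extract_centreline(tap)
  dt <- suppressWarnings(diameters(tap, clt, level_fractions = c(mid = 0.5)))
  expect_equal(unname(dt$levels[["mid"]]), 15, tolerance = 0.03)
  expect_error(diameters(cy, cl, level_fractions = c(bad = 1.2)), "level")
})

test_that("arch height and width recover the semi-ellipse construction", {
  # analytic: semi-ellipse semi-axes (T/2, A) = (30, 40) plus straight limbs
  th <- seq(0, pi, length.out = 200)
  ell <- cbind(30 * cos(th), 0, 40 * sin(th))
  P <- rbind(cbind(30, 0, seq(-30, -0.5, 0.5)), ell,
             cbind(-30, 0, seq(-0.5, -30, -0.5)))
  cl <- structure(list(points = P,
                       arc_length = c(0, cumsum(sqrt(rowSums(diff(P)^2))))),
                  class = "centreline")
  aw <- arch_height_width(cl)
  expect_equal(aw$A, 40, tolerance = 0.02)
  expect_equal(aw$T, 60, tolerance = 0.02)
  expect_equal(aw$ratio_A_T, aw$A / aw$T, tolerance = 1e-12)
  # straight tube: no apex
  cyl <- extract_centreline(tube_mesh(10, 100))
  expect_error(arch_height_width(cyl), "no apex")
  # rigid rotation leaves (A, T) unchanged
  set.seed(41)
  arch <- generate_arch(arch_params(seed = 41))
  R <- random_rotation()
  aw1 <- arch_height_width(extract_centreline(arch))
  aw2 <- arch_height_width(extract_centreline(apply_rigid(arch, R, c(5, -9, 4))))
  expect_equal(aw2$A, aw1$A, tolerance = 0.01)
  expect_equal(aw2$T, aw1$T, tolerance = 0.01)
})

test_that("descriptor assembly is consistent and BSA indexing divides", {
  arch <- generate_arch(arch_params(noise_sd = 0, seed = 42))
  d <- suppressWarnings(compute_descriptors(arch, bsa = 2))
  expect_equal(d$ratio_A_surf_V, d$A_surf / d$V, tolerance = 1e-9)
  expect_equal(d$iL_CL, d$L_CL / 2, tolerance = 1e-12)
  expect_equal(d$iV, d$V / 2, tolerance = 1e-12)
  expect_equal(d$iD_med, d$D_med / 2, tolerance = 1e-12)
  expect_true(d$D_min <= d$D_med && d$D_med <= d$D_max)
  expect_gte(d$To_CL, 0)
  # without BSA no indexed fields
  d2 <- suppressWarnings(compute_descriptors(arch))
  expect_null(d2$iL_CL)
})

test_that("descriptors scale correctly under similarity transforms", {
  arch <- generate_arch(arch_params(noise_sd = 0, seed = 43,
                                    tortuosity_amp = 0))
  d1 <- suppressWarnings(compute_descriptors(arch))
  big <- arch
  big$vertices <- big$vertices * 2
  d2 <- suppressWarnings(compute_descriptors(big))
  expect_equal(d2$L_CL, 2 * d1$L_CL, tolerance = 0.02)
  expect_equal(d2$D_med, 2 * d1$D_med, tolerance = 0.02)
  expect_equal(d2$A_surf, 4 * d1$A_surf, tolerance = 0.01)
  expect_equal(d2$V, 8 * d1$V, tolerance = 0.01)
  expect_equal(d2$C_med, d1$C_med / 2, tolerance = 0.05)
  expect_equal(d2$To_CL, d1$To_CL, tolerance = 0.05)
})
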