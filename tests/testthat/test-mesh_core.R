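test_that("mesh formats round-trip and STL facets merge shared vertices", {
  cb <- cube_mesh(1)
  for (ext in c("vtk", "ply", "obj", "stl")) {
    tf <- tempfile(fileext = paste0(".", ext))
    write_surface(cb, tf)
    back <- read_surface(tf)
    expect_equal(nrow(back$vertices), 8L, info = ext)
    expect_equal(nrow(back$faces), 12L, info = ext)
    expect_equal(surface_measures(back)$area, 6, tolerance = 1e-6, info = ext)
    # same vertex multiset up to reindexing
    key <- function(v) sort(apply(round(v, 6), 1, paste, collapse = "/"))
    expect_identical(key(back$vertices), key(cb$vertices), info = ext)
  }
  # binary STL (duplicated vertices per facet get merged into a closed cube)
  tfb <- tempfile(fileext = ".stl")
  write_surface(cb, tfb, binary = TRUE)
  backb <- read_surface(tfb)
  expect_equal(nrow(backb$vertices), 8L)
  expect_true(vesselssm:::is_closed_surface(backb))
})

test_that("non-triangular faces are rejected", {
  tf <- tempfile(fileext = ".obj")
  writeLines(c("v 0 0 0", "v 1 0 0", "v 1 1 0", "v 0 1 0",
               "f 1 2 3 4"), tf)
  expect_error(read_surface(tf), "non-triangular")
})

test_that("surface measures match analytic area and volume", {
  cb <- cube_mesh(1)
  m <- surface_measures(cb)
  expect_equal(m$area, 6)
  expect_equal(m$volume, 1)
  sp <- sphere_mesh(10, 3)
  ms <- surface_measures(sp)
  expect_equal(ms$area, 4 * pi * 100, tolerance = 0.01)
  expect_equal(ms$volume, 4 / 3 * pi * 1000, tolerance = 0.01)
  cy <- tube_mesh(10, 100)
  mc <- surface_measures(cy)
  expect_equal(mc$area, 2 * pi * 10 * 100, tolerance = 0.01)
  expect_true(is.na(mc$volume))
  expect_false(mc$closed)
})

test_that("area and volume are rigid-invariant and origin-independent", {
  set.seed(42)
  sp <- sphere_mesh(7, 2, center = c(3, -2, 8))
  m0 <- surface_measures(sp)
  for (i in 1:3) {
    R <- random_rotation()
    t_ <- rnorm(3, sd = 50)
    m1 <- surface_measures(apply_rigid(sp, R, t_))
    expect_equal(m1$area, m0$area, tolerance = 1e-9)
    expect_equal(m1$volume, m0$volume, tolerance = 1e-9)
  }
  # divergence-theorem volume independent of origin (pure translation)
  far <- apply_rigid(sp, diag(3), c(1e4, -2e4, 3e3))
  expect_equal(surface_measures(far)$volume, m0$volume, tolerance = 1e-9)
})

test_that("surface distance is symmetric and matches analytic gaps", {
  sq1 <- triangle_surface(cbind(c(0, 1, 0, 1), c(0, 0, 1, 1), 0),
                          rbind(c(1, 2, 3), c(2, 4, 3)))
  sq2 <- sq1
  sq2$vertices[, 3] <- 3
  d <- surface_distance(sq1, sq2)
  expect_equal(d$max, 3)
  expect_equal(d$mean, 3)
  sp <- sphere_mesh(10, 3)
  expect_equal(surface_distance(sp, sp)$max, 0)
  d2 <- surface_distance(sp, sphere_mesh(11, 3))
  expect_equal(d2$max, 1, tolerance = 0.02)
  expect_equal(d2$mean, 1, tolerance = 0.02)
  # symmetry of the implementation
  a <- tube_mesh(8, 40, n_theta = 10, n_z = 8)
  b <- apply_rigid(a, diag(3), c(2, 1, 0))
  expect_equal(surface_distance(a, b)$max, surface_distance(b, a)$max)
})

test_that("re-meshing hits the target density and smoothing denoises", {
  sp <- sphere_mesh(10, 3)               # ~0.1 faces/mm^2... actually 1280 faces
  d0 <- nrow(sp$faces) / surface_measures(sp)$area
  lo <- remesh_and_smooth(sp, d0 * 0.2, iterations = 0)
  got <- nrow(lo$faces) / surface_measures(lo)$area
  expect_lt(abs(got - d0 * 0.2) / (d0 * 0.2), 0.1)
  # no-op: matching density and zero smoothing leaves the area alone
  same <- remesh_and_smooth(sp, d0, iterations = 0)
  expect_lt(abs(surface_measures(same)$area - surface_measures(sp)$area) /
              surface_measures(sp)$area, 0.005)
  # smoothing a jittered sphere moves it back toward the ideal sphere
  set.seed(7)
  noisy <- sp
  noisy$vertices <- noisy$vertices + matrix(rnorm(length(noisy$vertices), sd = 0.2),
                                            ncol = 3)
  err <- function(s) max(abs(vesselssm:::rownorm(s$vertices) - 10))
  smoothed <- vesselssm:::taubin_smooth(noisy, passband = 0.1, iterations = 30)
  expect_lt(err(smoothed), err(noisy))
  # non-shrinking: area change of the clean sphere under smoothing <= 1 %
  sm <- vesselssm:::taubin_smooth(sp, passband = 0.1, iterations = 30)
  expect_lt(abs(surface_measures(sm)$area - surface_measures(sp)$area) /
              surface_measures(sp)$area, 0.01)
})

test_that("mesh density selection picks the coarsest density within tolerance", {
  sp <- sphere_mesh(10, 3)
  scan <- select_mesh_density(sp, c(0.1, 0.3, 0.75, 1.5), tolerance = 0.005)
  expect_s3_class(scan, "density_scan")
  # the selected density is the first that passes; all coarser ones fail
  pass <- scan$deviations <= scan$tolerance
  expect_true(pass[match(scan$selected_density, scan$densities)])
  expect_true(all(!pass[scan$densities < scan$selected_density]))
  # minimality: if the lowest density passes it is selected
  scan2 <- select_mesh_density(sp, c(0.75, 1.5), tolerance = 0.01)
  expect_equal(scan2$selected_density, 0.75)
  # failure path lists the best deviation achieved
  expect_error(select_mesh_density(sp, c(0.05, 0.1), tolerance = 1e-5),
               "tolerance")
})
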