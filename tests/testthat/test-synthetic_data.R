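test_that("arch generation is deterministic under a fixed seed", {
  s1 <- generate_arch(arch_params(seed = 50))
  s2 <- generate_arch(arch_params(seed = 50))
  expect_identical(s1$vertices, s2$vertices)
  expect_identical(s1$faces, s2$faces)
  s3 <- generate_arch(arch_params(seed = 51))
  expect_false(identical(s1$vertices, s3$vertices))
  # exactly two boundary loops (open tube)
  expect_length(vesselssm:::boundary_loops(s1), 2L)
})

test_that("clean geometry is recovered by morphometry within 3 %", {
  p <- arch_params(noise_sd = 0, tortuosity_amp = 0, seed = 52)
  p$multipliers <- numeric(0)
  p$positions <- numeric(0)
  s <- generate_arch(p)
  gt <- attr(s, "ground_truth")
  d <- suppressWarnings(compute_descriptors(s, config = list(step_factor = 0.35)))
  expect_equal(d$A, gt$A, tolerance = 0.03)
  expect_equal(d$T, gt$T, tolerance = 0.03)
  expect_equal(d$D_med, gt$D_base, tolerance = 0.03)
  expect_equal(d$L_CL, gt$L_tot, tolerance = 0.03)
})

test_that("an isthmus narrowing multiplier is measured as D_min", {
  p <- arch_params(noise_sd = 0, tortuosity_amp = 0, seed = 53,
                   multipliers = c(isth = 0.6), positions = c(isth = 0.6),
                   bump_width = 0.05)
  s <- generate_arch(p)
  d <- suppressWarnings(compute_descriptors(s))
  # D_min = 2 * base_radius * 0.6 = 1.2 * base_radius
  expect_equal(d$D_min, 1.2 * p$base_radius, tolerance = 0.03)
  # removing the narrowing removes the difference
  p0 <- p
  p0$multipliers <- numeric(0)
  p0$positions <- numeric(0)
  d0 <- suppressWarnings(compute_descriptors(generate_arch(p0)))
  expect_gt(d0$D_min, d$D_min * 1.3)
})

test_that("population generation is seeded, reproducible and covariate-coupled", {
  spec <- population_spec(n = 6, coupling_noise_sd = 0, noise_sd = 0, seed = 54)
  r1 <- generate_population(spec)
  r2 <- generate_population(spec)
  expect_identical(r1, r2, ignore_attr = TRUE)
  s1 <- attr(r1, "surfaces")
  s2 <- attr(r2, "surfaces")
  expect_identical(s1[[3]]$vertices, s2[[3]]$vertices)
  # scale is a deterministic linear map of BSA at zero coupling noise
  expect_equal(abs(cor(r1$gt_scale, r1$BSA)), 1, tolerance = 1e-12)
  # minimal cohort still generates
  rmin <- generate_population(population_spec(n = 2, seed = 55))
  expect_identical(nrow(rmin), 2L)
  expect_length(attr(rmin, "surfaces"), 2L)
})

test_that("the manifest round-trips through disk", {
  dir <- tempfile("cohort")
  spec <- population_spec(n = 3, seed = 56)
  rec <- generate_population(spec, out_dir = dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- vesselssm:::read_manifest(file.path(dir, "manifest.csv"))
  expect_identical(back$subject_id, rec$subject_id)
  s_disk <- attr(back, "surfaces")[[2]]
  s_mem <- attr(rec, "surfaces")[[2]]
  expect_equal(s_disk$vertices, s_mem$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  unlink(dir, recursive = TRUE)
})

test_that("measured diameters follow the generator's radius profile", {
  for (seed in c(57, 58)) {
    s <- generate_arch(arch_params(seed = seed))
    gt <- attr(s, "ground_truth")
    d <- suppressWarnings(compute_descriptors(s))
    # oracle: the profile evaluated on a dense arc grid
    r_gt <- gt$radius_at(seq(0.05, 0.95, by = 0.005))
    expect_equal(d$D_min, 2 * min(r_gt), tolerance = 0.05)
    expect_equal(d$D_max, 2 * max(r_gt), tolerance = 0.05)
    expect_equal(d$D_med, 2 * median(r_gt), tolerance = 0.05)
  }
})
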