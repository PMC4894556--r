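test_that("probed-fraction rule reproduces the published kernel widths", {
  kp <- estimate_initial_lambdas(8825, 0.025, 0.25)
  expect_identical(c(kp$lambda_w, kp$lambda_v), c(15, 47))
  kp2 <- estimate_initial_lambdas(100, 1, 1)
  expect_identical(c(kp2$lambda_w, kp2$lambda_v), c(10, 10))
  expect_identical(estimate_initial_lambdas(8825, 0.01, 0.25)$lambda_w, 9)
  expect_error(estimate_initial_lambdas(-5), "> 0")
})

test_that("matching gradients agree with finite differences", {
  set.seed(11)
  s <- sphere_mesh(10, 1)
  tgt_s <- apply_rigid(s, diag(3), c(3, 0, 0))
  tgt <- vesselssm:::target_current(tgt_s, 8)
  Q <- s$vertices[vesselssm:::subsample_points(s$vertices, 6), ]
  K <- nrow(Q)
  A <- matrix(rnorm(K * 3, sd = 0.5), K, 3)
  ev <- vesselssm:::matching_cost_grad(s$vertices, s$faces, Q, A, tgt,
                                       8, 15, 0.5, 5, grad_vertices = TRUE)
  f <- function(Avec, Xvec = NULL) {
    X <- if (is.null(Xvec)) s$vertices else matrix(Xvec, ncol = 3)
    vesselssm:::matching_cost_grad(X, s$faces, Q, matrix(Avec, K, 3), tgt,
                                   8, 15, 0.5, 5, want_grad = FALSE)$cost
  }
  h <- 1e-5
  idx <- sample(K * 3, 10)
  fd <- vapply(idx, function(i) {
    a1 <- as.vector(A); a2 <- a1
    a1[i] <- a1[i] + h; a2[i] <- a2[i] - h
    (f(a1) - f(a2)) / (2 * h)
  }, numeric(1))
  expect_equal(as.vector(ev$grad_momenta)[idx], fd, tolerance = 1e-4)
  xv <- as.vector(s$vertices)
  idx2 <- sample(length(xv), 10)
  fd2 <- vapply(idx2, function(i) {
    a1 <- xv; a2 <- xv
    a1[i] <- a1[i] + h; a2[i] <- a2[i] - h
    (f(as.vector(A), a1) - f(as.vector(A), a2)) / (2 * h)
  }, numeric(1))
  expect_equal(as.vector(ev$grad_vertices)[idx2], fd2, tolerance = 1e-4)
})

test_that("surface matching recovers an identity and a translation", {
  kp <- kernel_params(8, 15)
  s <- sphere_mesh(10, 2)
  m0 <- match_surfaces(s, s, kp, max_iter = 10)
  expect_lt(sqrt(sum(vesselssm:::initial_momenta(m0$deformation)^2)), 1e-6)
  expect_lt(m0$diagnostics$cost_ratio, 1e-6)
  tgt <- apply_rigid(s, diag(3), c(5, 0, 0))
  m <- match_surfaces(s, tgt, kp, gamma = 0.01, n_time_steps = 10)
  d0 <- surface_distance(s, tgt)$max
  d1 <- surface_distance(m$deformed, tgt)$max
  expect_lt(d1, 0.2)
  expect_gt(1 - d1 / d0, 0.8)
  # zero-momenta deformation is exactly the identity
  df0 <- deformation_field(m$deformation$control_points,
                           matrix(0, nrow(m$deformation$control_points), 3),
                           10, 15)
  expect_identical(apply_deformation(df0, s)$vertices, s$vertices)
})

test_that("matching reduces the currents distance of a narrowed tube", {
  kp <- kernel_params(10, 20)
  straight <- tube_mesh(10, 80, n_theta = 12, n_z = 16)
  narrowed <- tube_mesh(10, 80, n_theta = 12, n_z = 16,
                        radius_fun = function(z)
                          10 * (1 - 0.4 * exp(-(z - 40)^2 / (2 * 8^2))))
  m <- match_surfaces(straight, narrowed, kp, gamma = 0.005, max_iter = 80)
  ratio <- m$diagnostics$data_term_final / m$diagnostics$data_term_initial
  expect_lt(ratio, 0.2)
})

test_that("matching cost is invariant under joint rigid motion", {
  set.seed(12)
  kp <- kernel_params(8, 15)
  s <- sphere_mesh(8, 1)
  tgt_s <- sphere_mesh(10, 1)
  Q <- s$vertices[vesselssm:::subsample_points(s$vertices, 6), ]
  A <- matrix(rnorm(nrow(Q) * 3, sd = 0.3), ncol = 3)
  cost_of <- function(src, tg, Qm, Am) {
    vesselssm:::matching_cost_grad(src$vertices, src$faces, Qm, Am,
                                   vesselssm:::target_current(tg, 8),
                                   8, 15, 0.01, 5, want_grad = FALSE)$cost
  }
  c0 <- cost_of(s, tgt_s, Q, A)
  R <- random_rotation()
  t_ <- rnorm(3, sd = 30)
  # the whole problem rotates: source, target, control points and momenta
  c1 <- cost_of(apply_rigid(s, R, t_), apply_rigid(tgt_s, R, t_),
                sweep(Q %*% t(R), 2, -t_), A %*% t(R))
  expect_equal(c1, c0, tolerance = 1e-8)
})

test_that("weaker regularisation lowers the data term at the optimum", {
  kp <- kernel_params(8, 15)
  s <- sphere_mesh(9, 2)
  tgt <- sphere_mesh(11, 2)
  d_hi <- match_surfaces(s, tgt, kp, gamma = 1, max_iter = 40)$diagnostics$data_term_final
  d_lo <- match_surfaces(s, tgt, kp, gamma = 0.01, max_iter = 40)$diagnostics$data_term_final
  expect_lte(d_lo, d_hi + 1e-9)
})

test_that("the template of identical meshes is the mesh with zero momenta", {
  s <- sphere_mesh(10, 2)
  tm <- compute_template(list(s, s, s), kernel_params(6, 12),
                         outer_iter = 2, inner_iter = 15, template_iter = 5)
  expect_lt(surface_distance(tm$surface, s)$max, 0.1)
  expect_lt(max(vapply(tm$deformations, function(d)
    sqrt(sum(d$momenta^2)), numeric(1))), 1e-6)
  # cost trace never increases
  expect_true(all(diff(tm$cost_trace) <= 1e-8 * max(abs(tm$cost_trace[1]), 1)))
})

test_that("the template of two spheres lands between them", {
  tm <- compute_template(list(sphere_mesh(8, 2), sphere_mesh(12, 2)),
                         kernel_params(5, 10),
                         outer_iter = 3, inner_iter = 30, template_iter = 10)
  ctr <- colMeans(tm$surface$vertices)
  d_med <- 2 * median(sqrt(rowSums(sweep(tm$surface$vertices, 2, ctr)^2)))
  expect_equal(d_med, 20, tolerance = 0.05)
})

test_that("moment-matrix rows reproduce the deformation kernel metric", {
  set.seed(13)
  tm <- compute_template(list(sphere_mesh(8, 2), sphere_mesh(12, 2)),
                         kernel_params(5, 10),
                         outer_iter = 2, inner_iter = 20, template_iter = 5)
  mm <- moment_matrix(tm)
  expect_identical(dim(mm$rows),
                   c(2L, 3L * nrow(tm$control_points)))
  K <- vesselssm:::gauss_kernel(tm$control_points, tm$control_points, 10)
  for (i in 1:2) {
    for (j in 1:2) {
      Ai <- vesselssm:::initial_momenta(tm$deformations[[i]])
      Aj <- vesselssm:::initial_momenta(tm$deformations[[j]])
      want <- sum(K * tcrossprod(Ai, Aj))
      expect_equal(sum(mm$rows[i, ] * mm$rows[j, ]), want, tolerance = 1e-8)
    }
  }
  # identity deformation flattens to the zero row
  tm0 <- tm
  tm0$deformations[[1]] <- deformation_field(
    tm$control_points, matrix(0, nrow(tm$control_points), 3), 10, 10)
  expect_equal(max(abs(moment_matrix(tm0)$rows[1, ])), 0)
})

test_that("lambda refinement accepts degenerate matches and honours search order", {
  arch <- generate_arch(arch_params(noise_sd = 0, seed = 6,
                                    n_section = 8, axial_step = 12))
  init <- estimate_initial_lambdas(surface_measures(arch)$area, 0.025, 0.25)
  # identical shapes: zero baseline counts as an immediate pass
  out <- refine_lambdas(arch, arch, init, lambda_v_floor = init$lambda_v - 5)
  expect_identical(out$lambda_w, init$lambda_w)
  expect_identical(out$lambda_v, init$lambda_v)
  # a local narrowing (Gaussian bump, sigma = 8 mm) is only matchable once
  # the kernel widths resolve it: the scan must walk down from the coarse
  # start and return a resolution no coarser than the bump width
  straight <- tube_mesh(10, 80, n_theta = 12, n_z = 16)
  narrowed <- tube_mesh(10, 80, n_theta = 12, n_z = 16,
                        radius_fun = function(z)
                          10 * (1 - 0.3 * exp(-(z - 40)^2 / (2 * 8^2))))
  start <- kernel_params(14, 16)
  out2 <- refine_lambdas(straight, narrowed, start,
                         reduction_target = 0.9,
                         lambda_v_floor = 12,
                         gamma = 0.005, max_iter = 30)
  srch <- attr(out2, "search")
  expect_false(is.null(srch))
  # every pair evaluated before the returned one failed the target, so
  # among passing pairs the returned lambda_w is maximal
  prior <- srch[-nrow(srch), , drop = FALSE]
  if (nrow(prior) > 0) expect_true(all(prior$reduction < 0.9))
  expect_gte(srch$reduction[nrow(srch)], 0.9)
  expect_lte(out2$lambda_w, 16)   # no coarser than the 2-sigma bump width
})
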