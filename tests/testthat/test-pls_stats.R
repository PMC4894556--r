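make_moments <- function(n = 8, p = 5, seed = 21) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

test_that("PLS is exact on a rank-1 noiseless problem", {
  set.seed(20)
  x <- rnorm(8)
  X <- cbind(x)
  y <- 2 * x
  fit <- pls_fit(X, y, 1)
  expect_equal(abs(cor(fit$x_scores[, 1], y)), 1, tolerance = 1e-12)
  expect_equal(fit$fitted, y, tolerance = 1e-10)
  expect_equal(fit$explained_shape_variability, 1, tolerance = 1e-12)
})

test_that("the first PLS weight is the normalised X'y direction", {
  X <- make_moments(6, 4)
  set.seed(22)
  y <- rnorm(6)
  fit <- pls_fit(X, y, 1)
  Xc <- sweep(X, 2, colMeans(X))
  w_direct <- crossprod(Xc, y - mean(y))
  w_direct <- w_direct / sqrt(sum(w_direct^2))
  expect_equal(as.vector(fit$x_weights[, 1]), as.vector(w_direct),
               tolerance = 1e-10)
})

test_that("explained shape variability sums to one over all components", {
  X <- make_moments(7, 4, seed = 23)
  set.seed(24)
  y <- rnorm(7)
  fit <- pls_fit(X, y, 4)
  expect_equal(sum(fit$explained_shape_variability), 1, tolerance = 1e-8)
  expect_true(all(fit$explained_shape_variability >= 0))
  # successive score vectors are mutually orthogonal
  G <- crossprod(fit$x_scores)
  expect_lt(max(abs(G[upper.tri(G)])) / max(diag(G)), 1e-8)
  expect_error(pls_fit(X, y, 7), "rank")
  expect_error(pls_fit(X, rep(1, 7)), "constant")
})

test_that("PLS component-1 scores agree with an independent implementation", {
  X <- make_moments(10, 6, seed = 25)
  set.seed(26)
  y <- as.vector(X %*% rnorm(6)) + rnorm(10, sd = 0.1)
  fit <- pls_fit(X, y, 1)
  ref <- mixOmics::pls(X, y, ncomp = 1, mode = "regression", scale = FALSE)
  expect_equal(abs(cor(fit$x_scores[, 1], ref$variates$X[, 1])), 1,
               tolerance = 1e-6)
})

test_that("shape vectors are the scores in-sample and centre to zero", {
  X <- make_moments(9, 5, seed = 27)
  set.seed(28)
  y <- rnorm(9)
  fit <- pls_fit(X, y, 2)
  for (comp in 1:2) {
    sv <- shape_vector(fit, X, component = comp)
    expect_equal(sv$values, as.vector(fit$x_scores[, comp]), tolerance = 1e-10)
  }
  # a subject at the cohort mean projects to zero
  sv0 <- shape_vector(fit, rbind(colMeans(X)))
  expect_equal(sv0$values, 0, tolerance = 1e-10)
})

test_that("residualization deflates the size mode", {
  X <- make_moments(10, 6, seed = 29)
  set.seed(30)
  y <- rnorm(10)
  fit <- pls_fit(X, y, 1)
  Xr <- residualize(X, fit)
  # scores orthogonal to every residual column
  expect_lt(max(abs(crossprod(fit$x_scores, Xr))), 1e-8)
  # Frobenius norm strictly decreases (centered)
  frob <- function(M) sum(sweep(M, 2, colMeans(M))^2)
  expect_lt(frob(Xr), frob(X))
  # double deflation: a second fit on the residuals carries nothing of the
  # removed direction -- its scores are orthogonal to the first scores and
  # the residual matrix has no variance left along them
  fit2 <- pls_fit(Xr, y, 1)
  expect_lt(abs(cor(fit2$x_scores[, 1], fit$x_scores[, 1])), 1e-8)
  proj <- crossprod(fit$x_scores[, 1], sweep(Xr, 2, colMeans(Xr)))
  expect_lt(sum(proj^2) / frob(X), 1e-16)
  # residualize-then-fit equals projecting onto the orthocomplement
  P_perp <- diag(10) - tcrossprod(fit$x_scores[, 1]) / sum(fit$x_scores[, 1]^2)
  Xc <- sweep(X, 2, colMeans(X))
  X_proj <- P_perp %*% Xc
  set.seed(31)
  z <- rnorm(10)
  s1 <- pls_fit(Xr, z, 1)$x_scores[, 1]
  s2 <- pls_fit(X_proj, z, 1)$x_scores[, 1]
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("Cook's distances match an independent leave-one-out regression loop", {
  set.seed(32)
  x <- rnorm(10)
  y <- 1.5 * x + rnorm(10, sd = 0.3)
  X <- cbind(x)
  rep_ <- cooks_flag(X, y, n_components = 1)
  # with one predictor, PLS1 is simple least squares: replicate D_i with lm
  full <- lm(y ~ x)
  yhat <- fitted(full)
  mse <- mean(residuals(full)^2)
  D_ref <- vapply(seq_along(y), function(i) {
    fi <- lm(y ~ x, subset = -i)
    yhat_i <- predict(fi, newdata = data.frame(x = x))
    sum((yhat - yhat_i)^2) / (2 * mse)
  }, numeric(1))
  expect_equal(rep_$distances, D_ref, tolerance = 1e-10)
  expect_equal(rep_$threshold, 4 * mean(D_ref), tolerance = 1e-10)
})

test_that("Cook screening flags a planted outlier and is scale/shift invariant", {
  set.seed(33)
  X <- make_moments(10, 4, seed = 33)
  beta <- rnorm(4)
  y <- as.vector(X %*% beta) + rnorm(10, sd = 0.05)
  sigma <- sd(y - mean(y))
  y_out <- y
  y_out[7] <- y[7] + 10 * sigma
  rep_ <- cooks_flag(X, y_out)
  expect_identical(rep_$flagged, 7L)
  # no flags on the clean, exactly linear cohort
  y_clean <- as.vector(X %*% beta)
  expect_length(cooks_flag(X, y_clean)$flagged, 0)
  # invariance of the flag set under y -> 3 y and y -> y + c
  expect_identical(cooks_flag(X, 3 * y_out)$flagged, rep_$flagged)
  expect_identical(cooks_flag(X, y_out + 11)$flagged, rep_$flagged)
  expect_equal(cooks_flag(X, 3 * y_out)$distances, rep_$distances,
               tolerance = 1e-9)
})

test_that("the correlation gate follows Shapiro-Wilk normality", {
  set.seed(34)
  a <- rnorm(25)
  r1 <- correlate(a, 2 * a + 1)
  expect_identical(r1$method, "pearson")
  expect_equal(r1$coefficient, 1, tolerance = 1e-12)
  # heavy-tailed monotone map: Kendall branch, tau = 1
  b <- rt(25, df = 1)
  r2 <- correlate(b, exp(b))
  expect_identical(r2$method, "kendall")
  expect_equal(r2$coefficient, 1, tolerance = 1e-12)
  expect_error(correlate(rep(1, 10), rnorm(10)), "constant")
})

test_that("mode deformation returns the template at t = 0 and bends it at t != 0", {
  set.seed(35)
  tm <- compute_template(list(sphere_mesh(8, 1), sphere_mesh(10, 1),
                              sphere_mesh(12, 1)),
                         kernel_params(5, 10),
                         outer_iter = 2, inner_iter = 15, template_iter = 3)
  mm <- moment_matrix(tm)
  y <- c(8, 10, 12)
  fit <- pls_fit(mm, y, 1)
  seq_ <- mode_deform_sequence(tm, fit, c(-1, 0, 1), mm = mm)
  expect_identical(seq_[[2]]$vertices, tm$surface$vertices)
  r_of <- function(s) median(vesselssm:::rownorm(
    sweep(s$vertices, 2, colMeans(s$vertices))))
  r <- vapply(seq_, r_of, numeric(1))
  # moving along the size mode changes the radius monotonically
  expect_true(all(diff(r) > 0) || all(diff(r) < 0))
  # +/- t are approximately mirror-symmetric around the template radius
  expect_equal(r[2] - r[1], r[3] - r[2], tolerance = 0.35)
})
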