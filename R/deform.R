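# Control-point deformation model. A deformation is parameterised by a
# momentum 3-vector per control point; the velocity field
#   v(x) = sum_k exp(-||x - q_k||^2 / lambda_V^2) alpha_k
# is integrated with forward Euler over n_time_steps while the control
# points themselves flow with the deformation. Momenta are optimised tied
# across time (stationary parameterisation): the full (T, K, 3) momentum
# array of the fitted field repeats the initial momenta, which keeps the
# initial momenta a complete description of the deformation and makes the
# moment matrix (and PLS mode shooting) exact.

#' Deformation field
#'
#' @param control_points K x 3 matrix of control point positions \[mm\].
#' @param momenta K x 3 matrix (one momentum per control point, applied at
#'   every time step) or a (T, K, 3) array of time-varying momenta.
#' @param n_time_steps number of forward-Euler steps.
#' @param lambda_v deformation kernel width (stiffness) \[mm\].
#' @return a `deformation_field` object.
#' @export
deformation_field <- function(control_points, momenta, n_time_steps = 10L,
                              lambda_v) {
  control_points <- as.matrix(control_points)
  if (length(dim(momenta)) == 2L) {
    momenta <- aperm(array(rep(as.matrix(momenta), n_time_steps),
                           dim = c(nrow(control_points), 3L, n_time_steps)),
                     c(3L, 1L, 2L))
  }
  stopifnot(length(dim(momenta)) == 3L,
            dim(momenta)[1] == n_time_steps,
            dim(momenta)[2] == nrow(control_points),
            dim(momenta)[3] == 3L)
  structure(list(control_points = control_points, momenta = momenta,
                 n_time_steps = as.integer(n_time_steps),
                 lambda_v = lambda_v),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf(
    "deformation_field: %d control points, %d time steps, lambda_V = %g mm, |momenta| = %.4g\n",
    nrow(x$control_points), x$n_time_steps, x$lambda_v,
    sqrt(sum(x$momenta[1, , ]^2))))
  invisible(x)
}

initial_momenta <- function(df) {
  matrix(df$momenta[1, , ], ncol = 3L)
}

#' Apply a deformation field to points or a surface
#'
#' @param df a [deformation_field()].
#' @param x a [triangle_surface()] or an N x 3 point matrix.
#' @return deformed surface or point matrix.
#' @export
apply_deformation <- function(df, x) {
  is_surf <- inherits(x, "triangle_surface")
  P <- if (is_surf) x$vertices else as.matrix(x)
  Q <- df$control_points
  T_ <- df$n_time_steps
  dt <- 1 / T_
  lam <- df$lambda_v
  for (t in seq_len(T_)) {
    A <- matrix(df$momenta[t, , ], ncol = 3L)
    if (sum(A * A) == 0) next
    P <- P + dt * gauss_kernel(P, Q, lam) %*% A
    Q <- Q + dt * gauss_kernel(Q, Q, lam) %*% A
  }
  if (is_surf) { x$vertices <- P; x } else P
}

# Gradient of the squared currents distance between surface(X, faces) and a
# fixed target current, with respect to the vertex coordinates X.
currents_grad_vertices <- function(X, faces, target, lambda_w) {
  ctr <- face_centers(X, faces)
  nrm <- face_normals(X, faces)
  lam2 <- lambda_w^2
  Kss <- gauss_kernel(ctr, ctr, lambda_w)
  Kst <- gauss_kernel(ctr, target$centers, lambda_w)
  Wss <- Kss * tcrossprod(nrm, nrm)
  Wst <- Kst * tcrossprod(nrm, target$normals)
  Gc <- (-4 / lam2) * (ctr * rowSums(Wss) - Wss %*% ctr) +
        (4 / lam2) * (ctr * rowSums(Wst) - Wst %*% target$centers)
  Gn <- 2 * (Kss %*% nrm) - 2 * (Kst %*% target$normals)
  a <- X[faces[, 1], , drop = FALSE]
  b <- X[faces[, 2], , drop = FALSE]
  c_ <- X[faces[, 3], , drop = FALSE]
  ga <- Gc / 3 + 0.5 * cross3(b - c_, Gn)
  gb <- Gc / 3 + 0.5 * cross3(c_ - a, Gn)
  gc <- Gc / 3 + 0.5 * cross3(a - b, Gn)
  G <- matrix(0, nrow(X), 3L)
  idx <- c(faces[, 1], faces[, 2], faces[, 3])
  acc <- rowsum(rbind(ga, gb, gc), group = idx, reorder = TRUE)
  G[sort(unique(idx)), ] <- acc
  G
}

# Cost and gradients of the matching functional
#   J = ||[phi(X0)] - [target]||^2_{W} + gamma * sum_t dt tr(A' K_V(Q_t) A)
# for stationary momenta A. Returns the cost, its pieces, grad wrt A and
# (optionally) grad wrt the source vertices X0.
matching_cost_grad <- function(X0, faces, Q0, A, target, lambda_w, lambda_v,
                               gamma, n_time_steps, grad_vertices = FALSE,
                               want_grad = TRUE) {
  T_ <- n_time_steps
  dt <- 1 / T_
  lam2 <- lambda_v^2
  Xs <- vector("list", T_ + 1L)
  Qs <- vector("list", T_ + 1L)
  Kxq <- vector("list", T_)
  Kqq <- vector("list", T_)
  Xs[[1L]] <- X0
  Qs[[1L]] <- Q0
  reg <- 0
  for (t in seq_len(T_)) {
    Kxq[[t]] <- gauss_kernel(Xs[[t]], Qs[[t]], lambda_v)
    Kqq[[t]] <- gauss_kernel(Qs[[t]], Qs[[t]], lambda_v)
    reg <- reg + dt * sum(A * (Kqq[[t]] %*% A))
    Xs[[t + 1L]] <- Xs[[t]] + dt * Kxq[[t]] %*% A
    Qs[[t + 1L]] <- Qs[[t]] + dt * Kqq[[t]] %*% A
  }
  XT <- Xs[[T_ + 1L]]
  cur <- structure(list(centers = face_centers(XT, faces),
                        normals = face_normals(XT, faces),
                        lambda_w = lambda_w), class = "currents_rep")
  data_term <- currents_inner(cur, cur) - 2 * currents_inner(cur, target) +
    attr(target, "self_inner")
  cost <- data_term + gamma * reg
  if (!want_grad) {
    return(list(cost = cost, data_term = data_term, reg = reg,
                deformed_vertices = XT))
  }
  GX <- currents_grad_vertices(XT, faces, target, lambda_w)
  GQ <- matrix(0, nrow(Q0), 3L)
  GA <- matrix(0, nrow(Q0), 3L)
  for (t in rev(seq_len(T_))) {
    X <- Xs[[t]]; Q <- Qs[[t]]
    Kx <- Kxq[[t]]; Kq <- Kqq[[t]]
    # regularity: direct dependence on A and Q_t
    GA <- GA + gamma * dt * 2 * (Kq %*% A)
    M <- Kq * tcrossprod(A, A)
    GQ_reg <- gamma * dt * (-4 / lam2) * (Q * rowSums(M) - M %*% Q)
    # X step: X_{t+1} = X_t + dt Kx A
    GA <- GA + dt * crossprod(Kx, GX)
    W <- Kx * tcrossprod(GX, A)
    GX_new <- GX + dt * (-2 / lam2) * (X * rowSums(W) - W %*% Q)
    GQ_from_x <- dt * (2 / lam2) * (crossprod(W, X) - Q * colSums(W))
    # Q step: Q_{t+1} = Q_t + dt Kq A (Q in both kernel slots)
    GA <- GA + dt * crossprod(Kq, GQ)
    U <- Kq * tcrossprod(GQ, A)
    GQ_new <- GQ +
      dt * (-2 / lam2) * (Q * rowSums(U) - U %*% Q) +
      dt * (2 / lam2) * (crossprod(U, Q) - Q * colSums(U)) +
      GQ_from_x + GQ_reg
    GX <- GX_new
    GQ <- GQ_new
  }
  list(cost = cost, data_term = data_term, reg = reg,
       grad_momenta = GA,
       grad_vertices = if (grad_vertices) GX else NULL,
       grad_control = GQ,
       deformed_vertices = XT)
}

# Prepare a target current with its cached self inner product.
target_current <- function(s_or_rep, lambda_w) {
  rep_ <- if (inherits(s_or_rep, "currents_rep")) s_or_rep
          else to_currents(s_or_rep, lambda_w)
  attr(rep_, "self_inner") <- currents_inner(rep_, rep_)
  rep_
}

# Greedy Poisson-disk-style subsampling: keep points at least `spacing`
# apart, always including the first point.
subsample_points <- function(P, spacing) {
  n <- nrow(P)
  keep <- logical(n)
  keep[1L] <- TRUE
  kept <- P[1L, , drop = FALSE]
  for (i in 2:n) {
    d2 <- rowSums(sweep(kept, 2L, P[i, ])^2)
    if (min(d2) >= spacing^2) {
      keep[i] <- TRUE
      kept <- rbind(kept, P[i, ])
    }
  }
  which(keep)
}

#' Match a source surface onto a target by kernel-parameterised deformation
#'
#' Minimises the currents data term plus a kernel regularity penalty over
#' the control-point momenta by gradient descent with backtracking line
#' search. Control points default to the source vertices subsampled at a
#' spacing of `lambda_v / 2`.
#'
#' @param source,target [triangle_surface()] objects (source is deformed).
#' @param kernel a [kernel_params()] (uses `lambda_w`, `lambda_v`).
#' @param gamma regularity weight (default 0.01).
#' @param n_time_steps forward-Euler steps (default 10).
#' @param control_spacing control point spacing \[mm\]; default `lambda_v/2`.
#' @param control_points optional explicit K x 3 control point matrix.
#' @param max_iter maximum gradient iterations (default 60).
#' @param tol relative cost-change convergence tolerance (default 1e-4).
#' @param init_momenta optional K x 3 warm start.
#' @return list with `deformation` (a [deformation_field()]) and
#'   `diagnostics`: cost trace, initial and final data term and cost ratio,
#'   surface-distance before/after, flipped-triangle count (warned on).
#' @export
match_surfaces <- function(source, target, kernel, gamma = 0.01,
                           n_time_steps = 10L, control_spacing = NULL,
                           control_points = NULL, max_iter = 60L,
                           tol = 1e-4, init_momenta = NULL) {
  stopifnot(inherits(source, "triangle_surface"),
            inherits(target, "triangle_surface"))
  lw <- kernel$lambda_w
  lv <- kernel$lambda_v
  if (is.null(control_points)) {
    if (is.null(control_spacing)) control_spacing <- lv / 2
    control_points <- source$vertices[
      subsample_points(source$vertices, control_spacing), , drop = FALSE]
  }
  tgt <- target_current(target, lw)
  X0 <- source$vertices
  faces <- source$faces
  A <- if (is.null(init_momenta)) matrix(0, nrow(control_points), 3L)
       else as.matrix(init_momenta)
  ev <- matching_cost_grad(X0, faces, control_points, A, tgt, lw, lv,
                           gamma, n_time_steps)
  cost0 <- ev$cost
  data0 <- ev$data_term
  trace <- cost0
  step <- NULL
  for (it in seq_len(max_iter)) {
    g <- ev$grad_momenta
    gn2 <- sum(g * g)
    if (gn2 < 1e-30) break
    if (is.null(step)) {
      # first step: limit the max control point displacement scale to ~1 mm
      step <- 1 / (sqrt(max(rowSums(g^2))) + 1e-12)
    }
    accepted <- FALSE
    for (ls in seq_len(25L)) {
      A_new <- A - step * g
      ev_new <- matching_cost_grad(X0, faces, control_points, A_new, tgt,
                                   lw, lv, gamma, n_time_steps)
      if (is.finite(ev_new$cost) && ev_new$cost < ev$cost) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    rel <- (ev$cost - ev_new$cost) / max(abs(cost0), 1e-12)
    A <- A_new
    ev <- ev_new
    trace <- c(trace, ev$cost)
    step <- step * 1.5
    if (rel < tol) break
  }
  df <- deformation_field(control_points, A, n_time_steps, lv)
  deformed <- source
  deformed$vertices <- ev$deformed_vertices
  nrm0 <- face_normals(source$vertices, faces)
  nrm1 <- face_normals(ev$deformed_vertices, faces)
  flipped <- sum(rowSums(nrm0 * nrm1) < 0)
  if (flipped > 0) {
    warning(sprintf("%d triangle(s) flipped orientation at the optimum", flipped))
  }
  list(deformation = df,
       deformed = deformed,
       diagnostics = list(cost_trace = trace,
                          data_term_initial = data0,
                          data_term_final = ev$data_term,
                          cost_ratio = ev$cost / max(cost0, 1e-300),
                          flipped_triangles = flipped,
                          iterations = length(trace) - 1L))
}
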