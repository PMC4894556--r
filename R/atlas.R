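# Template (atlas) estimation under the forward approach: every subject is
# modelled as a deformation of a common template plus residual. The two
# kernel widths are the currents resolution lambda_W (what counts as a
# shape feature) and the deformation stiffness lambda_V (how local the
# template deformations may be).

#' Kernel parameters of the shape model
#'
#' @param lambda_w currents resolution \[mm\].
#' @param lambda_v deformation stiffness \[mm\]; should be >= `lambda_w`
#'   (stiffness acts at a coarser scale) -- a warning is issued otherwise.
#' @param p_w,p_v probed surface-area fractions the widths were derived
#'   from (recorded for provenance; may be `NA`).
#' @param a_surf_min smallest cohort surface area \[mm^2\] (provenance).
#' @return a `kernel_params` object.
#' @export
kernel_params <- function(lambda_w, lambda_v, p_w = NA_real_, p_v = NA_real_,
                          a_surf_min = NA_real_) {
  if (lambda_w <= 0 || lambda_v <= 0) stop("kernel widths must be > 0")
  if (lambda_v < lambda_w) {
    warning("lambda_v < lambda_w: deformation stiffness finer than currents resolution")
  }
  structure(list(lambda_w = lambda_w, lambda_v = lambda_v,
                 p_w = p_w, p_v = p_v, a_surf_min = a_surf_min),
            class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf("kernel_params: lambda_W = %g mm, lambda_V = %g mm", x$lambda_w,
              x$lambda_v))
  if (!is.na(x$p_w)) {
    cat(sprintf("  (p_W = %g%%, p_V = %g%%, A_surf,min = %g mm^2)",
                100 * x$p_w, 100 * x$p_v, x$a_surf_min))
  }
  cat("\n")
  invisible(x)
}

#' A-priori kernel widths from a probed surface-area fraction
#'
#' Rule-of-thumb initialisation: a kernel width is the side of a square
#' patch covering the chosen fraction of the smallest surface area in the
#' cohort, `lambda = sqrt(p * A_surf_min)`, rounded to the nearest
#' integer millimetre. With `A_surf_min = 8825` mm^2, `p_w = 0.025` and
#' `p_v = 0.25` this gives `lambda_w = 15` mm and `lambda_v = 47` mm.
#'
#' @param a_surf_min smallest surface area in the cohort \[mm^2\].
#' @param p_w probed fraction for the currents resolution (default 0.025).
#' @param p_v probed fraction for the deformation stiffness (default 0.25).
#' @return a [kernel_params()] with integer-mm widths.
#' @export
estimate_initial_lambdas <- function(a_surf_min, p_w = 0.025, p_v = 0.25) {
  if (a_surf_min <= 0) stop("a_surf_min must be > 0")
  if (p_w <= 0 || p_w > 1 || p_v <= 0 || p_v > 1) stop("fractions must be in (0, 1]")
  kernel_params(lambda_w = round(sqrt(p_w * a_surf_min)),
                lambda_v = round(sqrt(p_v * a_surf_min)),
                p_w = p_w, p_v = p_v, a_surf_min = a_surf_min)
}

#' Refine kernel widths against the hardest subject
#'
#' Starting from the initial widths, deforms the initial template towards
#' the hardest subject (the one with the smallest surface area) for each
#' candidate `(lambda_w, lambda_v)` pair, decreasing `lambda_v` in 1-mm
#' steps from its initial value down to `lambda_v_floor` and, if no
#' setting reduces the baseline maximum surface distance by at least
#' `reduction_target`, decreasing `lambda_w` by 1 mm and repeating. High
#' `lambda_w` is prioritised (cheaper, smoother templates); within one
#' `lambda_w` the first (highest) passing `lambda_v` is returned.
#'
#' @param initial_template [triangle_surface()] used as matching source.
#' @param hardest_subject [triangle_surface()] target (smallest A_surf).
#' @param init initial [kernel_params()].
#' @param reduction_target required fractional reduction of the maximum
#'   surface distance (default 0.8).
#' @param lambda_v_floor smallest stiffness tried \[mm\].
#' @param ... further arguments passed to [match_surfaces()].
#' @return a [kernel_params()] (the selected pair) with a `search` attribute
#'   recording every evaluated pair and its error reduction.
#' @export
refine_lambdas <- function(initial_template, hardest_subject, init,
                           reduction_target = 0.8, lambda_v_floor,
                           ...) {
  if (lambda_v_floor >= init$lambda_v) stop("lambda_v_floor must be < initial lambda_v")
  baseline <- surface_distance(initial_template, hardest_subject)$max
  if (baseline <= 1e-9) {
    # degenerate pass: nothing to match
    return(init)
  }
  log <- list()
  for (lw in seq(init$lambda_w, 2, by = -1)) {
    for (lv in seq(init$lambda_v, lambda_v_floor, by = -1)) {
      kp <- kernel_params(lw, max(lv, lw), p_w = init$p_w, p_v = init$p_v,
                          a_surf_min = init$a_surf_min)
      kp$lambda_v <- lv   # allow the scanned value even when < lambda_w
      m <- match_surfaces(initial_template, hardest_subject, kp, ...)
      err <- surface_distance(m$deformed, hardest_subject)$max
      red <- 1 - err / baseline
      log[[length(log) + 1L]] <- data.frame(lambda_w = lw, lambda_v = lv,
                                            max_distance = err,
                                            reduction = red)
      if (red >= reduction_target) {
        out <- kernel_params(lw, lv, p_w = init$p_w, p_v = init$p_v,
                             a_surf_min = init$a_surf_min)
        attr(out, "search") <- do.call(rbind, log)
        return(out)
      }
    }
  }
  stop("lambda_w exhausted without reaching the error-reduction target; ",
       sprintf("best reduction %.1f%%",
               100 * max(vapply(log, function(d) d$reduction, numeric(1)))))
}

#' Atlas configuration
#'
#' Bundles the optimiser settings of [compute_template()] so that the same
#' configuration can be reused across Procrustes iterations and
#' cross-validation folds.
#'
#' @param kernel a [kernel_params()].
#' @param gamma regularity weight (default 0.01).
#' @param n_time_steps forward-Euler steps (default 10).
#' @param outer_iter alternating (momenta, template) rounds (default 3).
#' @param inner_iter gradient iterations per subject matching (default 40).
#' @param template_iter gradient iterations on the template vertices per
#'   round (default 10).
#' @param control_spacing control point spacing \[mm\]; default `lambda_v/2`.
#' @param mean_current_init regress the initial template toward the cohort
#'   mean current before the alternating rounds (default TRUE).
#' @param tol relative cost-change convergence tolerance (default 1e-4).
#' @return list of settings.
#' @export
atlas_config <- function(kernel, gamma = 0.01, n_time_steps = 10L,
                         outer_iter = 3L, inner_iter = 40L,
                         template_iter = 10L, control_spacing = NULL,
                         mean_current_init = TRUE, tol = 1e-4) {
  list(kernel = kernel, gamma = gamma, n_time_steps = n_time_steps,
       outer_iter = outer_iter, inner_iter = inner_iter,
       template_iter = template_iter, control_spacing = control_spacing,
       mean_current_init = mean_current_init, tol = tol)
}

#' Estimate the population template and per-subject deformations
#'
#' Alternating minimisation of
#' `sum_i ||[phi_i(template)] - [S_i]||^2_W + gamma R(alpha_i)`
#' over the template vertex positions and all subject momenta. The
#' template is initialised from the initial reference surface `init` and,
#' honouring the view of the template as the average of all currents,
#' optionally first regressed toward the cohort mean current. Template
#' vertex steps use backtracking line search on the total cost and only
#' decreasing steps are accepted, so the cost trace is non-increasing.
#'
#' @param surfaces list of aligned [triangle_surface()] objects.
#' @param kernel a [kernel_params()].
#' @param gamma,n_time_steps,outer_iter,inner_iter,template_iter,control_spacing,mean_current_init,tol
#'   see [atlas_config()].
#' @param init initial template surface (the reference subject).
#' @return an `ssm_template`: `surface`, `deformations` (one
#'   [deformation_field()] per subject), `control_points`, `cost_trace`,
#'   `kernel`, `converged`, `subject_ids`.
#' @export
compute_template <- function(surfaces, kernel, gamma = 0.01,
                             n_time_steps = 10L, init = NULL,
                             outer_iter = 3L, inner_iter = 40L,
                             template_iter = 10L, control_spacing = NULL,
                             mean_current_init = TRUE, tol = 1e-4) {
  n <- length(surfaces)
  if (n < 2L) stop("need at least 2 surfaces")
  if (is.null(init)) init <- surfaces[[1L]]
  lw <- kernel$lambda_w
  lv <- kernel$lambda_v
  if (is.null(control_spacing)) control_spacing <- lv / 2
  tmpl <- init
  targets <- lapply(surfaces, target_current, lambda_w = lw)
  # control points in template coordinates, shared by all subjects
  Q <- tmpl$vertices[subsample_points(tmpl$vertices, control_spacing), ,
                     drop = FALSE]
  if (mean_current_init) {
    mean_cur <- target_current(pooled_currents(surfaces, lw), lw)
    tmpl <- descend_template(tmpl, list(mean_cur),
                             list(matrix(0, nrow(Q), 3L)), Q,
                             lw, lv, gamma, n_time_steps,
                             max_iter = template_iter)$surface
  }
  A <- replicate(n, matrix(0, nrow(Q), 3L), simplify = FALSE)
  total_cost <- function(tm, Alist) {
    sum(vapply(seq_len(n), function(i) {
      matching_cost_grad(tm$vertices, tm$faces, Q, Alist[[i]], targets[[i]],
                         lw, lv, gamma, n_time_steps, want_grad = FALSE)$cost
    }, numeric(1)))
  }
  trace <- total_cost(tmpl, A)
  for (round in seq_len(outer_iter)) {
    # (a) per-subject momenta
    for (i in seq_len(n)) {
      m <- match_surfaces(tmpl, surfaces[[i]], kernel, gamma = gamma,
                          n_time_steps = n_time_steps,
                          control_points = Q, max_iter = inner_iter,
                          tol = tol, init_momenta = A[[i]])
      A[[i]] <- initial_momenta(m$deformation)
    }
    trace <- c(trace, total_cost(tmpl, A))
    # (b) template vertices
    res <- descend_template(tmpl, targets, A, Q, lw, lv, gamma, n_time_steps,
                            max_iter = template_iter)
    tmpl <- res$surface
    trace <- c(trace, res$cost)
    if (length(trace) >= 4L &&
        abs(trace[length(trace) - 2L] - trace[length(trace)]) <
        tol * max(abs(trace[1L]), 1e-12) * 3) break
  }
  converged <- length(trace) >= 4L &&
    abs(diff(utils::tail(trace, 2L))) <= tol * max(abs(trace[1L]), 1e-12) * 3
  # warn only when the cost was still dropping substantially at the cap
  if (!converged && length(trace) >= 2L &&
      abs(diff(utils::tail(trace, 2L))) > 0.05 * max(abs(trace[1L]), 1e-12)) {
    warning("template estimation stopped at the iteration cap; returning best iterate")
  }
  structure(list(surface = tmpl,
                 deformations = lapply(A, function(a)
                   deformation_field(Q, a, n_time_steps, lv)),
                 control_points = Q,
                 cost_trace = trace,
                 kernel = kernel,
                 gamma = gamma,
                 n_time_steps = n_time_steps,
                 converged = converged,
                 subject_ids = vapply(seq_len(n), function(i) {
                   id <- surfaces[[i]]$subject_id
                   if (is.null(id)) sprintf("S%02d", i) else id
                 }, character(1))),
            class = "ssm_template")
}

# Gradient descent with backtracking on the template vertices, all momenta
# fixed. Accepts only cost decreases.
descend_template <- function(tmpl, targets, A, Q, lw, lv, gamma,
                             n_time_steps, max_iter = 10L) {
  n <- length(targets)
  eval_all <- function(V, want_grad = TRUE) {
    cost <- 0
    G <- if (want_grad) matrix(0, nrow(V), 3L) else NULL
    for (i in seq_len(n)) {
      ev <- matching_cost_grad(V, tmpl$faces, Q, A[[i]], targets[[i]],
                               lw, lv, gamma, n_time_steps,
                               grad_vertices = want_grad,
                               want_grad = want_grad)
      cost <- cost + ev$cost
      if (want_grad) G <- G + ev$grad_vertices
    }
    list(cost = cost, grad = G)
  }
  V <- tmpl$vertices
  ev <- eval_all(V)
  step <- NULL
  for (it in seq_len(max_iter)) {
    g <- ev$grad
    if (sum(g * g) < 1e-30) break
    if (is.null(step)) step <- 0.5 / (sqrt(max(rowSums(g^2))) + 1e-12)
    accepted <- FALSE
    for (ls in seq_len(20L)) {
      V_new <- V - step * g
      ev_new <- eval_all(V_new, want_grad = FALSE)
      if (is.finite(ev_new$cost) && ev_new$cost < ev$cost) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    V <- V_new
    ev <- eval_all(V)
    step <- step * 1.5
  }
  tmpl$vertices <- V
  list(surface = tmpl, cost = ev$cost)
}

#' @export
print.ssm_template <- function(x, ...) {
  cat(sprintf(
    "ssm_template: %d subjects, %d control points, lambda_W = %g mm, lambda_V = %g mm\n",
    length(x$deformations), nrow(x$control_points),
    x$kernel$lambda_w, x$kernel$lambda_v))
  cat(sprintf("  template mesh: %d vertices, %d faces; total cost %.4g -> %.4g%s\n",
              nrow(x$surface$vertices), nrow(x$surface$faces),
              x$cost_trace[1L], utils::tail(x$cost_trace, 1L),
              if (x$converged) "" else " (iteration cap)"))
  invisible(x)
}

#' @export
summary.ssm_template <- function(object, ...) {
  print(object)
  mom <- vapply(object$deformations, function(d)
    sqrt(sum(initial_momenta(d)^2)), numeric(1))
  cat("  per-subject |momenta|: ",
      paste(sprintf("%.3g", mom), collapse = ", "), "\n")
  invisible(mom)
}

#' Moment matrix of a fitted template
#'
#' One row per subject: the initial momenta flattened and whitened with a
#' square root of the control-point kernel matrix `K_V`, so that the
#' Euclidean inner product of two rows equals the kernel inner product
#' `sum_kl K_V(q_k, q_l) <alpha_k, beta_l>` of the corresponding momenta.
#' These rows are the PLS predictors.
#'
#' @param t an `ssm_template` from [compute_template()].
#' @return a `moment_matrix`: `rows` (subjects x 3K), `subject_ids`,
#'   `control_points`, `lambda_v`, `whitener` (the kernel square root).
#' @export
moment_matrix <- function(t) {
  stopifnot(inherits(t, "ssm_template"))
  Q <- t$control_points
  K <- gauss_kernel(Q, Q, t$kernel$lambda_v)
  R <- tryCatch(chol(K), error = function(e) {
    warning("singular control-point kernel; jitter-regularised")
    chol(K + diag(1e-8 * mean(diag(K)), nrow(K)))
  })
  rows <- t(vapply(t$deformations, function(d)
    as.vector(R %*% initial_momenta(d)), numeric(3L * nrow(Q))))
  structure(list(rows = rows, subject_ids = t$subject_ids,
                 control_points = Q, lambda_v = t$kernel$lambda_v,
                 whitener = R),
            class = "moment_matrix")
}

#' @export
print.moment_matrix <- function(x, ...) {
  cat(sprintf("moment_matrix: %d subjects x %d whitened momentum coordinates (lambda_V = %g mm)\n",
              nrow(x$rows), ncol(x$rows), x$lambda_v))
  invisible(x)
}

# Reverse the whitening: map a moment-matrix row back to K x 3 momenta.
unwhiten_momenta <- function(mm, row) {
  backsolve(mm$whitener, matrix(row, ncol = 3L))
}

#' Write a template bundle to disk
#'
#' Writes the template mesh (VTK), per-subject initial momenta and the
#' shared control points (CSV), the kernel/configuration echo (YAML) and
#' the cost trace (CSV).
#'
#' @param t an `ssm_template`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_template_bundle <- function(t, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_surface(t$surface, file.path(dir, "template.vtk"))
  utils::write.csv(as.data.frame(t$control_points) |>
                     stats::setNames(c("x", "y", "z")),
                   file.path(dir, "control_points.csv"), row.names = FALSE)
  mom <- do.call(rbind, lapply(seq_along(t$deformations), function(i) {
    a <- initial_momenta(t$deformations[[i]])
    data.frame(subject_id = t$subject_ids[i], control_point = seq_len(nrow(a)),
               mx = a[, 1], my = a[, 2], mz = a[, 3])
  }))
  utils::write.csv(mom, file.path(dir, "momenta.csv"), row.names = FALSE)
  yaml::write_yaml(list(lambda_w = t$kernel$lambda_w,
                        lambda_v = t$kernel$lambda_v,
                        gamma = t$gamma,
                        n_time_steps = t$n_time_steps,
                        n_subjects = length(t$deformations),
                        converged = t$converged),
                   file.path(dir, "config.yaml"))
  utils::write.csv(data.frame(iteration = seq_along(t$cost_trace) - 1L,
                              cost = t$cost_trace),
                   file.path(dir, "cost_trace.csv"), row.names = FALSE)
  invisible(dir)
}
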