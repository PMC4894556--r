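# Partial least squares (PLS1, NIPALS) on the moment matrix: extracts
# shape modes -- deformation directions most correlated with a response
# (BSA for size, EF for function) -- and per-subject shape vectors, plus
# the residualization and Cook's-distance screening used around them.

mm_rows <- function(X) if (inherits(X, "moment_matrix")) X$rows else as.matrix(X)

#' Fit a PLS regression of a response on the moment matrix
#'
#' NIPALS PLS1: the first weight vector is proportional to `X' y` on the
#' centered data; scores, loadings and deflation follow the standard
#' algorithm. `explained_shape_variability` per component is
#' `||t_c p_c'||_F^2 / ||X_centered||_F^2`, the fraction of (whitened,
#' i.e. kernel-metric) moment variance reconstructed by the component.
#'
#' @param X a [moment_matrix()] or numeric matrix (subjects x predictors).
#' @param y numeric response, one value per subject.
#' @param n_components number of components (default 1).
#' @return a `pls_model` with `x_weights`, `x_loadings`, `x_scores`,
#'   `y_loadings`, `x_center`, `y_center`, `explained_shape_variability`,
#'   `coefficients` (regression vector on the original scale), `fitted`.
#' @export
pls_fit <- function(X, y, n_components = 1L) {
  Xm <- mm_rows(X)
  y <- as.numeric(y)
  n <- nrow(Xm)
  if (n < 3L) stop("need at least 3 subjects")
  if (length(y) != n) stop("response length must match subject count")
  if (any(!is.finite(y))) stop("response must be finite")
  if (stats::sd(y) == 0) stop("constant response")
  x_center <- colMeans(Xm)
  y_center <- mean(y)
  E <- sweep(Xm, 2L, x_center)
  f <- y - y_center
  ssx <- sum(E^2)
  rank_max <- qr(E)$rank
  if (n_components > rank_max) {
    stop(sprintf("n_components (%d) exceeds rank(X) = %d", n_components, rank_max))
  }
  W <- P <- matrix(0, ncol(Xm), n_components)
  TT <- matrix(0, n, n_components)
  q <- numeric(n_components)
  expl <- numeric(n_components)
  for (c_ in seq_len(n_components)) {
    w <- crossprod(E, f)
    wn <- sqrt(sum(w^2))
    if (wn < 1e-300) stop("response uncorrelated with remaining predictors")
    w <- w / wn
    t_ <- as.vector(E %*% w)
    tt <- sum(t_^2)
    p <- as.vector(crossprod(E, t_)) / tt
    qc <- sum(f * t_) / tt
    expl[c_] <- tt * sum(p^2) / ssx
    E <- E - tcrossprod(t_, p)
    f <- f - qc * t_
    W[, c_] <- w; P[, c_] <- p; TT[, c_] <- t_; q[c_] <- qc
  }
  # regression vector on centered X: b = W (P'W)^{-1} q
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- as.vector(sweep(Xm, 2L, x_center) %*% B) + y_center
  structure(list(x_weights = W, x_loadings = P, x_scores = TT,
                 y_loadings = q, x_center = x_center, y_center = y_center,
                 n_components = n_components,
                 explained_shape_variability = expl,
                 coefficients = as.vector(B), fitted = fitted,
                 subject_ids = if (inherits(X, "moment_matrix")) X$subject_ids
                               else rownames(Xm)),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("pls_model: %d component(s), %d predictors\n",
              x$n_components, length(x$x_center)))
  cat(sprintf("  explained shape variability: %s\n",
              paste(sprintf("%.1f%%", 100 * x$explained_shape_variability),
                    collapse = ", ")))
  invisible(x)
}

#' Predicted response for (new) moment rows
#'
#' @param object a `pls_model`.
#' @param newdata [moment_matrix()] or matrix; defaults to fitted values.
#' @param ... unused.
#' @export
predict.pls_model <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Xm <- mm_rows(newdata)
  as.vector(sweep(Xm, 2L, object$x_center) %*% object$coefficients) +
    object$y_center
}

#' Shape vector: per-subject projection onto a shape mode
#'
#' Projects centered moment rows onto the weight direction of one PLS
#' component. For in-sample rows of the training matrix this equals the
#' stored x-scores exactly; new subjects are projected with the stored
#' center and weights (with deflation for components beyond the first).
#'
#' @param model a `pls_model`.
#' @param X a [moment_matrix()] or matrix.
#' @param component which component (default 1).
#' @param response_name label for reports.
#' @return a `shape_vector`: `values` (one scalar per subject),
#'   `response_name`, `component`, `subject_ids`.
#' @export
shape_vector <- function(model, X, component = 1L, response_name = "response") {
  stopifnot(inherits(model, "pls_model"))
  Xm <- mm_rows(X)
  if (ncol(Xm) != length(model$x_center)) stop("dimension mismatch")
  E <- sweep(Xm, 2L, model$x_center)
  vals <- NULL
  for (c_ in seq_len(component)) {
    t_ <- as.vector(E %*% model$x_weights[, c_])
    if (c_ == component) vals <- t_
    E <- E - tcrossprod(t_, model$x_loadings[, c_])
  }
  structure(list(values = vals, response_name = response_name,
                 component = component,
                 subject_ids = if (inherits(X, "moment_matrix")) X$subject_ids
                               else rownames(Xm)),
            class = "shape_vector")
}

#' @export
print.shape_vector <- function(x, ...) {
  cat(sprintf("shape_vector (%s, component %d): n = %d, range [%.3g, %.3g]\n",
              x$response_name, x$component, length(x$values),
              min(x$values), max(x$values)))
  invisible(x)
}

#' Remove a fitted shape mode from the moment matrix
#'
#' Deflates the rank-one structure of each fitted component:
#' `X_resid = X_orig - XS XL'`. After residualization the scores of the
#' removed mode are orthogonal to every residual column, so a subsequent
#' PLS (e.g. with EF as response) extracts shape features uncorrelated
#' with the removed (size/BSA) mode.
#'
#' @param X_orig the [moment_matrix()] (or matrix) the model was fitted on.
#' @param first_fit the `pls_model` fitted on `X_orig`.
#' @return object of the same type as `X_orig` with deflated rows.
#' @export
residualize <- function(X_orig, first_fit) {
  stopifnot(inherits(first_fit, "pls_model"))
  Xm <- mm_rows(X_orig)
  if (ncol(Xm) != length(first_fit$x_center)) stop("model/matrix mismatch")
  recon <- tcrossprod(first_fit$x_scores, first_fit$x_loadings)
  out <- Xm - recon
  if (inherits(X_orig, "moment_matrix")) {
    X_orig$rows <- out
    X_orig
  } else {
    out
  }
}

#' Cook's-distance screening of influential subjects in a PLS fit
#'
#' For each subject i the PLS regression is refitted on the remaining
#' n - 1 subjects and all n responses are re-predicted;
#' `D_i = sum_j (yhat_j - yhat_j(i))^2 / (p * MSE)` with
#' `MSE = mean((y - yhat)^2)` from the full fit and `p` the number of
#' regression coefficients (components + intercept). Subjects with
#' `D_i > 4 * mean(D)` are flagged as potentially influential.
#'
#' @param X a [moment_matrix()] or matrix.
#' @param y numeric response.
#' @param n_components PLS components (default 1).
#' @param threshold_factor multiple of the mean defining the flag threshold
#'   (default 4).
#' @return a `cook_report`: `distances`, `threshold`, `flagged` (indices),
#'   `flagged_ids`, `mse`, `p`.
#' @export
cooks_flag <- function(X, y, n_components = 1L, threshold_factor = 4) {
  Xm <- mm_rows(X)
  n <- nrow(Xm)
  if (n < 4L) stop("need at least 4 subjects")
  full <- pls_fit(Xm, y, n_components)
  yhat <- full$fitted
  mse <- mean((y - yhat)^2)
  p <- n_components + 1L
  D <- numeric(n)
  for (i in seq_len(n)) {
    fit_i <- tryCatch(pls_fit(Xm[-i, , drop = FALSE], y[-i], n_components),
                      error = function(e) NULL)
    if (is.null(fit_i)) {
      D[i] <- Inf
      next
    }
    yhat_i <- predict(fit_i, Xm)
    D[i] <- sum((yhat - yhat_i)^2) / (p * mse)
  }
  thr <- threshold_factor * mean(D[is.finite(D)])
  flagged <- which(D > thr | !is.finite(D))
  ids <- if (inherits(X, "moment_matrix")) X$subject_ids else rownames(Xm)
  structure(list(distances = D, threshold = thr, flagged = flagged,
                 flagged_ids = if (!is.null(ids)) ids[flagged] else NULL,
                 mse = mse, p = p, n = n),
            class = "cook_report")
}

#' @export
print.cook_report <- function(x, ...) {
  cat(sprintf("cook_report: n = %d, threshold = %.4g (4 x mean D)\n",
              x$n, x$threshold))
  if (length(x$flagged) == 0L) {
    cat("  no influential subjects flagged\n")
  } else {
    cat("  flagged:",
        paste(if (is.null(x$flagged_ids)) x$flagged else x$flagged_ids,
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Correlation with a normality gate
#'
#' Shapiro-Wilk normality is tested on both variables; if either test is
#' significant at the 0.05 level, non-parametric Kendall's tau is
#' reported, otherwise Pearson's r. Both coefficients are retrievable
#' from the returned object. P-values are two-tailed and unadjusted.
#'
#' @param a,b numeric vectors of equal length >= 3.
#' @return a `correlation_report`: `coefficient`, `p_value`, `method`
#'   ("pearson"/"kendall"), `normality_p` (length 2), `pearson`, `kendall`.
#' @export
correlate <- function(a, b) {
  a <- as.numeric(a)
  b <- as.numeric(b)
  if (length(a) != length(b) || length(a) < 3L) stop("need equal lengths >= 3")
  if (any(!is.finite(a)) || any(!is.finite(b))) stop("inputs must be finite")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("constant input: correlation undefined")
  }
  sw <- c(a = stats::shapiro.test(a)$p.value, b = stats::shapiro.test(b)$p.value)
  method <- if (any(sw < 0.05)) "kendall" else "pearson"
  pear <- stats::cor.test(a, b, method = "pearson")
  ken <- suppressWarnings(stats::cor.test(a, b, method = "kendall"))
  chosen <- if (method == "pearson") pear else ken
  structure(list(coefficient = unname(chosen$estimate),
                 p_value = chosen$p.value,
                 method = method,
                 normality_p = sw,
                 pearson = unname(pear$estimate),
                 kendall = unname(ken$estimate)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  sym <- if (x$method == "pearson") "r" else "tau"
  cat(sprintf("correlation_report: %s = %.3f (p = %.4g, %s; Shapiro-Wilk p = %.3g / %.3g)\n",
              sym, x$coefficient, x$p_value, x$method,
              x$normality_p[1], x$normality_p[2]))
  invisible(x)
}

#' Deform the template along a shape mode
#'
#' Reconstructs the mode direction in momentum space (un-whitening the PLS
#' weight vector through the kernel square root) and shoots the template
#' along it: for each `t` in `t_values` the momenta are
#' `t * sd(scores) * direction`, so `t = 0` returns the template itself
#' and `t = +/-1` show the mode at one score standard deviation.
#'
#' @param template an `ssm_template`.
#' @param model a `pls_model` fitted on the template's [moment_matrix()].
#' @param t_values numeric multipliers (in score standard deviations).
#' @param mm the [moment_matrix()] used for the fit (supplies the
#'   whitener); recomputed from `template` if omitted.
#' @param component mode to visualise (default 1).
#' @return list of [triangle_surface()] meshes, one per `t` value.
#' @export
mode_deform_sequence <- function(template, model, t_values, mm = NULL,
                                 component = 1L) {
  stopifnot(inherits(template, "ssm_template"), inherits(model, "pls_model"))
  if (is.null(mm)) mm <- moment_matrix(template)
  if (any(abs(t_values) > 3)) {
    warning("t beyond +/-3 score standard deviations extrapolates the mode")
  }
  w <- model$x_weights[, component]
  A_dir <- unwhiten_momenta(mm, w)
  sigma <- stats::sd(model$x_scores[, component])
  lapply(t_values, function(t_) {
    if (t_ == 0) return(template$surface)
    df <- deformation_field(template$control_points, t_ * sigma * A_dir,
                            template$n_time_steps, template$kernel$lambda_v)
    apply_deformation(df, template$surface)
  })
}

#' Write a shape-vector table to CSV
#'
#' @param sv a `shape_vector`.
#' @param response the measured response values (optional).
#' @param path output CSV path.
#' @export
write_shape_vector <- function(sv, response = NULL, path) {
  df <- data.frame(
    subject_id = if (is.null(sv$subject_ids)) seq_along(sv$values) else sv$subject_ids,
    shape_vector = sv$values)
  if (!is.null(response)) df[[sv$response_name]] <- response
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
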