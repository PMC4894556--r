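# Currents representation of a surface: each triangle contributes a Dirac
# delta current at its barycenter carrying the area-weighted face normal.
# Two currents are compared through a Gaussian reproducing kernel of width
# lambda_w; the kernel convention used throughout is
#   k(x, y) = exp(-||x - y||^2 / lambda_w^2)
# (no factor 2 in the denominator), so that kernel widths derived from
# probed surface-area fractions keep their meaning. Normals carry units of
# mm^2 and inner products mm^4.

#' Convert a surface to its currents representation
#'
#' @param s a [triangle_surface()].
#' @param lambda_w kernel width \[mm\] of the currents metric; controls the
#'   spatial scale below which shape features are smoothed away.
#' @return a `currents_rep` object: `centers` (face barycenters, mm),
#'   `normals` (area-weighted face normals, mm^2), `lambda_w`.
#' @export
to_currents <- function(s, lambda_w) {
  stopifnot(inherits(s, "triangle_surface"))
  if (lambda_w <= 0) stop("lambda_w must be > 0")
  structure(list(centers = face_centers(s$vertices, s$faces),
                 normals = face_normals(s$vertices, s$faces),
                 lambda_w = lambda_w),
            class = "currents_rep")
}

#' @export
print.currents_rep <- function(x, ...) {
  cat(sprintf("currents_rep: %d Dirac currents, lambda_W = %g mm, |total| = %.3g mm^2\n",
              nrow(x$centers), x$lambda_w, sqrt(sum(colSums(x$normals)^2))))
  invisible(x)
}

check_same_lambda <- function(a, b) {
  if (!isTRUE(all.equal(a$lambda_w, b$lambda_w))) {
    stop("kernel-width mismatch between currents representations")
  }
}

# Gaussian kernel matrix exp(-||x_i - y_j||^2 / lambda^2)
gauss_kernel <- function(X, Y, lambda) {
  d2 <- outer(rowSums(X * X), rowSums(Y * Y), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(d2, 0) / lambda^2)
}

#' Currents inner product
#'
#' Direct double-sum evaluation
#' `sum_f sum_g exp(-||c_f - c_g||^2 / lambda_W^2) (n_f . n_g)` \[mm^4\].
#'
#' @param a,b `currents_rep` objects with matching `lambda_w`.
#' @return scalar inner product \[mm^4\].
#' @export
currents_inner <- function(a, b) {
  stopifnot(inherits(a, "currents_rep"), inherits(b, "currents_rep"))
  check_same_lambda(a, b)
  K <- gauss_kernel(a$centers, b$centers, a$lambda_w)
  sum(K * tcrossprod(a$normals, b$normals))
}

#' Squared currents distance
#'
#' `||a||^2 - 2 <a, b> + ||b||^2`; zero iff the two currents coincide
#' (up to numerical tolerance).
#'
#' @param a,b `currents_rep` objects with matching `lambda_w`.
#' @return non-negative scalar \[mm^4\].
#' @export
currents_distance2 <- function(a, b) {
  max(currents_inner(a, a) - 2 * currents_inner(a, b) + currents_inner(b, b), 0)
}

#' Currents Gram matrix of a set of surfaces
#'
#' @param surfaces list of [triangle_surface()] objects.
#' @param lambda_w kernel width \[mm\].
#' @return symmetric positive semi-definite matrix of pairwise inner
#'   products \[mm^4\].
#' @export
currents_gram <- function(surfaces, lambda_w) {
  reps <- lapply(surfaces, to_currents, lambda_w = lambda_w)
  n <- length(reps)
  G <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      G[i, j] <- G[j, i] <- currents_inner(reps[[i]], reps[[j]])
    }
  }
  G
}

# Pooled currents of several surfaces with weights (used for the mean
# current: weights = 1/N). Represented as one currents_rep whose normals
# are scaled by the weights.
pooled_currents <- function(surfaces, lambda_w, weights = NULL) {
  reps <- lapply(surfaces, to_currents, lambda_w = lambda_w)
  if (is.null(weights)) weights <- rep(1 / length(reps), length(reps))
  structure(list(
    centers = do.call(rbind, lapply(reps, `[[`, "centers")),
    normals = do.call(rbind, mapply(function(r, w) r$normals * w,
                                    reps, weights, SIMPLIFY = FALSE)),
    lambda_w = lambda_w), class = "currents_rep")
}

# Dump (centers, normals) for debugging / external inspection.
currents_to_csv <- function(x, path) {
  df <- data.frame(cx = x$centers[, 1], cy = x$centers[, 2], cz = x$centers[, 3],
                   nx = x$normals[, 1], ny = x$normals[, 2], nz = x$normals[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
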