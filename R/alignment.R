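# Rigid alignment: ICP to an initial reference picked by gross geometry,
# then a Generalised-Procrustes-style loop re-aligning to successive
# templates until model compactness stops decreasing. Rigid only -- no
# scaling: size is retained deliberately and handled later by BSA
# residualization.

# Kabsch/SVD solve for the rigid transform minimising ||R P + t - Q||^2.
kabsch_rigid <- function(P, Q) {
  cp <- colMeans(P)
  cq <- colMeans(Q)
  H <- crossprod(sweep(P, 2L, cp), sweep(Q, 2L, cq))
  sv <- svd(H)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  t_ <- cq - as.vector(R %*% cp)
  list(rotation = R, translation = t_)
}

#' Rigid ICP registration of one surface onto another
#'
#' Iterates closest-point correspondence (moving vertices against the
#' fixed mesh's triangles) with an SVD rigid solve (rotation +
#' translation only, no scaling). Stops when the RMS change drops below
#' `tol` or after `max_iter` iterations; iterations that would increase
#' the RMS are rejected and terminate the loop.
#'
#' @param moving,fixed [triangle_surface()] objects.
#' @param max_iter maximum iterations (default 50).
#' @param tol RMS change convergence tolerance \[mm\] (default 1e-4).
#' @return list with `rotation` (3x3), `translation` \[mm\], final `rms`
#'   \[mm\], `iterations`, and `aligned` (the transformed moving surface).
#' @export
icp_rigid <- function(moving, fixed, max_iter = 50L, tol = 1e-4) {
  stopifnot(inherits(moving, "triangle_surface"),
            inherits(fixed, "triangle_surface"))
  if (nrow(moving$vertices) == 0L || nrow(fixed$vertices) == 0L) {
    stop("empty mesh")
  }
  P0 <- moving$vertices
  # initialise with centroid alignment
  R <- diag(3)
  t_ <- colMeans(fixed$vertices) - colMeans(P0)
  P <- sweep(P0, 2L, -t_)
  cp <- closest_points_on_surface(P, fixed)
  rms <- sqrt(mean(cp$distance^2))
  iters <- 0L
  for (it in seq_len(max_iter)) {
    if (max(cp$distance) < 1e-12) break
    if (sum(apply(cp$points, 2L, stats::var)) < 1e-20) {
      stop("degenerate correspondence: all target points coincident")
    }
    tr <- kabsch_rigid(P, cp$points)
    P_new <- sweep(P %*% t(tr$rotation), 2L, -tr$translation)
    cp_new <- closest_points_on_surface(P_new, fixed)
    rms_new <- sqrt(mean(cp_new$distance^2))
    if (rms_new > rms + 1e-12) break   # never accept an RMS increase
    R <- tr$rotation %*% R
    t_ <- as.vector(tr$rotation %*% t_) + tr$translation
    P <- P_new
    cp <- cp_new
    iters <- it
    if (abs(rms - rms_new) < tol) { rms <- rms_new; break }
    rms <- rms_new
  }
  aligned <- moving
  aligned$vertices <- P
  list(rotation = R, translation = t_, rms = rms, iterations = iters,
       aligned = aligned)
}

#' Pick the initial reference subject
#'
#' The reference is the subject closest to the population "centre" in
#' terms of gross geometry: each of the four descriptors (V, A_surf,
#' L_CL, D_med) is z-scored across subjects and the subject with the
#' smallest Euclidean distance to the zero vector is returned. Ties break
#' to the lowest index; zero-variance descriptors are dropped with a
#' warning.
#'
#' @param descriptors data frame or matrix with one row per subject and
#'   columns for the gross descriptors (typically V, A_surf, L_CL, D_med).
#' @return the selected subject's row index.
#' @export
pick_initial_reference <- function(descriptors) {
  X <- as.matrix(descriptors)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  if (any(!is.finite(X))) stop("descriptors must be finite")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance descriptor(s) dropped: ",
            paste(colnames(X)[sds == 0], collapse = ", "))
    X <- X[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  if (ncol(X) == 0L) return(1L)
  Z <- scale(X, center = TRUE, scale = sds)
  which.min(rowSums(Z^2))
}

#' Model compactness of a deformation model
#'
#' Total variance of the subject deformations: the sum of the eigenvalues
#' of the covariance of the moment-matrix rows, computed equivalently as
#' the mean squared deviation of rows from the row mean. A lower value
#' means a tighter (more compact) shape model; the GPA loop stops when it
#' no longer decreases.
#'
#' @param X moment matrix (subjects x parameters), a [moment_matrix()]
#'   object or plain matrix.
#' @return non-negative scalar.
#' @export
model_compactness <- function(X) {
  if (inherits(X, "moment_matrix")) X <- X$rows
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 subjects")
  mu <- colMeans(X)
  mean(rowSums(sweep(X, 2L, mu)^2))
}

#' Procrustes-style alignment loop against successive templates
#'
#' All surfaces are first rigidly aligned (ICP) to a reference; a template
#' is computed; then the loop re-aligns every subject to the current
#' template, recomputes the template, and evaluates the model compactness.
#' The loop stops as soon as the compactness fails to decrease, returning
#' the last accepted configuration and the compactness trace.
#'
#' @param surfaces list of [triangle_surface()] objects.
#' @param atlas_config list of arguments passed to [compute_template()]
#'   (kernel etc.); see [atlas_config()].
#' @param reference index of the initial reference subject; if `NULL` it is
#'   chosen by [pick_initial_reference()] on gross mesh descriptors
#'   (A_surf, bounding-box diagonal and mean centroid distance as cheap
#'   stand-ins when centreline descriptors are unavailable).
#' @param max_iter maximum Procrustes iterations (default 5).
#' @return list with `aligned` (surfaces of the last accepted iteration),
#'   `template` (its template), `compactness_trace`, `transforms`
#'   (per-subject rotation/translation of the last accepted iteration) and
#'   `reference` index.
#' @export
gpa_align <- function(surfaces, atlas_config = NULL, reference = NULL,
                      max_iter = 5L) {
  n <- length(surfaces)
  if (n < 2L) stop("need at least 2 surfaces")
  if (is.null(atlas_config)) atlas_config <- list()
  if (is.null(reference)) {
    desc <- t(vapply(surfaces, function(s) {
      m <- surface_measures(s)
      bb <- apply(s$vertices, 2L, range)
      ctr <- colMeans(s$vertices)
      c(a_surf = m$area,
        bbox_diag = sqrt(sum((bb[2, ] - bb[1, ])^2)),
        mean_radius = mean(sqrt(rowSums(sweep(s$vertices, 2L, ctr)^2))))
    }, numeric(3)))
    reference <- pick_initial_reference(desc)
  }
  align_to <- function(target, surfs) {
    lapply(surfs, function(s) icp_rigid(s, target))
  }
  res <- align_to(surfaces[[reference]], surfaces)
  aligned <- lapply(res, `[[`, "aligned")
  transforms <- lapply(res, function(r) r[c("rotation", "translation")])
  tmpl <- do.call(compute_template,
                  c(list(surfaces = aligned, init = aligned[[reference]]),
                    atlas_config))
  comp <- model_compactness(moment_matrix(tmpl))
  trace <- comp
  best <- list(aligned = aligned, template = tmpl, transforms = transforms)
  for (it in seq_len(max_iter)) {
    res_new <- align_to(tmpl$surface, surfaces)
    aligned_new <- lapply(res_new, `[[`, "aligned")
    tmpl_new <- do.call(compute_template,
                        c(list(surfaces = aligned_new,
                               init = tmpl$surface), atlas_config))
    comp_new <- model_compactness(moment_matrix(tmpl_new))
    trace <- c(trace, comp_new)
    if (comp_new >= comp - 1e-12) break
    comp <- comp_new
    tmpl <- tmpl_new
    best <- list(aligned = aligned_new, template = tmpl_new,
                 transforms = lapply(res_new, function(r)
                   r[c("rotation", "translation")]))
  }
  c(best, list(compactness_trace = trace, reference = reference))
}

# Alignment report: per-subject transforms (rotation as quaternion +
# translation) and the compactness trace, as JSON.
write_alignment_report <- function(gpa, path) {
  quat <- function(R) {
    tr <- sum(diag(R))
    if (tr > 0) {
      s <- sqrt(tr + 1) * 2
      c((R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
        (R[2, 1] - R[1, 2]) / s, 0.25 * s)[c(4, 1, 2, 3)]
    } else {
      i <- which.max(diag(R))
      j <- i %% 3L + 1L; k <- j %% 3L + 1L
      s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
      q <- numeric(4)
      q[i + 1L] <- 0.25 * s
      q[j + 1L] <- (R[j, i] + R[i, j]) / s
      q[k + 1L] <- (R[k, i] + R[i, k]) / s
      q[1L] <- (R[k, j] - R[j, k]) / s
      q
    }
  }
  report <- list(
    reference = gpa$reference,
    compactness_trace = gpa$compactness_trace,
    transforms = lapply(gpa$transforms, function(tr)
      list(quaternion_wxyz = quat(tr$rotation), translation = tr$translation)))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
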