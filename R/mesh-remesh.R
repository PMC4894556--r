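# Re-meshing by midpoint subdivision (refinement) and grid vertex
# clustering (decimation), plus a Taubin-type non-shrinking passband
# smoother. Mesh density is measured as faces / A_surf [cells/mm^2].

mesh_density <- function(s) nrow(s$faces) / surface_measures(s)$area

# 1:4 midpoint subdivision (each triangle split at edge midpoints).
subdivide_midpoint <- function(s) {
  v <- s$vertices
  f <- s$faces
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  keys <- ekey(e[, 1], e[, 2])
  uk <- !duplicated(keys)
  mids <- (v[e[uk, 1L], , drop = FALSE] + v[e[uk, 2L], , drop = FALSE]) / 2
  mid_idx <- stats::setNames(nrow(v) + seq_len(sum(uk)), keys[uk])
  v2 <- rbind(v, mids)
  m12 <- mid_idx[ekey(f[, 1], f[, 2])]
  m23 <- mid_idx[ekey(f[, 2], f[, 3])]
  m31 <- mid_idx[ekey(f[, 3], f[, 1])]
  f2 <- rbind(cbind(f[, 1], m12, m31),
              cbind(m12, f[, 2], m23),
              cbind(m31, m23, f[, 3]),
              cbind(m12, m23, m31))
  triangle_surface(v2, f2, subject_id = s$subject_id, clean = FALSE)
}

# Decimation by uniform-grid vertex clustering with cell size h.
# Boundary vertices are never merged so boundary loops survive.
cluster_decimate <- function(s, h) {
  v <- s$vertices
  f <- s$faces
  bnd <- unique(as.vector(boundary_edges(s)))
  cell <- floor(sweep(v, 2L, apply(v, 2L, min)) / h)
  key <- paste(cell[, 1], cell[, 2], cell[, 3], sep = "/")
  key[bnd] <- paste0("b", seq_along(bnd))   # boundary vertices stay distinct
  grp <- match(key, key)
  reps <- sort(unique(grp))
  remap <- integer(nrow(v))
  remap[reps] <- seq_along(reps)
  # cluster representative = centroid of members (boundary: the vertex itself)
  v2 <- rowsum(v, group = grp) / as.vector(table(grp)[as.character(reps)])
  f2 <- matrix(remap[grp[f]], ncol = 3L)
  ok <- f2[, 1] != f2[, 2] & f2[, 2] != f2[, 3] & f2[, 1] != f2[, 3]
  f2 <- f2[ok, , drop = FALSE]
  # drop duplicated faces and zero-area slivers; keep inherited orientation
  # (orientation re-check is skipped: clustering preserves traversal order)
  if (nrow(f2) > 0L) {
    fk <- apply(f2, 1L, function(r) paste(sort(r), collapse = "-"))
    f2 <- f2[!duplicated(fk), , drop = FALSE]
    ar <- triangle_areas(v2, f2)
    f2 <- f2[ar > 1e-12, , drop = FALSE]
  }
  used <- sort(unique(as.vector(f2)))
  if (length(used) < nrow(v2)) {
    remap3 <- integer(nrow(v2))
    remap3[used] <- seq_along(used)
    v2 <- v2[used, , drop = FALSE]
    f2 <- matrix(remap3[f2], ncol = 3L)
  }
  triangle_surface(v2, f2, subject_id = s$subject_id, clean = FALSE)
}

# Taubin lambda/mu smoothing with passband k_pb = 1/lambda + 1/mu.
# Boundary vertices are kept fixed so open ends do not collapse.
taubin_smooth <- function(s, passband = 0.1, iterations = 30L) {
  if (iterations <= 0L) return(s)
  lambda <- 0.33
  mu <- 1 / (passband - 1 / lambda)
  v <- s$vertices
  f <- s$faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)], f[, 2:1], f[, 3:2], f[, c(1L, 3L)])
  e <- unique(e)
  deg <- tabulate(e[, 1], nbins = nrow(v))
  bnd <- unique(as.vector(boundary_edges(s)))
  movable <- setdiff(seq_len(nrow(v)), bnd)
  step <- function(v, w) {
    nb_sum <- rowsum(v[e[, 2], , drop = FALSE], group = e[, 1],
                     reorder = TRUE)
    lap <- nb_sum / pmax(deg, 1L) - v
    v[movable, ] <- v[movable, , drop = FALSE] + w * lap[movable, , drop = FALSE]
    v
  }
  for (it in seq_len(iterations)) {
    v <- step(v, lambda)
    v <- step(v, mu)
  }
  s$vertices <- v
  s
}

#' Re-mesh to a target density and smooth
#'
#' The mesh is refined by midpoint subdivision and/or decimated by grid
#' vertex clustering until the face count is within 10 % of
#' `target_density * A_surf`, then smoothed with a Taubin-type
#' non-shrinking passband filter. Boundary loops are preserved (boundary
#' vertices are neither merged nor moved).
#'
#' @param s a [triangle_surface()].
#' @param target_density faces per mm^2 of surface (the paper-style
#'   cells/mm^2 unit).
#' @param passband smoothing passband (dimensionless), default 0.1.
#' @param iterations smoothing iterations, default 30; 0 disables smoothing.
#' @return re-meshed and smoothed `triangle_surface`.
#' @export
remesh_and_smooth <- function(s, target_density, passband = 0.1,
                              iterations = 30L) {
  stopifnot(inherits(s, "triangle_surface"))
  if (target_density <= 0) stop("target_density must be > 0")
  area <- surface_measures(s)$area
  target_faces <- target_density * area
  if (target_faces < 4) stop("density too low to preserve topology")
  # refine until at/above target
  guard <- 0L
  while (nrow(s$faces) < target_faces && guard < 8L) {
    s <- subdivide_midpoint(s)
    guard <- guard + 1L
  }
  if (nrow(s$faces) > 1.1 * target_faces) {
    # bisection on the clustering cell size; larger h -> fewer faces
    h_edge <- sqrt(2 / (target_density * sqrt(3)))   # isotropic edge length
    lo <- h_edge / 8
    hi <- h_edge * 8
    best <- NULL
    for (it in seq_len(30L)) {
      h <- sqrt(lo * hi)
      cand <- cluster_decimate(s, h)
      nf <- nrow(cand$faces)
      if (is.null(best) ||
          abs(nf - target_faces) < abs(nrow(best$faces) - target_faces)) {
        best <- cand
      }
      if (abs(nf - target_faces) <= 0.05 * target_faces) break
      if (nf > target_faces) lo <- h else hi <- h
    }
    s <- best
  }
  if (nrow(s$faces) > 1.1 * target_faces + 2 ||
      nrow(s$faces) < 0.9 * target_faces - 2) {
    warning(sprintf("re-meshing reached %d faces for target %.0f (>10%% off)",
                    nrow(s$faces), target_faces))
  }
  if (iterations > 0L) s <- taubin_smooth(s, passband, iterations)
  s
}

#' Scan mesh densities and select the coarsest acceptable one
#'
#' Re-meshes `s` at each density and selects the lowest density whose
#' surface area deviates from the original mesh's area by at most
#' `tolerance` (relative). This mirrors the practice of picking the
#' coarsest resolution whose surface error stays below a cut-off
#' (0.5 % by default) to keep template computation cheap.
#'
#' @param s a [triangle_surface()] (the original, reference mesh).
#' @param densities ascending vector of candidate densities \[cells/mm^2\].
#' @param tolerance maximum tolerated relative area deviation (default 0.005).
#' @param smooth_iterations smoothing iterations applied per candidate
#'   (default 0: measure the re-meshing error alone).
#' @return a `density_scan` object: `densities`, `areas`, `deviations`,
#'   `reference_area`, `selected_density`.
#' @export
select_mesh_density <- function(s, densities, tolerance = 0.005,
                                smooth_iterations = 0L) {
  stopifnot(length(densities) >= 1L)
  if (is.unsorted(densities)) stop("densities must be sorted ascending")
  ref <- surface_measures(s)$area
  areas <- vapply(densities, function(d) {
    surface_measures(remesh_and_smooth(s, d, iterations = smooth_iterations))$area
  }, numeric(1))
  dev <- abs(areas - ref) / ref
  pass <- which(dev <= tolerance)
  if (length(pass) == 0L) {
    stop(sprintf(
      "no scanned density meets the %.2f%% area tolerance (best deviation %.3f%% at %.3g cells/mm^2)",
      100 * tolerance, 100 * min(dev), densities[which.min(dev)]))
  }
  structure(list(densities = densities, areas = areas, deviations = dev,
                 reference_area = ref, tolerance = tolerance,
                 selected_density = densities[pass[1L]]),
            class = "density_scan")
}

#' @export
print.density_scan <- function(x, ...) {
  cat("mesh density scan (reference A_surf =",
      sprintf("%.1f mm^2)\n", x$reference_area))
  for (i in seq_along(x$densities)) {
    cat(sprintf("  %6.3g cells/mm^2: A_surf %10.2f, deviation %6.3f%%%s\n",
                x$densities[i], x$areas[i], 100 * x$deviations[i],
                if (x$densities[i] == x$selected_density) "  <- selected" else ""))
  }
  invisible(x)
}
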