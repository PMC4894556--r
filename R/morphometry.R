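# Centreline-based morphometry of tubular surfaces: a marching
# cross-section centreline (a deliberately simple replacement for
# medial-axis extractors), length/tortuosity/curvature descriptors,
# equivalent-area diameters along and at named levels of the vessel, and
# the 2D-style arch height A and width T.

# Intersection of the mesh with the plane through `point` with `normal`.
# Returns a list of loops; each loop has `points` (ordered polyline),
# `centroid`, `area` (planar polygon area) and `radius` = sqrt(area/pi).
cross_section <- function(s, point, normal) {
  normal <- normal / sqrt(sum(normal^2))
  d <- as.vector(sweep(s$vertices, 2L, point) %*% normal)
  f <- s$faces
  dmat <- matrix(d[f], ncol = 3L)
  hit <- which(apply(dmat, 1L, min) < 0 & apply(dmat, 1L, max) > 0)
  if (length(hit) == 0L) return(list())
  segs <- vector("list", length(hit))
  for (k in seq_along(hit)) {
    tri <- f[hit[k], ]
    dd <- d[tri]
    pts <- NULL
    for (e in list(c(1L, 2L), c(2L, 3L), c(3L, 1L))) {
      d1 <- dd[e[1L]]; d2 <- dd[e[2L]]
      if ((d1 < 0) != (d2 < 0)) {
        w <- d1 / (d1 - d2)
        p <- (1 - w) * s$vertices[tri[e[1L]], ] + w * s$vertices[tri[e[2L]], ]
        pts <- rbind(pts, p)
      }
    }
    if (!is.null(pts) && nrow(pts) == 2L) segs[[k]] <- pts
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0L) return(list())
  # chain segments into loops by matching endpoints
  ends <- do.call(rbind, segs)               # 2 rows per segment
  key <- apply(round(ends, 6L), 1L, paste, collapse = "/")
  nseg <- length(segs)
  used <- logical(nseg)
  by_key <- split(seq_len(2L * nseg), key)
  loops <- list()
  for (start in seq_len(nseg)) {
    if (used[start]) next
    used[start] <- TRUE
    path <- list(segs[[start]][1L, ], segs[[start]][2L, ])
    cur_key <- key[2L * start]
    repeat {
      cand <- by_key[[cur_key]]
      cand_seg <- ceiling(cand / 2)
      nxt <- cand[!used[cand_seg]]
      if (length(nxt) == 0L) break
      j <- nxt[1L]
      sj <- ceiling(j / 2)
      used[sj] <- TRUE
      other <- if (j %% 2L == 1L) 2L * sj else 2L * sj - 1L
      path[[length(path) + 1L]] <- ends[other, ]
      cur_key <- key[other]
    }
    P <- do.call(rbind, path)
    if (nrow(P) < 3L) next
    # drop the duplicated closing point if present
    if (sqrt(sum((P[1L, ] - P[nrow(P), ])^2)) < 1e-9) P <- P[-nrow(P), , drop = FALSE]
    if (nrow(P) < 3L) next
    loops[[length(loops) + 1L]] <- P
  }
  lapply(loops, function(P) {
    # planar polygon area via the cross-product sum projected on the normal
    ctr <- colMeans(P)
    Pc <- sweep(P, 2L, ctr)
    nr <- nrow(Pc)
    cr <- cross3(Pc, Pc[c(2:nr, 1L), , drop = FALSE])
    area <- abs(sum(colSums(cr) * normal)) / 2
    list(points = P, centroid = ctr, area = area, radius = sqrt(area / pi))
  })
}

loop_centroid_area <- function(s, loop_idx) {
  P <- s$vertices[loop_idx, , drop = FALSE]
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  # best-fit plane normal from the loop itself
  sv <- svd(Pc)
  nrm <- sv$v[, 3L]
  nr <- nrow(Pc)
  cr <- cross3(Pc, Pc[c(2:nr, 1L), , drop = FALSE])
  area <- abs(sum(colSums(cr) * nrm)) / 2
  list(centroid = ctr, area = area, radius = sqrt(area / pi), normal = nrm)
}

#' Extract a centreline by marching cross-sections
#'
#' Starting from the inlet boundary-loop centroid, the mesh is repeatedly
#' sliced with a plane normal to the running tangent; the intersection
#' loop whose centroid is nearest to the previous point provides the next
#' centreline point and the local equivalent radius
#' `sqrt(section area / pi)`. The march advances by `step_factor` times
#' the local radius and terminates at the outlet loop. The polyline is
#' smoothed with a small spline.
#'
#' @param s an open tubular [triangle_surface()] with exactly 2 boundary
#'   loops (or explicit loop choices).
#' @param inlet,outlet boundary loop indices (defaults: 1 and 2; loops are
#'   ordered as discovered).
#' @param step_factor advance per step in units of the local radius
#'   (default 0.5).
#' @param smooth_passes binomial (1-2-1) smoothing passes applied to the
#'   marched polyline (default 2); removes section-centroid jitter without
#'   distorting the global shape.
#' @param max_steps safety cap on marching steps.
#' @return a `centreline`: `points` (ordered polyline), `radii`,
#'   `arc_length` (cumulative, starting at 0).
#' @export
extract_centreline <- function(s, inlet = 1L, outlet = 2L, step_factor = 0.5,
                               smooth_passes = 2L, max_steps = 2000L) {
  loops <- boundary_loops(s)
  if (length(loops) == 0L) stop("non-tubular surface: closed mesh has no boundary loops")
  if (length(loops) != 2L && (inlet > length(loops) || outlet > length(loops))) {
    stop(sprintf("non-tubular surface: found %d boundary loops", length(loops)))
  }
  lin <- loop_centroid_area(s, loops[[inlet]])
  lout <- loop_centroid_area(s, loops[[outlet]])
  p <- lin$centroid
  mesh_ctr <- colMeans(s$vertices)
  # initial tangent: the inlet loop's plane normal, oriented inward
  t_ <- lin$normal
  if (sum(t_ * (mesh_ctr - p)) < 0) t_ <- -t_
  pts <- rbind(p)
  radii <- lin$radius
  r_loc <- lin$radius
  for (it in seq_len(max_steps)) {
    step <- step_factor * r_loc
    probe <- p + step * t_
    d_out <- sqrt(sum((probe - lout$centroid)^2))
    if (d_out < max(step, r_loc)) break
    secs <- cross_section(s, probe, t_)
    if (length(secs) == 0L) break
    dists <- vapply(secs, function(l) sqrt(sum((l$centroid - probe)^2)), numeric(1))
    sec <- secs[[which.min(dists)]]
    t_new <- sec$centroid - p
    nt <- sqrt(sum(t_new^2))
    if (nt < 1e-9) break
    # damped tangent update: avoids oscillation of the marching direction
    t_ <- 0.6 * t_new / nt + 0.4 * t_
    t_ <- t_ / sqrt(sum(t_^2))
    p <- sec$centroid
    r_loc <- sec$radius
    pts <- rbind(pts, p)
    radii <- c(radii, r_loc)
  }
  pts <- rbind(pts, lout$centroid)
  radii <- c(radii, lout$radius)
  n <- nrow(pts)
  if (n >= 5L && smooth_passes > 0L) {
    for (pass in seq_len(smooth_passes)) {
      interior <- 2:(n - 1L)
      pts[interior, ] <- (pts[interior - 1L, , drop = FALSE] +
                          2 * pts[interior, , drop = FALSE] +
                          pts[interior + 1L, , drop = FALSE]) / 4
    }
  }
  u <- c(0, cumsum(sqrt(rowSums(diff(pts)^2))))
  structure(list(points = pts, radii = radii, arc_length = u),
            class = "centreline")
}

#' @export
print.centreline <- function(x, ...) {
  cat(sprintf("centreline: %d points, length %.1f mm, radius %.2f-%.2f mm\n",
              nrow(x$points), max(x$arc_length), min(x$radii), max(x$radii)))
  invisible(x)
}

# Discrete curvature at interior points: reciprocal circumradius of point
# triples spaced `stencil` indices apart (wider stencils average out
# sampling jitter; exact for points on a circle at any spacing).
discrete_curvature <- function(P, stencil = 1L) {
  n <- nrow(P)
  k <- as.integer(stencil)
  if (n < 2L * k + 1L) return(numeric(0))
  p1 <- P[1:(n - 2L * k), , drop = FALSE]
  p2 <- P[(1L + k):(n - k), , drop = FALSE]
  p3 <- P[(1L + 2L * k):n, , drop = FALSE]
  a <- rownorm(p2 - p1)
  b <- rownorm(p3 - p2)
  c_ <- rownorm(p3 - p1)
  area2 <- rownorm(cross3(p2 - p1, p3 - p1))   # 2 * triangle area
  ifelse(area2 < 1e-12, 0, 2 * area2 / (a * b * c_))
}

#' Length, tortuosity and median curvature of a centreline
#'
#' `L_CL` is the polyline arc length; tortuosity is
#' `To_CL = L_CL / ||end - start|| - 1` (zero for a straight vessel);
#' `C_med` is the median of the discrete (circumradius-reciprocal)
#' curvature over consecutive point triples.
#'
#' @param c a [extract_centreline()] result (or list with `points`).
#' @return list `L_CL` \[mm\], `To_CL` \[-\], `C_med` \[1/mm\].
#' @export
centreline_descriptors <- function(c) {
  P <- c$points
  if (nrow(P) < 3L) stop("need at least 3 centreline points")
  L <- sum(rownorm(diff(P)))
  chord <- sqrt(sum((P[nrow(P), ] - P[1L, ])^2))
  if (chord < 1e-9) stop("coincident endpoints: tortuosity undefined")
  list(L_CL = L, To_CL = L / chord - 1,
       C_med = stats::median(discrete_curvature(P)))
}

#' Diameters along the centreline
#'
#' The per-point diameter is the equivalent-area circle diameter
#' `2 sqrt(A_section / pi)` of the cross-section normal to the local
#' tangent. The first and last 5 % of arc length are trimmed before
#' taking max/min/median (open-boundary sections are unreliable); level
#' diameters are interpolated at named arc-length fractions.
#'
#' @param s the tubular [triangle_surface()].
#' @param c its [extract_centreline()].
#' @param level_fractions named arc-length fractions in (0,1), e.g.
#'   `c(asc = 0.15, trans = 0.40, isth = 0.55, desc = 0.80)`.
#' @param trim fraction of arc length trimmed at each end (default 0.05).
#' @return list with `D_max`, `D_min`, `D_med` \[mm\], `levels` (named
#'   diameters), `profile` (data frame arc_fraction/diameter).
#' @export
diameters <- function(s, c, level_fractions = c(asc = 0.15, trans = 0.40,
                                                isth = 0.55, desc = 0.80),
                      trim = 0.05) {
  if (length(level_fractions) && (any(level_fractions <= 0) ||
                                  any(level_fractions >= 1))) {
    stop("level fractions must lie in (0, 1)")
  }
  P <- c$points
  u <- c$arc_length
  L <- max(u)
  n <- nrow(P)
  tang <- rbind(P[2L, ] - P[1L, ],
                P[3:n, , drop = FALSE] - P[1:(n - 2L), , drop = FALSE],
                P[n, ] - P[n - 1L, ])
  tang <- tang / pmax(rownorm(tang), 1e-12)
  D <- rep(NA_real_, n)
  multi <- FALSE
  for (i in seq_len(n)) {
    secs <- cross_section(s, P[i, ], tang[i, ])
    if (length(secs) == 0L) next
    if (length(secs) > 1L) multi <- TRUE
    dists <- vapply(secs, function(l) sqrt(sum((l$centroid - P[i, ])^2)),
                    numeric(1))
    D[i] <- 2 * secs[[which.min(dists)]]$radius
  }
  if (multi) warning("section plane intersected the mesh in multiple loops; nearest loop used")
  keep <- which(u >= trim * L & u <= (1 - trim) * L & !is.na(D))
  if (length(keep) < 3L) stop("too few valid sections after trimming")
  prof <- data.frame(arc_fraction = u[keep] / L, diameter = D[keep])
  lev <- vapply(level_fractions, function(fr)
    stats::approx(prof$arc_fraction, prof$diameter, xout = fr, rule = 2)$y,
    numeric(1))
  list(D_max = max(prof$diameter), D_min = min(prof$diameter),
       D_med = stats::median(prof$diameter), levels = lev, profile = prof)
}

#' Arch height A and width T of an arch-shaped centreline
#'
#' The centreline is projected onto its best-fit (PCA) plane and oriented
#' apex-up. Walking from the apex down each side, the shoulder-to-limb
#' transition is the first point where the discrete curvature drops below
#' `curvature_frac` times the arch's peak curvature (limbs are straight,
#' the arch is curved, so the transition sits at the arch base); the point
#' is refined by interpolating between the last curved and first straight
#' sample. The reference level is the mean height of the two transitions,
#' `A` is the apex elevation above it and `T` the horizontal distance
#' between the transition points. A numeric `level_height` instead
#' measures both at that height above the endpoints' mean level.
#'
#' @param c a [extract_centreline()] result.
#' @param level_height `"auto"` (default) or a height \[mm\] above the
#'   endpoints' mean level.
#' @param curvature_frac fraction of the peak arch curvature below which a
#'   point counts as limb (default 0.15).
#' @return list with `A` \[mm\], `T` \[mm\], `ratio_A_T`.
#' @export
arch_height_width <- function(c, level_height = "auto", curvature_frac = 0.15) {
  P <- c$points
  n <- nrow(P)
  if (n < 5L) stop("too few centreline points")
  ctr <- colMeans(P)
  Pc <- sweep(P, 2L, ctr)
  sv <- svd(Pc)
  g1 <- sv$v[, 1L]
  g2 <- sv$v[, 2L]
  x1 <- as.vector(Pc %*% g1)
  x2 <- as.vector(Pc %*% g2)
  # "up" = opposite of the mean in-plane direction of the two limb ends
  # (both limbs leave the arch downward); this stays anatomical even when
  # the limbs have unequal lengths and the endpoint chord is tilted.
  # Fallback when the end tangents cancel: perpendicular to the chord,
  # toward the point farthest from it.
  mid <- c(mean(c(x1[1L], x1[n])), mean(c(x2[1L], x2[n])))
  scale <- max(c$arc_length)
  arc <- c(0, cumsum(sqrt(diff(x1)^2 + diff(x2)^2)))
  j1 <- max(which(arc <= 0.08 * max(arc)))
  j2 <- min(which(arc >= 0.92 * max(arc)))
  j1 <- max(j1, 2L)
  j2 <- min(j2, n - 1L)
  w1 <- c(x1[1L] - x1[j1], x2[1L] - x2[j1])
  w2 <- c(x1[n] - x1[j2], x2[n] - x2[j2])
  w1 <- w1 / max(sqrt(sum(w1^2)), 1e-12)
  w2 <- w2 / max(sqrt(sum(w2^2)), 1e-12)
  down <- w1 + w2
  if (sqrt(sum(down^2)) > 0.5) {
    up <- -down / sqrt(sum(down^2))
  } else {
    ch <- c(x1[n] - x1[1L], x2[n] - x2[1L])
    nch <- sqrt(sum(ch^2))
    if (nch < 1e-6 * scale) stop("coincident endpoints")
    ch <- ch / nch
    proj <- (x1 - mid[1L]) * ch[1L] + (x2 - mid[2L]) * ch[2L]
    r1 <- (x1 - mid[1L]) - proj * ch[1L]
    r2 <- (x2 - mid[2L]) - proj * ch[2L]
    far <- which.max(r1^2 + r2^2)
    up <- c(r1[far], r2[far])
    nu <- sqrt(sum(up^2))
    if (nu < 1e-3 * scale) stop("no apex: centreline is monotone")
    up <- up / nu
  }
  uu <- (x1 - mid[1L]) * (-up[2L]) + (x2 - mid[2L]) * up[1L]
  vv <- (x1 - mid[1L]) * up[1L] + (x2 - mid[2L]) * up[2L]
  # resample the in-plane curve at uniform arc spacing so the curvature
  # analysis is independent of the marching step, then smooth away the
  # interpolation knots (running mean scaled to the original spacing)
  uarc <- c(0, cumsum(sqrt(diff(uu)^2 + diff(vv)^2)))
  L2 <- uarc[length(uarc)]
  spacing_orig <- L2 / (n - 1L)
  h <- max(min(1.5, L2 / 100), L2 / 400)
  grid <- seq(0, L2, by = h)
  uu <- stats::approx(uarc, uu, xout = grid)$y
  vv <- stats::approx(uarc, vv, xout = grid)$y
  n <- length(grid)
  passes <- min(8L, max(2L, ceiling((spacing_orig / h)^2 / 2)))
  for (ps in seq_len(passes)) {
    interior <- 2:(n - 1L)
    uu[interior] <- (uu[interior - 1L] + 2 * uu[interior] + uu[interior + 1L]) / 4
    vv[interior] <- (vv[interior - 1L] + 2 * vv[interior] + vv[interior + 1L]) / 4
  }
  v_end <- mean(c(vv[1L], vv[n]))
  apex <- which.max(vv)
  if (apex <= 1L || apex >= n || vv[apex] - v_end < 1e-3 * scale) {
    stop("no apex: centreline is monotone")
  }
  if (identical(level_height, "auto")) {
    # in-plane discrete curvature on a ~6 mm stencil, median-smoothed
    P2 <- cbind(uu, vv, 0)
    spacing <- h
    k <- max(2L, min(round(6 / spacing), (n - 1L) %/% 2 - 1L))
    kap <- c(rep(0, k), discrete_curvature(P2, stencil = k), rep(0, k))
    if (n >= 11L) kap <- stats::runmed(kap, 5L)
    kmax <- max(kap[max(apex - 2L, 1L):min(apex + 2L, n)], kap[apex])
    thr <- curvature_frac * kmax
    # The curvature profile drops from the arch plateau to ~0 over a ramp
    # (stencil-smeared step) at the arch base; the transition is the ramp
    # midpoint: halfway between the last clearly-curved and the first
    # clearly-straight sample.
    find_trans <- function(idx_seq) {
      kk <- kap[idx_seq]
      sub <- which(kk < thr)
      sub <- sub[sub > 1L]
      if (length(sub) == 0L) {
        i <- idx_seq[length(idx_seq)]
        return(c(u = uu[i], v = vv[i]))
      }
      first_sub <- sub[1L]
      # arch-plateau curvature: one stencil width before the drop
      plateau <- kk[max(first_sub - 2L * k, 1L)]
      hi_cand <- which(kk[seq_len(first_sub)] >= 0.75 * plateau)
      hi <- idx_seq[if (length(hi_cand)) max(hi_cand) else max(first_sub - 1L, 1L)]
      lo_cand <- which(kk <= 0.25 * plateau)
      lo_cand <- lo_cand[lo_cand >= first_sub - 1L]
      lo <- if (length(lo_cand)) idx_seq[lo_cand[1L]] else idx_seq[first_sub]
      c(u = (uu[hi] + uu[lo]) / 2, v = (vv[hi] + vv[lo]) / 2)
    }
    tl <- find_trans(seq(apex, 1L))
    tr_ <- find_trans(seq(apex, n))
    ref <- mean(c(tl["v"], tr_["v"]))
    T_ <- abs(tr_["u"] - tl["u"])
  } else {
    ref <- v_end + level_height
    # crossings of the reference level on each side of the apex
    cross_u <- function(idx_seq) {
      for (k in seq_len(length(idx_seq) - 1L)) {
        i <- idx_seq[k]; j <- idx_seq[k + 1L]
        if ((vv[i] - ref) * (vv[j] - ref) <= 0) {
          w <- (ref - vv[i]) / (vv[j] - vv[i] + 1e-300)
          return(uu[i] + w * (uu[j] - uu[i]))
        }
      }
      NA_real_
    }
    uL <- cross_u(seq(apex, 1L))
    uR <- cross_u(seq(apex, n))
    if (is.na(uL) || is.na(uR)) stop("reference level does not intersect both limbs")
    T_ <- abs(uR - uL)
  }
  A_ <- unname(vv[apex] - ref)
  T_ <- unname(T_)
  list(A = A_, T = T_, ratio_A_T = A_ / T_)
}

# Cap all boundary loops with centroid fans (used to measure the volume of
# an open tube); the result is cleaned and re-oriented.
cap_boundary_loops <- function(s) {
  loops <- boundary_loops(s)
  if (length(loops) == 0L) return(s)
  v <- s$vertices
  f <- s$faces
  for (lp in loops) {
    ctr <- colMeans(v[lp, , drop = FALSE])
    ci <- nrow(v) + 1L
    v <- rbind(v, ctr)
    nl <- length(lp)
    f <- rbind(f, cbind(ci, lp, lp[c(2:nl, 1L)]))
  }
  triangle_surface(v, f, subject_id = s$subject_id)
}

#' Compute the full geometric descriptor set of a tubular surface
#'
#' Assembles volume, surface area, centreline descriptors, diameters,
#' arch height/width and their ratios; when `bsa` is supplied the
#' BSA-indexed variants (prefix `i`, value divided by BSA) are added for
#' V, A_surf, L_CL, To_CL, C_med, all diameters, A and T. The volume of an
#' open tube is measured after capping the boundary loops with centroid
#' fans; `A_surf` always refers to the uncapped surface.
#'
#' @param s a tubular [triangle_surface()].
#' @param config list: `level_fractions` (see [diameters()]), `step_factor`,
#'   `trim`, `level_height`.
#' @param bsa body surface area \[m^2\] or `NULL`.
#' @param centreline optionally a precomputed [extract_centreline()].
#' @return a `geometric_descriptors` object (named list of scalars).
#' @export
compute_descriptors <- function(s, config = list(), bsa = NULL,
                                centreline = NULL) {
  lf <- config$level_fractions %||% c(asc = 0.15, trans = 0.40,
                                      isth = 0.55, desc = 0.80)
  m <- surface_measures(s)
  V <- if (m$closed) m$volume else surface_measures(cap_boundary_loops(s))$volume
  cl <- centreline %||% extract_centreline(
    s, step_factor = config$step_factor %||% 0.5)
  cd <- centreline_descriptors(cl)
  dia <- diameters(s, cl, level_fractions = lf, trim = config$trim %||% 0.05)
  aw <- tryCatch(arch_height_width(cl, config$level_height %||% "auto"),
                 error = function(e) list(A = NA_real_, T = NA_real_,
                                          ratio_A_T = NA_real_))
  out <- list(V = V, A_surf = m$area, ratio_A_surf_V = m$area / V,
              L_CL = cd$L_CL, To_CL = cd$To_CL, C_med = cd$C_med,
              D_max = dia$D_max, D_min = dia$D_min, D_med = dia$D_med)
  for (nm in names(dia$levels)) out[[paste0("D_", nm)]] <- dia$levels[[nm]]
  out$A <- aw$A
  out$T <- aw$T
  out$ratio_A_T <- aw$ratio_A_T
  if (!is.null(out$D_desc) && !is.null(out$D_asc)) {
    out$ratio_D_asc_D_desc <- out$D_asc / out$D_desc
    out$ratio_D_trans_D_desc <- out$D_trans / out$D_desc
    out$ratio_D_isth_D_desc <- out$D_isth / out$D_desc
  }
  if (!is.null(bsa)) {
    idx_fields <- c("V", "A_surf", "L_CL", "To_CL", "C_med",
                    "D_max", "D_min", "D_med",
                    paste0("D_", names(dia$levels)), "A", "T")
    for (nm in idx_fields) {
      if (!is.null(out[[nm]])) out[[paste0("i", nm)]] <- out[[nm]] / bsa
    }
    out$BSA <- bsa
  }
  structure(out, class = "geometric_descriptors")
}

#' @export
print.geometric_descriptors <- function(x, ...) {
  cat("geometric_descriptors:\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %12.4g\n", nm, x[[nm]]))
  }
  invisible(x)
}

#' Descriptor table of a cohort
#'
#' @param surfaces list of tubular [triangle_surface()] objects.
#' @param bsa optional numeric vector of BSA values \[m^2\].
#' @param config see [compute_descriptors()].
#' @return data frame, one row per subject.
#' @export
descriptor_table <- function(surfaces, bsa = NULL, config = list()) {
  rows <- lapply(seq_along(surfaces), function(i) {
    d <- compute_descriptors(surfaces[[i]], config = config,
                             bsa = if (is.null(bsa)) NULL else bsa[i])
    id <- surfaces[[i]]$subject_id
    cbind(data.frame(subject_id = if (is.null(id)) sprintf("S%02d", i) else id),
          as.data.frame(unclass(d)))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
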