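# Low-level triangle geometry shared across modules.

cross3 <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

rownorm <- function(m) sqrt(rowSums(m * m))

# Area-weighted face normals: |n_f| = area of face f.
face_normals <- function(vertices, faces) {
  a <- vertices[faces[, 1], , drop = FALSE]
  b <- vertices[faces[, 2], , drop = FALSE]
  c_ <- vertices[faces[, 3], , drop = FALSE]
  0.5 * cross3(b - a, c_ - a)
}

triangle_areas <- function(vertices, faces) rownorm(face_normals(vertices, faces))

face_centers <- function(vertices, faces) {
  (vertices[faces[, 1], , drop = FALSE] +
   vertices[faces[, 2], , drop = FALSE] +
   vertices[faces[, 3], , drop = FALSE]) / 3
}

#' Surface area and enclosed volume of a mesh
#'
#' `A_surf` is the sum of triangle areas. The volume is computed with the
#' divergence theorem and is defined only for closed meshes; for open
#' meshes (boundary loops present) it is reported as `NA`. Outward-oriented
#' faces give a positive signed volume; the absolute value is returned and
#' a warning is emitted when the signed volume is negative (inward
#' orientation).
#'
#' @param s a [triangle_surface()].
#' @return list with `area` \[mm^2\], `volume` \[mm^3\] (`NA` if open),
#'   `closed` flag and the `signed_volume`.
#' @export
surface_measures <- function(s) {
  stopifnot(inherits(s, "triangle_surface"))
  if (nrow(s$faces) == 0L) stop("empty mesh")
  area <- sum(triangle_areas(s$vertices, s$faces))
  closed <- is_closed_surface(s)
  vol <- NA_real_
  sv <- NA_real_
  if (closed) {
    # measure about the centroid: the divergence-theorem sum is then free
    # of the catastrophic cancellation a distant origin would cause
    v0 <- sweep(s$vertices, 2L, colMeans(s$vertices))
    a <- v0[s$faces[, 1], , drop = FALSE]
    b <- v0[s$faces[, 2], , drop = FALSE]
    c_ <- v0[s$faces[, 3], , drop = FALSE]
    sv <- sum(rowSums(a * cross3(b, c_))) / 6
    if (sv < 0) warning("mesh is inward-oriented; reporting |V|")
    vol <- abs(sv)
  }
  list(area = area, volume = vol, closed = closed, signed_volume = sv)
}

#' Apply a rigid transform to a surface
#'
#' @param s a [triangle_surface()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 translation \[mm\].
#' @return transformed `triangle_surface`.
#' @export
apply_rigid <- function(s, rotation = diag(3), translation = c(0, 0, 0)) {
  s$vertices <- sweep(s$vertices %*% t(rotation), 2L, -translation)
  s
}

# Row-wise closest point on triangle (A_i, B_i, C_i) from point P_i.
# Candidates: the interior plane projection (when the barycentric
# coordinates admit it) and the three clamped edges.
closest_point_pairs <- function(P, A, B, C) {
  ab <- B - A; ac <- C - A
  ap <- P - A
  d1 <- rowSums(ab * ap); d2 <- rowSums(ac * ap)
  a11 <- rowSums(ab * ab); a22 <- rowSums(ac * ac); a12 <- rowSums(ab * ac)
  det <- pmax(a11 * a22 - a12 * a12, 1e-300)
  u <- (a22 * d1 - a12 * d2) / det
  v <- (a11 * d2 - a12 * d1) / det
  inside <- u >= 0 & v >= 0 & (u + v) <= 1
  proj <- A + ab * u + ac * v
  seg <- function(S, Q) {
    d <- Q - S
    tt <- rowSums((P - S) * d) / pmax(rowSums(d * d), 1e-300)
    tt <- pmin(pmax(tt, 0), 1)
    S + d * tt
  }
  cand1 <- seg(A, B); cand2 <- seg(B, C); cand3 <- seg(A, C)
  d2of <- function(M) rowSums((M - P)^2)
  dall <- cbind(ifelse(inside, d2of(proj), Inf),
                d2of(cand1), d2of(cand2), d2of(cand3))
  which_min <- max.col(-dall, ties.method = "first")
  best <- proj
  best[which_min == 2L, ] <- cand1[which_min == 2L, , drop = FALSE]
  best[which_min == 3L, ] <- cand2[which_min == 3L, , drop = FALSE]
  best[which_min == 4L, ] <- cand3[which_min == 4L, , drop = FALSE]
  list(d2 = dall[cbind(seq_len(nrow(P)), which_min)], pts = best)
}

# For each query point (rows of P), the closest point on surface s and the
# distance. The `candidates` nearest faces by barycenter distance are
# tested exactly (vectorised over all points at once); faces whose
# barycenter could still beat the best candidate (barycenter distance
# within best + 2 * max face radius) are added in a second pass.
closest_points_on_surface <- function(P, s, candidates = 16L) {
  fA <- s$vertices[s$faces[, 1], , drop = FALSE]
  fB <- s$vertices[s$faces[, 2], , drop = FALSE]
  fC <- s$vertices[s$faces[, 3], , drop = FALSE]
  ctr <- face_centers(s$vertices, s$faces)
  nf <- nrow(fA)
  n <- nrow(P)
  k <- min(candidates, nf)
  # point-to-barycenter squared distances, n x nf
  D2 <- outer(rowSums(P * P), rowSums(ctr * ctr), "+") - 2 * tcrossprod(P, ctr)
  rad <- sqrt(pmax(rowSums((fA - ctr)^2), rowSums((fB - ctr)^2),
                   rowSums((fC - ctr)^2)))
  rmax <- max(rad)
  ord <- t(apply(D2, 1L, order))[, seq_len(k), drop = FALSE]
  best_d2 <- rep(Inf, n)
  best_p <- matrix(0, n, 3L)
  for (c_ in seq_len(k)) {
    j <- ord[, c_]
    res <- closest_point_pairs(P, fA[j, , drop = FALSE],
                               fB[j, , drop = FALSE], fC[j, , drop = FALSE])
    upd <- res$d2 < best_d2
    best_d2[upd] <- res$d2[upd]
    best_p[upd, ] <- res$pts[upd, , drop = FALSE]
  }
  # guarantee pass: any face whose barycenter ball could still win
  bound <- (sqrt(best_d2) + rmax)^2
  pending <- which(rowSums(D2 <= bound) > k)
  for (i in pending) {
    extra <- which(D2[i, ] <= bound[i])
    extra <- setdiff(extra, ord[i, ])
    if (length(extra) == 0L) next
    Pi <- matrix(P[i, ], length(extra), 3L, byrow = TRUE)
    res <- closest_point_pairs(Pi, fA[extra, , drop = FALSE],
                               fB[extra, , drop = FALSE],
                               fC[extra, , drop = FALSE])
    j <- which.min(res$d2)
    if (res$d2[j] < best_d2[i]) {
      best_d2[i] <- res$d2[j]
      best_p[i, ] <- res$pts[j, ]
    }
  }
  list(distance = sqrt(best_d2), points = best_p)
}

#' Symmetric surface distance between two meshes
#'
#' Vertices of each mesh are measured against the other mesh's triangles
#' (point-to-triangle distance); maximum and mean are taken over both
#' directions. With `supersample = TRUE` face barycenters are added to the
#' sample set.
#'
#' @param a,b [triangle_surface()] objects.
#' @param supersample also sample face barycenters.
#' @return list with `max` and `mean` distance \[mm\].
#' @export
surface_distance <- function(a, b, supersample = FALSE) {
  stopifnot(inherits(a, "triangle_surface"), inherits(b, "triangle_surface"))
  if (nrow(a$faces) == 0L || nrow(b$faces) == 0L) stop("empty mesh")
  Pa <- a$vertices
  Pb <- b$vertices
  if (supersample) {
    Pa <- rbind(Pa, face_centers(a$vertices, a$faces))
    Pb <- rbind(Pb, face_centers(b$vertices, b$faces))
  }
  dab <- closest_points_on_surface(Pa, b)$distance
  dba <- closest_points_on_surface(Pb, a)$distance
  list(max = max(dab, dba), mean = mean(c(dab, dba)))
}
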