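#' Triangle surface mesh
#'
#' The universal shape carrier of the package: an indexed triangle mesh in
#' millimetres. Faces are stored as 1-based vertex index triples with
#' consistent orientation (each interior edge is traversed in opposite
#' directions by its two adjacent faces). Meshes may be open: boundary
#' loops are allowed and are what the centreline extractor uses to find the
#' vessel inlet and outlet.
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z \[mm\].
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param subject_id optional subject identifier carried through the pipeline.
#' @param clean if `TRUE` (default), merge duplicate vertices, drop
#'   zero-area faces and unreferenced vertices, and make the face
#'   orientation consistent (error if the surface is non-orientable).
#' @return An object of class `triangle_surface` with elements `vertices`,
#'   `faces` and `subject_id`.
#' @export
triangle_surface <- function(vertices, faces, subject_id = NULL, clean = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  if (ncol(vertices) != 3L) stop("vertices must have 3 columns")
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(faces) != 3L) stop("non-triangular face: faces must have 3 columns")
  if (nrow(faces) > 0L &&
      (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop("face indices out of range")
  }
  s <- structure(list(vertices = vertices, faces = faces,
                      subject_id = subject_id),
                 class = "triangle_surface")
  if (clean) s <- clean_surface(s)
  s
}

#' @export
print.triangle_surface <- function(x, ...) {
  nb <- tryCatch(length(boundary_loops(x)), error = function(e) NA_integer_)
  cat(sprintf("triangle_surface%s: %d vertices, %d faces, %s\n",
              if (is.null(x$subject_id)) "" else paste0(" [", x$subject_id, "]"),
              nrow(x$vertices), nrow(x$faces),
              if (is.na(nb)) "boundary unknown"
              else if (nb == 0L) "closed"
              else sprintf("%d boundary loop(s)", nb)))
  invisible(x)
}

#' @export
summary.triangle_surface <- function(object, ...) {
  m <- surface_measures(object)
  cat(sprintf("triangle_surface: %d vertices, %d faces\n",
              nrow(object$vertices), nrow(object$faces)))
  cat(sprintf("  A_surf = %.2f mm^2, V = %s\n", m$area,
              if (is.na(m$volume)) "undefined (open mesh)"
              else sprintf("%.2f mm^3", m$volume)))
  bb <- apply(object$vertices, 2, range)
  cat(sprintf("  bounding box [mm]: x %.1f..%.1f, y %.1f..%.1f, z %.1f..%.1f\n",
              bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  invisible(m)
}

# Merge duplicate vertices (exact to `digits` decimals), drop degenerate
# faces and unreferenced vertices, and orient faces consistently.
clean_surface <- function(s, digits = 8L) {
  v <- s$vertices
  f <- s$faces
  key <- paste(round(v[, 1], digits), round(v[, 2], digits),
               round(v[, 3], digits), sep = "/")
  idx <- match(key, key)           # representative per duplicate group
  keep <- sort(unique(idx))
  remap <- integer(nrow(v))
  remap[keep] <- seq_along(keep)
  v <- v[keep, , drop = FALSE]
  if (nrow(f) > 0L) {
    f <- matrix(remap[idx[f]], ncol = 3L)
    # drop combinatorially degenerate faces
    ok <- f[, 1] != f[, 2] & f[, 2] != f[, 3] & f[, 1] != f[, 3]
    f <- f[ok, , drop = FALSE]
    # drop geometrically degenerate (zero-area) faces
    if (nrow(f) > 0L) {
      ar <- triangle_areas(v, f)
      f <- f[ar > 1e-12, , drop = FALSE]
    }
    # drop duplicated faces (same vertex set)
    if (nrow(f) > 0L) {
      fk <- apply(f, 1L, function(r) paste(sort(r), collapse = "-"))
      f <- f[!duplicated(fk), , drop = FALSE]
    }
  }
  # drop unreferenced vertices
  used <- sort(unique(as.vector(f)))
  if (length(used) < nrow(v)) {
    remap2 <- integer(nrow(v))
    remap2[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap2[f], ncol = 3L)
  }
  s$vertices <- v
  s$faces <- f
  if (nrow(f) > 1L) s <- orient_consistently(s)
  s
}

# Breadth-first propagation of orientation across shared edges.
# Errors if an interior edge is shared by > 2 faces or the surface is
# non-orientable (a face would need both orientations).
orient_consistently <- function(s) {
  f <- s$faces
  nf <- nrow(f)
  ekey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  e1 <- ekey(f[, 1], f[, 2]); e2 <- ekey(f[, 2], f[, 3]); e3 <- ekey(f[, 3], f[, 1])
  edge_all <- c(e1, e2, e3)
  face_of <- rep(seq_len(nf), 3L)
  tab <- split(face_of, edge_all)
  if (any(lengths(tab) > 2L)) stop("non-orientable surface: edge shared by >2 faces")
  visited <- rep(FALSE, nf)
  flipped <- rep(FALSE, nf)
  dirs <- function(fi) {
    r <- f[fi, ]
    if (flipped[fi]) r <- r[c(1L, 3L, 2L)]
    rbind(r[c(1L, 2L)], r[c(2L, 3L)], r[c(3L, 1L)])
  }
  for (seed in seq_len(nf)) {
    if (visited[seed]) next
    queue <- seed
    visited[seed] <- TRUE
    while (length(queue) > 0L) {
      fi <- queue[[1L]]; queue <- queue[-1L]
      dd <- dirs(fi)
      for (k in 1:3) {
        a <- dd[k, 1L]; b <- dd[k, 2L]
        nb <- tab[[ekey(a, b)]]
        nb <- nb[nb != fi]
        for (fj in nb) {
          ddj <- dirs(fj)
          same <- any(ddj[, 1L] == a & ddj[, 2L] == b)
          if (!visited[fj]) {
            flipped[fj] <- same   # neighbour must traverse b -> a
            visited[fj] <- TRUE
            queue <- c(queue, fj)
          } else {
            ddj <- dirs(fj)
            if (any(ddj[, 1L] == a & ddj[, 2L] == b)) {
              stop("non-orientable surface")
            }
          }
        }
      }
    }
  }
  if (any(flipped)) {
    f[flipped, ] <- f[flipped, c(1L, 3L, 2L), drop = FALSE]
    s$faces <- f
  }
  s
}

# Boundary edges: edges referenced by exactly one face.
boundary_edges <- function(s) {
  f <- s$faces
  if (nrow(f) == 0L) return(matrix(integer(0), ncol = 2L))
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3L, 1L)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]), sep = "-")
  cnt <- table(key)
  e[key %in% names(cnt)[cnt == 1L], , drop = FALSE]
}

# Boundary loops as ordered vertex index cycles (list of integer vectors).
boundary_loops <- function(s) {
  be <- boundary_edges(s)
  if (nrow(be) == 0L) return(list())
  nxt <- split(c(be[, 2], be[, 1]), c(be[, 1], be[, 2]))
  loops <- list()
  remaining <- unique(as.vector(be))
  used_edge <- new.env(hash = TRUE)
  ek <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "-")
  while (length(remaining) > 0L) {
    start <- remaining[[1L]]
    loop <- start
    cur <- start
    repeat {
      cand <- nxt[[as.character(cur)]]
      cand <- cand[!vapply(cand, function(x)
        isTRUE(get0(ek(cur, x), envir = used_edge)), logical(1))]
      if (length(cand) == 0L) break
      nxt_v <- cand[[1L]]
      assign(ek(cur, nxt_v), TRUE, envir = used_edge)
      if (nxt_v == start) break
      loop <- c(loop, nxt_v)
      cur <- nxt_v
    }
    loops[[length(loops) + 1L]] <- loop
    remaining <- setdiff(remaining, loop)
  }
  loops
}

is_closed_surface <- function(s) nrow(boundary_edges(s)) == 0L
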