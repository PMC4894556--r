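#' Read a triangle surface mesh from disk
#'
#' Supported formats: legacy VTK polydata (`.vtk`, ASCII), PLY (`.ply`,
#' ASCII), STL (`.stl`, ASCII or binary) and Wavefront OBJ (`.obj`).
#' Coordinates are taken as millimetres; no unit conversion is performed.
#' The mesh is cleaned on load: duplicate vertices merged, zero-area faces
#' dropped, orientation made consistent (error if non-orientable).
#'
#' @param path file path.
#' @param format one of `"auto"` (from extension), `"vtk"`, `"ply"`,
#'   `"stl"`, `"obj"`.
#' @param subject_id optional id attached to the surface.
#' @return a [triangle_surface()].
#' @export
read_surface <- function(path, format = c("auto", "vtk", "ply", "stl", "obj"),
                         subject_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    if (!ext %in% c("vtk", "ply", "stl", "obj")) {
      stop("cannot infer mesh format from extension: ", ext)
    }
    format <- ext
  }
  raw <- switch(format,
    vtk = read_vtk_polydata(path),
    ply = read_ply(path),
    stl = read_stl(path),
    obj = read_obj(path))
  triangle_surface(raw$vertices, raw$faces, subject_id = subject_id)
}

#' Write a triangle surface mesh to disk
#'
#' @param s a [triangle_surface()].
#' @param path output path; format inferred from extension unless given.
#' @param format `"auto"`, `"vtk"`, `"ply"`, `"stl"` (ASCII) or `"obj"`.
#' @param binary write binary STL instead of ASCII (STL only).
#' @return `path`, invisibly.
#' @export
write_surface <- function(s, path, format = c("auto", "vtk", "ply", "stl", "obj"),
                          binary = FALSE) {
  stopifnot(inherits(s, "triangle_surface"))
  format <- match.arg(format)
  if (format == "auto") format <- tolower(tools::file_ext(path))
  switch(format,
    vtk = write_vtk_polydata(s, path),
    ply = write_ply(s, path),
    stl = if (binary) write_stl_binary(s, path) else write_stl_ascii(s, path),
    obj = write_obj(s, path),
    stop("unsupported mesh format: ", format))
  invisible(path)
}

numeric_tokens <- function(lines) {
  as.numeric(unlist(strsplit(trimws(lines), "[[:space:]]+")))
}

read_vtk_polydata <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) >= 3L && grepl("BINARY", lines[3L], ignore.case = TRUE)) {
    stop("binary legacy VTK is not supported; write ASCII")
  }
  ip <- grep("^POINTS", lines)
  if (length(ip) != 1L) stop("unreadable VTK polydata: no POINTS section")
  np <- as.integer(strsplit(trimws(lines[ip]), "[[:space:]]+")[[1L]][2L])
  # points span following lines until we have 3*np numbers
  vals <- numeric(0)
  i <- ip + 1L
  while (length(vals) < 3L * np && i <= length(lines)) {
    vals <- c(vals, numeric_tokens(lines[i]))
    i <- i + 1L
  }
  v <- matrix(vals[seq_len(3L * np)], ncol = 3L, byrow = TRUE)
  ifc <- grep("^POLYGONS", lines)
  if (length(ifc) != 1L) stop("unreadable VTK polydata: no POLYGONS section")
  hdr <- as.integer(strsplit(trimws(lines[ifc]), "[[:space:]]+")[[1L]][2:3])
  nf <- hdr[1L]
  vals <- numeric(0)
  i <- ifc + 1L
  while (length(vals) < hdr[2L] && i <= length(lines)) {
    vals <- c(vals, numeric_tokens(lines[i]))
    i <- i + 1L
  }
  f <- matrix(NA_integer_, nf, 3L)
  pos <- 1L
  for (k in seq_len(nf)) {
    cnt <- vals[pos]
    if (cnt != 3) stop("non-triangular face in VTK polydata")
    f[k, ] <- as.integer(vals[pos + 1:3]) + 1L
    pos <- pos + cnt + 1L
  }
  list(vertices = v, faces = f)
}

write_vtk_polydata <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "vesselssm surface", "ASCII", "DATASET POLYDATA",
               sprintf("POINTS %d float", nrow(s$vertices))), con)
  writeLines(apply(s$vertices, 1L, function(r)
    sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])), con)
  nf <- nrow(s$faces)
  writeLines(sprintf("POLYGONS %d %d", nf, 4L * nf), con)
  writeLines(apply(s$faces, 1L, function(r)
    sprintf("3 %d %d %d", r[1] - 1L, r[2] - 1L, r[3] - 1L)), con)
}

read_ply <- function(path) {
  head <- readLines(path, n = 1L, warn = FALSE)
  if (!identical(trimws(head), "ply")) stop("unreadable PLY file")
  lines <- readLines(path, warn = FALSE)
  end <- grep("^end_header", lines)[1L]
  if (is.na(end)) stop("unreadable PLY: no end_header")
  hdr <- lines[seq_len(end)]
  if (any(grepl("^format binary", hdr))) {
    stop("binary PLY is not supported; export ASCII PLY")
  }
  nv <- as.integer(sub("^element vertex\\s+", "", hdr[grepl("^element vertex", hdr)]))
  nf <- as.integer(sub("^element face\\s+", "", hdr[grepl("^element face", hdr)]))
  body <- lines[(end + 1L):length(lines)]
  body <- body[nzchar(trimws(body))]
  vlines <- body[seq_len(nv)]
  v <- do.call(rbind, lapply(strsplit(trimws(vlines), "[[:space:]]+"), function(t)
    as.numeric(t[1:3])))
  flines <- body[nv + seq_len(nf)]
  f <- do.call(rbind, lapply(strsplit(trimws(flines), "[[:space:]]+"), function(t) {
    cnt <- as.integer(t[1L])
    if (cnt != 3L) stop("non-triangular face in PLY")
    as.integer(t[2:4]) + 1L
  }))
  list(vertices = v, faces = f)
}

write_ply <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(s$vertices)),
               "property float x", "property float y", "property float z",
               sprintf("element face %d", nrow(s$faces)),
               "property list uchar int vertex_indices",
               "end_header"), con)
  writeLines(apply(s$vertices, 1L, function(r)
    sprintf("%.9g %.9g %.9g", r[1], r[2], r[3])), con)
  writeLines(apply(s$faces, 1L, function(r)
    sprintf("3 %d %d %d", r[1] - 1L, r[2] - 1L, r[3] - 1L)), con)
}

read_stl <- function(path) {
  # binary STL: 80-byte header, uint32 count, 50 bytes per facet
  sz <- file.info(path)$size
  con <- file(path, "rb")
  head80 <- readBin(con, "raw", 80L)
  nf_bin <- tryCatch(readBin(con, "integer", 1L, size = 4L, endian = "little"),
                     error = function(e) -1L)
  close(con)
  is_binary <- !is.na(nf_bin) && nf_bin >= 0 && sz == 84 + 50 * as.numeric(nf_bin)
  if (is_binary) return(read_stl_binary(path, nf_bin))
  txt <- readLines(path, warn = FALSE)
  if (!any(grepl("facet", txt))) stop("unreadable STL file")
  vl <- grep("^\\s*vertex", txt, value = TRUE)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"), function(t)
    as.numeric(t[2:4])))
  if (nrow(v) %% 3L != 0L) stop("unreadable STL: vertex count not multiple of 3")
  f <- matrix(seq_len(nrow(v)), ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_stl_binary <- function(path, nf) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  v <- matrix(0, 3L * nf, 3L)
  for (k in seq_len(nf)) {
    vals <- readBin(con, "numeric", 12L, size = 4L, endian = "little")
    readBin(con, "raw", 2L)
    v[3L * k - 2L, ] <- vals[4:6]
    v[3L * k - 1L, ] <- vals[7:9]
    v[3L * k, ] <- vals[10:12]
  }
  list(vertices = v, faces = matrix(seq_len(3L * nf), ncol = 3L, byrow = TRUE))
}

write_stl_ascii <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  n <- face_normals(s$vertices, s$faces)
  n <- n / pmax(rownorm(n), 1e-300)
  writeLines("solid vesselssm", con)
  for (k in seq_len(nrow(s$faces))) {
    tri <- s$vertices[s$faces[k, ], , drop = FALSE]
    writeLines(c(sprintf("  facet normal %.9g %.9g %.9g", n[k, 1], n[k, 2], n[k, 3]),
                 "    outer loop",
                 sprintf("      vertex %.9g %.9g %.9g", tri[, 1], tri[, 2], tri[, 3]),
                 "    endloop", "  endfacet"), con)
  }
  writeLines("endsolid vesselssm", con)
}

write_stl_binary <- function(s, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80L), con)
  nf <- nrow(s$faces)
  writeBin(as.integer(nf), con, size = 4L, endian = "little")
  n <- face_normals(s$vertices, s$faces)
  n <- n / pmax(rownorm(n), 1e-300)
  for (k in seq_len(nf)) {
    tri <- s$vertices[s$faces[k, ], , drop = FALSE]
    writeBin(as.numeric(c(n[k, ], t(tri))), con, size = 4L, endian = "little")
    writeBin(raw(2L), con)
  }
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (length(vl) == 0L || length(fl) == 0L) stop("unreadable OBJ file")
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "[[:space:]]+"), function(t)
    as.numeric(t[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "[[:space:]]+"), function(t) {
    idx <- t[-1L]
    if (length(idx) != 3L) stop("non-triangular face in OBJ")
    as.integer(sub("/.*$", "", idx))
  }))
  list(vertices = v, faces = f)
}

write_obj <- function(s, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(s$vertices, 1L, function(r)
    sprintf("v %.9g %.9g %.9g", r[1], r[2], r[3])), con)
  writeLines(apply(s$faces, 1L, function(r)
    sprintf("f %d %d %d", r[1], r[2], r[3])), con)
}
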