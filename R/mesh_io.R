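#' Triangulated surface mesh
#'
#' @param vertices numeric matrix, one row per vertex, columns x/y/z in
#'   micrometres (internal ML/PD/AP frame).
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @return An object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) > 0 &&
      (min(faces) < 1L || max(faces) > nrow(vertices)))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("<surface_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (nrow(x$vertices)) {
    bb <- apply(x$vertices, 2, range)
    cat(sprintf("  bbox [%.1f, %.1f] x [%.1f, %.1f] x [%.1f, %.1f] um\n",
                bb[1, 1], bb[2, 1], bb[1, 2], bb[2, 2], bb[1, 3], bb[2, 3]))
  }
  invisible(x)
}

# merge coincident vertices (within tol, um) and reindex faces
dedup_vertices <- function(vertices, faces, tol = 1e-6) {
  if (nrow(vertices) == 0L) return(list(vertices = vertices, faces = faces))
  key <- apply(round(vertices / tol), 1, paste, collapse = ",")
  first <- !duplicated(key)
  map <- match(key, key[first])
  list(vertices = vertices[first, , drop = FALSE],
       faces = matrix(map[faces], ncol = 3L))
}

#' Read a triangular mesh from an STL file
#'
#' Binary and ASCII STL are both supported; the per-triangle vertex soup is
#' merged into an indexed mesh within `merge_tol`.
#'
#' @param path STL file.
#' @param merge_tol vertex merge tolerance in micrometres.
#' @return A [surface_mesh()].
#' @export
read_mesh <- function(path, merge_tol = 1e-6) {
  if (!file.exists(path)) stop("cannot read mesh: ", path, call. = FALSE)
  size <- file.size(path)
  if (size < 15) stop("truncated STL file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", n = 80)
  is_binary <- FALSE
  if (size >= 84) {
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(ntri) && ntri >= 0 && size == 84 + 50 * as.numeric(ntri))
      is_binary <- TRUE
  }
  if (is_binary) {
    if (ntri == 0L) stop("empty STL file: ", path, call. = FALSE)
    buf <- readBin(con, "raw", n = 50 * ntri)
    m <- matrix(buf, nrow = 50)
    tri <- vapply(seq_len(ntri), function(i)
      readBin(m[13:48, i], "double", n = 9, size = 4, endian = "little"),
      numeric(9))
    verts <- matrix(as.vector(tri), ncol = 3, byrow = TRUE)
  } else {
    txt <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", txt, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3L != 0L)
      stop("malformed or empty ASCII STL: ", path, call. = FALSE)
    nums <- lapply(strsplit(trimws(vl), "\\s+"), function(p) as.numeric(p[2:4]))
    verts <- do.call(rbind, nums)
    if (anyNA(verts)) stop("malformed ASCII STL coordinates", call. = FALSE)
  }
  faces <- matrix(seq_len(nrow(verts)), ncol = 3, byrow = TRUE)
  dd <- dedup_vertices(verts, faces, merge_tol)
  surface_mesh(dd$vertices, dd$faces)
}

#' Write a mesh to binary STL
#'
#' @param mesh a [surface_mesh()].
#' @param path output STL path.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  stopifnot(inherits(mesh, "surface_mesh"))
  v <- mesh$vertices
  f <- mesh$faces
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(80), con)
  writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
  for (i in seq_len(nrow(f))) {
    a <- v[f[i, 1], ]; b <- v[f[i, 2], ]; c3 <- v[f[i, 3], ]
    n <- c((b[2] - a[2]) * (c3[3] - a[3]) - (b[3] - a[3]) * (c3[2] - a[2]),
           (b[3] - a[3]) * (c3[1] - a[1]) - (b[1] - a[1]) * (c3[3] - a[3]),
           (b[1] - a[1]) * (c3[2] - a[2]) - (b[2] - a[2]) * (c3[1] - a[1]))
    len <- sqrt(sum(n^2))
    if (len > 0) n <- n / len
    writeBin(c(n, a, b, c3), con, size = 4, endian = "little")
    writeBin(raw(2), con)
  }
  invisible(path)
}

#' Mesh surface area
#' @param mesh a [surface_mesh()].
#' @return total triangle area in square micrometres.
#' @export
mesh_area <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cr <- cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
              a[, 3] * b[, 1] - a[, 1] * b[, 3],
              a[, 1] * b[, 2] - a[, 2] * b[, 1])
  sum(sqrt(rowSums(cr^2))) / 2
}

#' Enclosed mesh volume
#'
#' Signed volume by the divergence theorem; requires a closed, consistently
#' oriented surface (as produced by [mesh_from_binary()]).
#'
#' @param mesh a [surface_mesh()].
#' @return enclosed volume in cubic micrometres (absolute value).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]
  p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
         p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
         p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  abs(sum(det)) / 6
}

#' Mirror a mesh across a plane perpendicular to one axis
#'
#' Used to handle chirality when pairing left and right knees before
#' registration: the contralateral bone is mirrored across the ML axis.
#' Face orientation is flipped so surface normals remain outward.
#'
#' @param mesh a [surface_mesh()].
#' @param axis 1 (ML), 2 (PD) or 3 (AP).
#' @param centre plane position in micrometres; default: bbox centre.
#' @return the mirrored [surface_mesh()].
#' @export
mirror_mesh <- function(mesh, axis = 1L, centre = NULL) {
  v <- mesh$vertices
  if (is.null(centre)) centre <- mean(range(v[, axis]))
  v[, axis] <- 2 * centre - v[, axis]
  surface_mesh(v, mesh$faces[, c(1, 3, 2), drop = FALSE])
}
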