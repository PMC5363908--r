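#' Rigid transform (rotation + translation)
#'
#' @param rotation 3x3 orthonormal matrix with determinant +1.
#' @param translation length-3 numeric vector in micrometres.
#' @return An object of class `rigid_transform`. Points transform as
#'   `rotation %*% p + translation`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3L)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9)
    stop("rotation matrix is not orthonormal", call. = FALSE)
  if (det(rotation) < 0)
    stop("rotation has determinant -1 (reflection)", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.3f deg, translation (%.2f, %.2f, %.2f) um\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose and invert rigid transforms
#'
#' `compose_transform(t2, t1)` applies `t1` first, then `t2`.
#'
#' @param t1,t2,transform [rigid_transform()] objects.
#' @return a [rigid_transform()].
#' @export
compose_transform <- function(t2, t1) {
  rigid_transform(t2$rotation %*% t1$rotation,
                  as.numeric(t2$rotation %*% t1$translation) + t2$translation)
}

#' @rdname compose_transform
#' @export
invert_transform <- function(transform) {
  rigid_transform(t(transform$rotation),
                  -as.numeric(t(transform$rotation) %*% transform$translation))
}

#' Random rigid transform
#'
#' Rotations about each axis uniform in `[-max_angle_deg, max_angle_deg]`,
#' translations uniform in `[-max_translation_um, max_translation_um]`.
#' Uses the current RNG state.
#'
#' @param max_angle_deg maximum per-axis rotation in degrees.
#' @param max_translation_um maximum per-axis translation in micrometres.
#' @return a [rigid_transform()].
#' @export
random_rigid_transform <- function(max_angle_deg = 10,
                                   max_translation_um = 100) {
  ang <- runif(3, -max_angle_deg, max_angle_deg) * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0, -sin(ang[3]), cos(ang[3]),
                 0, 0, 0, 1), 3, 3)
  rigid_transform(rz %*% ry %*% rx, runif(3, -max_translation_um,
                                          max_translation_um))
}

#' Apply a rigid transform to a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param transform a [rigid_transform()].
#' @return the transformed [surface_mesh()]; faces unchanged.
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(mesh, "surface_mesh"),
            inherits(transform, "rigid_transform"))
  v <- mesh$vertices %*% t(transform$rotation)
  v <- sweep(v, 2, transform$translation, "+")
  surface_mesh(v, mesh$faces)
}

#' Persist a rigid transform as a 12-number text file
#'
#' Row-major 3x3 rotation followed by the translation vector.
#'
#' @param transform a [rigid_transform()].
#' @param path text file path.
#' @return `write_transform()`: `path`; `read_transform()`: the transform.
#' @export
write_transform <- function(transform, path) {
  stopifnot(inherits(transform, "rigid_transform"))
  writeLines(format(c(as.vector(t(transform$rotation)),
                      transform$translation), digits = 17), path)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  x <- as.numeric(readLines(path, warn = FALSE))
  if (length(x) != 12L || anyNA(x))
    stop("transform file must hold 12 numbers", call. = FALSE)
  rigid_transform(matrix(x[1:9], 3, 3, byrow = TRUE), x[10:12])
}

#' Extract an isosurface mesh from a binary volume
#'
#' The binary volume is optionally smoothed with a small Gaussian (which
#' anti-aliases the staircase voxel interface) and the isosurface at
#' `iso` is triangulated by marching tetrahedra. Vertex coordinates are in
#' micrometres in the world frame (`(index - 1) * voxel_size_um`).
#'
#' @param binary a [binary_volume()] with non-empty foreground.
#' @param iso iso level on the 0--1 binary scale (default 0.5).
#' @param smooth_sigma pre-smoothing sigma in voxels (default 1; 0 gives
#'   the raw blocky interface).
#' @return a closed [surface_mesh()].
#' @export
mesh_from_binary <- function(binary, iso = 0.5, smooth_sigma = 1) {
  stopifnot(inherits(binary, "binary_volume"))
  if (sum(binary$data) == 0L)
    stop("empty object: no foreground voxels", call. = FALSE)
  field <- as.numeric(binary$data)
  if (smooth_sigma > 0)
    field <- cpp_gauss3d(field, dim(binary$data), smooth_sigma)
  res <- cpp_march_tets(field, dim(binary$data), iso, binary$voxel_size_um)
  if (nrow(res$vertices) == 0L)
    stop("isosurface is empty at the requested level", call. = FALSE)
  surface_mesh(res$vertices, res$faces)
}

# closed-form least-squares rigid fit (Kabsch/SVD with reflection guard):
# finds R, t minimising ||R p + t - q||^2
fit_rigid <- function(p, q) {
  cp <- colMeans(p)
  cq <- colMeans(q)
  h <- crossprod(sweep(p, 2, cp), sweep(q, 2, cq))
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  rigid_transform(rot, cq - as.numeric(rot %*% cp))
}

#' Rigid surface registration by iterative closest point
#'
#' Estimates the rigid transform aligning `target` onto `source`. Each
#' iteration pairs every (transformed) target vertex with the closest
#' location on the source surface (exact closest point on the incident
#' triangles of the grid-nearest vertex) and solves the closed-form
#' least-squares rigid fit over the corresponding point pairs; the
#' correspondence RMS is non-increasing across iterations. Vertex-to-
#' surface pairing avoids the discretisation floor of vertex-to-vertex
#' matching, so exact copies re-align to machine precision. Translation
#' is initialised from the vertex centroids.
#'
#' @param target,source [surface_mesh()] objects (non-empty).
#' @param max_iter maximum number of iterations (default 100).
#' @param tol convergence tolerance: absolute change of the correspondence
#'   RMS between iterations, in micrometres (default 1e-6).
#' @param init optional initial [rigid_transform()]; default: centroid
#'   alignment.
#' @param max_vertices when the target has more vertices, a deterministic,
#'   ordering-invariant spatial subsample of this size drives the
#'   correspondences (the source stays complete). `Inf` disables.
#' @return An object of class `icp_result`: `transform` (the
#'   [rigid_transform()] mapping target onto source), `rms` (final
#'   correspondence RMS in micrometres), `rms_trace` (per iteration),
#'   `iterations` and `converged`.
#' @export
icp_register <- function(target, source, max_iter = 100L, tol = 1e-6,
                         init = NULL, max_vertices = 5000L) {
  stopifnot(inherits(target, "surface_mesh"), inherits(source, "surface_mesh"))
  p0 <- target$vertices
  q <- source$vertices
  if (nrow(p0) == 0L || nrow(q) == 0L)
    stop("cannot register empty meshes", call. = FALSE)
  if (is.null(init))  # centroids of the complete vertex sets
    init <- rigid_transform(diag(3), colMeans(q) - colMeans(p0))
  if (nrow(p0) > max_vertices) {
    # lexicographic order makes the subsample independent of vertex order
    ord <- order(p0[, 1], p0[, 2], p0[, 3])
    keep <- ord[seq(1L, nrow(p0), length.out = max_vertices)]
    p0 <- p0[keep, , drop = FALSE]
  }
  transform <- init
  rms_trace <- numeric(0)
  prev <- Inf
  converged <- FALSE
  qf <- source$faces
  best_rms <- Inf
  best_transform <- transform
  for (it in seq_len(max_iter)) {
    p <- sweep(p0 %*% t(transform$rotation), 2, transform$translation, "+")
    cp <- cpp_closest_on_mesh(p, q, qf)
    rms <- sqrt(mean(cp$dist^2))
    rms_trace <- c(rms_trace, rms)
    if (rms < best_rms) { best_rms <- rms; best_transform <- transform }
    # an exact fit cannot improve; the SVD refit would only add rounding
    if (rms < 1e-9 || abs(prev - rms) < tol) { converged <- TRUE; break }
    prev <- rms
    transform <- fit_rigid(p0, cp$point)
  }
  structure(list(transform = best_transform, rms = best_rms,
                 rms_trace = rms_trace, iterations = length(rms_trace),
                 converged = converged),
            class = "icp_result")
}

#' @export
print.icp_result <- function(x, ...) {
  cat(sprintf("<icp_result> %d iterations, final RMS %.4g um, converged: %s\n",
              x$iterations, x$rms, x$converged))
  print(x$transform)
  invisible(x)
}

#' Voxelize a closed mesh onto a regular grid
#'
#' A voxel becomes foreground iff its centre lies inside the closed
#' surface (parity counting along grid rays). The output geometry is the
#' requested grid, conventionally the resolution of the original scans.
#'
#' @param mesh a closed [surface_mesh()].
#' @param dim integer vector of grid dimensions (ML, PD, AP).
#' @param voxel_size_um isotropic voxel size of the grid.
#' @param side medial side flag for the output volume.
#' @return a [binary_volume()]. If the mesh lies entirely outside the
#'   grid an empty volume is returned with a warning.
#' @export
voxelize <- function(mesh, dim, voxel_size_um, side = c("low", "high")) {
  side <- match.arg(side)
  stopifnot(inherits(mesh, "surface_mesh"))
  dim <- as.integer(dim)
  ext <- (dim - 1) * voxel_size_um
  bb_lo <- apply(mesh$vertices, 2, min)
  bb_hi <- apply(mesh$vertices, 2, max)
  if (any(bb_hi < 0) || any(bb_lo > ext)) {
    warning("mesh lies outside the voxel grid; returning empty volume")
    return(binary_volume(array(0L, dim), voxel_size_um, side = side))
  }
  vox <- cpp_voxelize(mesh$vertices, mesh$faces, dim, voxel_size_um)
  binary_volume(array(vox, dim), voxel_size_um, side = side)
}
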