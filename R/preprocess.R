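#' Otsu threshold of a grey-level volume
#'
#' Exhaustive scan of the 0--255 integer thresholds maximising the
#' between-class variance of the intensity histogram; ties are broken
#' towards the lowest threshold. Foreground is `intensity > threshold`.
#'
#' @param volume an [image_volume()].
#' @return the integer threshold.
#' @export
otsu_threshold <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  v <- as.integer(round(volume$data))
  h <- tabulate(v + 1L, nbins = 256L)
  if (sum(h > 0) < 2L)
    stop("degenerate histogram: volume has fewer than 2 distinct intensities",
         call. = FALSE)
  p <- h / sum(h)
  levels <- 0:255
  omega <- cumsum(p)                  # P(class0) for threshold t = level
  mu <- cumsum(p * levels)
  mu_t <- mu[256]
  # between-class variance for foreground > t, t = 0..254
  w0 <- omega[1:255]
  m0 <- mu[1:255]
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, 255)
  sigma_b[valid] <- (mu_t * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  which.max(sigma_b) - 1L            # lowest maximiser
}

#' Binarize a grey-level volume at a global threshold
#'
#' Foreground (bone) is `intensity > threshold`; geometry metadata is
#' copied from the source volume.
#'
#' @param volume an [image_volume()].
#' @param threshold intensity threshold on the 0--255 scale.
#' @return A [binary_volume()].
#' @export
binarize <- function(volume, threshold) {
  stopifnot(inherits(volume, "image_volume"))
  if (threshold < 0 || threshold > 255)
    stop("threshold must be in [0, 255]", call. = FALSE)
  binary_volume((volume$data > threshold) * 1L, volume$voxel_size_um,
                side = volume$side)
}

# threshold per config: Otsu if enabled, else the configured global value
config_threshold <- function(volume, config) {
  if (isTRUE(config$otsu_enabled)) otsu_threshold(volume)
  else config$global_threshold
}

#' Slice-wise morphological cleanup
#'
#' Applies the given morphological operations, in order, to every coronal
#' (fixed-AP) slice with a 2D disk structuring element, matching the
#' disk-shaped kernel used to remove thresholding noise.
#'
#' @param binary a [binary_volume()].
#' @param radius_um disk radius in micrometres (>= one voxel).
#' @param ops ordered subset of `"open"`, `"close"`, `"dilate"`, `"erode"`.
#' @return the cleaned [binary_volume()].
#' @export
morph_clean <- function(binary, radius_um, ops = c("open", "close")) {
  stopifnot(inherits(binary, "binary_volume"))
  if (radius_um < binary$voxel_size_um)
    stop("kernel radius smaller than one voxel", call. = FALSE)
  ops <- match.arg(ops, c("open", "close", "dilate", "erode"),
                   several.ok = TRUE)
  r <- radius_vox(radius_um, binary$voxel_size_um)
  kern <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  dat <- binary$data
  for (op in ops) {
    dat <- switch(op,
                  open   = EBImage::opening(dat, kern),
                  close  = EBImage::closing(dat, kern),
                  dilate = EBImage::dilate(dat, kern),
                  erode  = EBImage::erode(dat, kern))
  }
  dat <- array(as.integer(dat > 0), dim = dim(binary$data))
  binary_volume(dat, binary$voxel_size_um, side = binary$side)
}

#' 3D Gaussian smoothing
#'
#' Separable Gaussian convolution with reflective boundary handling;
#' `sigma_vox = 0` is the identity.
#'
#' @param volume an [image_volume()].
#' @param sigma_vox standard deviation in voxels (>= 0).
#' @return the smoothed [image_volume()].
#' @export
gaussian_smooth <- function(volume, sigma_vox) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.finite(sigma_vox) || sigma_vox < 0)
    stop("sigma must be non-negative", call. = FALSE)
  if (sigma_vox == 0) return(volume)
  sm <- cpp_gauss3d(as.numeric(volume$data), dim(volume$data), sigma_vox)
  image_volume(array(sm, dim(volume$data)), volume$voxel_size_um,
               side = volume$side)
}

#' Fill internal cavities
#'
#' Background components not 6-connected to the volume border are set to
#' foreground ("whole structure filling"); border-connected background is
#' untouched and foreground is never removed.
#'
#' @param binary a [binary_volume()].
#' @return the filled [binary_volume()].
#' @export
fill_cavities <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  filled <- cpp_fill_cavities(as.integer(binary$data), dim(binary$data))
  binary_volume(array(filled, dim(binary$data)), binary$voxel_size_um,
                side = binary$side)
}
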