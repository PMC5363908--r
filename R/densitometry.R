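#' Two-point hydroxyapatite BMD calibration
#'
#' Linear calibration between grey-level intensity and bone mineral
#' density, derived from two hydroxyapatite phantoms (conventionally 0.25
#' and 0.75 g/cm^3) imaged with the same settings as the specimens.
#'
#' @param low,high numeric vectors `c(density_g_cm3, mean_grey)` for the
#'   low- and high-density phantom.
#' @return An object of class `bmd_calibration` with `slope` (g/cm^3 per
#'   intensity unit) and `intercept` (g/cm^3).
#' @export
calibrate_bmd <- function(low, high) {
  stopifnot(length(low) == 2L, length(high) == 2L)
  d <- c(low[1], high[1])
  g <- c(low[2], high[2])
  if (g[1] == g[2])
    stop("degenerate calibration: phantom grey levels are equal", call. = FALSE)
  if (d[1] == d[2])
    stop("degenerate calibration: phantom densities are equal", call. = FALSE)
  slope <- (d[2] - d[1]) / (g[2] - g[1])
  intercept <- d[1] - slope * g[1]
  structure(list(slope = slope, intercept = intercept,
                 phantom_densities = d, phantom_intensities = g),
            class = "bmd_calibration")
}

#' @export
print.bmd_calibration <- function(x, ...) {
  cat(sprintf("<bmd_calibration> BMD = %.6g * grey + %.6g  [g/cm^3]\n",
              x$slope, x$intercept))
  cat(sprintf("  phantoms: %.3g g/cm^3 @ grey %.4g, %.3g g/cm^3 @ grey %.4g\n",
              x$phantom_densities[1], x$phantom_intensities[1],
              x$phantom_densities[2], x$phantom_intensities[2]))
  invisible(x)
}

#' Apply a BMD calibration to grey values
#'
#' @param cal a [calibrate_bmd()] object.
#' @param grey numeric grey values.
#' @return densities in g/cm^3.
#' @export
apply_calibration <- function(cal, grey) {
  stopifnot(inherits(cal, "bmd_calibration"))
  cal$slope * grey + cal$intercept
}

#' Mean BMD within a mask
#'
#' The calibration is applied to the mean grey intensity of the masked
#' voxels of the original (not binarized) volume.
#'
#' @param volume an [image_volume()].
#' @param mask a [binary_volume()] with the same geometry.
#' @param cal a [calibrate_bmd()] object.
#' @return mean BMD in g/cm^3.
#' @export
mean_bmd <- function(volume, mask, cal) {
  stopifnot(inherits(volume, "image_volume"), inherits(mask, "binary_volume"))
  if (!same_geometry(volume, mask))
    stop("mask geometry does not match volume", call. = FALSE)
  n <- sum(mask$data)
  if (n == 0L) stop("empty mask", call. = FALSE)
  apply_calibration(cal, sum(volume$data[mask$data == 1L]) / n)
}
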