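#' Volumetric local thickness
#'
#' Model-independent local thickness: each foreground voxel receives the
#' diameter (in micrometres) of the largest sphere that lies entirely
#' within the foreground and contains the voxel. Computed by the Euclidean
#' distance transform, distance-ridge extraction and sphere painting.
#' Voxels outside the grid count as background.
#'
#' @param binary a [binary_volume()] with non-empty foreground.
#' @return An object of class `thickness_volume`: list with `data` (3D array
#'   of thickness in micrometres, 0 on background) and the source geometry.
#' @export
local_thickness <- function(binary) {
  stopifnot(inherits(binary, "binary_volume"))
  if (sum(binary$data) == 0L)
    stop("empty object: no foreground voxels", call. = FALSE)
  th <- cpp_local_thickness(as.integer(binary$data), dim(binary$data))
  structure(list(data = array(th * binary$voxel_size_um, dim(binary$data)),
                 voxel_size_um = binary$voxel_size_um,
                 axes = binary$axes, side = binary$side),
            class = "thickness_volume")
}

#' @export
print.thickness_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<thickness_volume> %d x %d x %d voxels, %.3g um/voxel, max thickness %.1f um\n",
              d[1], d[2], d[3], x$voxel_size_um, max(x$data)))
  invisible(x)
}

#' Top-surface thickness heat map
#'
#' Projects the thickness of the epiphyseal top edge onto the (ML, AP)
#' plane: for each column the thickness value at the first foreground voxel
#' encountered from the proximal direction; `NA` where the column contains
#' no foreground.
#'
#' @param thickness a [local_thickness()] result.
#' @return An object of class `thickness_map`: matrix `data` (ML x AP, in
#'   micrometres, `NA` = no data) plus `voxel_size_um`.
#' @export
surface_heatmap <- function(thickness) {
  stopifnot(inherits(thickness, "thickness_volume"))
  d <- dim(thickness$data)
  map <- matrix(NA_real_, nrow = d[1], ncol = d[3])
  fg <- thickness$data > 0
  for (k in seq_len(d[3])) {
    sl <- fg[, , k, drop = TRUE]
    hit <- apply(sl, 1, function(col) {
      w <- which(col)
      if (length(w)) w[1] else NA_integer_
    })
    has <- !is.na(hit)
    if (any(has))
      map[which(has), k] <- thickness$data[, , k][cbind(which(has), hit[has])]
  }
  structure(list(data = map, voxel_size_um = thickness$voxel_size_um),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("<thickness_map> %d x %d (ML x AP), %.3g um/voxel, %.0f%% columns defined\n",
              nrow(x$data), ncol(x$data), x$voxel_size_um,
              100 * mean(!is.na(x$data))))
  invisible(x)
}

#' Medial-lateral thickness profile
#'
#' Aggregates a [surface_heatmap()] over an anterior-posterior band of
#' fixed height (default 750 um) centred at `centre_ap`, yielding one value
#' per ML position.
#'
#' @param map a [surface_heatmap()] result.
#' @param band_um band height in micrometres.
#' @param centre_ap band centre as an AP world coordinate in micrometres;
#'   default: the middle of the AP extent.
#' @param agg `"mean"` (default) or `"max"` over the band; a single
#'   mid-plane trace is the degenerate `band_um = voxel_size_um` case.
#' @return numeric vector of length `nrow(map$data)` (ML positions), with
#'   the ML world coordinates as names.
#' @export
ml_profile <- function(map, band_um = 750, centre_ap = NULL,
                       agg = c("mean", "max")) {
  stopifnot(inherits(map, "thickness_map"))
  agg <- match.arg(agg)
  v <- map$voxel_size_um
  nap <- ncol(map$data)
  if (is.null(centre_ap)) centre_ap <- (nap - 1) / 2 * v
  n_band <- max(1L, as.integer(round(band_um / v)))
  kc <- as.integer(round(centre_ap / v)) + 1L
  k0 <- kc - (n_band - 1L) %/% 2L
  k1 <- k0 + n_band - 1L
  if (k0 < 1 || k1 > nap)
    stop("profile band does not fit within the map extent", call. = FALSE)
  band <- map$data[, k0:k1, drop = FALSE]
  f <- if (agg == "mean") {
    function(r) if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  } else {
    function(r) if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)
  }
  out <- apply(band, 1, f)
  names(out) <- format((seq_len(nrow(map$data)) - 1) * v)
  out
}

#' Export a thickness heat map
#'
#' `write_heatmap_tiff()` writes a 16-bit TIFF with thickness encoded as
#' integer tenths of micrometres (no-data as 0); `write_heatmap_csv()`
#' writes plain CSV in micrometres.
#'
#' @param map a [surface_heatmap()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_heatmap_tiff <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  enc <- round(map$data * 10)
  enc[is.na(enc)] <- 0
  enc <- pmin(enc, 65535)
  tiff::writeTIFF(t(enc) / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_heatmap_tiff
#' @export
write_heatmap_csv <- function(map, path) {
  stopifnot(inherits(map, "thickness_map"))
  write.csv(map$data, path, row.names = FALSE, na = "")
  invisible(path)
}
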