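#' Detect tibial plateau landmarks
#'
#' On the middle coronal (fixed-AP) slice, the proximal edge of the plate
#' surface is detected per ML column (first bone voxel from the proximal
#' side), its medial and lateral extremes are determined, and the centre of
#' each aspect of the plateau is placed a fixed fraction of the ML extent
#' inward from the corresponding extreme.
#'
#' @param binary a [binary_volume()].
#' @param config a [study_config()].
#' @return An object of class `plateau_landmarks`: `mid_coronal_index`,
#'   `proximal_edge` (per-column PD indices, `NA` where empty),
#'   `ml_extremes` and `centres` (voxel indices, medial first after side
#'   normalisation).
#' @export
detect_landmarks <- function(binary, config = study_config()) {
  stopifnot(inherits(binary, "binary_volume"))
  d <- dim(binary$data)
  mid <- (d[3] + 1L) %/% 2L
  slice <- binary$data[, , mid, drop = TRUE]
  if (sum(slice) == 0L)
    stop("landmark error: middle coronal slice contains no bone", call. = FALSE)
  edge <- apply(slice, 1, function(col) {
    w <- which(col == 1L)
    if (length(w)) w[1] else NA_integer_
  })
  cols <- which(!is.na(edge))
  lo <- min(cols)
  hi <- max(cols)
  medial_low <- identical(binary$side, "low")
  extent <- hi - lo
  off <- config$centre_offset_fraction * extent
  c_lo <- as.integer(round(lo + off))
  c_hi <- as.integer(round(hi - off))
  extremes <- if (medial_low) c(medial = lo, lateral = hi)
              else c(medial = hi, lateral = lo)
  centres <- if (medial_low) c(medial = c_lo, lateral = c_hi)
             else c(medial = c_hi, lateral = c_lo)
  structure(list(mid_coronal_index = mid, proximal_edge = edge,
                 ml_extremes = extremes, centres = centres,
                 voxel_size_um = binary$voxel_size_um),
            class = "plateau_landmarks")
}

#' @export
print.plateau_landmarks <- function(x, ...) {
  cat(sprintf("<plateau_landmarks> mid coronal slice %d; ML extremes %d (medial) / %d (lateral); centres %d / %d\n",
              x$mid_coronal_index, x$ml_extremes[1], x$ml_extremes[2],
              x$centres[1], x$centres[2]))
  invisible(x)
}

#' Place the fixed-size mapping windows
#'
#' One window per plateau aspect: `window_width_um` wide in ML centred at
#' the aspect centre, `window_depth_um` deep from the local proximal
#' surface, and `ap_extent_um` along AP centred on the middle coronal
#' slice. At 5 um/voxel with defaults this is 100 x 70 x 150 voxels.
#'
#' @param landmarks a [detect_landmarks()] result.
#' @param config a [study_config()].
#' @param dim grid dimensions of the volume being analysed.
#' @return list of two `mapping_window` objects (`medial`, `lateral`), each
#'   holding 1-based index ranges `ml_range`, `ap_range` and `depth_vox`.
#' @export
place_windows <- function(landmarks, config = study_config(), dim) {
  stopifnot(inherits(landmarks, "plateau_landmarks"))
  v <- landmarks$voxel_size_um
  w <- as.integer(round(config$window_width_um / v))
  depth <- as.integer(round(config$window_depth_um / v))
  nap <- as.integer(round(config$ap_extent_um / v))
  if (w < 1L || depth < 1L || nap < 1L)
    stop("window spans smaller than one voxel", call. = FALSE)
  mid <- landmarks$mid_coronal_index
  ap0 <- mid - nap %/% 2L
  ap1 <- ap0 + nap - 1L
  if (ap0 < 1L || ap1 > dim[3])
    stop("placement error: AP extent exceeds volume bounds", call. = FALSE)
  mk <- function(side) {
    centre <- landmarks$centres[[side]]
    x0 <- centre - w %/% 2L
    x1 <- x0 + w - 1L
    if (x0 < 1L || x1 > dim[1])
      stop("placement error: ", side, " window exceeds volume bounds",
           call. = FALSE)
    structure(list(side = side, ml_range = c(x0, x1), ap_range = c(ap0, ap1),
                   depth_vox = depth, voxel_size_um = v),
              class = "mapping_window")
  }
  list(medial = mk("medial"), lateral = mk("lateral"))
}

#' @export
print.mapping_window <- function(x, ...) {
  cat(sprintf("<mapping_window> %s: ML %d..%d, AP %d..%d, depth %d voxels (%.3g um/voxel)\n",
              x$side, x$ml_range[1], x$ml_range[2], x$ap_range[1],
              x$ap_range[2], x$depth_vox, x$voxel_size_um))
  invisible(x)
}

#' Partition a mapping window into plate and trabecular compartments
#'
#' Per coronal slice of the window, rows parallel to ML are scanned from
#' the proximal anchor (the median proximal-edge height of the window's
#' columns on that slice) downward; the first row whose bone volume
#' fraction falls below the cutoff (default 0.90, i.e. macro-porosity
#' >= 10%) marks the plate/trabecular boundary. The plate mask holds the
#' bone voxels above the boundary; the trabecular region runs from the
#' boundary to the window depth.
#'
#' @param binary a [binary_volume()].
#' @param window a `mapping_window` from [place_windows()].
#' @param config a [study_config()].
#' @return An object of class `compartment_masks`: window-shaped arrays
#'   `plate_mask` (bone above the boundary), `trab_region` (total
#'   trabecular compartment), `trab_bone` (bone within it), per-slice
#'   `boundary_depth_um`, plus the window and geometry.
#' @export
partition_window <- function(binary, window, config = study_config()) {
  stopifnot(inherits(binary, "binary_volume"),
            inherits(window, "mapping_window"))
  d <- dim(binary$data)
  xs <- window$ml_range[1]:window$ml_range[2]
  zs <- window$ap_range[1]:window$ap_range[2]
  depth <- window$depth_vox
  k_consec <- max(1L, config$boundary_consecutive)
  nxw <- length(xs)
  nzw <- length(zs)
  plate <- array(0L, c(nxw, depth, nzw))
  trab_region <- array(0L, c(nxw, depth, nzw))
  boundary_depth <- numeric(nzw)
  anchors <- integer(nzw)
  for (iz in seq_len(nzw)) {
    sl <- binary$data[xs, , zs[iz], drop = TRUE]
    edges <- apply(sl, 1, function(col) {
      w <- which(col == 1L)
      if (length(w)) w[1] else NA_integer_
    })
    anchor <- if (all(is.na(edges))) NA_integer_
              else as.integer(round(median(edges, na.rm = TRUE)))
    if (is.na(anchor)) { # empty slice: all trabecular, boundary at depth 0
      trab_region[, , iz] <- 1L
      boundary_depth[iz] <- 0
      anchors[iz] <- NA_integer_
      next
    }
    if (anchor + depth - 1L > d[2])
      stop("placement error: window depth exceeds volume bounds", call. = FALSE)
    rows <- sl[, anchor:(anchor + depth - 1L), drop = FALSE]
    bvf <- colMeans(rows)
    below <- bvf < config$plate_bvf_cutoff
    bnd <- depth + 1L # no transition: plate occupies the full depth
    if (any(below)) {
      run <- rle(below)
      ends <- cumsum(run$lengths)
      hit <- which(run$values & run$lengths >= k_consec)
      if (length(hit))
        bnd <- ends[hit[1]] - run$lengths[hit[1]] + 1L
    }
    if (bnd > 1L)
      plate[, seq_len(bnd - 1L), iz] <- rows[, seq_len(bnd - 1L)]
    if (bnd <= depth)
      trab_region[, bnd:depth, iz] <- 1L
    boundary_depth[iz] <- (bnd - 1L) * binary$voxel_size_um
    anchors[iz] <- anchor
  }
  trab_bone <- trab_region
  for (iz in seq_len(nzw)) {
    if (is.na(anchors[iz])) { trab_bone[, , iz] <- 0L; next }
    rows <- binary$data[xs, anchors[iz]:(anchors[iz] + depth - 1L), zs[iz]]
    trab_bone[, , iz] <- trab_region[, , iz] * rows
  }
  structure(list(plate_mask = plate, trab_region = trab_region,
                 trab_bone = trab_bone, boundary_depth_um = boundary_depth,
                 anchors = anchors, window = window,
                 voxel_size_um = binary$voxel_size_um,
                 dim = d),
            class = "compartment_masks")
}

# lift a window-shaped mask back into a full-size binary volume
window_mask_to_volume <- function(masks, which = c("plate_mask", "trab_region",
                                                   "trab_bone")) {
  which <- match.arg(which)
  w <- masks$window
  out <- array(0L, masks$dim)
  xs <- w$ml_range[1]:w$ml_range[2]
  zs <- w$ap_range[1]:w$ap_range[2]
  for (iz in seq_along(zs)) {
    a <- masks$anchors[iz]
    if (is.na(a)) next
    out[xs, a:(a + w$depth_vox - 1L), zs[iz]] <- masks[[which]][, , iz]
  }
  out
}

#' Quantify plate and trabecular compartments
#'
#' Computes the morphometric and densitometric metrics of a partitioned
#' window: plate volume (bone voxels x voxel volume), plate thickness
#' (mean local thickness over the plate mask; the mean boundary depth is
#' reported as a secondary metric), trabecular total volume (TV), bone
#' volume (BV), BV/TV in percent, and (if a grey volume and calibration
#' are supplied) plate and trabecular BMD.
#'
#' @param masks a [partition_window()] result.
#' @param grey optional [image_volume()] matching the analysed binary.
#' @param cal optional [calibrate_bmd()] object.
#' @param binary the [binary_volume()] the masks were derived from (used
#'   for local thickness; spheres may extend beyond the window).
#' @return An object of class `compartment_result` with fields
#'   `plate_volume_mm3`, `plate_thickness_um`, `boundary_depth_um`,
#'   `plate_bmd`, `trab_total_volume_mm3`, `trab_bone_volume_mm3`,
#'   `trab_bvtv_percent`, `trab_bmd`, `side`.
#' @export
quantify_compartments <- function(masks, binary, grey = NULL, cal = NULL) {
  stopifnot(inherits(masks, "compartment_masks"),
            inherits(binary, "binary_volume"))
  v <- masks$voxel_size_um
  voxvol_mm3 <- v^3 * 1e-9
  w <- masks$window
  plate_n <- sum(masks$plate_mask)
  tv_n <- sum(masks$trab_region)
  bv_n <- sum(masks$trab_bone)
  if (tv_n == 0L && plate_n == 0L)
    stop("window contains no compartments", call. = FALSE)

  # Plate thickness is measured on the segmented plate compartment: the
  # crop is cut at the detected plate/trabecular boundary so attached
  # trabecular walls do not inflate the inscribed spheres. The crop pad
  # exceeds half the window depth, so spheres for window voxels are never
  # clipped laterally (the plate continues beyond the window).
  plate_th <- NA_real_
  if (plate_n > 0L) {
    pad <- w$depth_vox + 2L
    d <- masks$dim
    xs <- max(1L, w$ml_range[1] - pad):min(d[1], w$ml_range[2] + pad)
    zs <- max(1L, w$ap_range[1] - pad):min(d[3], w$ap_range[2] + pad)
    ylo <- max(1L, min(masks$anchors, na.rm = TRUE) - pad)
    yhi <- min(d[2], max(masks$anchors, na.rm = TRUE) + 2L * w$depth_vox)
    crop <- binary$data[xs, ylo:yhi, zs, drop = FALSE]
    bnd_row <- round(masks$boundary_depth_um / v)
    bnd_med <- as.integer(round(median(bnd_row)))
    zwin <- w$ap_range[1]:w$ap_range[2]
    anc_med <- as.integer(round(median(masks$anchors, na.rm = TRUE)))
    for (iz in seq_along(zs)) {
      k <- match(zs[iz], zwin)
      cut <- if (!is.na(k) && !is.na(masks$anchors[k]))
        masks$anchors[k] + bnd_row[k] else anc_med + bnd_med
      cut_local <- cut - ylo + 1L
      if (cut_local <= dim(crop)[2])
        crop[, max(1L, cut_local):dim(crop)[2], iz] <- 0L
    }
    th <- cpp_local_thickness(as.integer(crop), dim(crop)) * v
    th <- array(th, dim(crop))
    pm <- window_mask_to_volume(masks, "plate_mask")[xs, ylo:yhi, zs, drop = FALSE]
    plate_th <- mean(th[pm == 1L])
  }

  bmd_plate <- bmd_trab <- NA_real_
  if (!is.null(grey) && !is.null(cal)) {
    if (plate_n > 0L) {
      pmfull <- window_mask_to_volume(masks, "plate_mask")
      bmd_plate <- mean_bmd(grey, binary_volume(pmfull, v, side = binary$side), cal)
    }
    if (bv_n > 0L) {
      tbfull <- window_mask_to_volume(masks, "trab_bone")
      bmd_trab <- mean_bmd(grey, binary_volume(tbfull, v, side = binary$side), cal)
    }
  }
  bvtv <- if (tv_n > 0L) 100 * bv_n / tv_n else NA_real_
  structure(list(side = w$side,
                 plate_volume_mm3 = plate_n * voxvol_mm3,
                 plate_thickness_um = plate_th,
                 boundary_depth_um = mean(masks$boundary_depth_um),
                 plate_bmd = bmd_plate,
                 trab_total_volume_mm3 = tv_n * voxvol_mm3,
                 trab_bone_volume_mm3 = bv_n * voxvol_mm3,
                 trab_bvtv_percent = bvtv,
                 trab_bmd = bmd_trab),
            class = "compartment_result")
}

#' @export
print.compartment_result <- function(x, ...) {
  cat(sprintf("<compartment_result> (%s)\n", x$side))
  cat(sprintf("  plate:      volume %.4g mm^3, thickness %.1f um (boundary depth %.1f um), BMD %s\n",
              x$plate_volume_mm3, x$plate_thickness_um, x$boundary_depth_um,
              ifelse(is.na(x$plate_bmd), "-", sprintf("%.3f g/cm^3", x$plate_bmd))))
  cat(sprintf("  trabecular: TV %.4g mm^3, BV %.4g mm^3, BV/TV %.1f%%, BMD %s\n",
              x$trab_total_volume_mm3, x$trab_bone_volume_mm3,
              x$trab_bvtv_percent,
              ifelse(is.na(x$trab_bmd), "-", sprintf("%.3f g/cm^3", x$trab_bmd))))
  invisible(x)
}

#' Full compartment analysis of one binarized volume
#'
#' Convenience wrapper: landmarks, window placement, partition and
#' quantification for both plateau aspects.
#'
#' @param binary a [binary_volume()].
#' @param config a [study_config()].
#' @param grey,cal optional grey volume and BMD calibration for
#'   densitometry.
#' @return named list of two [quantify_compartments()] results
#'   (`medial`, `lateral`), with the landmarks and windows attached as
#'   attributes.
#' @export
analyse_compartments <- function(binary, config = study_config(),
                                 grey = NULL, cal = NULL) {
  lm <- detect_landmarks(binary, config)
  wins <- place_windows(lm, config, dim(binary$data))
  res <- lapply(wins, function(w) {
    masks <- partition_window(binary, w, config)
    quantify_compartments(masks, binary, grey, cal)
  })
  attr(res, "landmarks") <- lm
  attr(res, "windows") <- wins
  res
}
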