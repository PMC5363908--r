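#' Grey-level image volume
#'
#' Container for a 3D micro-CT grey-level volume on the 0--255 intensity
#' scale with isotropic voxel size. Internally the array is always stored in
#' the order medial-lateral x proximal-distal x anterior-posterior
#' (`ML`, `PD`, `AP`), with index 1 of the PD axis at the proximal end.
#' World coordinates are `(index - 1) * voxel_size_um`.
#'
#' @param data 3D numeric array with all values in `[0, 255]`.
#' @param voxel_size_um isotropic voxel size in micrometres (> 0).
#' @param axes character vector of length 3 naming the anatomical direction
#'   of each array dimension; a permutation of `c("ML", "PD", "AP")`. The
#'   array is permuted to the internal `ML, PD, AP` order.
#' @param side which end of the ML axis is medial: `"low"` (default) or
#'   `"high"`. Left and right knees mirror each other, so this is supplied
#'   per specimen.
#' @return An object of class `image_volume`.
#' @export
image_volume <- function(data, voxel_size_um, axes = c("ML", "PD", "AP"),
                         side = c("low", "high")) {
  side <- match.arg(side)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1L ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0)
    stop("`voxel_size_um` must be a positive scalar", call. = FALSE)
  if (length(axes) != 3L || !setequal(axes, .INTERNAL_AXES))
    stop("`axes` must be a permutation of ML, PD, AP", call. = FALSE)
  rng <- range(data, finite = TRUE)
  if (rng[1] < 0 || rng[2] > 255)
    stop("intensities must lie in [0, 255]", call. = FALSE)
  perm <- match(.INTERNAL_AXES, axes)
  if (!identical(perm, 1:3)) data <- aperm(data, perm)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 axes = .INTERNAL_AXES, side = side),
            class = "image_volume")
}

#' Binary (bone/background) volume
#'
#' Same geometry conventions as [image_volume()], values restricted to
#' `{0, 1}`.
#'
#' @inheritParams image_volume
#' @return An object of class `binary_volume`.
#' @export
binary_volume <- function(data, voxel_size_um, axes = c("ML", "PD", "AP"),
                          side = c("low", "high")) {
  side <- match.arg(side)
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3D array", call. = FALSE)
  if (!all(data %in% c(0, 1)))
    stop("binary volume values must be 0 or 1", call. = FALSE)
  perm <- match(.INTERNAL_AXES, axes)
  storage.mode(data) <- "integer"
  if (!identical(perm, 1:3)) data <- aperm(data, perm)
  structure(list(data = data, voxel_size_um = as.numeric(voxel_size_um),
                 axes = .INTERNAL_AXES, side = side),
            class = "binary_volume")
}

is_volume <- function(x) inherits(x, c("image_volume", "binary_volume"))

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels (ML x PD x AP), %.3g um/voxel, medial = %s-x\n",
              d[1], d[2], d[3], x$voxel_size_um, x$side))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.binary_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<binary_volume> %d x %d x %d voxels (ML x PD x AP), %.3g um/voxel, medial = %s-x\n",
              d[1], d[2], d[3], x$voxel_size_um, x$side))
  cat(sprintf("  foreground: %d voxels (%.3g mm^3)\n", sum(x$data),
              sum(x$data) * x$voxel_size_um^3 * 1e-9))
  invisible(x)
}

same_geometry <- function(a, b) {
  identical(dim(a$data), dim(b$data)) &&
    isTRUE(all.equal(a$voxel_size_um, b$voxel_size_um))
}

# numeric-aware lexicographic sort for scanner slice exports
# (slice2 < slice10)
sort_slices <- function(files) {
  base <- basename(files)
  num <- suppressWarnings(as.numeric(gsub("\\D", "", base)))
  ord <- order(is.na(num), num, base)
  files[ord]
}

slice_matrix_from_file <- function(f) {
  ext <- tolower(tools::file_ext(f))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(f, as.is = TRUE)
    if (is.double(m) && max(m) <= 1) m <- m * 255
  } else if (ext == "bmp") {
    m <- read_bmp_gray(f)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop("png package required to read PNG slices", call. = FALSE)
    m <- png::readPNG(f)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m <- m * 255
  } else {
    stop("unsupported slice format: ", ext, call. = FALSE)
  }
  if (length(dim(m)) != 2L)
    stop("slice is not a single-channel 2D image: ", f, call. = FALSE)
  m
}

#' Read a grey-level volume from an image stack
#'
#' Reads either a multi-page TIFF file or a directory of per-slice images
#' (TIFF or 8-bit greyscale BMP). Slices are stacked along the
#' anterior-posterior axis in numeric-aware filename order.
#'
#' @param path multi-page TIFF file or a directory of slice images.
#' @param voxel_size_um isotropic voxel size in micrometres.
#' @param axes anatomical direction of (slice rows, slice columns, stack),
#'   default `c("PD", "ML", "AP")`.
#' @param side which ML end is medial, see [image_volume()].
#' @return An [image_volume()].
#' @export
read_volume <- function(path, voxel_size_um, axes = c("PD", "ML", "AP"),
                        side = c("low", "high")) {
  side <- match.arg(side)
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.(tif|tiff|bmp|png)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) < 1L) stop("no slice images found in ", path, call. = FALSE)
    files <- sort_slices(files)
    slices <- lapply(files, slice_matrix_from_file)
  } else if (file.exists(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    slices <- lapply(pages, function(m) {
      if (is.double(m) && max(m) <= 1) m * 255 else m
    })
  } else {
    stop("cannot read volume: ", path, call. = FALSE)
  }
  shp <- dim(slices[[1]])
  ok <- vapply(slices, function(s) identical(dim(s), shp), logical(1))
  if (!all(ok))
    stop("slice images have mismatched shapes", call. = FALSE)
  arr <- array(0, dim = c(shp[1], shp[2], length(slices)))
  for (i in seq_along(slices)) arr[, , i] <- slices[[i]]
  image_volume(arr, voxel_size_um, axes = axes, side = side)
}

#' Write a grey-level or binary volume as an image stack
#'
#' @param vol an [image_volume()] or [binary_volume()].
#' @param path output path: `.tif`/`.tiff` for a multi-page TIFF, otherwise
#'   treated as a directory of per-slice BMP images.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(is_volume(vol))
  dat <- vol$data
  if (inherits(vol, "binary_volume")) dat <- dat * 255L
  dat <- round(dat)
  # back to (slice rows = PD, cols = ML, stack = AP)
  dat <- aperm(dat, c(2, 1, 3))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(dim(dat)[3]), function(k) dat[, , k] / 255)
    tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  } else {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    nz <- dim(dat)[3]
    fmt <- paste0("slice_%0", max(4L, nchar(nz)), "d.bmp")
    for (k in seq_len(nz))
      write_bmp_gray(dat[, , k], file.path(path, sprintf(fmt, k)))
  }
  invisible(path)
}

# ---- minimal 8-bit greyscale BMP codec -------------------------------------
# Uncompressed BI_RGB, 8 bits per pixel with a 256-entry grey palette,
# bottom-up rows padded to 4 bytes. No installed package reads BMP, so the
# format (a fixed 54-byte header + palette) is parsed directly.

read_bmp_gray <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path, call. = FALSE)
  u32 <- function(off) sum(as.integer(raw[off + 1:4]) * 256^(0:3))
  u16 <- function(off) sum(as.integer(raw[off + 1:2]) * 256^(0:1))
  data_off <- u32(10)
  width <- u32(18); height <- u32(22)
  bpp <- u16(28); compression <- u32(30)
  if (bpp != 8L || compression != 0L)
    stop("only uncompressed 8-bit BMP supported", call. = FALSE)
  row_bytes <- 4L * ceiling(width / 4)
  px <- matrix(0L, nrow = height, ncol = width)
  for (r in seq_len(height)) {
    off <- data_off + (r - 1L) * row_bytes
    px[height - r + 1L, ] <- as.integer(raw[off + 1:width])
  }
  px
}

write_bmp_gray <- function(mat, path) {
  mat <- round(mat)
  stopifnot(all(mat >= 0 & mat <= 255))
  h <- nrow(mat); w <- ncol(mat)
  row_bytes <- 4L * ceiling(w / 4)
  data_size <- row_bytes * h
  palette_size <- 256L * 4L
  data_off <- 14L + 40L + palette_size
  u32 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256, x %/% 65536 %% 256,
                              x %/% 16777216 %% 256))
  u16 <- function(x) as.raw(c(x %% 256, x %/% 256 %% 256))
  hdr <- c(charToRaw("BM"), u32(data_off + data_size), u32(0), u32(data_off),
           u32(40), u32(w), u32(h), u16(1), u16(8), u32(0), u32(data_size),
           u32(2835), u32(2835), u32(256), u32(0))
  pal <- as.raw(as.vector(rbind(0:255, 0:255, 0:255, rep(0L, 256))))
  body <- raw(data_size)
  for (r in seq_len(h)) {
    off <- (r - 1L) * row_bytes
    body[off + 1:w] <- as.raw(mat[h - r + 1L, ])
  }
  writeBin(c(hdr, pal, body), path)
  invisible(path)
}
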