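# brute-force Otsu oracle: scan all 256 thresholds, maximise between-class
# variance directly from the histogram definition
otsu_oracle <- function(values) {
  v <- as.integer(round(values))
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:254) {
    g0 <- v[v <= t]
    g1 <- v[v > t]
    if (!length(g0) || !length(g1)) next
    w0 <- length(g0) / length(v)
    s <- w0 * (1 - w0) * (mean(g0) - mean(g1))^2
    if (s > best_s + 1e-12) { best_s <- s; best_t <- t }
  }
  best_t
}

test_that("Otsu threshold equals exhaustive between-class-variance search", {
  set.seed(3)
  for (i in 1:20) {
    arr <- array(sample(0:255, 6^3, replace = TRUE,
                        prob = runif(256)^2), c(6, 6, 6))
    vol <- image_volume(arr, 5)
    expect_identical(otsu_threshold(vol), otsu_oracle(arr))
  }
})

test_that("Otsu tie-breaks toward the lowest threshold on two delta peaks", {
  arr <- array(rep(c(30, 180), each = 500), c(10, 10, 10))
  t <- otsu_threshold(image_volume(arr, 5))
  expect_identical(t, otsu_oracle(arr))
  expect_identical(t, 30L)  # variance is flat on [30, 179]; lowest wins
})

test_that("Otsu rejects constant volumes", {
  expect_error(otsu_threshold(image_volume(array(100, c(4, 4, 4)), 5)),
               "degenerate")
})

test_that("binarization uses strict > and is monotone in the threshold", {
  arr <- array(rep(c(30, 180), 500), c(10, 10, 10))
  vol <- image_volume(arr, 5)
  b60 <- binarize(vol, 60)
  expect_true(all(b60$data == (arr > 60)))
  expect_identical(sum(binarize(vol, 255)$data), 0L)
  expect_identical(sum(binarize(image_volume(array(0, c(4, 4, 4)), 5), 60)$data), 0L)
  set.seed(4)
  rnd <- image_volume(array(sample(0:255, 1000, TRUE), c(10, 10, 10)), 5)
  prev <- binarize(rnd, 20)$data
  for (t in c(60, 120, 200)) {
    cur <- binarize(rnd, t)$data
    expect_true(all(cur <= prev))  # higher threshold: foreground subset
    prev <- cur
  }
  # boundary semantics: voxel exactly at the threshold is background
  expect_identical(sum(binarize(image_volume(array(60, c(2, 2, 2)), 5), 60)$data), 0L)
})

test_that("slice-wise morphology removes specks, fills gaps, and opening is idempotent", {
  arr <- array(0L, c(30, 30, 5))
  arr[15, 15, 3] <- 1L
  b <- binary_volume(arr, 5)
  expect_identical(sum(morph_clean(b, 10, "open")$data), 0L)

  bar <- array(0L, c(30, 30, 5))
  bar[5:25, 10:20, ] <- 1L
  bar[15, 10:20, ] <- 0L  # 1-voxel slit across a thick bar
  closed <- morph_clean(binary_volume(bar, 5), 10, "close")
  expect_identical(sum(closed$data[15, 10:20, ]), length(10:20) * 5L)

  blob <- make_blob(24)
  o1 <- morph_clean(blob, 10, "open")
  o2 <- morph_clean(o1, 10, "open")
  expect_identical(o1$data, o2$data)

  expect_error(morph_clean(blob, 2, "open"), "radius")
})

test_that("Gaussian smoothing preserves constants, identity at sigma 0, and mass", {
  vol <- image_volume(array(77, c(10, 10, 10)), 5)
  expect_equal(gaussian_smooth(vol, 2)$data, vol$data, tolerance = 1e-12)
  set.seed(5)
  rnd <- image_volume(array(runif(1000, 0, 255), c(10, 10, 10)), 5)
  expect_identical(gaussian_smooth(rnd, 0)$data, rnd$data)
  imp <- array(0, c(21, 21, 21)); imp[11, 11, 11] <- 255
  sm <- gaussian_smooth(image_volume(imp, 5), 2)
  expect_equal(sum(sm$data) / 255, 1, tolerance = 1e-3)
  expect_error(gaussian_smooth(rnd, -1), "non-negative")
})

test_that("cavity filling fills enclosed voids only and never removes foreground", {
  hollow <- generate_primitive("hollow_ball", list(outer_vox = 20, inner_vox = 10),
                               c(51, 51, 51), 5)
  solid <- make_ball(20, c(51, 51, 51))
  filled <- fill_cavities(hollow$volume)
  expect_identical(sum(filled$data), solid$truth$voxel_count)

  cube <- array(0L, c(20, 20, 20)); cube[5:15, 5:15, 5:15] <- 1L
  bc <- binary_volume(cube, 5)
  expect_identical(fill_cavities(bc)$data, bc$data)

  # C-shaped channel open to the border stays open
  cshape <- array(1L, c(20, 20, 20))
  cshape[8:12, 8:12, 1:12] <- 0L
  fc <- fill_cavities(binary_volume(cshape, 5))
  expect_identical(fc$data, cshape)

  blob <- make_blob(16)
  fb <- fill_cavities(blob)
  expect_true(all(fb$data >= blob$data))
})
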