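test_that("landmarks find the proximal edge, extremes and centres", {
  arr <- array(0L, c(100, 40, 9))
  arr[10:90, 15:30, ] <- 1L
  b <- binary_volume(arr, 5)
  lm <- detect_landmarks(b, study_config())
  expect_identical(lm$mid_coronal_index, 5L)
  expect_identical(unname(lm$ml_extremes), c(10L, 90L))
  expect_identical(unname(lm$centres), c(30L, 70L))  # 0.25 * 80 inward
  expect_true(all(lm$proximal_edge[10:90] == 15L))
  expect_true(all(is.na(lm$proximal_edge[c(1:9, 91:100)])))

  expect_error(detect_landmarks(binary_volume(array(0L, c(10, 10, 9)), 5)),
               "landmark")

  # side flag: medial at high x mirrors the labels
  bh <- binary_volume(arr, 5, side = "high")
  lmh <- detect_landmarks(bh, study_config())
  expect_identical(unname(lmh$ml_extremes), c(90L, 10L))
  expect_identical(unname(lmh$centres), c(70L, 30L))
})

test_that("windows honour the published micrometre geometry at both voxel sizes", {
  mk <- function(v) {
    n <- round(2200 / v)
    arr <- array(0L, c(n, round(700 / v), round(1000 / v)))
    arr[, 10, ] <- 1L
    arr[round(n * 0.1):round(n * 0.9), 10:round(500 / v), ] <- 1L
    binary_volume(arr, v)
  }
  for (v in c(5, 10)) {
    b <- mk(v)
    wins <- place_windows(detect_landmarks(b, study_config()), study_config(),
                          dim(b$data))
    for (w in wins) {
      expect_identical(diff(w$ml_range) + 1L, as.integer(round(500 / v)))
      expect_identical(w$depth_vox, as.integer(round(350 / v)))
      expect_identical(diff(w$ap_range) + 1L, as.integer(round(750 / v)))
    }
  }
  # 5 um: the published 100 x 70 x 150 voxel mapping
  b5 <- mk(5)
  w5 <- place_windows(detect_landmarks(b5, study_config()), study_config(),
                      dim(b5$data))$medial
  expect_identical(c(diff(w5$ml_range) + 1L, w5$depth_vox,
                     diff(w5$ap_range) + 1L), c(100L, 70L, 150L))

  # a centre too close to the border fails placement
  arr <- array(0L, c(30, 40, 9)); arr[2:29, 10:30, ] <- 1L
  expect_error(place_windows(detect_landmarks(binary_volume(arr, 5)),
                             study_config(), c(30, 40, 9)),
               "placement|AP extent")
})

test_that("the line-wise 90% rule partitions plate from trabecular bone", {
  # solid window: no transition, plate fills the full depth
  arr <- array(1L, c(120, 90, 160))
  b <- binary_volume(arr, 5)
  lm <- detect_landmarks(b, study_config())
  win <- structure(list(side = "medial", ml_range = c(11L, 110L),
                        ap_range = c(6L, 155L), depth_vox = 70L,
                        voxel_size_um = 5), class = "mapping_window")
  pm <- partition_window(b, win, study_config())
  expect_identical(sum(pm$trab_region), 0L)
  expect_identical(sum(pm$plate_mask), 100L * 70L * 150L)
  expect_true(all(pm$boundary_depth_um == 350))

  # first row already porous: empty plate, boundary at depth 0
  arr2 <- arr
  arr2[seq(1, 120, by = 2), , ] <- 0L  # 50% everywhere
  pm2 <- partition_window(binary_volume(arr2, 5), win, study_config())
  expect_identical(sum(pm2$plate_mask), 0L)
  expect_true(all(pm2$boundary_depth_um == 0))
  expect_identical(sum(pm2$trab_region), 100L * 70L * 150L)

  # compartment masks are disjoint and confined to the window
  pair <- cached_pair_10um()
  b10 <- binarize(pair$operated, otsu_threshold(pair$operated))
  lm10 <- detect_landmarks(b10, study_config())
  w10 <- place_windows(lm10, study_config(), dim(b10$data))$medial
  pm10 <- partition_window(b10, w10, study_config())
  expect_identical(sum(pm10$plate_mask * pm10$trab_region), 0L)
  expect_true(all(pm10$trab_bone <= pm10$trab_region))
  expect_lte(sum(pm10$plate_mask) + sum(pm10$trab_region),
             prod(dim(pm10$plate_mask)))
  # phantom truth: boundary at the plate thickness on every slice
  expect_true(all(abs(pm10$boundary_depth_um -
                        pair$truth$plate_thickness_um) <= 10))
})

test_that("compartment quantification recovers phantom ground truth", {
  pair <- cached_pair_10um()
  b <- binarize(pair$operated, otsu_threshold(pair$operated))
  cal <- calibrate_bmd(c(0.25, 100), c(0.75, 200))
  res <- analyse_compartments(b, study_config(), grey = pair$operated,
                              cal = cal)
  tw <- pair$truth$windows_operated
  for (side in c("medial", "lateral")) {
    r <- res[[side]]
    expect_equal(r$plate_volume_mm3, tw[[side]]$plate_volume_mm3,
                 tolerance = 0.05)
    expect_lte(abs(r$plate_thickness_um - pair$truth$plate_thickness_um), 10)
    expect_lte(abs(r$trab_bvtv_percent - tw[[side]]$bvtv_percent), 5)
    expect_true(r$trab_bone_volume_mm3 <= r$trab_total_volume_mm3)
    expect_equal(r$trab_bvtv_percent,
                 100 * r$trab_bone_volume_mm3 / r$trab_total_volume_mm3)
    # phantom bone grey is 180: BMD near the calibrated value for 180
    expect_equal(r$plate_bmd, 0.25 + 0.005 * 80, tolerance = 0.02)
    expect_equal(r$trab_bmd, 0.25 + 0.005 * 80, tolerance = 0.02)
  }
})

test_that("a uniform grey window reproduces the carried densitometry case", {
  arr <- array(1L, c(120, 90, 160))
  grey <- image_volume(array(150, c(120, 90, 160)), 5)
  b <- binary_volume(arr, 5)
  win <- structure(list(side = "medial", ml_range = c(11L, 110L),
                        ap_range = c(6L, 155L), depth_vox = 70L,
                        voxel_size_um = 5), class = "mapping_window")
  pm <- partition_window(b, win, study_config())
  cal <- calibrate_bmd(c(0.25, 100), c(0.75, 200))
  q <- quantify_compartments(pm, b, grey, cal)
  expect_equal(q$plate_bmd, 0.5)
  expect_true(is.na(q$trab_bmd))  # fully solid: no trabecular compartment
  expect_equal(q$plate_volume_mm3, 100 * 70 * 150 * 125 * 1e-9)
})
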