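
test_that("slab local thickness equals the analytic slab value mid-slab", {
  for (v in c(5, 10)) {
    for (t_um in c(50, 100, 200, 300)) {
      t_vox <- as.integer(round(t_um / v))
      n_lat <- t_vox + 26L  # wide enough that the grid edge cannot clip
      pr <- generate_primitive("slab", list(thickness_vox = t_vox),
                               c(n_lat, t_vox + 12L, n_lat), v)
      th <- local_thickness(pr$volume)
      cmid <- n_lat %/% 2L
      mid <- th$data[cmid, which(pr$volume$data[cmid, , cmid] == 1), cmid]
      # centre-to-centre distance convention rounds odd slabs up one voxel
      expect_lte(max(abs(mid - t_vox * v)), v)
    }
  }
})

test_that("ball local thickness matches the digital diameter within a voxel", {
  pr <- make_ball(15.5, c(41, 41, 41))
  th <- local_thickness(pr$volume)
  expect_lt(abs(th$data[21, 21, 21] - 31 * 5), 5 + 1e-9)
  expect_error(local_thickness(binary_volume(array(0L, c(5, 5, 5)), 5)),
               "empty")
})

test_that("local thickness equals the brute-force inscribed-sphere oracle", {
  blob <- make_blob(14, seed = 11)
  th <- local_thickness(blob)
  oracle <- thickness_oracle(blob$data, blob$voxel_size_um)
  fg <- blob$data == 1
  expect_lte(max(abs(th$data[fg] - oracle[fg])), blob$voxel_size_um)
})

test_that("local thickness is monotone under dilation", {
  blob <- make_blob(16, seed = 12)
  th1 <- local_thickness(blob)
  dil <- morph_clean(blob, blob$voxel_size_um * 2, "dilate")
  th2 <- local_thickness(dil)
  fg <- blob$data == 1
  expect_true(all(th2$data[fg] >= th1$data[fg] - 1e-9))
})

test_that("surface heat maps project the first proximal foreground voxel", {
  expect_true(all(abs(slab_heatmap_interior(100, 5) - 100) <= 5))

  # step phantom: two half-slabs of 100 and 200 um; plateau levels are
  # checked away from the junction and the grid edges
  arr <- array(0L, c(90, 60, 60))
  arr[1:40, 11:30, ] <- 1L   # 100 um = 20 voxels at 5 um
  arr[41:90, 11:50, ] <- 1L  # 200 um
  hm2 <- surface_heatmap(local_thickness(binary_volume(arr, 5)))
  expect_true(all(abs(hm2$data[15:28, 25:36] - 100) <= 5))
  expect_true(all(abs(hm2$data[65:75, 25:36] - 200) <= 5))

  # empty columns are no-data
  arr2 <- array(0L, c(10, 10, 10)); arr2[3:4, 5:6, 3:8] <- 1L
  hm3 <- surface_heatmap(local_thickness(binary_volume(arr2, 5)))
  expect_true(all(is.na(hm3$data[7:10, ])))
  expect_true(all(!is.na(hm3$data[3:4, 3:8])))
})

test_that("ML profiles aggregate the configured AP band", {
  const <- structure(list(data = matrix(120, 40, 30), voxel_size_um = 5),
                     class = "thickness_map")
  expect_true(all(ml_profile(const, band_um = 100) == 120))

  set.seed(13)
  m <- matrix(runif(40 * 30, 50, 250), 40, 30)
  map <- structure(list(data = m, voxel_size_um = 5),
                   class = "thickness_map")
  # single-row band equals that row
  centre <- 14 * 5  # 0-based world coordinate of column 15
  expect_equal(unname(ml_profile(map, band_um = 5, centre_ap = centre)),
               m[, 15])
  # known column means over an 11-row band
  prof <- ml_profile(map, band_um = 55, centre_ap = centre)
  expect_equal(unname(prof), rowMeans(m[, 10:20]))
  expect_error(ml_profile(map, band_um = 5000), "band")
})

test_that("heat maps export to 16-bit TIFF (tenths of um) and CSV", {
  map <- structure(list(data = matrix(c(NA, 123.45, 200.0, 55.5), 2, 2),
                        voxel_size_um = 5), class = "thickness_map")
  tif <- withr::local_tempfile(fileext = ".tif")
  write_heatmap_tiff(map, tif)
  enc <- round(tiff::readTIFF(tif, as.is = TRUE))
  expect_equal(sort(as.vector(enc)), sort(c(0, 1234, 2000, 555)))
  csv <- withr::local_tempfile(fileext = ".csv")
  write_heatmap_csv(map, csv)
  back <- as.matrix(read.csv(csv))
  expect_equal(unname(back[2, 1]), 123.45)
})
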