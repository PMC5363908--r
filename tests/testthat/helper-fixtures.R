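# Shared fixtures: all inputs are generated in code at test time.

# one in vivo resolution (10 um) phantom pair, reused across test files
.fixture_env <- new.env(parent = emptyenv())

cached_pair_10um <- function() {
  if (is.null(.fixture_env$pair10)) {
    .fixture_env$pair10 <- generate_epiphysis_pair(
      phantom_spec(voxel_size_um = 10, noise_sd = 10, seed = 42L))
  }
  .fixture_env$pair10
}

make_ball <- function(radius_vox, dim = rep(2L * ceiling(radius_vox) + 11L, 3),
                      voxel_size_um = 5) {
  generate_primitive("ball", list(radius_vox = radius_vox), dim,
                     voxel_size_um)
}

# small random blob: thresholded smoothed noise, morphologically plausible
make_blob <- function(n = 20L, voxel_size_um = 5, seed = 7L) {
  set.seed(seed)
  raw <- array(runif(n^3), rep(n, 3L))
  sm <- array(tibmorph:::cpp_gauss3d(as.numeric(raw), rep(n, 3L), 2),
              rep(n, 3L))
  binary_volume((sm > stats::quantile(sm, 0.6)) * 1L, voxel_size_um)
}

# axis-aligned unit-cube surface mesh (12 triangles, 8 unique vertices)
cube_mesh <- function(side_um = 1) {
  v <- unname(as.matrix(expand.grid(c(0, side_um), c(0, side_um),
                                    c(0, side_um))))
  f <- rbind(c(1, 3, 2), c(2, 3, 4),   # z = 0
             c(5, 6, 7), c(6, 8, 7),   # z = 1
             c(1, 2, 5), c(2, 6, 5),   # y = 0
             c(3, 7, 4), c(4, 7, 8),   # y = 1
             c(1, 5, 3), c(3, 5, 7),   # x = 0
             c(2, 4, 6), c(4, 8, 6))   # x = 1
  surface_mesh(v, f)
}

# uniform axis-angle rotation with total angle bounded by max_deg
random_bounded_rotation <- function(max_deg) {
  ax <- stats::rnorm(3)
  ax <- ax / sqrt(sum(ax^2))
  ang <- stats::runif(1, 0, max_deg) * pi / 180
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  diag(3) + sin(ang) * K + (1 - cos(ang)) * K %*% K
}

# registration test mesh: coarse epiphysis phantom outer surface
coarse_phantom_mesh <- function() {
  if (is.null(.fixture_env$mesh20)) {
    sp <- phantom_spec(voxel_size_um = 20, noise_sd = 0)
    pair <- generate_epiphysis_pair(sp)
    solid <- fill_cavities(binarize(pair$operated, 60))
    .fixture_env$mesh20 <- mesh_from_binary(solid)
  }
  .fixture_env$mesh20
}

expect_transform_close <- function(t1, t2, rot_tol = 1e-6, trans_tol = 1e-3) {
  expect_lt(max(abs(t1$rotation - t2$rotation)), rot_tol)
  expect_lt(max(abs(t1$translation - t2$translation)), trans_tol)
}

# Brute-force largest-inscribed-sphere oracle, straight from the
# definition: a sphere centred at a foreground voxel with radius equal to
# its brute-force distance to the nearest background centre lies inside
# the object; each voxel takes the diameter of the largest such sphere
# containing it strictly.
thickness_oracle <- function(bin_arr, voxel_size_um) {
  d <- dim(bin_arr)
  idx <- which(bin_arr == 1, arr.ind = TRUE)
  bg <- which(bin_arr == 0, arr.ind = TRUE)
  r <- apply(idx, 1, function(p) {
    inside <- if (nrow(bg)) sqrt(min(colSums((t(bg) - p)^2))) else Inf
    border <- min(p, d + 1 - p)  # outside the grid is background
    min(inside, border)
  })
  out <- numeric(nrow(idx))
  for (i in seq_len(nrow(idx))) {
    sep2 <- colSums((t(idx) - idx[i, ])^2)
    out[i] <- 2 * max(r[sep2 < r^2 - 1e-9])
  }
  th <- array(0, d)
  th[cbind(idx)] <- out * voxel_size_um
  th
}

make_ellipsoid_grey <- function(semi_um = c(600, 400, 500), voxel_size_um = 5,
                                bump_mm3 = 0) {
  v <- voxel_size_um
  dims <- round(2 * (semi_um + 100) / v)
  ctr <- (dims - 1) / 2
  ex <- (((seq_len(dims[1]) - 1) - ctr[1]) * v / semi_um[1])^2
  ey <- (((seq_len(dims[2]) - 1) - ctr[2]) * v / semi_um[2])^2
  ez <- (((seq_len(dims[3]) - 1) - ctr[3]) * v / semi_um[3])^2
  arr <- array(30, dims)
  for (k in seq_len(dims[3]))
    arr[, , k] <- ifelse(outer(ex, ey, "+") + ez[k] <= 1, 180, 30)
  bump_vox <- 0L
  if (bump_mm3 > 0) {
    # half-ball bump on the +x pole, scaled to the requested volume
    r_um <- (bump_mm3 * 1e9 / (2 / 3 * pi))^(1 / 3)
    r_vox <- r_um / v
    cx <- ctr[1] + semi_um[1] / v
    bx <- ((seq_len(dims[1]) - 1) - cx)
    for (k in seq_len(dims[3])) {
      bz2 <- (((k - 1) - ctr[3]))^2
      m <- outer(bx^2, (((seq_len(dims[2]) - 1) - ctr[2]))^2, "+") + bz2 <=
        r_vox^2
      m <- m & (bx >= 0) & arr[, , k] < 100
      bump_vox <- bump_vox + sum(m)
      arr[, , k][m] <- 180
    }
  }
  list(vol = image_volume(arr, v), bump_vox = bump_vox)
}

write_pair_stacks <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(pair$operated, file.path(dir, "operated.tif"))
  write_volume(pair$control, file.path(dir, "control.tif"))
  dir
}

make_manifest <- function(specs, root) {
  rows <- lapply(seq_along(specs), function(i) {
    pair <- generate_epiphysis_pair(specs[[i]])
    d <- write_pair_stacks(pair, file.path(root, paste0("spec", i)))
    data.frame(specimen = paste0("P", i),
               operated = file.path(d, "operated.tif"),
               control = file.path(d, "control.tif"),
               voxel_size_um = specs[[i]]$voxel_size_um,
               truth_plate_um = specs[[i]]$plate_thickness_um,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# heat map of a lateral-interior region of a digitized slab: columns closer
# than ~t/2 to the grid edge read thin because outside the grid is
# background, so the constant-map invariant applies to the interior
slab_heatmap_interior <- function(t_um, voxel_size_um) {
  t_vox <- as.integer(round(t_um / voxel_size_um))
  n_lat <- t_vox + 26L
  pr <- generate_primitive("slab", list(thickness_vox = t_vox),
                           c(n_lat, t_vox + 12L, n_lat), voxel_size_um)
  hm <- surface_heatmap(local_thickness(pr$volume))
  margin <- as.integer(ceiling(t_vox / 2)) + 2L
  hm$data[(margin + 1L):(n_lat - margin), (margin + 1L):(n_lat - margin)]
}
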