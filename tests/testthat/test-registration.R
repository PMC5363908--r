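test_that("rigid transforms compose, invert and persist", {
  set.seed(20)
  t1 <- random_rigid_transform(15, 100)
  t2 <- random_rigid_transform(15, 100)
  m <- cube_mesh(100)
  # (t2 o t1)(m) equals t2(t1(m)) vertex-wise
  expect_equal(apply_transform(m, compose_transform(t2, t1))$vertices,
               apply_transform(apply_transform(m, t1), t2)$vertices,
               tolerance = 1e-9)
  # inverse round trip
  back <- apply_transform(apply_transform(m, t1), invert_transform(t1))
  expect_lt(max(abs(back$vertices - m$vertices)), 1e-6)
  # identity leaves the mesh untouched
  expect_identical(apply_transform(m, rigid_transform())$vertices, m$vertices)
  # persistence as a 12-number text file
  path <- withr::local_tempfile(fileext = ".txt")
  write_transform(t1, path)
  expect_transform_close(read_transform(path), t1, 1e-12, 1e-9)
  writeLines(c("1", "2"), path)
  expect_error(read_transform(path), "12 numbers")
  # reflections are rejected
  expect_error(rigid_transform(diag(c(-1, 1, 1))), "reflection")
})

test_that("isosurface meshes reproduce analytic areas and volumes", {
  ball <- make_ball(20, c(51, 51, 51))
  m <- mesh_from_binary(ball$volume)
  expect_equal(mesh_area(m), 4 * pi * 100^2, tolerance = 0.05)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 100^3, tolerance = 0.05)

  cube <- array(0L, c(30, 30, 30)); cube[6:25, 6:25, 6:25] <- 1L
  mc <- mesh_from_binary(binary_volume(cube, 5))
  expect_equal(mesh_volume(mc), (20 * 5)^3, tolerance = 0.05)
  expect_error(mesh_from_binary(binary_volume(array(0L, c(4, 4, 4)), 5)),
               "empty")
})

test_that("registering a mesh to itself returns the identity", {
  m <- coarse_phantom_mesh()
  reg <- icp_register(m, m)
  expect_lt(reg$rms, 1e-3)
  expect_lt(max(abs(reg$transform$rotation - diag(3))), 1e-6)
  expect_lt(max(abs(reg$transform$translation)), 1e-3)
  expect_true(reg$converged)
})

test_that("a known rigid perturbation is recovered below 0.5 um RMS", {
  m <- coarse_phantom_mesh()
  ang <- 10 * pi / 180
  rx <- matrix(c(1, 0, 0, 0, cos(ang), sin(ang), 0, -sin(ang), cos(ang)), 3, 3)
  ry <- matrix(c(cos(ang), 0, -sin(ang), 0, 1, 0, sin(ang), 0, cos(ang)), 3, 3)
  rz <- matrix(c(cos(ang), sin(ang), 0, -sin(ang), cos(ang), 0, 0, 0, 1), 3, 3)
  tr <- rigid_transform(rz %*% ry %*% rx, c(50, -30, 20))
  m2 <- apply_transform(m, tr)
  reg <- icp_register(m2, m)
  expect_lt(reg$rms, 0.5)
  resid <- compose_transform(reg$transform, tr)
  expect_lt(max(abs(resid$rotation - diag(3))), 1e-3)
  # RMS is non-increasing across iterations
  expect_true(all(diff(reg$rms_trace) <= 1e-9))
})

test_that("registration is invariant to vertex ordering", {
  m <- coarse_phantom_mesh()
  set.seed(21)
  tr <- rigid_transform(random_bounded_rotation(10), c(40, 10, -25))
  m2 <- apply_transform(m, tr)
  perm <- sample(nrow(m2$vertices))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  m2p <- surface_mesh(m2$vertices[perm, ], matrix(inv[m2$faces], ncol = 3))
  r1 <- icp_register(m2, m)
  r2 <- icp_register(m2p, m)
  expect_transform_close(r1$transform, r2$transform, 1e-6, 1e-3)
})

test_that("non-overlapping shapes are flagged rather than silently aligned", {
  m <- cube_mesh(100)
  far <- apply_transform(cube_mesh(40), rigid_transform(diag(3), c(1e5, 1e5, 1e5)))
  reg <- icp_register(far, m, max_iter = 10)
  expect_true(!reg$converged || reg$rms > 0.5)
})

test_that("voxelization counts interior voxel centres exactly for a box", {
  # cube spanning exactly 10^3 voxel centres: centres 5..14 * 5 um, faces
  # half a voxel outside the outermost centres
  lo <- 5 * 5 - 2.5
  hi <- 14 * 5 + 2.5
  m <- cube_mesh(hi - lo)
  m$vertices <- m$vertices + lo
  vox <- voxelize(m, c(20, 20, 20), 5)
  expect_identical(sum(vox$data), 1000L)
  expect_true(all(vox$data[6:15, 6:15, 6:15] == 1L))
})

test_that("mesh/voxel round trips preserve the object", {
  ball <- make_ball(20, c(51, 51, 51))
  m <- mesh_from_binary(ball$volume)
  vox <- voxelize(m, c(51, 51, 51), 5)
  inter <- sum(vox$data & ball$volume$data)
  dice <- 2 * inter / (sum(vox$data) + sum(ball$volume$data))
  expect_gt(dice, 0.98)
  expect_equal(sum(vox$data), sum(ball$volume$data), tolerance = 0.03)

  outside <- apply_transform(m, rigid_transform(diag(3), c(1e4, 0, 0)))
  expect_warning(res <- voxelize(outside, c(51, 51, 51), 5), "outside")
  expect_identical(sum(res$data), 0L)
})

test_that("mirroring handles contralateral chirality and keeps orientation", {
  m <- coarse_phantom_mesh()
  mm <- mirror_mesh(m, axis = 1)
  expect_equal(mesh_volume(mm), mesh_volume(m), tolerance = 1e-9)
  expect_equal(mesh_area(mm), mesh_area(m), tolerance = 1e-9)
  # mirrored mesh registers back onto the original after mirroring again
  expect_lt(icp_register(mirror_mesh(mm, axis = 1), m)$rms, 1e-3)
})
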