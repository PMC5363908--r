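#' Specification of a synthetic epiphysis phantom
#'
#' Describes a tibial-epiphysis-like test object: a flat-topped dome
#' (power-8 superelliptic footprint with an elliptic shoulder) carrying a
#' compact surface shell (the subchondral plate) of known thickness over a
#' periodic honeycomb lattice interior of known bone volume fraction,
#' optionally with a medial marginal protrusion (osteophyte) of known
#' volume. Two grey levels plus additive Gaussian noise emulate a
#' binarizable micro-CT scan.
#'
#' The lattice interior is a prismatic honeycomb: two orthogonal families
#' of periodic walls (normal to ML and to PD, running through along AP), a
#' point being bone iff its ML or PD coordinate falls within a wall band of
#' width `strut_fraction * lattice_period_um`. This gives bone volume
#' fraction `1 - (1 - strut_fraction)^2` and, crucially, the same
#' line-wise porosity signature on every coronal slice: rows through a
#' PD-wall are fully dense, all other rows carry exactly the ML-wall
#' fraction. Wall phases are aligned to the voxel grid
#' (use periods and fractions that keep band edges on multiples of the
#' voxel size for exact digitization) and the first wall row sits
#' `lattice_gap_um` below the plate so the line-wise porosity rule has a
#' sharp, analytically known transition at the plate bottom.
#'
#' @param voxel_size_um voxel size (5 ex vivo, 10 in vivo conventions).
#' @param ml_semi_um,dome_height_um,ap_semi_um dome semi-extent (ML),
#'   height (PD) and semi-extent (AP) in micrometres.
#' @param flat_fraction normalised footprint radius up to which the top
#'   surface is flat.
#' @param plate_thickness_um compact shell thickness (control bone).
#' @param plate_thickness_operated_um shell thickness of the operated
#'   bone (default: same as control).
#' @param lattice_period_um,strut_fraction,lattice_gap_um lattice geometry.
#' @param osteophyte_volume_mm3 target protrusion volume (0 for none); the
#'   protrusion is a half-ellipsoid embedded at the medial margin, scaled
#'   so its digitized extra-dome volume matches the target.
#' @param grey_bone,grey_background the two grey levels (defaults 180, 30).
#' @param noise_sd additive Gaussian noise SD (clipped to 0--255).
#' @param jitter optional known [rigid_transform()] applied to the operated
#'   volume (nearest-neighbour resampling about the volume centre).
#' @param seed RNG seed for noise (truth is seed-independent).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(voxel_size_um = 5,
                         ml_semi_um = 1100,
                         dome_height_um = 700,
                         ap_semi_um = 650,
                         flat_fraction = 0.9,
                         plate_thickness_um = 150,
                         plate_thickness_operated_um = plate_thickness_um,
                         lattice_period_um = 100,
                         strut_fraction = 0.3,
                         lattice_gap_um = 40,
                         osteophyte_volume_mm3 = 0,
                         grey_bone = 180,
                         grey_background = 30,
                         noise_sd = 10,
                         jitter = NULL,
                         seed = 1L) {
  spec <- list(voxel_size_um = voxel_size_um, ml_semi_um = ml_semi_um,
               dome_height_um = dome_height_um, ap_semi_um = ap_semi_um,
               flat_fraction = flat_fraction,
               plate_thickness_um = plate_thickness_um,
               plate_thickness_operated_um = plate_thickness_operated_um,
               lattice_period_um = lattice_period_um,
               strut_fraction = strut_fraction,
               lattice_gap_um = lattice_gap_um,
               osteophyte_volume_mm3 = osteophyte_volume_mm3,
               grey_bone = grey_bone, grey_background = grey_background,
               noise_sd = noise_sd, jitter = jitter, seed = as.integer(seed))
  if (spec$plate_thickness_um >= spec$dome_height_um ||
      spec$plate_thickness_operated_um >= spec$dome_height_um)
    stop("plate thickness must be smaller than the dome height", call. = FALSE)
  if (spec$strut_fraction <= 0 || spec$strut_fraction >= 1)
    stop("strut_fraction must be in (0, 1)", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> %g um voxels, dome %g x %g x %g um, plate %g um, lattice BVF %.1f%%, osteophyte %g mm^3\n",
              x$voxel_size_um, 2 * x$ml_semi_um, x$dome_height_um,
              2 * x$ap_semi_um, x$plate_thickness_um,
              100 * (1 - (1 - x$strut_fraction)^2), x$osteophyte_volume_mm3))
  invisible(x)
}

# normalised power-8 footprint radius -> flat-top height profile in [0,1]
dome_profile <- function(rho, flat_fraction) {
  s <- numeric(length(rho))
  s[rho <= flat_fraction] <- 1
  sh <- rho > flat_fraction & rho <= 1
  s[sh] <- sqrt(pmax(0, 1 - ((rho[sh] - flat_fraction) /
                               (1 - flat_fraction))^2))
  s
}

# geometry shared by both members of a pair
phantom_frame <- function(spec) {
  v <- spec$voxel_size_um
  pad <- 60
  if (!is.null(spec$jitter)) {
    # enough margin that the jittered dome cannot leave the grid
    ang <- acos(pmin(1, pmax(-1, (sum(diag(spec$jitter$rotation)) - 1) / 2)))
    reach <- sqrt(spec$ml_semi_um^2 + spec$dome_height_um^2 +
                    spec$ap_semi_um^2)
    pad <- pad + ceiling((2 * sin(ang / 2) * reach +
                            sqrt(sum(spec$jitter$translation^2))) / v) * v
  }
  u_max <- if (spec$osteophyte_volume_mm3 > 0)
    osteophyte_semiaxis(spec$osteophyte_volume_mm3 * 1.6e9) else 0
  extra <- ceiling(u_max / v) * v
  a <- spec$ml_semi_um; b <- spec$dome_height_um; c3 <- spec$ap_semi_um
  nx <- as.integer(round((2 * a + 2 * pad + extra) / v))
  ny <- as.integer(round((b + 2 * pad) / v))
  nz <- as.integer(round((2 * c3 + 2 * pad) / v))
  x0 <- pad + extra + a    # dome centre, world um
  y_top <- pad             # flat-top surface height
  z0 <- pad + c3
  list(v = v, dim = c(nx, ny, nz), x0 = x0, y_top = y_top, z0 = z0,
       a = a, b = b, c3 = c3)
}

# nominal half-ellipsoid x-semi-axis for a target volume (um^3);
# semi-axes (u, 0.7u, u), half kept
osteophyte_semiaxis <- function(volume_um3) {
  ((volume_um3) / ((2 / 3) * pi * 0.7))^(1 / 3)
}

# digitized osteophyte mask over the full grid for semi-axis u;
# returns logical array restricted to voxels outside the solid dome
osteophyte_mask <- function(fr, spec, u, solid) {
  v <- fr$v
  xc <- fr$x0 - 0.97 * fr$a
  yc <- fr$y_top + 0.55 * fr$b
  zc <- fr$z0
  vy <- 0.7 * u
  wz <- u
  xs <- (seq_len(fr$dim[1]) - 1) * v
  ys <- (seq_len(fr$dim[2]) - 1) * v
  zs <- (seq_len(fr$dim[3]) - 1) * v
  out <- array(FALSE, fr$dim)
  ix <- which(xs <= xc & xs >= xc - u)
  iy <- which(abs(ys - yc) <= vy)
  iz <- which(abs(zs - zc) <= wz)
  if (!length(ix) || !length(iy) || !length(iz)) return(out)
  ex <- ((xs[ix] - xc) / u)^2
  ey <- ((ys[iy] - yc) / vy)^2
  ez <- ((zs[iz] - zc) / wz)^2
  for (k in seq_along(iz)) {
    m <- outer(ex, ey, "+") + ez[k] <= 1
    out[ix, iy, iz[k]] <- m & !solid[ix, iy, iz[k], drop = TRUE]
  }
  out
}

#' Generate a digitized geometric primitive with analytic truth
#'
#' Test primitives on a given grid: `slab` (PD-normal slab), `ball`,
#' `hollow_ball` (spherical shell) and `lattice` (the prismatic honeycomb
#' described in [phantom_spec()]).
#'
#' @param kind `"slab"`, `"ball"`, `"hollow_ball"` or `"lattice"`.
#' @param params named list: slab `thickness_vox`; ball `radius_vox`;
#'   hollow_ball `outer_vox`, `inner_vox`; lattice `period_vox`,
#'   `strut_fraction`.
#' @param dim grid dimensions.
#' @param voxel_size_um voxel size.
#' @return list with `volume` (a [binary_volume()]) and `truth` (closed-form
#'   volume/thickness/fraction values plus the exact digitized voxel count).
#' @export
generate_primitive <- function(kind = c("slab", "ball", "hollow_ball",
                                        "lattice"),
                               params, dim, voxel_size_um = 5) {
  kind <- match.arg(kind)
  dim <- as.integer(dim)
  v <- voxel_size_um
  arr <- array(0L, dim)
  truth <- list()
  ctr <- (dim - 1) / 2
  if (kind == "slab") {
    t_vox <- params$thickness_vox
    if (t_vox > dim[2] - 2) stop("slab does not fit in grid", call. = FALSE)
    y0 <- as.integer(floor((dim[2] - t_vox) / 2)) + 1L
    arr[, y0:(y0 + t_vox - 1L), ] <- 1L
    truth <- list(thickness_um = t_vox * v)
  } else if (kind %in% c("ball", "hollow_ball")) {
    r_out <- if (kind == "ball") params$radius_vox else params$outer_vox
    if (2 * r_out + 2 > min(dim)) stop("ball does not fit in grid", call. = FALSE)
    dx2 <- ((seq_len(dim[1]) - 1) - ctr[1])^2
    dy2 <- ((seq_len(dim[2]) - 1) - ctr[2])^2
    dz2 <- ((seq_len(dim[3]) - 1) - ctr[3])^2
    for (k in seq_len(dim[3])) {
      d2 <- outer(dx2, dy2, "+") + dz2[k]
      m <- d2 <= r_out^2
      if (kind == "hollow_ball") m <- m & d2 > params$inner_vox^2
      arr[, , k] <- m * 1L
    }
    truth <- if (kind == "ball")
      list(volume_um3 = 4 / 3 * pi * (r_out * v)^3, diameter_um = 2 * r_out * v)
    else list(outer_um = params$outer_vox * v, inner_um = params$inner_vox * v,
              solid_volume_um3 = 4 / 3 * pi * (params$outer_vox * v)^3)
  } else {
    p <- params$period_vox
    f <- params$strut_fraction
    if (p < 2 || f <= 0 || f >= 1) stop("invalid lattice params", call. = FALSE)
    s_w <- f * p
    wall <- function(n) ((seq_len(n) - 1) %% p) < s_w
    wx <- wall(dim[1]); wy <- wall(dim[2])
    m <- outer(wx, wy, "|")
    for (k in seq_len(dim[3])) arr[, , k] <- m * 1L
    truth <- list(bvf_nominal = 1 - (1 - f)^2)
  }
  vol <- binary_volume(arr, v)
  truth$voxel_count <- sum(arr)
  truth$volume_digitized_um3 <- sum(arr) * v^3
  list(volume = vol, truth = truth)
}

#' Generate a phantom operated/control pair with exact ground truth
#'
#' The control is the dome with plate shell and lattice interior; the
#' operated bone is the same dome with an optional medial osteophyte
#' protrusion and optionally thickened plate. Grey levels are assigned,
#' Gaussian noise added, and the operated volume optionally jittered by
#' the known rigid transform. Truth masks and values refer to the
#' noise-free, unjittered geometry.
#'
#' @param spec a [phantom_spec()].
#' @return list with `operated`, `control` ([image_volume()] objects) and
#'   `truth`, which holds the binary truth masks (`plate_mask`,
#'   `trabecular_mask`, `osteophyte_mask`, `solid_mask` for the filled
#'   epiphysis, all for the operated geometry), the scalar truths
#'   (`plate_thickness_um`, `plate_volume_mm3` and `bvtv_percent` per
#'   analytically placed window, `osteophyte_volume_mm3`,
#'   `epiphyseal_volume_mm3` control and operated) and the applied
#'   `jitter` transform.
#' @export
generate_epiphysis_pair <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(spec$seed)
  fr <- phantom_frame(spec)
  v <- fr$v
  nx <- fr$dim[1]; ny <- fr$dim[2]; nz <- fr$dim[3]
  xs <- (seq_len(nx) - 1) * v
  ys <- (seq_len(ny) - 1) * v
  zs <- (seq_len(nz) - 1) * v
  rho <- (abs(outer((xs - fr$x0) / fr$a, numeric(nz), "+"))^8 +
            abs(outer(numeric(nx), (zs - fr$z0) / fr$c3, "+"))^8)^(1 / 8)
  S <- matrix(dome_profile(as.vector(rho), spec$flat_fraction), nx, nz)
  ytop_col <- fr$y_top + fr$b * (1 - S)
  ybase <- fr$y_top + fr$b

  p <- spec$lattice_period_um
  s_w <- spec$strut_fraction * p
  phase_y <- fr$y_top + spec$plate_thickness_um + spec$lattice_gap_um
  wall_x <- ((xs - fr$x0) %% p) < s_w

  solid <- array(FALSE, fr$dim)
  for (iy in seq_len(ny)) {
    yw <- ys[iy]
    in_dome <- (S > 0) & (yw >= ytop_col) & (yw < ybase)
    if (any(in_dome)) solid[, iy, ] <- in_dome
  }
  # crust depth: distance to the exterior, so the shell follows the surface
  # everywhere (on the flat top it equals the vertical depth) and seals the
  # lattice channels at the dome shoulder and bottom
  crust_d2 <- array(cpp_edt_sq(solid * 1L, fr$dim), fr$dim)

  build_bone <- function(t_plate) {
    plate <- array(FALSE, fr$dim)
    trab <- array(FALSE, fr$dim)
    t_vox2 <- (t_plate / v)^2 + 1e-9
    wall_y <- ((ys - phase_y) %% p) < s_w
    for (iy in seq_len(ny)) {
      in_dome <- solid[, iy, ]
      if (!any(in_dome)) next
      in_plate <- in_dome & (crust_d2[, iy, ] <= t_vox2)
      plate[, iy, ] <- in_plate
      interior <- in_dome & !in_plate
      if (any(interior)) {
        lat <- if (wall_y[iy]) interior else interior & wall_x
        trab[, iy, ] <- lat
      }
    }
    list(solid = solid, plate = plate, trab = trab)
  }

  ctrl <- build_bone(spec$plate_thickness_um)
  oper <- if (spec$plate_thickness_operated_um == spec$plate_thickness_um)
    ctrl else build_bone(spec$plate_thickness_operated_um)

  # osteophyte: calibrate the semi-axis so the digitized extra-dome volume
  # matches the requested target
  osteo <- array(FALSE, fr$dim)
  if (spec$osteophyte_volume_mm3 > 0) {
    target <- spec$osteophyte_volume_mm3 * 1e9
    u_lo <- 0.7 * osteophyte_semiaxis(target)
    u_hi <- 1.4 * osteophyte_semiaxis(target)
    count_for <- function(u)
      sum(osteophyte_mask(fr, spec, u, oper$solid)) * v^3
    for (i in 1:18) {
      u_mid <- (u_lo + u_hi) / 2
      if (count_for(u_mid) < target) u_lo <- u_mid else u_hi <- u_mid
    }
    osteo <- osteophyte_mask(fr, spec, (u_lo + u_hi) / 2, oper$solid)
  }

  grey_of <- function(bone_mask) {
    g <- array(spec$grey_background, fr$dim)
    g[bone_mask] <- spec$grey_bone
    if (spec$noise_sd > 0)
      g <- g + rnorm(length(g), 0, spec$noise_sd)
    array(pmin(255, pmax(0, g)), fr$dim)
  }
  ctrl_grey <- grey_of(ctrl$plate | ctrl$trab)
  oper_grey <- grey_of(oper$plate | oper$trab | osteo)

  if (!is.null(spec$jitter)) {
    ctr_w <- (fr$dim - 1) / 2 * v
    rot <- spec$jitter$rotation
    tinv <- (ctr_w - as.numeric(t(rot) %*% (ctr_w + spec$jitter$translation))) / v
    oper_grey <- array(cpp_resample_nn(as.numeric(oper_grey), fr$dim,
                                       as.numeric(t(rot)), tinv,
                                       spec$grey_background), fr$dim)
  }

  # analytic window placement for the truth metrics (flat region)
  win_truth <- function(bone, t_plate) {
    w_vox <- round(500 / v); d_vox <- round(350 / v); nap <- round(750 / v)
    mid <- (nz + 1L) %/% 2L
    ap <- (mid - nap %/% 2L):(mid - nap %/% 2L + nap - 1L)
    # same edge rule as landmark detection, on the truth mask itself
    cols <- which(apply(bone$solid[, , mid], 1, any))
    lo_idx <- min(cols)
    hi_idx <- max(cols)
    res <- list()
    for (side in c("medial", "lateral")) {
      centre <- if (side == "medial") lo_idx + round(0.25 * (hi_idx - lo_idx))
                else hi_idx - round(0.25 * (hi_idx - lo_idx))
      x_rng <- (centre - w_vox %/% 2L):(centre - w_vox %/% 2L + w_vox - 1L)
      y0 <- round(fr$y_top / v) + 1L
      y_plate <- y0:(y0 + round(t_plate / v) - 1L)
      y_all <- y0:(y0 + d_vox - 1L)
      y_trab <- setdiff(y_all, y_plate)
      plate_n <- sum(bone$plate[x_rng, y_plate, ap])
      trab_n <- sum(bone$trab[x_rng, y_trab, ap])
      tv_n <- length(x_rng) * length(y_trab) * length(ap)
      res[[side]] <- list(plate_volume_mm3 = plate_n * v^3 * 1e-9,
                          bvtv_percent = 100 * trab_n / tv_n)
    }
    res
  }

  truth <- list(
    plate_mask = binary_volume(oper$plate * 1L, v),
    trabecular_mask = binary_volume(oper$trab * 1L, v),
    osteophyte_mask = binary_volume(osteo * 1L, v),
    solid_mask = binary_volume((oper$solid | osteo) * 1L, v),
    plate_thickness_um = spec$plate_thickness_operated_um,
    plate_thickness_control_um = spec$plate_thickness_um,
    windows_operated = win_truth(oper, spec$plate_thickness_operated_um),
    windows_control = win_truth(ctrl, spec$plate_thickness_um),
    bvtv_nominal_percent = 100 * (1 - (1 - spec$strut_fraction)^2),
    osteophyte_volume_mm3 = sum(osteo) * v^3 * 1e-9,
    epiphyseal_volume_control_mm3 = sum(ctrl$solid) * v^3 * 1e-9,
    epiphyseal_volume_operated_mm3 = sum(oper$solid | osteo) * v^3 * 1e-9,
    jitter = spec$jitter)

  list(operated = image_volume(oper_grey, v),
       control = image_volume(ctrl_grey, v),
       truth = truth)
}

#' Write a phantom pair as TIFF stacks with a truth sidecar
#'
#' @param pair a [generate_epiphysis_pair()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_phantom <- function(pair, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_volume(pair$operated, file.path(dir, "operated.tif"))
  write_volume(pair$control, file.path(dir, "control.tif"))
  tr <- pair$truth
  kv <- c(voxel_size_um = pair$operated$voxel_size_um,
          plate_thickness_um = tr$plate_thickness_um,
          plate_thickness_control_um = tr$plate_thickness_control_um,
          bvtv_nominal_percent = tr$bvtv_nominal_percent,
          osteophyte_volume_mm3 = tr$osteophyte_volume_mm3,
          epiphyseal_volume_control_mm3 = tr$epiphyseal_volume_control_mm3,
          epiphyseal_volume_operated_mm3 = tr$epiphyseal_volume_operated_mm3,
          medial_plate_volume_mm3 = tr$windows_operated$medial$plate_volume_mm3,
          lateral_plate_volume_mm3 = tr$windows_operated$lateral$plate_volume_mm3,
          medial_bvtv_percent = tr$windows_operated$medial$bvtv_percent,
          lateral_bvtv_percent = tr$windows_operated$lateral$bvtv_percent)
  writeLines(sprintf("%s = %.10g", names(kv), kv),
             file.path(dir, "truth.txt"))
  invisible(dir)
}
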