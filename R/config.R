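#' Study configuration
#'
#' All tunable parameters of the analysis pipeline, with the published
#' defaults. Lengths are in micrometres, intensities on the 0--255 scale.
#'
#' @param global_threshold fallback global binarization threshold (default
#'   60, the value found optimal for murine tibial scans on the 0--255
#'   scale) used when `otsu_enabled` is `FALSE`.
#' @param otsu_enabled compute the threshold by Otsu's method (default).
#' @param window_width_um ML width of each mapping window (500).
#' @param window_depth_um depth of each mapping window from the proximal
#'   plate surface (350).
#' @param ap_extent_um AP extent of the mapping windows (750; 375 anterior
#'   and 375 posterior of the middle coronal slice).
#' @param profile_band_um AP band height for medial-lateral thickness
#'   profiles (750).
#' @param plate_bvf_cutoff line-wise bone-volume-fraction below which the
#'   plate/trabecular transition is declared (0.90; plate macro-porosity
#'   < 10%).
#' @param boundary_consecutive number of consecutive sub-cutoff rows
#'   required to declare the transition (default 1: first crossing).
#' @param morph_radius_um disk kernel radius for morphological cleanup and
#'   for the osteophyte closing/dilation (default 2 voxels at read time;
#'   stored in micrometres, 10 um at the 5 um default voxel size).
#' @param gaussian_sigma Gaussian smoothing sigma in voxels for epiphyseal
#'   volume estimation (2).
#' @param osteophyte_voi_fraction medial fraction of the ML extent forming
#'   the osteophyte difference volume-of-interest (1/3).
#' @param centre_offset_fraction fractional inward offset of the window
#'   centres from the plateau ML extremes (0.25).
#' @param thickness_agg aggregator for ML profiles: `"mean"` or `"max"`.
#' @param bmd_bone_only restrict BMD averaging to bone voxels (default) or
#'   include intra-compartment pores.
#' @param random_seed seed used by stochastic helpers.
#' @return An object of class `study_config` (a named list).
#' @export
study_config <- function(global_threshold = 60,
                         otsu_enabled = TRUE,
                         window_width_um = 500,
                         window_depth_um = 350,
                         ap_extent_um = 750,
                         profile_band_um = 750,
                         plate_bvf_cutoff = 0.90,
                         boundary_consecutive = 1L,
                         morph_radius_um = 10,
                         gaussian_sigma = 2,
                         osteophyte_voi_fraction = 1 / 3,
                         centre_offset_fraction = 0.25,
                         thickness_agg = c("mean", "max"),
                         bmd_bone_only = TRUE,
                         random_seed = 1L) {
  thickness_agg <- match.arg(thickness_agg)
  cfg <- list(global_threshold = global_threshold,
              otsu_enabled = isTRUE(otsu_enabled),
              window_width_um = window_width_um,
              window_depth_um = window_depth_um,
              ap_extent_um = ap_extent_um,
              profile_band_um = profile_band_um,
              plate_bvf_cutoff = plate_bvf_cutoff,
              boundary_consecutive = as.integer(boundary_consecutive),
              morph_radius_um = morph_radius_um,
              gaussian_sigma = gaussian_sigma,
              osteophyte_voi_fraction = osteophyte_voi_fraction,
              centre_offset_fraction = centre_offset_fraction,
              thickness_agg = thickness_agg,
              bmd_bone_only = isTRUE(bmd_bone_only),
              random_seed = as.integer(random_seed))
  lens <- c(cfg$window_width_um, cfg$window_depth_um, cfg$ap_extent_um,
            cfg$profile_band_um, cfg$morph_radius_um)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all configured lengths must be positive", call. = FALSE)
  if (cfg$plate_bvf_cutoff <= 0 || cfg$plate_bvf_cutoff > 1)
    stop("plate_bvf_cutoff must be in (0, 1]", call. = FALSE)
  if (cfg$global_threshold < 0 || cfg$global_threshold > 255)
    stop("global_threshold must be on the 0-255 scale", call. = FALSE)
  class(cfg) <- "study_config"
  cfg
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config>\n")
  for (k in names(x)) cat(sprintf("  %-24s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Read / write a study configuration
#'
#' Flat `key = value` file (INI/TOML-style scalars, `#` comments). Unknown
#' keys are rejected.
#'
#' @param path config file path.
#' @return [read_config()]: a `study_config`; [write_config()]: `path`.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop("malformed config line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[`, "", 1L)
  vals <- vapply(kv, `[`, "", 2L)
  defaults <- formals(study_config)
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  parsed <- lapply(seq_along(keys), function(i) {
    v <- gsub("^\"|\"$", "", vals[i])
    if (v %in% c("true", "TRUE", "false", "FALSE"))
      return(as.logical(toupper(v)))
    n <- suppressWarnings(as.numeric(v))
    if (!is.na(n)) n else v
  })
  names(parsed) <- keys
  do.call(study_config, parsed)
}

#' @rdname read_config
#' @param config a `study_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "study_config"))
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v))
    else if (is.character(v)) sprintf("\"%s\"", v)
    else format(v, digits = 15)
  }
  writeLines(sprintf("%s = %s", names(config),
                     vapply(config, fmt, "")), path)
  invisible(path)
}

# radius in voxels for a configured radius in um
radius_vox <- function(radius_um, voxel_size_um) {
  max(1L, as.integer(round(radius_um / voxel_size_um)))
}
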