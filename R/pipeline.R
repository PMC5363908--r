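#' Run the full study pipeline over a manifest of specimen pairs
#'
#' For every pair: binarization (Otsu or the configured global threshold),
#' morphological cleanup, surface mesh generation, rigid surface
#' registration of the control onto the operated bone (and of the operated
#' bone onto a template mesh, when given), voxelization of registered
#' meshes back to image stacks, landmark detection, window placement,
#' plate/trabecular partition and quantification of both plateau aspects,
#' osteophyte volumetry by shape difference, and whole epiphyseal volumes.
#' Failures are isolated per specimen and the run continues.
#'
#' @param manifest a data frame (or CSV path) with columns `specimen`,
#'   `operated` (stack path), `control` (stack path), `voxel_size_um`,
#'   and optionally `side` (`"low"`/`"high"`, default `"low"`) and
#'   `timepoint`.
#' @param config a [study_config()].
#' @param out_dir directory for results and per-specimen intermediate
#'   artefacts (meshes, transforms, masks); `NULL` to keep everything in
#'   memory only.
#' @param cal optional [calibrate_bmd()] for densitometry.
#' @param template optional [surface_mesh()]: reference specimen the
#'   operated bones are aligned to before analysis.
#' @return An object of class `study_result`: `results` (one row per
#'   specimen x side), `failures` (named character vector of error
#'   messages), `config`. When `out_dir` is given, `results.csv` is
#'   written there.
#' @export
run_study <- function(manifest, config = study_config(), out_dir = NULL,
                      cal = NULL, template = NULL) {
  if (is.character(manifest)) manifest <- read.csv(manifest,
                                                   stringsAsFactors = FALSE)
  need <- c("specimen", "operated", "control", "voxel_size_um")
  if (!all(need %in% names(manifest)))
    stop("manifest must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(manifest$specimen))
    stop("specimen ids must be unique", call. = FALSE)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)

  rows <- list()
  failures <- character(0)
  for (i in seq_len(nrow(manifest))) {
    id <- as.character(manifest$specimen[i])
    res <- tryCatch(
      analyse_pair(operated_path = manifest$operated[i],
                   control_path = manifest$control[i],
                   voxel_size_um = manifest$voxel_size_um[i],
                   side = if ("side" %in% names(manifest))
                     manifest$side[i] else "low",
                   config = config, cal = cal, template = template,
                   artefact_dir = if (is.null(out_dir)) NULL
                                  else file.path(out_dir, id)),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[id] <- conditionMessage(res)
      next
    }
    for (side in c("medial", "lateral")) {
      cc <- res$operated_compartments[[side]]
      rows[[length(rows) + 1L]] <- data.frame(
        specimen = id,
        timepoint = if ("timepoint" %in% names(manifest))
          manifest$timepoint[i] else NA,
        aspect = side,
        plate_volume_mm3 = cc$plate_volume_mm3,
        plate_thickness_um = cc$plate_thickness_um,
        boundary_depth_um = cc$boundary_depth_um,
        plate_bmd = cc$plate_bmd,
        trab_total_volume_mm3 = cc$trab_total_volume_mm3,
        trab_bone_volume_mm3 = cc$trab_bone_volume_mm3,
        trab_bvtv_percent = cc$trab_bvtv_percent,
        trab_bmd = cc$trab_bmd,
        osteophyte_volume_mm3 = res$shape_difference$osteophyte_volume_mm3,
        epiphyseal_volume_operated_mm3 = res$epiphyseal_volume_operated,
        epiphyseal_volume_control_mm3 = res$epiphyseal_volume_control,
        registration_rms_um = res$registration$rms,
        stringsAsFactors = FALSE)
    }
  }
  results <- if (length(rows)) do.call(rbind, rows) else data.frame()
  if (!is.null(out_dir))
    write.csv(format(results, digits = 12, trim = TRUE, scientific = FALSE),
              file.path(out_dir, "results.csv"), row.names = FALSE)
  structure(list(results = results, failures = failures, config = config),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d rows (%d specimens), %d failure(s)\n",
              nrow(x$results), length(unique(x$results$specimen)),
              length(x$failures)))
  if (length(x$failures))
    for (id in names(x$failures))
      cat(sprintf("  FAILED %s: %s\n", id, x$failures[id]))
  invisible(x)
}

# full analysis of one operated/control pair; paths or in-memory volumes
analyse_pair <- function(operated_path, control_path, voxel_size_um,
                         side = "low", config = study_config(), cal = NULL,
                         template = NULL, artefact_dir = NULL) {
  vol_of <- function(x) {
    if (is_volume(x)) x
    else if (is.character(x) && (file.exists(x) || dir.exists(x)))
      read_volume(x, voxel_size_um, side = side)
    else stop("missing stack: ", x, call. = FALSE)
  }
  op_grey <- vol_of(operated_path)
  ct_grey <- vol_of(control_path)
  op_bin <- morph_clean(binarize(op_grey, config_threshold(op_grey, config)),
                        config$morph_radius_um, ops = c("open", "close"))
  ct_bin <- morph_clean(binarize(ct_grey, config_threshold(ct_grey, config)),
                        config$morph_radius_um, ops = c("open", "close"))

  # registration is driven by the outer surface: mesh the filled volumes
  op_mesh <- mesh_from_binary(fill_cavities(op_bin))
  template_reg <- NULL
  if (!is.null(template)) {
    # align the operated bone to the template, resample its grey volume
    # under the recovered transform, and re-binarize: compartment analysis
    # needs the internal structure, which a voxelized outer mesh lacks
    template_reg <- icp_register(op_mesh, template)
    op_mesh <- apply_transform(op_mesh, template_reg$transform)
    ctr <- template_reg$transform
    minv <- t(ctr$rotation)
    op_grey <- image_volume(
      array(cpp_resample_nn(as.numeric(op_grey$data), dim(op_grey$data),
                            as.numeric(minv),
                            -as.numeric(minv %*% ctr$translation) /
                              op_grey$voxel_size_um, 0),
            dim(op_grey$data)),
      op_grey$voxel_size_um, side = op_grey$side)
    op_bin <- morph_clean(binarize(op_grey, config_threshold(op_grey, config)),
                          config$morph_radius_um, ops = c("open", "close"))
  }
  ct_mesh <- mesh_from_binary(fill_cavities(ct_bin))
  reg <- icp_register(ct_mesh, op_mesh)
  ct_mesh_reg <- apply_transform(ct_mesh, reg$transform)
  ct_bin_reg <- voxelize(ct_mesh_reg, dim(op_bin$data),
                         op_bin$voxel_size_um, side = op_bin$side)

  comp <- analyse_compartments(op_bin, config, grey = op_grey, cal = cal)
  sd_res <- shape_difference(op_bin, ct_bin_reg, config)
  ev_op <- epiphyseal_volume(op_grey, config)
  ev_ct <- epiphyseal_volume(ct_grey, config)

  if (!is.null(artefact_dir)) {
    if (!dir.exists(artefact_dir)) dir.create(artefact_dir, recursive = TRUE)
    write_mesh(op_mesh, file.path(artefact_dir, "operated.stl"))
    write_mesh(ct_mesh_reg, file.path(artefact_dir, "control_registered.stl"))
    write_transform(reg$transform,
                    file.path(artefact_dir, "control_to_operated.txt"))
    write_volume(sd_res$difference_mask,
                 file.path(artefact_dir, "osteophyte_mask.tif"))
  }
  list(operated_compartments = comp, registration = reg,
       template_registration = template_reg, shape_difference = sd_res,
       epiphyseal_volume_operated = ev_op, epiphyseal_volume_control = ev_ct)
}

#' Validate automated measurements against a reference method
#'
#' The machinery behind method-validation tables: for every shared metric,
#' mean and SD per method, Pearson correlation, RMS error from the
#' linear-regression residuals, percent CV per method, and Bland-Altman
#' bias and limits of agreement. On phantoms the reference table can be
#' the generator ground truth; in animal studies it is manual
#' segmentation.
#'
#' @param results_auto,results_ref data frames sharing an id column and
#'   numeric metric columns.
#' @param id_col name of the id column (default `"specimen"`).
#' @param metrics metric columns to compare; default: all shared numeric
#'   columns.
#' @return An object of class `method_validation`: a data frame with one
#'   row per metric.
#' @export
validate_methods <- function(results_auto, results_ref,
                             id_col = "specimen", metrics = NULL) {
  stopifnot(id_col %in% names(results_auto), id_col %in% names(results_ref))
  keys_a <- do.call(paste, c(results_auto[intersect(c(id_col, "aspect"),
                                                    names(results_auto))],
                             sep = "|"))
  keys_r <- do.call(paste, c(results_ref[intersect(c(id_col, "aspect"),
                                                   names(results_ref))],
                             sep = "|"))
  shared <- intersect(keys_a, keys_r)
  if (length(shared) < 3L)
    stop("need at least 3 shared ids to validate", call. = FALSE)
  a <- results_auto[match(shared, keys_a), , drop = FALSE]
  r <- results_ref[match(shared, keys_r), , drop = FALSE]
  if (is.null(metrics)) {
    num <- function(df) names(df)[vapply(df, is.numeric, logical(1))]
    metrics <- setdiff(intersect(num(a), num(r)), id_col)
  }
  out <- lapply(metrics, function(m) {
    x <- a[[m]]; y <- r[[m]]
    ok <- is.finite(x) & is.finite(y)
    x <- x[ok]; y <- y[ok]
    if (length(x) < 3L) return(NULL)
    corr <- if (sd(x) > 0 && sd(y) > 0) correlation(x, y, "pearson")
            else list(estimate = NA_real_, p.value = NA_real_)
    ba <- bland_altman(x, y)
    data.frame(metric = m, n = length(x),
               mean_auto = mean(x), sd_auto = sd(x),
               mean_ref = mean(y), sd_ref = sd(y),
               pearson_r = corr$estimate, pearson_p = corr$p.value,
               rms_error = rms_error(y, x),
               cv_auto_percent = if (mean(x) != 0) cv_percent(x) else NA_real_,
               cv_ref_percent = if (mean(y) != 0) cv_percent(y) else NA_real_,
               bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("method_validation", "data.frame")
  out
}
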