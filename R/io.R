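#' Read a phantom configuration from a YAML or JSON file
#'
#' Keys mirror the arguments of [phantom_config()]; unknown keys raise an
#' error. Organ geometry may be overridden under an `organs:` mapping with
#' per-organ `center`, `semi_axes`, `radius`, `z_range` entries.
#'
#' @param path File path (`.yaml`/`.yml` or `.json`).
#' @return A [phantom_config()].
#' @export
read_phantom_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("package 'yaml' is required")
    yaml::read_yaml(path)
  } else if (ext == "json") {
    if (!requireNamespace("jsonlite", quietly = TRUE)) stop("package 'jsonlite' is required")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("read_phantom_config: expected a .yaml/.yml or .json file")
  }
  known <- c("grid_shape", "spacing_mm", "motion_amplitude_mm",
             "breathing_period_s", "n_phases", "reference_phase",
             "deformation_mode", "organs", "gtv_density", "jitter_mm", "seed")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  organs <- default_organs()
  if (!is.null(cfg$organs)) {
    for (nm in names(cfg$organs)) {
      if (!nm %in% names(organs)) stop("unknown organ: ", nm)
      for (f in names(cfg$organs[[nm]])) {
        organs[[nm]][[f]] <- unlist(cfg$organs[[nm]][[f]])
      }
    }
  }
  amp <- cfg$motion_amplitude_mm
  if (!is.null(amp)) amp <- unlist(amp)
  args <- list(
    organs = organs
  )
  for (k in setdiff(known, c("organs", "motion_amplitude_mm"))) {
    if (!is.null(cfg[[k]])) args[[k]] <- unlist(cfg[[k]])
  }
  if (!is.null(amp)) args$motion_amplitude_mm <- amp
  do.call(phantom_config, args)
}

#' Export a dose grid or phantom phase as a NIfTI volume
#'
#' Writes the array with correct voxel spacing so external viewers can
#' overlay dose and anatomy. Requires the suggested RNifti package.
#'
#' @param x A `dose_grid`, `rt_mask` or numeric array.
#' @param path Output file (`.nii` or `.nii.gz`).
#' @param grid Required for a bare array.
#' @return Invisibly, `path`.
#' @export
write_nifti_volume <- function(x, path, grid = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("package 'RNifti' is required for NIfTI export")
  }
  if (inherits(x, "dose_grid")) { arr <- x$values; grid <- x$grid }
  else if (inherits(x, "rt_mask")) { arr <- x$voxels + 0; grid <- x$grid }
  else { arr <- x; if (is.null(grid)) stop("grid required for a bare array") }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Export a 4-D phantom as per-phase NIfTI volumes with a JSON sidecar
#'
#' Writes one density volume per breathing phase
#' (`<prefix>_phase<k>.nii.gz`) and `<prefix>_motion.json` containing the
#' centre-of-volume trajectory, the measured per-axis amplitudes and the
#' reference phase.
#'
#' @param phantom A `four_d_phantom`.
#' @param prefix Output path prefix.
#' @return Invisibly, the sidecar path.
#' @export
export_phantom_nifti <- function(phantom, prefix) {
  if (!requireNamespace("jsonlite", quietly = TRUE)) {
    stop("package 'jsonlite' is required")
  }
  grid <- phantom$phases[[1]]$grid
  for (k in seq_along(phantom$phases)) {
    write_nifti_volume(phantom$phases[[k]]$density,
                       sprintf("%s_phase%02d.nii.gz", prefix, k), grid = grid)
  }
  amp <- motion_amplitudes(phantom$cov_trajectory)
  sidecar <- paste0(prefix, "_motion.json")
  jsonlite::write_json(
    list(
      reference_phase = phantom$reference_phase,
      breathing_trace = as.numeric(phantom$trace),
      cov_trajectory_mm = unname(as.data.frame(phantom$cov_trajectory)),
      amplitudes_mm = list(ap = amp$ap_mm, si = amp$si_mm, lr = amp$lr_mm,
                           motion3d = amp$motion3d_mm),
      spacing_mm = grid$spacing
    ),
    sidecar, auto_unbox = TRUE, digits = NA
  )
  invisible(sidecar)
}

#' Export a metrics table to CSV and JSON
#'
#' @param metrics Tibble (e.g. from [summarize_metrics()] or
#'   [summarize_virtual_cohort()]).
#' @param csv_path,json_path Output paths; either may be `NULL` to skip.
#' @return Invisibly, the metrics table.
#' @export
export_metrics <- function(metrics, csv_path = NULL, json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(metrics, csv_path, row.names = FALSE)
  if (!is.null(json_path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE)) {
      stop("package 'jsonlite' is required for JSON export")
    }
    jsonlite::write_json(metrics, json_path, digits = NA, auto_unbox = TRUE)
  }
  invisible(metrics)
}
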