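# NIfTI volume/mask I/O with JSON metadata sidecars, YAML study
# configuration, and study-report export (CSV tables + JSON summary).

#' Write a volume as NIfTI with a JSON sidecar
#'
#' @param vol an [image_volume()] or [binary_mask()] (masks are written as
#'   uint8).
#' @param path output `.nii`/`.nii.gz` path.
#' @param meta optional [patient_meta()] echoed into the sidecar.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, meta = NULL) {
  is_mask <- inherits(vol, "binary_mask")
  values <- if (is_mask) array(as.integer(vol$values), dim(vol$values))
            else vol$values
  attr(values, "pixdim") <- vol$spacing
  img <- RNifti::asNifti(values, datatype = if (is_mask) "uint8" else "double")
  RNifti::writeNifti(img, path)
  side <- list(semantic = if (is_mask) "MASK" else vol$semantic,
               spacing_mm = vol$spacing, origin_mm = vol$origin)
  if (!is.null(meta)) side$patient_meta <- unclass(meta)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  sub("\\.nii(\\.gz)?$", ".json", path)
}

#' Read a volume written by [write_volume()]
#'
#' The value semantic must be available, either from the JSON sidecar or via
#' the `semantic` argument; 4-D files are rejected.
#'
#' @param path NIfTI path.
#' @param semantic override/supply the value semantic.
#' @return an [image_volume()] or, for sidecar semantic `"MASK"`, a
#'   [binary_mask()].
#' @export
read_volume <- function(path, semantic = NULL) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) > 3) abort("4-D (or higher) volumes are not supported.")
  side <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) side <- jsonlite::read_json(sp, simplifyVector = TRUE)
  semantic <- semantic %||% side$semantic
  if (is.null(semantic)) {
    abort("no value semantic: supply `semantic` or provide the JSON sidecar.")
  }
  spacing <- side$spacing_mm %||% RNifti::pixdim(img)[seq_along(d)]
  origin <- side$origin_mm %||% rep(0, 3)
  vals <- array(as.vector(img), d)
  if (identical(semantic, "MASK")) {
    binary_mask(vals != 0, spacing, origin)
  } else {
    image_volume(vals, spacing, origin, semantic)
  }
}

#' Read a study configuration from YAML
#'
#' Scalar fields override the [study_config()] defaults; hardware models can
#' be given as a list of `kind`/`thickness_mm`/`mu`/`arc_radius_mm` entries.
#'
#' @param path YAML file.
#' @return a [study_config()].
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$hardware)) {
    raw$hardware <- lapply(raw$hardware, function(h) do.call(hardware_model, h))
  }
  known <- names(formals(study_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    abort(paste0("unknown config fields: ", paste(unknown, collapse = ", ")))
  }
  do.call(study_config, raw)
}

#' Write the study report to a directory
#'
#' CSV tables (full double precision; one row per GTV per variant for the
#' metabolic table, one row per histogram bin) plus a JSON summary.
#'
#' @param report a `study_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$parameters, file.path(dir, "parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(report$similarity, file.path(dir, "similarity.csv"),
                   row.names = FALSE)
  utils::write.csv(report$contours, file.path(dir, "contours.csv"),
                   row.names = FALSE)
  utils::write.csv(report$metabolic, file.path(dir, "metabolic.csv"),
                   row.names = FALSE)
  utils::write.csv(report$histogram, file.path(dir, "histogram.csv"),
                   row.names = FALSE)
  utils::write.csv(report$whole_image, file.path(dir, "whole_image.csv"),
                   row.names = FALSE)
  if (nrow(report$prognosis)) {
    utils::write.csv(report$prognosis, file.path(dir, "prognosis.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(glance = glance(report),
         seed = report$config$seed,
         n_patients = report$n_patients),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    dataframe = "rows")
  invisible(dir)
}
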