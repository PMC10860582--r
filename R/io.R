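#' Write / read a CTP series as NIfTI-1 plus a frame-time sidecar
#'
#' The 4D HU array goes to a `.nii.gz`; frame times (s) and voxel spacing
#' (mm) go to a JSON sidecar next to it (`<path>.json`).
#'
#' @param series A `ctp_series`.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_ctp_nifti <- function(series, path) {
  stopifnot(inherits(series, "ctp_series"))
  img <- RNifti::asNifti(series$voxels)
  RNifti::pixdim(img) <- c(series$spacing,
                           series$frame_times[2] - series$frame_times[1])
  RNifti::writeNifti(img, path)
  jsonlite::write_json(list(frame_times_s = series$frame_times,
                            spacing_mm = series$spacing),
                       paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' @rdname write_ctp_nifti
#' @export
read_ctp_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(voxels = array(as.numeric(img), dim = dim(img)),
                 frame_times = side$frame_times_s,
                 spacing = side$spacing_mm, geometry = NULL, truth = NULL),
            class = "ctp_series")
}

#' Write / read a single-phase CTA volume as NIfTI-1
#'
#' @param cta A `cta_volume`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cta_nifti <- function(cta, path) {
  stopifnot(inherits(cta, "cta_volume"))
  img <- RNifti::asNifti(cta$voxels)
  RNifti::pixdim(img) <- cta$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_cta_nifti
#' @export
read_cta_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  structure(list(voxels = array(as.numeric(img), dim = dim(img)),
                 spacing = RNifti::pixdim(img)[1:3], geometry = NULL,
                 t_acq = NA_real_),
            class = "cta_volume")
}

#' Write / read time-attenuation curves as CSV
#'
#' Columns: `time_s`, `hu`, `label`.
#'
#' @param curve Curve tibble (one or several labels stacked).
#' @param path CSV path.
#' @return `path` invisibly / the curve tibble.
#' @export
write_curve_csv <- function(curve, path) {
  readr::write_csv(curve, path)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    time_s = readr::col_double(), hu = readr::col_double(),
    label = readr::col_character()))
}

#' Read a patient cohort table from CSV
#'
#' Expects the documented schema (one row per patient; volumes in mL, times
#' in minutes): `id`, `cnn_volume_mL`, `fiv_mL`, `core_mL`, `penumbra_mL`,
#' `hir`, `miteff`, `tici`, `lkw_to_cta_min`, `wake_up`, `sleep_time`,
#' `wake_time`.
#'
#' @param path CSV path.
#' @return A cohort tibble.
#' @export
read_cohort_csv <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(),
    cnn_volume_mL = readr::col_double(),
    fiv_mL = readr::col_double(),
    core_mL = readr::col_double(),
    penumbra_mL = readr::col_double(),
    hir = readr::col_double(),
    miteff = readr::col_integer(),
    tici = readr::col_character(),
    lkw_to_cta_min = readr::col_double(),
    wake_up = readr::col_logical(),
    sleep_time = readr::col_character(),
    wake_time = readr::col_character()))
}

#' @rdname read_cohort_csv
#' @param cohort Cohort tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  readr::write_csv(cohort, path)
  invisible(path)
}
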