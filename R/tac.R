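#' Region-of-interest specification
#'
#' An ROI is a non-empty 3D logical mask with a label identifying the vessel
#' it samples (`"arterial"` for the AIF, e.g. supraclinoid ICA/ACA;
#' `"venous"` for the VOF, e.g. superior sagittal sinus). A sphere
#' definition (centre + radius in mm) may be given instead of a mask.
#'
#' @param label `"arterial"` or `"venous"`.
#' @param mask 3D logical array, or `NULL` if a sphere is given.
#' @param dim,spacing,center_mm,radius_mm Sphere definition forwarded to
#'   [sphere_mask()] when `mask` is `NULL`.
#' @return A list of class `roi_spec`.
#' @export
roi_spec <- function(label = c("arterial", "venous"), mask = NULL,
                     dim = NULL, spacing = NULL, center_mm = NULL,
                     radius_mm = NULL) {
  label <- match.arg(label)
  if (is.null(mask)) mask <- sphere_mask(dim, spacing, center_mm, radius_mm)
  if (!is.logical(mask) || length(dim(mask)) != 3)
    stop("roi_spec: mask must be a 3D logical array", call. = FALSE)
  if (!any(mask)) stop("roi_spec: empty ROI", call. = FALSE)
  structure(list(label = label, mask = mask), class = "roi_spec")
}

roi_mask <- function(roi, dim) {
  m <- if (inherits(roi, "roi_spec")) roi$mask else roi
  if (!identical(dim(m), as.integer(dim)))
    stop("ROI mask dimensions do not match the image grid", call. = FALSE)
  m
}

#' Extract a time-attenuation curve from a CTP series
#'
#' The curve value at each frame is the mean HU over the ROI voxels.
#'
#' @param series A `ctp_series` (see [simulate_ctp_series()] or
#'   [read_ctp_nifti()]).
#' @param roi A [roi_spec()] or a 3D logical mask.
#' @param label Curve label; defaults to `"AIF"` for arterial and `"VOF"`
#'   for venous ROIs.
#' @return A tibble with columns `time_s`, `hu`, `label`.
#' @export
extract_roi_curve <- function(series, roi, label = NULL) {
  stopifnot(inherits(series, "ctp_series"))
  m <- roi_mask(roi, dim(series$voxels)[1:3])
  if (!any(m)) stop("extract_roi_curve: empty ROI", call. = FALSE)
  if (is.null(label))
    label <- if (inherits(roi, "roi_spec") && roi$label == "venous") "VOF" else "AIF"
  nt <- length(series$frame_times)
  vox <- matrix(series$voxels, ncol = nt)
  tibble::tibble(time_s = series$frame_times,
                 hu = colMeans(vox[as.vector(m), , drop = FALSE]),
                 label = label)
}

#' Whole-field-of-view mean attenuation curve
#'
#' Per-frame mean HU over all voxels (or a brain mask), a surrogate for
#' overall brain attenuation.
#'
#' @inheritParams extract_roi_curve
#' @param mask Optional 3D logical brain mask; default whole grid.
#' @return A tibble with columns `time_s`, `hu`, `label = "FOV_mean"`.
#' @export
fov_mean_curve <- function(series, mask = NULL) {
  stopifnot(inherits(series, "ctp_series"))
  nt <- length(series$frame_times)
  vox <- matrix(series$voxels, ncol = nt)
  if (!is.null(mask)) {
    m <- roi_mask(mask, dim(series$voxels)[1:3])
    vox <- vox[as.vector(m), , drop = FALSE]
  }
  tibble::tibble(time_s = series$frame_times, hu = colMeans(vox),
                 label = "FOV_mean")
}

#' Constant arterial and venous HU values from a single-phase CTA
#'
#' @param cta A `cta_volume`.
#' @param arterial,venous [roi_spec()] objects or 3D logical masks.
#' @return A named numeric vector `c(arterial = , venous = )` of mean HU.
#' @export
cta_roi_values <- function(cta, arterial, venous) {
  stopifnot(inherits(cta, "cta_volume"))
  ma <- roi_mask(arterial, dim(cta$voxels))
  mv <- roi_mask(venous, dim(cta$voxels))
  if (!any(ma) || !any(mv)) stop("cta_roi_values: empty ROI", call. = FALSE)
  c(arterial = mean(cta$voxels[ma]), venous = mean(cta$voxels[mv]))
}

# integer-voxel translate of a 3D array, vacated voxels filled with `fill`
shift_volume <- function(vol, shift, fill) {
  d <- dim(vol)
  out <- array(fill, dim = d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    s <- shift[a]
    if (abs(s) >= d[a]) return(out)
    if (s >= 0) { dst[[a]] <- (1 + s):d[a]; src[[a]] <- 1:(d[a] - s) }
    else        { dst[[a]] <- 1:(d[a] + s); src[[a]] <- (1 - s):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- vol[src[[1]], src[[2]], src[[3]]]
  out
}

#' Translate a CTP frame by a known integer-voxel shift
#'
#' Utility for injecting ground-truth motion into phantoms; vacated voxels
#' are filled with the frame's edge median.
#'
#' @param series A `ctp_series`.
#' @param frame Frame index (>= 2; frame 1 is the registration reference).
#' @param shift Integer voxel shift, length 3.
#' @return The modified `ctp_series`.
#' @export
inject_motion <- function(series, frame, shift) {
  stopifnot(inherits(series, "ctp_series"), frame >= 2)
  vol <- series$voxels[, , , frame]
  series$voxels[, , , frame] <- shift_volume(vol, as.integer(shift),
                                             stats::median(vol))
  series
}

#' Translation-only motion correction of a CTP series
#'
#' Registers every frame to frame 1 by the integer-voxel translation that
#' maximises the normalised cross-correlation over the overlapping region,
#' searched exhaustively within `search_radius` voxels per axis.
#'
#' @param series A `ctp_series`.
#' @param search_radius Maximum |shift| searched per axis (voxels).
#' @return The corrected `ctp_series`, with a `shifts` tibble attached
#'   (`frame`, `dx`, `dy`, `dz` in voxels, `mm_x/mm_y/mm_z`, `degenerate`
#'   flag for constant frames).
#' @export
motion_correct <- function(series, search_radius = 3L) {
  stopifnot(inherits(series, "ctp_series"))
  nt <- length(series$frame_times)
  if (nt < 2) stop("motion_correct: need at least 2 frames", call. = FALSE)
  ref <- series$voxels[, , , 1]
  rng <- -search_radius:search_radius
  grid <- expand.grid(dx = rng, dy = rng, dz = rng)
  log <- vector("list", nt)
  log[[1]] <- c(0L, 0L, 0L, FALSE)
  ref_v <- as.vector(ref)
  for (k in 2:nt) {
    mov <- series$voxels[, , , k]
    if (stats::sd(mov) == 0 || stats::sd(ref) == 0) {
      log[[k]] <- c(0L, 0L, 0L, TRUE)
      next
    }
    fill <- stats::median(mov)
    best <- c(0L, 0L, 0L); best_ncc <- -Inf
    for (g in seq_len(nrow(grid))) {
      s <- c(grid$dx[g], grid$dy[g], grid$dz[g])
      # correlate the candidate-shifted frame with the reference over the
      # full grid (vacated voxels take the frame median), so differing
      # overlap sizes cannot bias the score
      cand <- shift_volume(mov, s, fill)
      sb <- stats::sd(cand)
      ncc <- if (sb == 0) -Inf else stats::cor(ref_v, as.vector(cand))
      if (ncc > best_ncc + 1e-12) { best_ncc <- ncc; best <- s }
    }
    series$voxels[, , , k] <- shift_volume(mov, best, fill)
    log[[k]] <- c(best, FALSE)
  }
  sh <- do.call(rbind, log)
  series$shifts <- tibble::tibble(
    frame = seq_len(nt),
    dx = as.integer(sh[, 1]), dy = as.integer(sh[, 2]), dz = as.integer(sh[, 3]),
    mm_x = sh[, 1] * series$spacing[1],
    mm_y = sh[, 2] * series$spacing[2],
    mm_z = sh[, 3] * series$spacing[3],
    degenerate = as.logical(sh[, 4])
  )
  series
}
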