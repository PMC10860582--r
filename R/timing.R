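#' Resample a time-attenuation curve onto a new time grid
#'
#' Linear interpolation; times outside the curve's support take the nearest
#' endpoint value.
#'
#' @param curve Tibble with `time_s`, `hu`, `label`.
#' @param times Target time grid (s), strictly increasing.
#' @return A tibble on the new grid.
#' @export
resample_curve <- function(curve, times) {
  stopifnot(all(diff(times) > 0))
  tibble::tibble(time_s = times,
                 hu = stats::approx(curve$time_s, curve$hu, xout = times,
                                    rule = 2)$y,
                 label = curve$label[1])
}

#' AIF minus VOF difference curve
#'
#' Subtracts the venous from the arterial time-attenuation curve pointwise.
#' The curves must share a time grid; use [resample_curve()] first if not.
#'
#' @param aif,vof Tibbles with `time_s`, `hu`.
#' @return A tibble with `time_s`, `hu` (AIF - VOF), `label = "AIF_minus_VOF"`.
#' @export
difference_curve <- function(aif, vof) {
  if (nrow(aif) != nrow(vof) || any(abs(aif$time_s - vof$time_s) > 1e-9))
    stop("difference_curve: curves are on different time grids; resample first",
         call. = FALSE)
  tibble::tibble(time_s = aif$time_s, hu = aif$hu - vof$hu,
                 label = "AIF_minus_VOF")
}

#' Level crossings of a piecewise-linear curve
#'
#' Finds every time at which the piecewise-linear interpolant of the curve
#' crosses the constant `level`. Crossings are solved exactly within each
#' bracketing segment; samples exactly equal to the level count once, at the
#' sample time.
#'
#' @param curve Tibble with `time_s`, `hu` (>= 2 rows, times increasing).
#' @param level The constant level (HU).
#' @return Sorted numeric vector of crossing times (s); empty (with
#'   attribute `out_of_range = TRUE`) when the level lies outside the
#'   curve's range.
#' @export
find_intersections <- function(curve, level) {
  t <- curve$time_s; v <- curve$hu
  stopifnot(length(t) >= 2, all(diff(t) > 0))
  if (level > max(v) || level < min(v)) {
    out <- numeric(0)
    attr(out, "out_of_range") <- TRUE
    return(out)
  }
  d <- v - level
  hits <- t[d == 0]
  i <- which(d[-length(d)] * d[-1] < 0)
  cross <- t[i] + (t[i + 1] - t[i]) * (-d[i]) / (d[i + 1] - d[i])
  sort(unique(c(hits, cross)))
}

# landmark times from sampled AIF/VOF curves:
#  t_peak_aif / t_peak_vof  argmax of the sampled curve
#  t_half_aif               first crossing of baseline + half peak enhancement
curve_landmarks <- function(aif, vof) {
  ia <- which.max(aif$hu); iv <- which.max(vof$hu)
  base <- min(aif$hu)
  half_level <- base + 0.5 * (max(aif$hu) - base)
  up <- find_intersections(aif, half_level)
  t_half <- if (length(up)) up[1] else aif$time_s[1]
  list(t_peak_aif = aif$time_s[ia], t_peak_vof = vof$time_s[iv],
       t_half_aif = t_half)
}

#' Assign a bolus phase to an acquisition time
#'
#' Classifies a time on the CTP bolus axis into one of four phases using
#' landmark times derived from the AIF and VOF curves: with `tA` the AIF
#' peak time, `tV` the VOF peak time, and `t50` the first time the AIF
#' exceeds half its peak enhancement, the phase is `early_arterial` on
#' `[t50, tA)`, `mid_arterial` on `[tA, (tA+tV)/2)`, `mid_to_venous` on
#' `[(tA+tV)/2, tV)`, and `delayed_venous` from `tV` on. Times before `t50`
#' are `early_arterial` with a `pre_bolus` flag.
#'
#' @param t_est Acquisition time (s).
#' @param aif,vof Time-attenuation curve tibbles.
#' @return A list with `phase` (factor over the four ordered levels) and
#'   `flags` (character vector).
#' @export
classify_phase <- function(t_est, aif, vof) {
  lm <- curve_landmarks(aif, vof)
  if (lm$t_peak_vof <= lm$t_peak_aif)
    stop("classify_phase: VOF peak does not follow AIF peak", call. = FALSE)
  mid <- (lm$t_peak_aif + lm$t_peak_vof) / 2
  flags <- character(0)
  if (t_est < lm$t_half_aif) {
    phase <- "early_arterial"; flags <- "pre_bolus"
  } else if (t_est < lm$t_peak_aif) phase <- "early_arterial"
  else if (t_est < mid) phase <- "mid_arterial"
  else if (t_est < lm$t_peak_vof) phase <- "mid_to_venous"
  else phase <- "delayed_venous"
  list(phase = factor(phase, levels = c("early_arterial", "mid_arterial",
                                        "mid_to_venous", "delayed_venous"),
                      ordered = TRUE),
       flags = flags, landmarks = lm)
}

#' Estimate the CTA acquisition time on the CTP bolus axis
#'
#' The central timing procedure: the constant CTA arterial-minus-venous HU
#' difference is intersected with the dynamic AIF-minus-VOF difference curve
#' from the CTP study. Each intersection is a candidate acquisition time;
#' when several exist (the difference curve is non-monotone), the candidate
#' minimising the joint absolute mismatch
#' `|AIF(t) - cta_arterial| + |VOF(t) - cta_venous|` is selected. When no
#' intersection exists (the level lies outside the curve's range), the time
#' minimising `|difference(t) - level|` is returned with a
#' `no_intersection` flag.
#'
#' Before venous contrast arrival the VOF is flat, so the two crossings
#' flanking the AIF peak carry identical arterial and venous values and the
#' two-value mismatch cannot separate them. Supplying the whole-field-of-view
#' mean curve (`fov`, from [fov_mean_curve()]) and its constant CTA value
#' (`cta_values["fov"]`) adds a `|FOV(t) - cta_fov|` term that breaks the
#' tie, because overall brain attenuation keeps evolving through the
#' arterial peak.
#'
#' @param aif,vof CTP time-attenuation curves (tibbles with `time_s`, `hu`)
#'   on a common grid.
#' @param cta_values Named vector `c(arterial = , venous = )` of constant
#'   CTA HU values, as from [cta_roi_values()]; an optional `fov` element is
#'   the whole-volume mean HU of the CTA.
#' @param fov Optional FOV-mean curve from the CTP study, used in candidate
#'   disambiguation when `cta_values["fov"]` is present.
#' @return A list of class `phase_estimate`: `t_est` (s), `candidates` (s),
#'   `phase` (ordered factor), `landmarks`, `level` (HU), `flags`.
#' @export
#' @examples
#' bp <- bolus_params(noise_sd = 0)
#' geo <- phantom_geometry()
#' ser <- simulate_ctp_series(bp, geo)
#' aif <- extract_roi_curve(ser, roi_spec("arterial", geo$arterial))
#' vof <- extract_roi_curve(ser, roi_spec("venous", geo$venous))
#' cta <- simulate_cta_snapshot(bp, geo, t_acq = 16)
#' vals <- cta_roi_values(cta, geo$arterial, geo$venous)
#' estimate_timing(aif, vof, vals)$t_est
estimate_timing <- function(aif, vof, cta_values, fov = NULL) {
  stopifnot(all(c("arterial", "venous") %in% names(cta_values)))
  dc <- difference_curve(aif, vof)
  if (max(dc$hu) - min(dc$hu) < .Machine$double.eps^0.5)
    stop("estimate_timing: flat difference curve carries no timing information",
         call. = FALSE)
  level <- unname(cta_values["arterial"] - cta_values["venous"])
  cand <- find_intersections(dc, level)
  flags <- character(0)
  if (length(cand) == 0) {
    flags <- "no_intersection"
    t_est <- dc$time_s[which.min(abs(dc$hu - level))]
  } else if (length(cand) == 1) {
    t_est <- cand
  } else {
    a_at <- stats::approx(aif$time_s, aif$hu, xout = cand)$y
    v_at <- stats::approx(vof$time_s, vof$hu, xout = cand)$y
    mism <- abs(a_at - cta_values["arterial"]) + abs(v_at - cta_values["venous"])
    if (!is.null(fov) && "fov" %in% names(cta_values)) {
      f_at <- stats::approx(fov$time_s, fov$hu, xout = cand)$y
      mism <- mism + abs(f_at - cta_values["fov"])
    }
    t_est <- cand[which.min(mism)]
    flags <- "multiple_intersections"
  }
  cls <- classify_phase(t_est, aif, vof)
  structure(list(t_est = t_est, candidates = cand, phase = cls$phase,
                 landmarks = cls$landmarks, level = level,
                 flags = c(flags, cls$flags)),
            class = "phase_estimate")
}

#' @export
print.phase_estimate <- function(x, ...) {
  cat(sprintf("CTA acquisition-time estimate: %.2f s (%s)\n",
              x$t_est, as.character(x$phase)))
  cat(sprintf("  candidates: %s\n",
              paste(sprintf("%.2f", x$candidates), collapse = ", ")))
  cat(sprintf("  AIF peak %.2f s, VOF peak %.2f s, AIF half-rise %.2f s\n",
              x$landmarks$t_peak_aif, x$landmarks$t_peak_vof,
              x$landmarks$t_half_aif))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
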