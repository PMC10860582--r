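#' Contrast-bolus parameter set
#'
#' Bundles the parameters of the gamma-variate first-pass bolus model used by
#' all phantom generators. The arterial input function (AIF) is a
#' gamma-variate enhancement on top of a constant pre-contrast baseline; the
#' venous output function (VOF) is the same curve delayed by `venous_delay`
#' and broadened by a Gaussian kernel (area preserved).
#'
#' @param t0 Bolus arrival time (s).
#' @param alpha Gamma-variate shape (dimensionless, > 0).
#' @param beta Gamma-variate scale (s, > 0). The AIF peaks at
#'   `t0 + alpha * beta`.
#' @param amplitude Peak arterial enhancement above baseline (HU, > 0).
#' @param baseline Pre-contrast attenuation (HU).
#' @param venous_delay AIF-to-VOF lag (s, >= 0).
#' @param venous_dispersion Broadening factor for the VOF (>= 1). 1 means no
#'   broadening; larger values widen the venous curve while preserving its
#'   area.
#' @param noise_sd Additive Gaussian voxel noise (HU, >= 0).
#' @param frame_interval CTP sampling period (s, > 0).
#' @param n_frames Number of CTP timesteps (>= 2).
#' @param seed RNG seed used by the simulators.
#'
#' @return A list of class `bolus_params`.
#' @export
#' @examples
#' bp <- bolus_params()
#' gamma_variate(bp$t0 + bp$alpha * bp$beta, bp) # equals the amplitude
bolus_params <- function(t0 = 10, alpha = 3, beta = 1.5, amplitude = 200,
                         baseline = 40, venous_delay = 10,
                         venous_dispersion = 1.6, noise_sd = 0,
                         frame_interval = 2, n_frames = 40, seed = 1L) {
  p <- list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
            baseline = baseline, venous_delay = venous_delay,
            venous_dispersion = venous_dispersion, noise_sd = noise_sd,
            frame_interval = frame_interval, n_frames = as.integer(n_frames),
            seed = as.integer(seed))
  num <- vapply(p[setdiff(names(p), "seed")], is.numeric, logical(1))
  if (!all(num) || !all(vapply(p, function(x) all(is.finite(x)), logical(1))))
    stop("bolus_params: all parameters must be finite numbers", call. = FALSE)
  stopifnot(p$alpha > 0, p$beta > 0, p$amplitude > 0, p$venous_delay >= 0,
            p$venous_dispersion >= 1, p$noise_sd >= 0,
            p$frame_interval > 0, p$n_frames >= 2)
  structure(p, class = "bolus_params")
}

#' Gamma-variate bolus enhancement
#'
#' Evaluates the canonical first-pass gamma-variate curve, normalised so the
#' peak equals `amplitude` at `t = t0 + alpha * beta`. Returns 0 for
#' `t <= t0` (pre-bolus).
#'
#' @param t Time(s) in seconds; vectorised.
#' @param params A [bolus_params()] object.
#' @return Enhancement above baseline in HU, same length as `t`.
#' @export
gamma_variate <- function(t, params) {
  stopifnot(inherits(params, "bolus_params"))
  if (!all(is.finite(t))) stop("gamma_variate: t must be finite", call. = FALSE)
  dt <- t - params$t0
  out <- numeric(length(t))
  pos <- dt > 0
  x <- dt[pos] / (params$alpha * params$beta)
  out[pos] <- params$amplitude * x^params$alpha *
    exp(params$alpha - dt[pos] / params$beta)
  out
}

# VOF enhancement: AIF delayed by venous_delay and convolved with a
# normalised Gaussian kernel of sd (venous_dispersion - 1) * beta seconds.
# Evaluated on a fine internal grid (dt = 0.05 s) so the kernel integrates
# to 1 and the bolus area is preserved; dispersion 1 short-circuits to the
# exact delayed curve.
vof_curve <- function(t, params) {
  sd_s <- (params$venous_dispersion - 1) * params$beta
  if (sd_s <= 0) return(gamma_variate(t - params$venous_delay, params))
  fine_dt <- 0.05
  half <- ceiling(4 * sd_s / fine_dt)
  lo <- min(t, params$t0) - half * fine_dt - params$venous_delay
  hi <- max(t) + half * fine_dt
  grid <- seq(lo, hi, by = fine_dt)
  aif <- gamma_variate(grid - params$venous_delay, params)
  kern <- stats::dnorm(seq(-half, half) * fine_dt, sd = sd_s)
  kern <- kern / sum(kern)
  sm <- stats::filter(aif, kern, sides = 2)
  keep <- !is.na(sm)
  stats::approx(grid[keep], as.numeric(sm[keep]), xout = t, rule = 2)$y
}

# Low-amplitude tissue curve used for background voxels and as the FOV-mean
# driver: a scaled, slightly delayed copy of the AIF.
tissue_curve <- function(t, params, scale = 0.08, delay = 2) {
  scale * gamma_variate(t - delay, params)
}

# Ground-truth noiseless curves (baseline included) on the CTP frame grid.
ground_truth_curves <- function(params) {
  times <- (seq_len(params$n_frames) - 1) * params$frame_interval
  tibble::tibble(
    time_s = rep(times, 3),
    hu = c(params$baseline + gamma_variate(times, params),
           params$baseline + vof_curve(times, params),
           params$baseline + tissue_curve(times, params)),
    label = rep(c("AIF", "VOF", "tissue"), each = length(times))
  )
}

#' Test-bolus acquisition-delay preset
#'
#' Emulates a stroke CTA protocol that starts the scan a fixed delay after
#' the test-bolus time-to-peak measured in the ascending aorta. The aorta
#' peak leads the intracranial AIF peak by `aorta_lead_s`, so the CTA
#' acquisition time on the CTP axis is
#' `t0 + alpha * beta - aorta_lead_s + delay_s`.
#'
#' @param params A [bolus_params()] object.
#' @param delay_s Scan delay after the aortic test-bolus peak (s); default 12.
#' @param aorta_lead_s Lead of the aortic peak over the intracranial AIF peak
#'   (s); default 8.
#' @return Acquisition time (s) on the CTP time axis.
#' @export
test_bolus_acquisition_time <- function(params, delay_s = 12, aorta_lead_s = 8) {
  params$t0 + params$alpha * params$beta - aorta_lead_s + delay_s
}
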