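#' Simulate a dynamic CT-perfusion series
#'
#' Fills a phantom grid with first-pass bolus dynamics: arterial ROI voxels
#' follow `baseline + AIF`, venous ROI voxels the delayed/broadened VOF, and
#' background voxels a low-amplitude tissue curve. Gaussian noise of
#' `noise_sd` HU is added independently per voxel and frame, seeded.
#'
#' @param bolus A [bolus_params()] object.
#' @param geometry A [phantom_geometry()] object.
#' @param anatomy_hu Amplitude (HU) of a static, smoothly varying background
#'   anatomy pattern added to every frame. It is zero inside the arterial
#'   and venous ROIs, so extracted vessel curves are unaffected; non-zero
#'   values give registration something time-invariant to lock onto.
#'   Default 0 (pure contrast phantom).
#' @return A list of class `ctp_series` with `voxels` (4D HU array,
#'   x-y-z-time), `frame_times` (s), `spacing` (mm), `geometry`, and `truth`
#'   (the noiseless ground-truth curves as a tibble).
#' @export
#' @examples
#' ser <- simulate_ctp_series(bolus_params(noise_sd = 0), phantom_geometry())
#' dim(ser$voxels)
simulate_ctp_series <- function(bolus, geometry = phantom_geometry(),
                                anatomy_hu = 0) {
  stopifnot(inherits(bolus, "bolus_params"),
            inherits(geometry, "phantom_geometry"))
  times <- (seq_len(bolus$n_frames) - 1) * bolus$frame_interval
  aif <- bolus$baseline + gamma_variate(times, bolus)
  vof <- bolus$baseline + vof_curve(times, bolus)
  tis <- bolus$baseline + tissue_curve(times, bolus)
  nvox <- prod(geometry$dim)
  vox <- array(0, dim = c(geometry$dim, bolus$n_frames))
  art <- which(geometry$arterial)
  ven <- which(geometry$venous)
  anat <- rep(0, nvox)
  if (anatomy_hu > 0) {
    d <- geometry$dim
    ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
    anat <- as.vector(outer(outer(sin(1.1 * ix), cos(0.9 * iy), `+`),
                            sin(0.7 * iz), `+`)) * anatomy_hu
    anat[c(art, ven)] <- 0
  }
  for (k in seq_along(times)) {
    frame <- rep(tis[k], nvox) + anat
    frame[art] <- aif[k]
    frame[ven] <- vof[k]
    vox[, , , k] <- frame
  }
  if (bolus$noise_sd > 0) {
    set.seed(bolus$seed)
    vox <- vox + stats::rnorm(length(vox), sd = bolus$noise_sd)
  }
  structure(list(voxels = vox, frame_times = times,
                 spacing = geometry$spacing, geometry = geometry,
                 truth = ground_truth_curves(bolus)),
            class = "ctp_series")
}

#' Simulate a single-phase CTA snapshot
#'
#' Freezes the same bolus dynamics at one acquisition time `t_acq`:
#' arterial, venous and background voxels take the values of their dynamic
#' curves at `t_acq`, plus seeded noise. The single time point is what makes
#' CTA-based core estimation phase-dependent.
#'
#' @inheritParams simulate_ctp_series
#' @param t_acq Acquisition time (s) within the simulated window.
#' @return A list of class `cta_volume` with `voxels` (3D HU array),
#'   `spacing`, `geometry`, and `t_acq` (ground truth, for recovery tests).
#' @export
simulate_cta_snapshot <- function(bolus, geometry = phantom_geometry(), t_acq) {
  stopifnot(inherits(bolus, "bolus_params"),
            inherits(geometry, "phantom_geometry"))
  t_max <- (bolus$n_frames - 1) * bolus$frame_interval
  if (t_acq < 0 || t_acq > t_max)
    stop("simulate_cta_snapshot: t_acq outside the simulated window",
         call. = FALSE)
  vox <- array(bolus$baseline + tissue_curve(t_acq, bolus),
               dim = geometry$dim)
  vox[geometry$arterial] <- bolus$baseline + gamma_variate(t_acq, bolus)
  vox[geometry$venous] <- bolus$baseline + vof_curve(t_acq, bolus)
  if (bolus$noise_sd > 0) {
    set.seed(bolus$seed)
    vox <- vox + stats::rnorm(length(vox), sd = bolus$noise_sd)
  }
  structure(list(voxels = vox, spacing = geometry$spacing,
                 geometry = geometry, t_acq = t_acq),
            class = "cta_volume")
}

#' Simulate perfusion parameter maps with known core, penumbra and HIR
#'
#' Builds a relative-CBF ratio map and a Tmax map whose thresholded volumes
#' match the request: `rCBF < 0.3` marks the requested core volume,
#' `Tmax > 6` s the requested penumbra volume, and the fraction of penumbra
#' voxels with `Tmax > 10` s matches `hir_target`. Lesions grow as compact
#' regions from the grid centre, so thresholded volumes are exact to the
#' voxel.
#'
#' @param core_volume_mL Requested core volume (mL); must not exceed
#'   `penumbra_volume_mL`.
#' @param penumbra_volume_mL Requested penumbra (Tmax > 6 s) volume (mL).
#' @param hir_target Requested hypoperfusion intensity ratio in \[0, 1\].
#' @param dim,spacing Grid dimensions and voxel spacing (mm).
#' @return A list of class `perfusion_maps` with `rcbf_ratio`, `tmax`
#'   (3D arrays) and `spacing`.
#' @export
simulate_perfusion_maps <- function(core_volume_mL, penumbra_volume_mL,
                                    hir_target,
                                    dim = c(64L, 64L, 32L),
                                    spacing = c(1, 1, 1)) {
  stopifnot(core_volume_mL >= 0, penumbra_volume_mL >= core_volume_mL,
            hir_target >= 0, hir_target <= 1, all(spacing > 0))
  voxvol <- prod(spacing) / 1000  # mL per voxel
  n_pen <- round(penumbra_volume_mL / voxvol)
  n_core <- round(core_volume_mL / voxvol)
  if (n_pen > prod(dim))
    stop("simulate_perfusion_maps: requested volume exceeds grid capacity",
         call. = FALSE)
  n_hir <- round(hir_target * n_pen)
  cx <- (seq_len(dim[1]) - 1) * spacing[1]
  cy <- (seq_len(dim[2]) - 1) * spacing[2]
  cz <- (seq_len(dim[3]) - 1) * spacing[3]
  ctr <- c(mean(range(cx)), mean(range(cy)), mean(range(cz)))
  d2 <- outer(outer((cx - ctr[1])^2, (cy - ctr[2])^2, `+`), (cz - ctr[3])^2, `+`)
  ord <- order(d2)
  rcbf <- array(1, dim = dim)
  tmax <- array(0, dim = dim)
  if (n_pen > 0) tmax[ord[seq_len(n_pen)]] <- 8
  if (n_hir > 0) tmax[ord[seq_len(n_hir)]] <- 12
  if (n_core > 0) rcbf[ord[seq_len(n_core)]] <- 0.2
  structure(list(rcbf_ratio = rcbf, tmax = tmax, spacing = as.numeric(spacing)),
            class = "perfusion_maps")
}

#' Cohort simulation parameters
#'
#' @param n_patients Cohort size (>= 1).
#' @param lambda_penumbra Fraction of the core-penumbra mismatch included in
#'   the CTA-based estimate, in \[0, 1\]. 0 means the estimate equals the
#'   core; 1 means it equals the penumbra.
#' @param estimate_noise_sd Gaussian noise on the estimate (mL).
#' @param collateral_effect Multiplier (> 0) linking collateral status (HIR
#'   and Miteff grade) to penumbra-to-infarct conversion; values > 1 make
#'   poor collaterals convert more penumbra into final infarct.
#' @param reperfusion_rate Probability of successful recanalisation
#'   (TICI 2b/2c/3).
#' @param seed RNG seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 121, lambda_penumbra = 0.5,
                          estimate_noise_sd = 10, collateral_effect = 2,
                          reperfusion_rate = 0.8, seed = 1L) {
  stopifnot(n_patients >= 1, lambda_penumbra >= 0, lambda_penumbra <= 1,
            reperfusion_rate >= 0, reperfusion_rate <= 1,
            estimate_noise_sd >= 0, collateral_effect > 0)
  structure(list(n_patients = as.integer(n_patients),
                 lambda_penumbra = lambda_penumbra,
                 estimate_noise_sd = estimate_noise_sd,
                 collateral_effect = collateral_effect,
                 reperfusion_rate = reperfusion_rate, seed = as.integer(seed)),
            class = "cohort_params")
}

# clock helper: minutes-past-midnight -> "HH:MM"
minutes_to_clock <- function(m) {
  m <- ((m %% 1440) + 1440) %% 1440
  sprintf("%02d:%02d", floor(m / 60), round(m %% 60))
}

#' Simulate a patient cohort
#'
#' Draws a per-patient table in which the CTA-based volume estimate lies
#' between the perfusion core and penumbra volumes
#' (`estimate = core + lambda * (penumbra - core) + noise`, floored at 0),
#' and the final infarct volume (FIV) is the core plus a collateral- and
#' reperfusion-dependent fraction of the mismatch. HIR is drawn from a Beta
#' distribution; the Miteff grade is a noisy discretisation of HIR (the two
#' are correlated surrogates of the same collateral status); TICI success is
#' Bernoulli with `reperfusion_rate`; last-known-well-to-CTA times mix an
#' early (< 6 h) and a late (6-24 h) window with a small unknown fraction,
#' and wake-up strokes carry sleep/wake clock times whose midpoint defines
#' the presumed LKW.
#'
#' @param params A [cohort_params()] object.
#' @return A tibble with one row per patient: `id`, `cnn_volume_mL`,
#'   `fiv_mL`, `core_mL`, `penumbra_mL`, `hir`, `miteff`, `tici`,
#'   `lkw_to_cta_min`, `wake_up`, `sleep_time`, `wake_time`.
#' @export
#' @examples
#' simulate_cohort(cohort_params(n_patients = 10))
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  penumbra <- stats::rlnorm(n, meanlog = log(80), sdlog = 0.6)
  core <- penumbra * stats::runif(n, 0.1, 0.8)
  hir <- stats::rbeta(n, 2, 3)
  # Miteff from HIR with misclassification noise: good collaterals (low HIR)
  # tend to grade 3, poor (high HIR) to grade 1.
  miteff <- ifelse(hir < 0.3, 3L, ifelse(hir < 0.55, 2L, 1L))
  flip <- stats::runif(n) < 0.15
  miteff[flip] <- pmin(3L, pmax(1L, miteff[flip] +
                                  sample(c(-1L, 1L), sum(flip), replace = TRUE)))
  success <- stats::runif(n) < params$reperfusion_rate
  tici <- ifelse(success,
                 sample(c("2b", "2c", "3"), n, replace = TRUE),
                 sample(c("0", "1", "2a"), n, replace = TRUE))
  # penumbra-to-infarct conversion: base growth halved by reperfusion,
  # scaled by collateral_effect^w with w increasing in HIR and decreasing
  # in Miteff grade.
  w <- ((hir - 0.5) * 2 + (2 - miteff)) / 2
  g <- pmin(1, pmax(0, ifelse(success, 0.25, 0.6) * params$collateral_effect^w))
  fiv <- core + g * (penumbra - core)
  cnn <- core + params$lambda_penumbra * (penumbra - core)
  if (params$estimate_noise_sd > 0)
    cnn <- cnn + stats::rnorm(n, sd = params$estimate_noise_sd)
  cnn <- pmax(0, cnn)
  window <- sample(c("early", "late", "unknown"), n, replace = TRUE,
                   prob = c(0.65, 0.325, 0.025))
  lkw <- ifelse(window == "early", stats::runif(n, 60, 359),
                ifelse(window == "late", stats::runif(n, 360, 1440), NA_real_))
  wake_up <- window == "late" & stats::runif(n) < 0.4
  sleep_min <- stats::runif(n, 21.5 * 60, 24.5 * 60)   # 21:30 - 00:30
  wake_min <- stats::runif(n, 5.5 * 60, 8 * 60)        # 05:30 - 08:00
  tibble::tibble(
    id = sprintf("P%03d", seq_len(n)),
    cnn_volume_mL = cnn,
    fiv_mL = fiv,
    core_mL = core,
    penumbra_mL = penumbra,
    hir = hir,
    miteff = miteff,
    tici = tici,
    lkw_to_cta_min = round(lkw),
    wake_up = wake_up,
    sleep_time = ifelse(wake_up, minutes_to_clock(sleep_min), NA_character_),
    wake_time = ifelse(wake_up, minutes_to_clock(wake_min), NA_character_)
  )
}
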