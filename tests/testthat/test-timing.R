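test_that("difference curve subtracts pointwise and demands a common grid", {
  t <- seq(0, 10, by = 1)
  a <- tibble::tibble(time_s = t, hu = sin(t) + 50, label = "AIF")
  v <- tibble::tibble(time_s = t, hu = sin(t), label = "VOF")
  d <- difference_curve(a, v)
  expect_equal(d$hu, rep(50, length(t)))
  expect_equal(difference_curve(a, a)$hu, rep(0, length(t)))
  v2 <- tibble::tibble(time_s = t + 0.5, hu = sin(t), label = "VOF")
  expect_error(difference_curve(a, v2), "grid")
  expect_equal(difference_curve(a, resample_curve(v2, t))$hu,
               a$hu - approx(v2$time_s, v2$hu, xout = t, rule = 2)$y)
})

test_that("level crossings are solved exactly within bracketing segments", {
  cur <- tibble::tibble(time_s = c(0, 1), hu = c(-10, 10))
  expect_equal(find_intersections(cur, 0), 0.5)
  rising <- tibble::tibble(time_s = 0:3, hu = c(0, 1, 2, 3))
  out <- find_intersections(rising, 10)
  expect_length(out, 0)
  expect_true(isTRUE(attr(out, "out_of_range")))
  # sample exactly on the level counts once
  flat_hit <- tibble::tibble(time_s = 0:2, hu = c(-1, 0, 1))
  expect_equal(find_intersections(flat_hit, 0), 1)
})

test_that("crossings agree with a dense-grid sign-change oracle", {
  ph <- make_phantom()
  d <- difference_curve(ph$aif, ph$vof)
  for (level in c(5, 20, 60, 100)) {
    got <- find_intersections(d, level)
    ref <- oracle_crossings(d$time_s, d$hu, level)
    expect_equal(length(got), length(ref))
    expect_true(all(abs(got - ref) < 2e-3))
  }
})

test_that("acquisition time is recovered on noiseless phantoms", {
  ph <- make_phantom()
  for (ta in c(13, 15.5, 18, 22, 27, 35)) {
    vals <- snapshot_values(ph$bp, ph$geo, ta)
    est <- estimate_timing(ph$aif, ph$vof, vals, fov = ph$fov)
    expect_lt(abs(est$t_est - ta), ph$bp$frame_interval)
    expect_true(length(est$candidates) == 0 || est$t_est %in% est$candidates)
  }
})

test_that("flat difference curve raises an estimation error", {
  t <- seq(0, 10, 1)
  a <- tibble::tibble(time_s = t, hu = rep(100, 11), label = "AIF")
  expect_error(estimate_timing(a, a, c(arterial = 100, venous = 100)), "flat")
})

test_that("phase boundaries follow the AIF/VOF landmark definition", {
  ph <- make_phantom()
  lm <- bolusphase:::curve_landmarks(ph$aif, ph$vof)
  expect_identical(as.character(classify_phase(lm$t_peak_aif, ph$aif, ph$vof)$phase),
                   "mid_arterial")
  expect_identical(as.character(classify_phase(lm$t_peak_vof, ph$aif, ph$vof)$phase),
                   "delayed_venous")
  mid <- (lm$t_peak_aif + lm$t_peak_vof) / 2
  expect_identical(as.character(classify_phase(mid, ph$aif, ph$vof)$phase),
                   "mid_to_venous")
  early <- classify_phase(lm$t_half_aif, ph$aif, ph$vof)
  expect_identical(as.character(early$phase), "early_arterial")
  pre <- classify_phase(2, ph$aif, ph$vof)
  expect_true("pre_bolus" %in% pre$flags)
  # non-physiological ordering: VOF peaking before AIF
  expect_error(classify_phase(10, ph$vof, ph$aif), "peak")
})

test_that("assigned phases never move backwards as acquisition time advances", {
  ph <- make_phantom()
  phases <- vapply(seq(11, 50, length.out = 60), function(ta) {
    vals <- snapshot_values(ph$bp, ph$geo, ta)
    as.integer(estimate_timing(ph$aif, ph$vof, vals, fov = ph$fov)$phase)
  }, integer(1))
  expect_true(all(diff(phases) >= 0))
  expect_setequal(unique(phases), 1:4)
})

test_that("timing is robust to 5 HU voxel noise", {
  errs <- vapply(1:20, function(s) {
    bp <- bolus_params(noise_sd = 5, seed = s)
    ph <- make_phantom(bp)
    set.seed(s); ta <- runif(1, 13, 30)
    bp2 <- bolus_params(noise_sd = 5, seed = s + 10000L)
    vals <- snapshot_values(bp2, ph$geo, ta)
    abs(estimate_timing(ph$aif, ph$vof, vals, fov = ph$fov)$t_est - ta)
  }, numeric(1))
  expect_lte(median(errs), 2 * bolus_params()$frame_interval)
})
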