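test_that("thresholded volume equals brute-force voxel counting", {
  set.seed(31)
  for (i in 1:5) {
    m <- array(runif(20 * 20 * 8, 0, 12), dim = c(20, 20, 8))
    sp <- runif(3, 0.5, 2)
    got <- thresholded_volume(m, function(x) x > 6, sp)
    cnt <- 0
    for (v in m) if (v > 6) cnt <- cnt + 1
    expect_equal(got, cnt * prod(sp) / 1000)
  }
  expect_equal(thresholded_volume(array(0, c(4, 4, 4)), function(x) x > 6,
                                  c(1, 1, 1)), 0)
  m1 <- array(0, c(30, 30, 23)); m1[seq_len(20000)] <- 10
  expect_equal(thresholded_volume(m1, function(x) x > 6, c(1, 1, 1)), 20)
  expect_error(thresholded_volume(array(NA_real_, c(2, 2, 2)),
                                  function(x) x > 6, c(1, 1, 1)))
})

test_that("HIR is the nested Tmax volume ratio and stays in [0, 1]", {
  m <- simulate_perfusion_maps(10, 40, 0.35)
  hir <- compute_hir(m)
  expect_gte(hir, 0); expect_lte(hir, 1)
  expect_equal(hir, sum(m$tmax > 10) / sum(m$tmax > 6))
  # boundary constructions
  all_severe <- list(tmax = array(12, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(compute_hir(all_severe), 1)
  none_severe <- list(tmax = array(8, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_equal(compute_hir(none_severe), 0)
  empty <- list(tmax = array(0, c(4, 4, 4)), spacing = c(1, 1, 1))
  expect_error(compute_hir(empty), "undefined")
  # monotone in the thresholds
  expect_lte(compute_hir(m, severe_s = 11), compute_hir(m, severe_s = 10))
  expect_lte(compute_hir(m, any_s = 5), compute_hir(m, any_s = 6))
})

test_that("HIR dichotomy is good below 0.5 and poor at or above", {
  expect_identical(classify_collaterals_hir(c(0, 0.49, 0.5, 1)),
                   c("good", "good", "poor", "poor"))
  expect_error(classify_collaterals_hir(1.2))
})

test_that("probability-map volumetry applies the inclusion filters", {
  d <- c(24L, 24L, 12L)
  hemi <- array("ipsilateral", dim = d)
  hemi[13:24, , ] <- "contralateral"
  hemi[, , 1:2] <- "cerebellum"
  prob <- array(0, dim = d)
  # kept: 5x5x8 ipsilateral block = 0.2 mL at 1 mm
  prob[3:7, 3:7, 5:12] <- 0.9
  # rejected by size: 50-voxel ipsilateral blob (0.05 mL <= 0.1 mL)
  prob[10:11, 3:7, 5:9] <- 0.8
  # rejected by side: contralateral 5 mL blob
  prob[15:22, 10:20, 4:11] <- 0.95
  # rejected: cerebellar component
  prob[3:6, 15:20, 1:2] <- 0.7
  # below probability threshold everywhere: never a component
  prob[20:22, 2:4, 3:4] <- 0.4
  res <- lesion_volume_from_probability(prob, hemi, c(1, 1, 1))
  expect_equal(res$volume_mL, 5 * 5 * 8 / 1000)
  expect_equal(res$n_components_kept, 1L)
  expect_equal(res$n_components_rejected, 3L)
  # empty map
  res0 <- lesion_volume_from_probability(array(0, d), hemi, c(1, 1, 1))
  expect_equal(res0$volume_mL, 0)
  expect_equal(res0$n_components_kept + res0$n_components_rejected, 0L)
  expect_error(lesion_volume_from_probability(prob, NULL, c(1, 1, 1)))
  expect_error(lesion_volume_from_probability(prob + 2, hemi, c(1, 1, 1)))
})

test_that("lesion volume is monotone in both filter thresholds", {
  set.seed(77)
  prob <- array(runif(18^3), dim = c(18, 18, 18))
  hemi <- array("ipsilateral", dim = c(18, 18, 18))
  v_by_p <- sapply(c(0.3, 0.5, 0.7),
    function(p) lesion_volume_from_probability(prob, hemi, c(1, 1, 1),
                                               prob_threshold = p)$volume_mL)
  expect_true(all(diff(v_by_p) <= 1e-12))
  v_by_min <- sapply(c(0, 0.1, 0.5),
    function(mv) lesion_volume_from_probability(prob, hemi, c(1, 1, 1),
                                                min_volume_mL = mv)$volume_mL)
  expect_true(all(diff(v_by_min) <= 1e-12))
})

test_that("26-connectivity joins diagonal voxels into one component", {
  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE  # corner neighbours
  lab <- bolusphase:::label_components_26(m)
  expect_equal(max(lab), 1L)
  m[5, 5, 5] <- TRUE  # isolated
  lab2 <- bolusphase:::label_components_26(m)
  expect_equal(max(lab2), 2L)
})
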