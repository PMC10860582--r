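# shared phantom builders and independent oracles

make_phantom <- function(bp = bolus_params(noise_sd = 0),
                         geo = phantom_geometry()) {
  ser <- simulate_ctp_series(bp, geo)
  list(bp = bp, geo = geo, ser = ser,
       aif = extract_roi_curve(ser, roi_spec("arterial", geo$arterial)),
       vof = extract_roi_curve(ser, roi_spec("venous", geo$venous)),
       fov = fov_mean_curve(ser))
}

# snapshot -> CTA ROI values (+ whole-volume FOV mean) at a given time
snapshot_values <- function(bp, geo, t_acq) {
  cta <- simulate_cta_snapshot(bp, geo, t_acq)
  c(cta_roi_values(cta, geo$arterial, geo$venous), fov = mean(cta$voxels))
}

# randomly jittered bolus parameters emulating between-patient variation
jitter_bolus <- function(seed, noise_sd = 0) {
  set.seed(seed)
  bolus_params(t0 = runif(1, 8, 12), alpha = runif(1, 2.5, 3.5),
               beta = runif(1, 1.3, 1.7), venous_delay = runif(1, 10, 12),
               noise_sd = noise_sd, seed = seed)
}

# ---- independent brute-force oracles (kept free of package internals) ----

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n; sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  b <- sum((x - mx) * (y - my)) / sum((x - mx)^2)
  c(slope = b, intercept = my - b * mx)
}

# linear-interpolation percentile (type 7) by explicit order statistics
oracle_quantile <- function(v, p) {
  s <- sort(v); n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Kruskal-Wallis H with tie correction, written from the definition
oracle_kw_h <- function(values, groups) {
  r <- rank(values); n <- length(values)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * (mean(ri) - (n + 1) / 2)^2))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# exact permutation distribution of H for two small groups
oracle_kw_perm_p <- function(g1, g2) {
  vals <- c(g1, g2); n1 <- length(g1)
  idx <- utils::combn(length(vals), n1)
  h_obs <- oracle_kw_h(vals, rep(1:2, c(n1, length(g2))))
  hs <- apply(idx, 2, function(i) {
    grp <- rep(2L, length(vals)); grp[i] <- 1L
    oracle_kw_h(vals, grp)
  })
  mean(hs >= h_obs - 1e-12)
}

# dense-grid sign-change scan for level crossings of a piecewise-linear curve
oracle_crossings <- function(times, values, level, res = 1e-3) {
  grid <- seq(min(times), max(times), by = res)
  v <- approx(times, values, xout = grid)$y - level
  s <- sign(v)
  hit <- which(s[-1] * s[-length(s)] <= 0 & (s[-1] != 0 | s[-length(s)] != 0))
  zero <- which(s == 0)
  sort(unique(c(grid[hit], grid[zero])))
}
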