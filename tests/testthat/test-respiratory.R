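g0 <- 9.80665

test_that("pitch and roll formulas match direct evaluation", {
  level <- matrix(c(0, 0, 9.81), 1)
  expect_equal(adr_pitch(level), 0)
  expect_equal(adr_roll(level), 0)

  tilted <- matrix(c(0, g0 * tan(pi / 6), g0), 1)   # 30 degrees of pitch
  expect_equal(adr_pitch(tilted), pi / 6, tolerance = 1e-9)
  tilted_r <- matrix(c(g0 * tan(pi / 6), 0, g0), 1)
  expect_equal(adr_roll(tilted_r), pi / 6, tolerance = 1e-9)
})

test_that("the small-angle approximation agrees with the exact form", {
  acc <- matrix(c(0, 0.0981, g0), 1)
  expect_lt(abs(adr_pitch(acc) - adr_pitch(acc, "approx")), 1e-4)
})

test_that("roll is pitch with the x and y axes swapped", {
  set.seed(1)
  acc <- cbind(rnorm(50, 0, 0.3), rnorm(50, 0, 0.3), rnorm(50, g0, 0.1))
  expect_equal(adr_roll(acc), adr_pitch(acc[, c(2, 1, 3)]))
})

test_that("a zero gravity denominator is reported with its sample index", {
  acc <- matrix(c(0, 1, 0, 0, 1, 0), 2, byrow = TRUE)
  acc[2, ] <- c(0, 0, 9.8)
  expect_error(adr_pitch(acc), "sample 1")
})

test_that("gyro integration recovers sinusoidal tilt amplitudes", {
  fs <- 100
  expect_equal(gdr_integrate(numeric(1000), fs), numeric(1000))
  for (f in c(0.1, 0.25, 0.5)) {
    t <- (0:(60 * fs - 1)) / fs
    rate <- 0.1 * cos(2 * pi * f * t)
    ang <- gdr_integrate(rate, fs)
    i <- t > 10 & t < 50
    expect_equal(max(abs(ang[i])), 0.1 / (2 * pi * f), tolerance = 0.01)
  }
  # constant rate integrates to a ramp before detrending
  ramp <- gdr_integrate(rep(0.01, 10 * 100), 100, detrend = FALSE)
  expect_equal(ramp[1000], 0.1, tolerance = 0.002)
})

test_that("extract_respiration recovers the generating tilt", {
  sim <- simulate_chest_motion(sim_config(duration_s = 60, noise_sd = 0,
                                          artifact_rate_per_min = 0, seed = 2))
  rs <- extract_respiration(sim$recording)
  expect_equal(dim(rs$R), c(5, sim$recording$n_samples))
  expect_gt(cor(rs$adr_y, sim$truth$pitch), 0.99)
  expect_gt(cor(rs$gdr_x, sim$truth$pitch), 0.99)
  expect_gt(abs(cor(rs$adr_y, rs$gdr_x)), 0.95)   # ADR/GDR consistency
})

test_that("a static recording produces near-zero inclination channels", {
  n <- 40 * 800
  rec <- imu_recording(cbind(rep(0, n), rep(0, n), rep(g0, n)),
                       matrix(0, n, 3), fs = 800)
  rs <- extract_respiration(rec)
  for (ch in c("adr_x", "adr_y", "gdr_x", "gdr_y", "gdr_z"))
    expect_lt(max(abs(rs[[ch]])), 1e-6)
})

test_that("polarity correction flips anti-correlated channels and is idempotent", {
  sim <- simulate_chest_motion(sim_config(duration_s = 60, noise_sd = 0,
                                          artifact_rate_per_min = 0, seed = 3))
  rs <- extract_respiration(sim$recording)
  rs$adr_y <- -rs$adr_y
  rs$R["adr_y", ] <- -rs$R["adr_y", ]
  fixed <- polarity_correct(rs, sim$recording)
  expect_equal(fixed$polarity_flags[["adr_y"]], -1)
  expect_gt(cor(fixed$adr_y, fixed$reference), 0)
  again <- polarity_correct(fixed, sim$recording)
  expect_equal(again$polarity_flags, fixed$polarity_flags)
  expect_identical(again$adr_y, fixed$adr_y)
})

test_that("PCA fusion handles the rank-1 case and normalizes loadings", {
  n <- 2000
  common <- sin(2 * pi * 0.25 * (0:(n - 1)) / 25)
  R <- matrix(rep(common, 5), nrow = 5, byrow = TRUE)
  rownames(R) <- c("adr_x", "adr_y", "gdr_x", "gdr_y", "gdr_z")
  set <- structure(c(as.list(as.data.frame(t(R))),
                     list(fs = 25, R = R,
                          polarity_flags = setNames(rep(1, 5), rownames(R)))),
                   class = "respiration_set")
  names(set)[1:5] <- rownames(R)
  fu <- pca_fuse(set)
  expect_equal(fu$explained_var_ratio, 1.0, tolerance = 1e-12)
  expect_gt(abs(cor(fu$pc1, common)), 0.999999)
  expect_equal(sqrt(sum(fu$loadings^2)), 1, tolerance = 1e-12)
})

test_that("PCA fusion beats every single channel on noisy common-signal sets", {
  sim <- simulate_respiration_set(seed = 7)
  fu <- pca_fuse(sim$set)
  r_fused <- cor(fu$pc1, sim$truth)
  r_single <- vapply(sim$set[c("adr_x", "adr_y", "gdr_x", "gdr_y", "gdr_z")],
                     function(ch) abs(cor(ch, sim$truth)), numeric(1))
  expect_gte(r_fused, max(r_single))
})

test_that("fusion output is invariant to input sign flips after polarity", {
  sim <- simulate_chest_motion(sim_config(duration_s = 60, noise_sd = 0,
                                          artifact_rate_per_min = 0, seed = 8))
  rs <- polarity_correct(extract_respiration(sim$recording), sim$recording)
  fu1 <- pca_fuse(rs)
  flipped <- extract_respiration(sim$recording)
  flipped$gdr_y <- -flipped$gdr_y
  flipped$R["gdr_y", ] <- -flipped$R["gdr_y", ]
  fu2 <- pca_fuse(polarity_correct(flipped, sim$recording))
  expect_gt(cor(fu1$pc1, fu2$pc1), 0.999999)
})

test_that("breath detection finds alternating crests and troughs of a sinusoid", {
  fs <- 25
  t <- (0:(60 * fs - 1)) / fs
  pc1 <- sin(2 * pi * 0.25 * t)
  br <- detect_breaths(pc1, fs)
  expect_length(br$inhalation_peaks, 15)
  expect_length(br$exhalation_troughs, 15)
  crests <- 1 + 4 * (0:14)
  expect_true(all(abs(br$inhalation_peaks - crests) <= 1 / fs + 1e-9))
  ev <- sort(c(br$inhalation_peaks, br$exhalation_troughs))
  kinds <- ifelse(ev %in% br$inhalation_peaks, 1, -1)
  expect_true(all(abs(diff(kinds)) == 2))        # strict alternation
  # parabolic triggers are sub-sample refinements of the crests
  expect_true(all(abs(br$triggers - crests) < 0.5 / fs + 1e-9))
})

test_that("small ripples are removed by the median-distance rule", {
  fs <- 25
  t <- (0:(60 * fs - 1)) / fs
  pc1 <- sin(2 * pi * 0.25 * t) + 0.1 * sin(2 * pi * 0.75 * t)
  br <- detect_breaths(pc1, fs)
  expect_length(br$inhalation_peaks, 15)
})

test_that("breath detection fails cleanly on degenerate input", {
  expect_error(detect_breaths(rep(1, 1000), 25), "constant")
  expect_error(detect_breaths(sin(2 * pi * 0.25 * (0:49) / 25), 25), "longer")
})

test_that("amplitude bins split the robust range evenly", {
  fs <- 25
  pc1 <- sin(2 * pi * 0.25 * (0:(60 * fs - 1)) / fs)
  rb <- make_resp_bins(pc1, fs, n_bins = 4, mode = "amplitude")
  q <- quantile(pc1, c(0.05, 0.95), names = FALSE)
  expect_equal(diff(rb$edges), rep((q[2] - q[1]) / 4, 4))
  expect_true(all(rb$labels %in% 1:4))
  expect_error(make_resp_bins(pc1, fs, n_bins = 1), "n_bins")
})

test_that("phase bins occupy equal fractions for a pure sinusoid", {
  fs <- 25
  pc1 <- sin(2 * pi * 0.25 * (0:(60 * fs - 1)) / fs)
  br <- detect_breaths(pc1, fs)
  rb <- make_resp_bins(pc1, fs, br, n_bins = 4, mode = "phase")
  occ <- table(rb$labels) / sum(!is.na(rb$labels))
  expect_equal(as.numeric(occ), rep(0.25, 4), tolerance = 0.01)
})
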