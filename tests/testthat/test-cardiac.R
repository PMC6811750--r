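make_sources <- function(fs = 400, dur = 30, seed = 1) {
  tr <- double_burst_train(fs, dur, period = 0.9, eject = NULL, seed = seed)
  s2 <- sin(2 * pi * 7 * (0:(dur * fs - 1)) / fs)
  list(burst = tr$x, sine = s2, beats = tr$beats)
}

test_that("ICA recovers the burst source from a 2x2 mixture", {
  src <- make_sources(seed = 3)
  x1 <- zscore(1.0 * src$burst + 0.3 * src$sine)
  x2 <- zscore(0.4 * src$burst + 1.0 * src$sine)
  f <- ica_fuse(x1, x2, fs = 400, seed = 1)
  expect_gt(abs(cor(f$cardiac, src$burst)), 0.95)
  # whitening contract: zero mean, unit variance
  expect_lt(max(abs(rowMeans(f$sources))), 1e-6)
  expect_equal(unname(apply(f$sources, 1, var)), c(1, 1), tolerance = 1e-3)
})

test_that("collinear channels are rejected as rank deficient", {
  x <- zscore(rnorm(2000))
  expect_error(ica_fuse(x, x, fs = 400), "collinear|rank")
})

test_that("the selected component has positive deflections at beats", {
  src <- make_sources(seed = 5)
  x1 <- zscore(-1.0 * src$burst + 0.2 * src$sine)  # inverted mixture
  x2 <- zscore(-0.3 * src$burst + 1.0 * src$sine)
  f <- ica_fuse(x1, x2, fs = 400, seed = 1)
  idx <- round(src$beats * 400) + 1
  window_max <- vapply(idx, function(i)
    max(f$cardiac[max(1, i - 20):min(length(f$cardiac), i + 20)]), numeric(1))
  expect_gt(median(window_max), 0)
})

test_that("envelope has one dominant lobe per burst and is non-negative", {
  fs <- 800
  expect_equal(envelope_signal(numeric(4000), fs), numeric(4000))

  x <- numeric(4 * fs)
  k <- oracle_gabor(fs, 15, 0.013)
  c_idx <- fs + 1
  half <- (length(k) - 1) %/% 2
  x[(c_idx - half):(c_idx + half)] <- k
  env <- envelope_signal(x, fs)
  expect_lt(abs(which.max(env) - c_idx) / fs, 0.05)

  set.seed(1)
  expect_true(all(envelope_signal(rnorm(4000), fs) >= 0))
})

test_that("AMPD matches analytic peak locations on a sinusoid", {
  t <- (0:999) / 100
  pk <- ampd_peaks(sin(2 * pi * t))
  expect_length(pk, 10)
  expected <- round((0.25 + 0:9) * 100) + 1
  expect_true(all(abs(pk - expected) <= 1))
})

test_that("AMPD returns nothing on monotone and constant signals", {
  expect_length(ampd_peaks(as.numeric(1:500)), 0)
  expect_length(ampd_peaks(rep(2.5, 300)), 0)
})

test_that("AMPD equals the brute-force oracle on assorted signals", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(30:300, 1)
    x <- cumsum(rnorm(n))
    expect_identical(ampd_peaks(x), ampd_oracle(x))
  }
})

test_that("refine_beats relocates offset envelope peaks onto burst maxima", {
  fs <- 800
  tr <- double_burst_train(fs, 30, period = 1.0, eject = NULL, jit = 0,
                           seed = 2)
  true_pk <- vapply(tr$beats, function(b) {
    i <- round(b * fs) + 1
    (i - 30) + which.max(tr$x[(i - 30):(i + 30)]) - 1
  }, numeric(1))
  offset_pk <- as.integer(true_pk + round(0.03 * fs))   # +30 ms offset
  bs <- refine_beats(tr$x, offset_pk, fs)
  expect_length(bs$beat_times, length(true_pk))
  expect_true(all(abs(bs$beat_times - (true_pk - 1) / fs) <= 1 / fs + 1e-9))
})

test_that("the refractory period keeps the larger of two close candidates", {
  fs <- 800
  x <- numeric(2 * fs)
  x[fs - 1 + c(-1, 0, 1)] <- c(0.5, 1.0, 0.5)          # peak amp 1.0
  x[fs + 79 + c(-1, 0, 1)] <- c(0.8, 1.6, 0.8)         # 100 ms later, larger
  bs <- refine_beats(x, c(fs - 1L, fs + 79L), fs)
  expect_length(bs$beat_times, 1)
  expect_equal(bs$beat_times, (fs + 79 - 1) / fs)
})

test_that("an all-zero cardiac signal yields no accepted beats", {
  bs <- refine_beats(numeric(4000), c(1000L, 2000L, 3000L), 800)
  expect_length(bs$beat_times, 0)
})

test_that("cycle and ejection are recovered from a double-burst train", {
  fs <- 800
  tr <- double_burst_train(fs, 20, period = 1.0, eject = 0.35, seed = 1)
  seg <- segment_cycles(tr$x, fs)$segments
  expect_true(all(seg$valid))
  expect_equal(seg$cycle_len_s, rep(1.0, nrow(seg)), tolerance = 0.011)
  expect_equal(seg$ejection_s, rep(0.35, nrow(seg)), tolerance = 0.011)
  expect_false(any(seg$ejection_fallback))
})

test_that("a single-burst train falls back to ejection = 0.35 x cycle", {
  fs <- 800
  tr <- double_burst_train(fs, 20, period = 1.0, eject = NULL, jit = 0.004,
                           seed = 2)
  seg <- segment_cycles(tr$x, fs)$segments
  expect_true(all(seg$valid))
  expect_true(all(seg$ejection_fallback))
  expect_equal(seg$ejection_s, 0.35 * seg$cycle_len_s)
})

test_that("white noise segments are marked invalid", {
  set.seed(3)
  seg <- segment_cycles(rnorm(20 * 800), 800)$segments
  expect_false(any(seg$valid))
})

test_that("cardiac bins divide systole evenly and diastole in one bin", {
  beats <- beat_set(c(0, 1.0, 2.0))
  seg <- structure(list(segments = data.frame(
    start_s = 0, end_s = 20, cycle_len_s = 1, ejection_s = 0.4,
    valid = TRUE, ejection_fallback = FALSE), segment_s = 20, fs = 800),
    class = "cycle_segmentation")
  bins <- make_cardiac_bins(beats, seg, n_bins = 5)
  expect_equal(bins$boundaries[[1]], c(0, 0.1, 0.2, 0.3, 0.4))
  # partition of [b, b2): boundaries strictly inside, starts at b
  expect_true(all(diff(bins$boundaries[[1]]) > 0))
  expect_lt(max(bins$boundaries[[1]]), 1.0)

  b2 <- make_cardiac_bins(beats, seg, n_bins = 2)
  expect_equal(b2$boundaries[[1]], c(0, 0.4))

  seg$segments$ejection_s <- 0.95
  two_beats <- beat_set(c(0, 1.0))
  expect_warning(b3 <- make_cardiac_bins(two_beats, seg, n_bins = 5), "clamped")
  expect_lt(max(b3$boundaries[[1]]), 1.0)
})

test_that("cycle length agrees with the median inter-beat interval", {
  sim <- simulate_chest_motion(sim_config(duration_s = 60, noise_sd = 0,
                                          artifact_rate_per_min = 0, seed = 6))
  res <- run_dual_gating(sim$recording, dual_config(seed = 6))
  segs <- res$segmentation$segments
  expect_true(any(segs$valid))
  med_cycle <- median(segs$cycle_len_s[segs$valid])
  med_ibi <- median(res$beats$ibi)
  expect_lt(abs(med_cycle - med_ibi) / med_ibi, 0.05)
})
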