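test_that("pearson satisfies the basic identities", {
  set.seed(1)
  x <- rnorm(500)
  expect_equal(pearson(x, x), 1)
  expect_equal(pearson(x, -x), -1)
  t <- (0:9999) / 1000
  expect_lt(abs(pearson(sin(2 * pi * t), cos(2 * pi * t))), 0.01)
  expect_error(pearson(x, rep(1, 500)), "constant")
  expect_error(pearson(x, x[1:10]), "length")
  # affine invariance
  expect_equal(pearson(3 * x + 2, x), 1)
})

test_that("trigger offsets are exact for shifted and identical lists", {
  ref <- seq(2, 58, by = 4)
  same <- trigger_offset(ref, ref)
  expect_equal(same$mean_abs_offset_s, 0)
  expect_equal(same$sd_abs_offset_s, 0)

  shifted <- trigger_offset(ref + 0.2, ref)
  expect_equal(shifted$mean_abs_offset_s, 0.2)
  expect_equal(shifted$sd_abs_offset_s, 0)

  # a spurious trigger falling in a gap, farther than half the median
  # spacing from every reference trigger, is excluded from the mean
  ref_gap <- ref[ref != 26]          # gap between 22 and 30
  test <- sort(c(ref_gap, 26))
  res <- trigger_offset(test, ref_gap)
  expect_equal(res$n_unmatched_test, 1)
  expect_equal(res$mean_abs_offset_s, 0)

  expect_error(trigger_offset(numeric(0), ref), "non-empty")
})

test_that("beat matching computes TPR, PPV, F1 and RMSE as defined", {
  same <- match_beats(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(same$tpr, same$ppv, same$f1), c(1, 1, 1))
  expect_equal(same$rmse_ms, 0)

  partial <- match_beats(c(1, 2), c(1, 2, 3))
  expect_equal(partial$tpr, 2 / 3)
  expect_equal(partial$ppv, 1)
  expect_equal(partial$f1, 0.8)

  shifted <- match_beats(c(1, 2, 3) + 0.05, c(1, 2, 3))
  expect_equal(shifted$rmse_ms, 50)

  expect_error(match_beats(c(1, 2), numeric(0)), "non-empty")
})

test_that("matching is one-to-one and saturates at the shorter list", {
  res <- match_beats(c(1, 1.01, 1.02), c(1, 5, 9), tolerance_ms = Inf)
  expect_equal(res$tp, 3)
  res2 <- match_beats(seq(1, 10), seq(1, 5), tolerance_ms = Inf)
  expect_equal(res2$tp, 5)
})

test_that("F1 treats sensitivity and precision symmetrically", {
  a <- match_beats(c(1, 2), c(1, 2, 3))      # fn = 1
  b <- match_beats(c(1, 2, 3), c(1, 2))      # fp = 1
  expect_equal(a$f1, b$f1)
  expect_equal(a$tpr, b$ppv)
  expect_equal(a$ppv, b$tpr)
})

test_that("heart rate is 60 over the mean inter-beat interval", {
  expect_equal(heart_rate(beat_set(0:10)), 60)
  alt <- beat_set(cumsum(c(0, rep(c(0.5, 1.5), 5))))
  expect_equal(heart_rate(alt), 60)
  expect_error(heart_rate(beat_set(1)), "two beats")
})

test_that("CCP is the ratio of summed ejections to summed cycles", {
  seg1 <- structure(list(segments = data.frame(
    start_s = 0, end_s = 60, cycle_len_s = 1, ejection_s = 0.35,
    valid = TRUE, ejection_fallback = FALSE)), class = "cycle_segmentation")
  beats <- beat_set(seq(0.5, 10.5, by = 1))
  expect_equal(ccp(beats, seg1), 35)

  seg2 <- structure(list(segments = data.frame(
    start_s = c(0, 30), end_s = c(30, 60), cycle_len_s = c(1, 1),
    ejection_s = c(0.3, 0.4), valid = c(TRUE, TRUE),
    ejection_fallback = FALSE)), class = "cycle_segmentation")
  two <- beat_set(c(10, 40))
  expect_equal(ccp(two, seg2), 35)

  seg3 <- structure(list(segments = data.frame(
    start_s = 0, end_s = 60, cycle_len_s = 1, ejection_s = 0.35,
    valid = FALSE, ejection_fallback = FALSE)), class = "cycle_segmentation")
  expect_error(ccp(beats, seg3), "valid")
})
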