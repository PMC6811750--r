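write_demo_csv <- function(path, n = 800, fs = 800, tweak = identity) {
  df <- data.frame(time = (seq_len(n) - 1) / fs,
                   acc_x = rnorm(n), acc_y = rnorm(n), acc_z = rnorm(n) + 9.8,
                   gyro_x = rnorm(n), gyro_y = rnorm(n), gyro_z = rnorm(n))
  df <- tweak(df)
  utils::write.csv(df, path, row.names = FALSE)
  df
}

test_that("read_recording parses a six-channel CSV and derives duration", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(1)
  write_demo_csv(path)
  rec <- read_recording(path, fs = 800)
  expect_s3_class(rec, "imu_recording")
  expect_equal(rec$n_samples, 800)
  expect_equal(rec$n_samples / rec$fs, 1.0)
  # fs derivable from the time column too
  rec2 <- read_recording(path)
  expect_equal(rec2$fs, 800)
})

test_that("read_recording converts g and deg/s into canonical units", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(2)
  df <- write_demo_csv(path)
  rec <- read_recording(path, fs = 800,
                        units = list(acc = "g", gyro = "deg/s"))
  expect_equal(rec$acc[, 1], df$acc_x * 9.80665)
  expect_equal(rec$gyro[, 3], df$gyro_z * pi / 180)
})

test_that("a missing channel column is reported by name", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_demo_csv(path, tweak = function(df) { df$gyro_y <- NULL; df })
  expect_error(read_recording(path, fs = 800), "gyro_y")
})

test_that("non-finite samples fail fast unless linear imputation is chosen", {
  path <- withr::local_tempfile(fileext = ".csv")
  set.seed(3)
  df <- write_demo_csv(path, tweak = function(df) { df$acc_z[10] <- NA; df })
  expect_error(read_recording(path, fs = 800), "acc_z")
  rec <- read_recording(path, fs = 800, impute = "linear")
  expect_equal(unname(rec$acc[10, 3]), (df$acc_z[9] + df$acc_z[11]) / 2)
})

test_that("resampling preserves constants, in-band sinusoids, and duration", {
  expect_equal(resample_signal(rep(3, 25 * 4), 25, 800), rep(3, 800 * 4))

  fs <- 800
  t_in <- (0:(10 * fs - 1)) / fs
  x <- sin(2 * pi * 1 * t_in)
  y <- resample_signal(x, fs, 25)
  t_out <- (seq_along(y) - 1) / 25
  expect_length(y, round(10 * 25))
  expect_gt(cor(y, sin(2 * pi * 1 * t_out)), 0.999)
  expect_lt(abs(max(abs(y)) - 1), 0.01)

  expect_error(resample_signal(x, fs, 0), "positive")
  expect_error(resample_signal(x, -1, 25), "positive")
})

test_that("annotation tables round-trip exactly through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  empty <- annotation_table()
  write_annotations(empty, path)
  expect_identical(readLines(path), "time_s,kind,bin_index")
  expect_equal(nrow(read_annotations(path)), 0)

  tab <- annotation_table(c(1.25, 2.5, 3.123456), rep("beat", 3))
  write_annotations(tab, path)
  back <- read_annotations(path)
  expect_equal(back$time_s, tab$time_s)
  expect_identical(back$kind, tab$kind)

  mixed <- annotation_table(c(0.5, 0.6, 1.1), c("bin_boundary", "bin_boundary",
                                                "peak_inhalation"),
                            c(1L, 2L, NA))
  write_annotations(mixed, path)
  expect_equal(read_annotations(path), mixed, ignore_attr = TRUE)
})

test_that("annotation tables validate kinds and per-kind ordering", {
  expect_error(annotation_table(1, "blip"), "kind")
  expect_error(annotation_table(c(2, 1), c("beat", "beat")), "non-decreasing")
})
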