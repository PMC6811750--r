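#' Six-axis chest-motion recording
#'
#' Container for a synchronized tri-axial accelerometer + tri-axial gyroscope
#' recording. Axes follow the supine chest convention: x lateral
#' (sinister-dexter), y longitudinal (superior-inferior), z dorsoventral.
#' Accelerations are in m/s^2 and angular rates in rad/s; sample `i`
#' (1-based) is at time `t0 + (i - 1) / fs` seconds.
#'
#' @param acc numeric matrix with columns `x`, `y`, `z` (m/s^2).
#' @param gyro numeric matrix with columns `x`, `y`, `z` (rad/s).
#' @param fs sampling rate in Hz (positive scalar).
#' @param t0 start time in seconds (default 0).
#' @return An object of class `imu_recording`: list with elements `acc`,
#'   `gyro` (n x 3 matrices), `fs`, `t0`, `n_samples`.
#' @export
imu_recording <- function(acc, gyro, fs, t0 = 0) {
  acc <- as.matrix(acc); gyro <- as.matrix(gyro)
  if (!is_scalar_num(fs) || fs <= 0) stopf("fs must be a positive number")
  if (ncol(acc) != 3 || ncol(gyro) != 3)
    stopf("acc and gyro must each have 3 columns (x, y, z)")
  if (nrow(acc) != nrow(gyro))
    stopf("acc and gyro must have the same number of samples")
  if (any(!is.finite(acc)) || any(!is.finite(gyro)))
    stopf("non-finite samples in recording")
  colnames(acc) <- colnames(gyro) <- c("x", "y", "z")
  structure(list(acc = acc, gyro = gyro, fs = fs, t0 = t0,
                 n_samples = nrow(acc)),
            class = "imu_recording")
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf("<imu_recording> %d samples @ %g Hz (%.1f s), t0 = %g s\n",
              x$n_samples, x$fs, x$n_samples / x$fs, x$t0))
  invisible(x)
}

#' Sample times of a recording
#' @param rec an `imu_recording`.
#' @return numeric vector of times in seconds.
#' @export
rec_times <- function(rec) rec$t0 + (seq_len(rec$n_samples) - 1) / rec$fs

#' Read a six-axis recording from delimited text
#'
#' Reads a CSV/TSV file with one column per channel. Column names are mapped
#' through `column_map`; unit conversion to the canonical m/s^2 / rad/s is
#' applied according to `units`. The sampling rate is either supplied or
#' derived from a time column.
#'
#' @param path file path to a delimited text file with a header row.
#' @param column_map named character vector mapping canonical names
#'   (`time`, `acc_x`, `acc_y`, `acc_z`, `gyro_x`, `gyro_y`, `gyro_z`) to the
#'   file's column names. Defaults to the identity mapping; `time` is optional
#'   when `fs` is given.
#' @param fs sampling rate in Hz; if `NULL`, derived from the time column.
#' @param units list with elements `acc` (`"m/s2"` or `"g"`) and `gyro`
#'   (`"rad/s"` or `"deg/s"`).
#' @param impute missing-value policy: `"fail"` (default) rejects non-finite
#'   samples; `"linear"` linearly interpolates interior gaps of at most
#'   `max_gap` samples.
#' @param max_gap maximum interior gap length (samples) for linear imputation.
#' @param sep field separator; `NULL` auto-detects comma vs tab.
#' @return an [imu_recording()].
#' @export
read_recording <- function(path, column_map = NULL, fs = NULL,
                           units = list(acc = "m/s2", gyro = "rad/s"),
                           impute = c("fail", "linear"), max_gap = 5,
                           sep = NULL) {
  impute <- match.arg(impute)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (is.null(sep)) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  canon <- c("time", "acc_x", "acc_y", "acc_z", "gyro_x", "gyro_y", "gyro_z")
  map <- stats::setNames(canon, canon)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  need <- canon[-1]
  for (nm in need) {
    if (!map[[nm]] %in% names(df))
      stopf("missing column \"%s\" (mapped from %s) in %s", map[[nm]], nm, path)
  }
  t0 <- 0
  if (is.null(fs)) {
    if (!map[["time"]] %in% names(df))
      stopf("fs not supplied and no time column \"%s\" present", map[["time"]])
    tv <- as.numeric(df[[map[["time"]]]])
    dt <- stats::median(diff(tv))
    if (!is.finite(dt) || dt <= 0) stopf("cannot derive fs from time column")
    fs <- 1 / dt
    t0 <- tv[1]
  } else if (map[["time"]] %in% names(df)) {
    t0 <- as.numeric(df[[map[["time"]]]][1])
  }

  get_chan <- function(nm) {
    v <- as.numeric(df[[map[[nm]]]])
    bad <- which(!is.finite(v))
    if (length(bad)) {
      if (impute == "fail")
        stopf("non-finite values in column %s (e.g. row %d); set impute = \"linear\"",
              nm, bad[1])
      runs <- split(bad, cumsum(c(1, diff(bad) != 1)))
      for (r in runs) {
        if (length(r) > max_gap || r[1] == 1 || r[length(r)] == length(v))
          stopf("gap of %d non-finite values in %s cannot be imputed", length(r), nm)
      }
      ok <- which(is.finite(v))
      v[bad] <- stats::approx(ok, v[ok], xout = bad)$y
    }
    v
  }
  acc <- cbind(get_chan("acc_x"), get_chan("acc_y"), get_chan("acc_z"))
  gyro <- cbind(get_chan("gyro_x"), get_chan("gyro_y"), get_chan("gyro_z"))
  if (identical(units$acc, "g")) acc <- acc * 9.80665
  else if (!identical(units$acc, "m/s2")) stopf("unknown acc unit: %s", units$acc)
  if (identical(units$gyro, "deg/s")) gyro <- gyro * pi / 180
  else if (!identical(units$gyro, "rad/s")) stopf("unknown gyro unit: %s", units$gyro)
  imu_recording(acc, gyro, fs = fs, t0 = t0)
}

#' Write a six-axis recording to CSV
#'
#' @param rec an [imu_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  df <- data.frame(time = rec_times(rec),
                   acc_x = rec$acc[, 1], acc_y = rec$acc[, 2], acc_z = rec$acc[, 3],
                   gyro_x = rec$gyro[, 1], gyro_y = rec$gyro[, 2], gyro_z = rec$gyro[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Resample a uniformly sampled signal
#'
#' Linear resampling onto a new uniform grid starting at the same instant.
#' Constants (and DC in general) are preserved exactly; in-band sinusoids are
#' preserved to within interpolation error.
#'
#' @param x numeric vector of samples.
#' @param fs_in source sampling rate (Hz).
#' @param fs_out target sampling rate (Hz).
#' @return numeric vector of length `round(length(x) / fs_in * fs_out)`.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (!is_scalar_num(fs_in) || fs_in <= 0) stopf("fs_in must be positive")
  if (!is_scalar_num(fs_out) || fs_out <= 0) stopf("fs_out must be positive")
  n_in <- length(x)
  n_out <- round(n_in / fs_in * fs_out)
  if (n_out < 1) stopf("resampled length would be empty")
  t_in <- (seq_len(n_in) - 1) / fs_in
  t_out <- (seq_len(n_out) - 1) / fs_out
  stats::approx(t_in, x, xout = t_out, rule = 2)$y
}

#' Reference series (respiration surrogate or beat annotations)
#'
#' @param kind `"respiration_surrogate"` or `"beat_annotations"`.
#' @param values numeric samples (surrogate only).
#' @param fs sampling rate in Hz (surrogate only).
#' @param beat_times strictly increasing beat times in seconds
#'   (annotations only).
#' @return object of class `reference_series`.
#' @export
reference_series <- function(kind = c("respiration_surrogate", "beat_annotations"),
                             values = NULL, fs = NULL, beat_times = NULL) {
  kind <- match.arg(kind)
  if (kind == "respiration_surrogate") {
    if (!is_scalar_num(fs) || fs <= 0) stopf("respiration surrogate needs fs > 0")
    if (is.null(values)) stopf("respiration surrogate needs values")
  } else {
    beat_times <- as.numeric(beat_times)
    if (length(beat_times) && any(diff(beat_times) <= 0))
      stopf("beat_times must be strictly increasing")
  }
  structure(list(kind = kind, values = values, fs = fs, beat_times = beat_times),
            class = "reference_series")
}

#' Annotation table of timed gating events
#'
#' @param time_s event times in seconds.
#' @param kind character vector of event kinds (`beat`, `peak_inhalation`,
#'   `peak_exhalation`, `bin_boundary`, `artifact`).
#' @param bin_index optional integer bin index per event (`NA` if absent).
#' @return a `data.frame` of class `annotation_table` with columns
#'   `time_s`, `kind`, `bin_index`.
#' @export
annotation_table <- function(time_s = numeric(0), kind = character(0),
                             bin_index = NA_integer_) {
  kinds <- c("beat", "peak_inhalation", "peak_exhalation", "bin_boundary",
             "artifact")
  n <- length(time_s)
  kind <- rep_len(as.character(kind), if (n) n else length(kind))
  if (length(kind) != n) stopf("kind must match time_s length")
  if (n && !all(kind %in% kinds))
    stopf("unknown event kind(s): %s", paste(setdiff(kind, kinds), collapse = ", "))
  bin_index <- rep_len(as.integer(bin_index), max(n, 0L))
  df <- data.frame(time_s = as.numeric(time_s), kind = kind,
                   bin_index = bin_index, stringsAsFactors = FALSE)
  for (k in unique(df$kind)) {
    tk <- df$time_s[df$kind == k]
    if (is.unsorted(tk)) stopf("times must be non-decreasing within kind %s", k)
  }
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Write annotations to CSV
#'
#' Times are printed at fixed microsecond precision so that a write/read
#' round trip reproduces the table exactly.
#'
#' @param table an [annotation_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(table, path) {
  lines <- c("time_s,kind,bin_index",
             if (nrow(table))
               sprintf("%.6f,%s,%s", table$time_s, table$kind,
                       ifelse(is.na(table$bin_index), "",
                              as.character(table$bin_index))))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read annotations written by [write_annotations()]
#' @param path annotation CSV path.
#' @return an [annotation_table()].
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c("numeric", "character", "integer"))
  annotation_table(df$time_s, df$kind, df$bin_index)
}
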