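#' Preprocessing configuration
#'
#' Band edges follow the analysis bands for sternal cardiomechanical signals:
#' 4--40 Hz for accelerations, 1--20 Hz for angular rates, 0.1--2 Hz for the
#' respiration channels. Artifact screening uses non-overlapping 500 ms
#' frames and flags frames whose RMS exceeds `rms_median_factor` times the
#' median frame RMS.
#'
#' @param frame_ms artifact-screening frame length (ms).
#' @param rms_median_factor flagging threshold as a multiple of the median
#'   frame RMS.
#' @param acc_band_hz accelerometer cardiac band, `c(low, high)` Hz.
#' @param gyro_band_hz gyroscope cardiac band, `c(low, high)` Hz.
#' @param resp_band_hz respiration band, `c(low, high)` Hz.
#' @param filter_order Butterworth order (applied forward-backward).
#' @param zero_phase logical; apply the filter forward-backward.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(frame_ms = 500, rms_median_factor = 3,
                              acc_band_hz = c(4, 40), gyro_band_hz = c(1, 20),
                              resp_band_hz = c(0.1, 2),
                              filter_order = 4, zero_phase = TRUE) {
  if (!is_scalar_num(frame_ms) || frame_ms <= 0) stopf("frame_ms must be positive")
  for (nm in c("acc_band_hz", "gyro_band_hz", "resp_band_hz")) {
    b <- get(nm)
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2])
      stopf("%s must satisfy 0 < low < high", nm)
  }
  structure(list(frame_ms = frame_ms, rms_median_factor = rms_median_factor,
                 acc_band_hz = acc_band_hz, gyro_band_hz = gyro_band_hz,
                 resp_band_hz = resp_band_hz, filter_order = filter_order,
                 zero_phase = zero_phase),
            class = "preprocess_config")
}

#' Frame-wise RMS artifact removal
#'
#' Splits the channel into consecutive non-overlapping frames (500 ms by
#' default), computes each frame's RMS, and flags frames whose RMS exceeds
#' `rms_median_factor` times the median frame RMS. The flagged frames
#' localize a spike; its actual beginning and end are then refined by
#' walking outward from the flagged run while a short-window amplitude
#' envelope stays above 1.5 x the median level (an artifact straddling a
#' frame boundary is thereby removed in full even when the neighbouring
#' frame's RMS stays under threshold). The samples strictly between the
#' spike's beginning and end are replaced by zeros, with a 10 ms linear
#' taper just inside the boundaries to avoid step discontinuities. Samples
#' outside the reported windows are returned bit-identical.
#'
#' All RMS statistics and the zero level are taken relative to the channel
#' mean: a static offset (gravity on the accelerometer z axis) would
#' otherwise swamp the frame RMS ratios and zeroing would cut a step into
#' the record.
#'
#' @param x numeric channel.
#' @param fs sampling rate (Hz).
#' @param config a [preprocess_config()].
#' @return list with `clean` (modified channel), `windows` (data.frame of
#'   zeroed spike extents `start_s`/`end_s`), and `flagged_frames` (integer
#'   frame indices, 1-based).
#' @export
remove_artifacts <- function(x, fs, config = preprocess_config()) {
  frame_len <- round(config$frame_ms / 1000 * fs)
  n <- length(x)
  if (n < frame_len) stopf("channel shorter than one %g ms frame", config$frame_ms)
  n_frames <- floor(n / frame_len)
  idx <- rep(seq_len(n_frames), each = frame_len)
  used <- n_frames * frame_len
  mu <- mean(x)
  xc <- x - mu
  frame_rms <- sqrt(tapply(xc[seq_len(used)]^2, idx, mean))
  med <- stats::median(frame_rms)
  flagged <- which(frame_rms > config$rms_median_factor * med)  # 0 > 3*0 is FALSE
  clean <- x
  windows <- data.frame(start_s = numeric(0), end_s = numeric(0))
  if (length(flagged)) {
    amp <- moving_average(abs(xc), round(0.05 * fs))
    amp_thr <- 1.5 * med
    runs <- split(flagged, cumsum(c(1, diff(flagged) != 1)))
    for (r in runs) {
      first <- (r[1] - 1L) * frame_len + 1L
      last <- min(n, r[length(r)] * frame_len)
      while (first > 1L && amp[first - 1L] > amp_thr) first <- first - 1L
      while (last < n && amp[last + 1L] > amp_thr) last <- last + 1L
      if (last - first < 2L) next
      clean <- zero_window(clean, first, last, fs, mu)
      windows <- rbind(windows,
                       data.frame(start_s = (first - 1) / fs, end_s = last / fs))
    }
  }
  list(clean = clean, windows = windows, flagged_frames = as.integer(flagged))
}

# Zero the fluctuation (value - level) strictly inside [first, last], with a
# 10 ms linear taper just inside the boundaries.
zero_window <- function(x, first, last, fs, level = 0) {
  taper_len <- round(0.010 * fs)
  interior <- (first + 1L):(last - 1L)
  orig <- x[interior]
  x[interior] <- level
  if (taper_len > 1 && length(interior) > 2 * taper_len) {
    ramp <- seq(1, 0, length.out = taper_len)
    lo <- seq_len(taper_len)
    hi <- (length(interior) - taper_len + 1L):length(interior)
    x[interior[lo]] <- level + (orig[lo] - level) * ramp
    x[interior[hi]] <- level + (orig[hi] - level) * rev(ramp)
  }
  x
}

# Zero-phase Butterworth band-pass; decimates first when the band lies far
# below Nyquist (direct transfer-function realization is unstable there),
# then interpolates back onto the original grid.
bp_filter <- function(x, fs, band, order = 4, zero_phase = TRUE) {
  if (band[2] >= fs / 2) stopf("band high edge %g Hz must be below Nyquist %g Hz",
                               band[2], fs / 2)
  if (band[1] <= 0 || band[1] >= band[2]) stopf("invalid band [%g, %g]", band[1], band[2])
  x <- x - mean(x)   # large DC (e.g. gravity) otherwise rings at the edges
  n <- length(x)
  # odd-reflection padding suppresses the start/end transients that one-pass
  # decimation filters and plain forward-backward filtering leave on finite
  # records
  p <- min(n - 1L, round(3 * fs / band[1]))
  xp <- if (p > 0)
    c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  else x
  apply_bp <- function(v, rate) {
    bt <- signal::butter(order, band / (rate / 2), type = "pass")
    if (zero_phase) signal::filtfilt(bt, v) else
      as.numeric(signal::filter(bt, v))
  }
  fac <- floor(fs / (10 * band[2]))
  y <- if (fac >= 4) {
    xd <- signal::decimate(xp, fac, ftype = "fir")
    yd <- apply_bp(xd, fs / fac)
    td <- (seq_along(yd) - 1) * fac / fs
    t_full <- (seq_along(xp) - 1) / fs
    stats::approx(td, yd, xout = t_full, rule = 2)$y
  } else {
    apply_bp(xp, fs)
  }
  y[(p + 1):(p + n)]
}

#' Zero-phase band-pass filter
#'
#' 4th-order Butterworth applied forward-backward (zero phase), so event
#' timing is preserved. DC is rejected: a constant input maps to (numerical)
#' zero.
#'
#' @param x numeric channel.
#' @param fs sampling rate (Hz).
#' @param band_hz `c(low, high)` band edges in Hz.
#' @param config a [preprocess_config()] (supplies `filter_order` and
#'   `zero_phase`).
#' @return filtered channel, same length as `x`.
#' @export
bandpass <- function(x, fs, band_hz, config = preprocess_config()) {
  bp_filter(x, fs, band_hz, order = config$filter_order,
            zero_phase = config$zero_phase)
}

#' Zero-mean, unit-variance normalization
#'
#' @param x numeric channel with non-zero variance.
#' @return standardized channel.
#' @export
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stopf("cannot z-score a constant channel")
  (x - mean(x)) / s
}
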