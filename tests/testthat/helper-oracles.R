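# Independent reference implementations and signal builders used as oracles.

# Brute-force multiscale peak detector: double loop, same boundary
# conventions as documented for ampd_peaks (out-of-range fails the scale
# statistic, passes vacuously in extraction; endpoints excluded).
ampd_oracle <- function(x, fs = NULL, max_scale_s = NULL) {
  n <- length(x)
  if (n < 3) return(integer(0))
  K <- max(1L, (n - 1L) %/% 2L)
  if (!is.null(max_scale_s)) K <- min(K, max(1L, floor(max_scale_s * fs)))
  gamma <- integer(K)
  for (k in seq_len(K)) {
    cnt <- 0L
    for (i in seq_len(n)) {
      is_max <- (i - k >= 1L) && (i + k <= n) &&
        x[i] > x[i - k] && x[i] > x[i + k]
      if (!is_max) cnt <- cnt + 1L
    }
    gamma[k] <- cnt
  }
  lambda <- which.min(gamma)
  peaks <- integer(0)
  for (i in 2:(n - 1)) {
    good <- TRUE
    for (k in seq_len(lambda)) {
      okl <- (i - k < 1L) || x[i] > x[i - k]
      okr <- (i + k > n) || x[i] > x[i + k]
      if (!(okl && okr)) { good <- FALSE; break }
    }
    if (good) peaks <- c(peaks, i)
  }
  peaks
}

# Hand-written damped-oscillation burst, unit peak.
oracle_gabor <- function(fs, f0, sigma) {
  half <- round(4 * sigma * fs)
  tt <- (-half:half) / fs
  k <- exp(-tt^2 / (2 * sigma^2)) * sin(2 * pi * f0 * tt)
  k / max(abs(k))
}

# Double-burst train: a systolic burst every `period` (with optional IBI
# jitter) and a weaker, sharper diastolic burst `eject` later.
double_burst_train <- function(fs, dur, period, eject, jit = 0.005,
                               rel_amp = 0.4, seed = 1) {
  set.seed(seed)
  n <- round(dur * fs)
  k_sys <- oracle_gabor(fs, 15, 0.013)
  k_dia <- oracle_gabor(fs, 25, 0.006)
  beats <- cumsum(c(0.5, pmax(0.4, rnorm(ceiling(dur / period) + 5,
                                         period, jit))))
  beats <- beats[beats < dur - 0.5]
  add_bursts <- function(x, at, w, kern) {
    half <- (length(kern) - 1) %/% 2
    for (a in at) {
      c_idx <- round(a * fs) + 1L
      lo <- max(1L, c_idx - half); hi <- min(n, c_idx + half)
      klo <- 1L + (lo - (c_idx - half)); khi <- length(kern) - ((c_idx + half) - hi)
      x[lo:hi] <- x[lo:hi] + w * kern[klo:khi]
    }
    x
  }
  x <- add_bursts(numeric(n), beats, 1, k_sys)
  if (!is.null(eject)) x <- add_bursts(x, beats + eject, rel_amp, k_dia)
  list(x = x, beats = beats)
}

expect_no_match_times <- function(a, b, tol) {
  expect_true(all(vapply(a, function(t) min(abs(b - t)) > tol, logical(1))))
}
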