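#' Fuse dorsoventral acceleration and superior-inferior angular rate by ICA
#'
#' The two cardiac-carrying channels are modeled as a 2x2 linear mixture of
#' two latent precordial vibration sources (myocardial movement and blood-flow
#' ballistic forces). A fastICA-style estimator (whitening followed by a
#' symmetric fixed-point iteration maximizing non-Gaussianity via the
#' fourth-moment contrast) recovers the sources; the cardiac component must
#' be super-Gaussian (positive excess kurtosis -- cardiac burst trains are
#' strongly spiky, while sinusoid-like interference is sub-Gaussian) and,
#' among super-Gaussian candidates, is the one whose autocorrelation has the
#' more prominent side peak in the physiological 0.25--2 s lag band (a lone
#' motion-artifact residue is spiky but not rhythmic). The component's arbitrary sign is fixed so that the
#' median amplitude at its envelope peaks is positive (downstream beat search
#' assumes positive deflections).
#'
#' @param acc_z preprocessed (band-passed, standardized) accelerometer
#'   z channel.
#' @param gyro_y preprocessed gyroscope y channel, same length.
#' @param fs sampling rate (Hz); used by the component-selection heuristics.
#' @param seed RNG seed for the fixed-point initialization.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the rotation update.
#' @return object of class `ica_fusion`: list with `sources` (2 x n matrix),
#'   `mixing` (2 x 2 estimated mixing matrix, observations = mixing %*%
#'   sources), `selected` (1 or 2), and `cardiac` (the selected component,
#'   unit variance).
#' @export
ica_fuse <- function(acc_z, gyro_y, fs, seed = 1, max_iter = 200, tol = 1e-8) {
  if (length(acc_z) != length(gyro_y))
    stopf("acc_z and gyro_y must have the same length")
  n <- length(acc_z)
  if (n < 16) stopf("channels too short for ICA")
  x1 <- zscore(acc_z); x2 <- zscore(gyro_y)
  r12 <- stats::cor(x1, x2)
  if (abs(r12) > 1 - 1e-6)
    stopf(paste("acc_z and gyro_y are collinear (|r| = %.8f); ICA is rank",
                "deficient -- fall back to single-channel processing"), abs(r12))
  X <- rbind(x1, x2)
  # whitening
  C <- X %*% t(X) / n
  eg <- eigen(C, symmetric = TRUE)
  wh <- diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  dewh <- eg$vectors %*% diag(sqrt(eg$values))
  Z <- wh %*% X

  sym_decorrelate <- function(W) {
    sv <- svd(W)
    sv$u %*% t(sv$v)
  }
  W <- with_seed(seed, matrix(stats::rnorm(4), 2, 2))
  W <- sym_decorrelate(W)
  tZ <- t(Z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    W_new <- (WZ^3 %*% tZ) / n - 3 * W
    W_new <- sym_decorrelate(W_new)
    delta <- 1 - min(abs(diag(W_new %*% t(W))))
    W <- W_new
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    stopf("ICA fixed-point iteration did not converge after %d iterations", max_iter)
  S <- W %*% Z                       # unit-variance, zero-mean sources
  mixing <- dewh %*% t(W)            # X ~ mixing %*% S

  kurt <- apply(S, 1, function(s) mean(s^4) - 3)
  side_prom <- function(s) {
    lags <- round(c(0.25, 2) * fs)
    r <- norm_autocorr(s, min(lags[2], length(s) - 1))
    seg <- r[(lags[1] + 1):length(r)]
    if (length(seg) < 3) return(0)
    pk <- local_maxima(seg)
    if (!length(pk)) 0 else max(seg[pk])
  }
  # cardiac component = spiky (super-Gaussian) AND rhythmic: positive excess
  # kurtosis gates the candidates (rejects sinusoid-like interference, which
  # is sub-Gaussian); among spiky candidates the stronger physiological-band
  # autocorrelation side peak decides (a lone artifact residue is spiky but
  # not rhythmic)
  prom <- c(side_prom(S[1, ]), side_prom(S[2, ]))
  spiky <- which(kurt > 0)
  selected <- if (length(spiky) == 1) spiky
              else if (length(spiky) == 2) which.max(prom)
              else which.max(kurt)
  cardiac <- S[selected, ]

  env <- envelope_signal(cardiac, fs)
  pks <- envelope_peaks(env, fs)
  if (length(pks) && stats::median(cardiac[pks]) < 0) {
    cardiac <- -cardiac
    S[selected, ] <- cardiac
    mixing[, selected] <- -mixing[, selected]
  }
  structure(list(sources = S, mixing = mixing, selected = selected,
                 cardiac = cardiac, iterations = it),
            class = "ica_fusion")
}

#' Smooth amplitude envelope of the cardiac signal
#'
#' Magnitude of the analytic signal smoothed by a moving average. The
#' default 250 ms window is chosen so that the systolic complex and the
#' diastolic complex ~300--400 ms later merge into one dominant non-negative
#' lobe per heartbeat, which is what the downstream multiscale peak detector
#' assumes.
#'
#' @param x cardiac signal samples (band-limited).
#' @param fs sampling rate (Hz).
#' @param smooth_ms moving-average length (ms).
#' @return non-negative envelope, same length as `x`.
#' @export
envelope_signal <- function(x, fs, smooth_ms = 250) {
  env <- Mod(analytic_signal(x))
  moving_average(env, round(smooth_ms / 1000 * fs))
}

#' Automatic multiscale peak detection (AMPD)
#'
#' Scale-space local-maxima voting: sample `i` is a `k`-scale maximum iff
#' `x[i] > x[i-k]` and `x[i] > x[i+k]` (out-of-range neighbours fail the
#' test). The global scale `lambda` minimizes the per-scale count of
#' non-maxima marks; peaks are the samples that are maxima at every scale
#' `1..lambda`.
#'
#' @param x numeric signal, length >= 3.
#' @param fs sampling rate (Hz); only needed when `max_scale_s` is given.
#' @param max_scale_s optional cap on the largest scale, in seconds
#'   (`K <= max_scale_s * fs`). Keeps cost linear in the expected peak
#'   spacing rather than the record length.
#' @return integer vector of peak sample indices (1-based), possibly empty.
#' @export
ampd_peaks <- function(x, fs = NULL, max_scale_s = NULL) {
  n <- length(x)
  if (n < 3) return(integer(0))
  K <- max(1L, (n - 1L) %/% 2L)
  if (!is.null(max_scale_s)) {
    if (is.null(fs)) stopf("fs required when max_scale_s is given")
    K <- min(K, max(1L, floor(max_scale_s * fs)))
  }
  # strict in-range k-scale maxima (out-of-range neighbours fail): used for
  # the scale statistic, mirroring the random-filled boundary entries of the
  # original local-maxima scalogram
  strict_max <- function(k) {
    ok <- rep(FALSE, n)
    i <- (k + 1L):(n - k)
    ok[i] <- x[i] > x[i - k] & x[i] > x[i + k]
    ok
  }
  # boundary-tolerant variant for peak extraction: a comparison that would
  # leave the record passes vacuously (record endpoints are never peaks)
  lenient_max <- function(k) {
    il <- seq_len(n) - k; ir <- seq_len(n) + k
    okl <- il < 1L; okl[!okl] <- x[!okl] > x[il[!okl]]
    okr <- ir > n; okr[!okr] <- x[!okr] > x[ir[!okr]]
    okl & okr
  }
  gamma <- vapply(seq_len(K), function(k) n - sum(strict_max(k)), integer(1))
  lambda <- which.min(gamma)
  is_peak <- rep(TRUE, n)
  is_peak[c(1L, n)] <- FALSE
  for (k in seq_len(lambda)) is_peak <- is_peak & lenient_max(k)
  which(is_peak)
}

#' Locate envelope peaks
#'
#' Runs AMPD on the (smooth) envelope, decimated to ~100 Hz for speed, and
#' refines each detected peak to the envelope's local maximum at full rate.
#' The scale cap defaults to 0.6 s, just under the shortest plausible
#' resting inter-beat interval: larger scales let the multiscale test "skip
#' over" neighbouring beat lobes, which silently drops beats on sparse
#' envelopes.
#'
#' @param env envelope samples (non-negative, smooth).
#' @param fs sampling rate (Hz).
#' @param max_scale_s AMPD scale cap (s).
#' @return integer vector of full-rate peak sample indices.
#' @export
envelope_peaks <- function(env, fs, max_scale_s = 0.6) {
  n <- length(env)
  stride <- max(1L, floor(fs / 100))
  idx_d <- seq(1L, n, by = stride)
  pk_d <- ampd_peaks(env[idx_d], fs / stride, max_scale_s)
  if (!length(pk_d)) return(integer(0))
  vapply(idx_d[pk_d], function(i) {
    lo <- max(1L, i - stride); hi <- min(n, i + stride)
    as.integer(lo + which.max(env[lo:hi]) - 1L)
  }, integer(1))
}

#' Beat set
#'
#' @param beat_times refined beat times (s), strictly increasing.
#' @param envelope_peaks pre-refinement envelope peak times (s).
#' @return object of class `beat_set` with `beat_times`, `envelope_peaks`,
#'   and inter-beat intervals `ibi`.
#' @export
beat_set <- function(beat_times, envelope_peaks = numeric(0)) {
  beat_times <- as.numeric(beat_times)
  if (length(beat_times) > 1 && any(diff(beat_times) <= 0))
    stopf("beat times must be strictly increasing")
  structure(list(beat_times = beat_times,
                 envelope_peaks = as.numeric(envelope_peaks),
                 ibi = diff(beat_times)),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  cat(sprintf("<beat_set> %d beats", length(x$beat_times)))
  if (length(x$ibi))
    cat(sprintf(", mean IBI %.3f s (%.1f bpm)", mean(x$ibi), 60 / mean(x$ibi)))
  cat("\n")
  invisible(x)
}

#' Relocate envelope peaks onto the cardiac signal with adaptive thresholds
#'
#' For each envelope peak a +/- `window_ms` search window is scanned for the
#' largest local maximum of the cardiac signal; if none exists the envelope
#' peak location itself is kept. The candidate is accepted when its amplitude
#' exceeds the adaptive threshold `THR = N + 0.25 (S - N)`, where the signal
#' and noise peak levels are updated as `S <- 0.125 p + 0.875 S` on
#' acceptance and `N <- 0.125 p + 0.875 N` on rejection. Since processing is
#' offline, the signal level is initialized from the median candidate
#' amplitude (robust to an outlying first complex). A 0.25 s refractory
#' period keeps the larger-amplitude beat of any closer pair.
#'
#' @param cardiac cardiac signal samples (positive-deflection convention).
#' @param envelope_peaks integer sample indices of envelope peaks, sorted.
#' @param fs sampling rate (Hz).
#' @param window_ms half-width of the relocation search window (ms).
#' @param refractory_s minimum inter-beat interval (s).
#' @return a [beat_set()].
#' @export
refine_beats <- function(cardiac, envelope_peaks, fs, window_ms = 150,
                         refractory_s = 0.25) {
  n <- length(cardiac)
  if (!length(envelope_peaks))
    return(beat_set(numeric(0)))
  w <- round(window_ms / 1000 * fs)
  locate <- function(p) {
    lo <- max(1L, p - w); hi <- min(n, p + w)
    seg <- cardiac[lo:hi]
    lm <- local_maxima(seg)
    if (length(lm)) as.integer(lo + lm[which.max(seg[lm])] - 1L) else p
  }
  cands <- vapply(as.integer(envelope_peaks), locate, integer(1))
  S_lvl <- max(stats::median(cardiac[cands]), 0)
  N_lvl <- 0
  acc_idx <- integer(0); acc_amp <- numeric(0)
  for (cand in cands) {
    amp <- cardiac[cand]
    thr <- N_lvl + 0.25 * (S_lvl - N_lvl)
    if (amp > thr) {
      if (length(acc_idx) &&
          (cand - acc_idx[length(acc_idx)]) / fs < refractory_s) {
        if (amp > acc_amp[length(acc_amp)]) {
          acc_idx[length(acc_idx)] <- cand
          acc_amp[length(acc_amp)] <- amp
          S_lvl <- 0.125 * amp + 0.875 * S_lvl
        }
      } else {
        acc_idx <- c(acc_idx, cand)
        acc_amp <- c(acc_amp, amp)
        S_lvl <- 0.125 * amp + 0.875 * S_lvl
      }
    } else {
      N_lvl <- 0.125 * amp + 0.875 * N_lvl
    }
  }
  beat_set((acc_idx - 1) / fs, (as.integer(envelope_peaks) - 1) / fs)
}

#' Segment-wise cardiac cycle and ejection estimation by autocorrelation
#'
#' The cardiac signal is cut into non-overlapping segments (20 s by default)
#' and each segment's normalized autocorrelation is computed up to
#' `max_lag_s`. The cycle length is the lag of the largest autocorrelation
#' local maximum beyond a 0.25 s physiological floor; the ejection time is
#' the lag of the largest local maximum strictly between the floor and the
#' cycle lag (the "semi side-peak" left by the diastolic burst train). The
#' cycle peak must exceed a height floor of 0.1 x the zero-lag value or the
#' segment is marked invalid. Semi side-peak candidates are scored by their
#' prominence over a +/- 25 ms base (>= half the floor) and must lie at
#' least 50 ms before the cycle peak and within the physiological 0.6 s
#' ejection bound; near ties (10%) go to the smaller lag, and with no
#' qualifying candidate the ejection falls back to 0.35 x cycle.
#'
#' "First dominant" is taken literally: among side peaks within
#' `dominance_frac` (70%) of the tallest, the smallest lag wins. This guards
#' against period doubling, since beat-to-beat jitter attenuates the
#' two-cycle autocorrelation peak more than the one-cycle peak but can make
#' individual realizations trade places.
#'
#' @param cardiac cardiac signal samples.
#' @param fs sampling rate (Hz).
#' @param segment_s segment length (s).
#' @param max_lag_s maximum autocorrelation lag (s).
#' @param floor_s physiological lag floor (s); 0.25 s corresponds to 240 bpm.
#' @param prominence_floor minimum normalized autocorrelation height.
#' @param dominance_frac fraction of the tallest side peak a candidate must
#'   reach to count as dominant.
#' @return object of class `cycle_segmentation`: data.frame `segments` with
#'   columns `start_s`, `end_s`, `cycle_len_s`, `ejection_s`, `valid`,
#'   `ejection_fallback`.
#' @export
segment_cycles <- function(cardiac, fs, segment_s = 20, max_lag_s = 5,
                           floor_s = 0.25, prominence_floor = 0.1,
                           dominance_frac = 0.7) {
  n <- length(cardiac)
  seg_len <- round(segment_s * fs)
  if (n < seg_len)
    stopf("recording (%.1f s) shorter than one %g-s segment", n / fs, segment_s)
  n_seg <- floor(n / seg_len)
  out <- data.frame(start_s = numeric(0), end_s = numeric(0),
                    cycle_len_s = numeric(0), ejection_s = numeric(0),
                    valid = logical(0), ejection_fallback = logical(0))
  for (s in seq_len(n_seg)) {
    i0 <- (s - 1L) * seg_len + 1L
    seg <- cardiac[i0:(i0 + seg_len - 1L)]
    if (seg_len < 2 * round(max_lag_s * fs)) {
      warnf("segment %d shorter than twice the maximum lag; skipped", s)
      next
    }
    max_lag <- round(max_lag_s * fs)
    r <- norm_autocorr(seg, max_lag)
    floor_lag <- round(floor_s * fs)
    pk_all <- local_maxima(r)
    pk_all <- pk_all[pk_all > floor_lag + 1L]
    pk <- pk_all[r[pk_all] >= prominence_floor]   # cycle-peak candidates
    row <- data.frame(start_s = (i0 - 1) / fs, end_s = (i0 - 1 + seg_len) / fs,
                      cycle_len_s = NA_real_, ejection_s = NA_real_,
                      valid = FALSE, ejection_fallback = FALSE)
    if (length(pk)) {
      h_max <- max(r[pk])
      cyc_pk <- pk[r[pk] >= dominance_frac * h_max][1]  # first dominant
      cycle <- (cyc_pk - 1) / fs
      # candidates must clear the cycle peak's own carrier structure and
      # stay within the physiological ejection range (<= 0.6 s)
      semi <- pk_all[pk_all < cyc_pk - round(0.05 * fs) &
                       (pk_all - 1) / fs <= 0.6]
      # score semi candidates by prominence over a +/- 25 ms base: the
      # systole->diastole lag is an exact same-beat distance and gives a
      # sharp peak, while its mirror (cycle minus ejection) spans adjacent
      # beats and is smeared flat by beat-to-beat jitter
      d <- round(0.025 * fs)
      prom <- vapply(semi, function(p) {
        lo <- max(1L, p - d); hi <- min(length(r), p + d)
        r[p] - (r[lo] + r[hi]) / 2
      }, numeric(1))
      semi <- semi[prom >= prominence_floor / 2]
      prom <- prom[prom >= prominence_floor / 2]
      if (length(semi)) {
        best <- max(prom)
        semi_pk <- semi[prom >= best * 0.9][1]   # near-tie -> earliest
        ejection <- (semi_pk - 1) / fs
        fallback <- FALSE
      } else {
        ejection <- 0.35 * cycle
        fallback <- TRUE
      }
      row$cycle_len_s <- cycle
      row$ejection_s <- ejection
      row$valid <- TRUE
      row$ejection_fallback <- fallback
    }
    out <- rbind(out, row)
  }
  structure(list(segments = out, segment_s = segment_s, fs = fs),
            class = "cycle_segmentation")
}

#' @export
print.cycle_segmentation <- function(x, ...) {
  ok <- x$segments$valid
  cat(sprintf("<cycle_segmentation> %d segments (%d valid)",
              nrow(x$segments), sum(ok)))
  if (any(ok))
    cat(sprintf(", median cycle %.3f s, median ejection %.3f s",
                stats::median(x$segments$cycle_len_s[ok]),
                stats::median(x$segments$ejection_s[ok])))
  cat("\n")
  invisible(x)
}

#' Per-beat cardiac gating bins
#'
#' For a beat at `b` with successor `b2` and segment ejection time `e`, the
#' first `n_bins - 1` bins equally divide the systolic interval `[b, b + e)`
#' and the last bin spans the diastolic remainder `[b + e, b2)`. An
#' ejection time exceeding 90% of the beat interval is clamped to 90% (with
#' a warning) so the diastolic bin is never empty.
#'
#' @param beats a [beat_set()].
#' @param seg a [segment_cycles()] result.
#' @param n_bins total number of bins (>= 2).
#' @return list with `boundaries` (per-beat list of bin start times),
#'   `table` (an [annotation_table()] of kind `bin_boundary` with
#'   `bin_index`), and `n_bins`.
#' @export
make_cardiac_bins <- function(beats, seg, n_bins = 5) {
  if (n_bins < 2) stopf("n_bins must be >= 2")
  bt <- beats$beat_times
  if (length(bt) < 2) stopf("need at least two beats to form bins")
  segs <- seg$segments
  eject_for <- function(b) {
    row <- which(segs$valid & segs$start_s <= b & b < segs$end_s)
    if (!length(row)) {
      row <- which(segs$valid)
      if (!length(row)) return(NA_real_)
      row <- row[which.min(abs((segs$start_s[row] + segs$end_s[row]) / 2 - b))]
    } else row <- row[1]
    segs$ejection_s[row]
  }
  res <- vector("list", length(bt) - 1L)
  times <- numeric(0); bins <- integer(0)
  for (i in seq_len(length(bt) - 1L)) {
    b <- bt[i]; b2 <- bt[i + 1]
    e <- eject_for(b)
    if (is.na(e)) next
    if (e > 0.9 * (b2 - b)) {
      warnf("ejection %.3f s leaves no diastolic bin in the %.3f s beat interval at t = %.2f s; clamped",
            e, b2 - b, b)
      e <- 0.9 * (b2 - b)
    }
    bounds <- c(b + (0:(n_bins - 2)) * e / (n_bins - 1), b + e)
    res[[i]] <- bounds
    times <- c(times, bounds)
    bins <- c(bins, seq_len(n_bins))
  }
  tab <- annotation_table(times, rep("bin_boundary", length(times)), bins)
  list(boundaries = res, table = tab, n_bins = n_bins)
}
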