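GRAVITY <- 9.80665  # m/s^2

#' Chest pitch angle from gravity projections
#'
#' Pitch (inclination about the lateral x axis) from the accelerometer:
#' exact form `beta = arctan(Accy / sqrt(Accz^2 + Accx^2))`; small-angle
#' approximation `beta ~ Accy / g`.
#'
#' @param acc n x 3 matrix of accelerations (m/s^2), columns x, y, z.
#' @param mode `"exact"` (default) or `"approx"`.
#' @return pitch angle channel in radians.
#' @export
adr_pitch <- function(acc, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  acc <- as.matrix(acc)
  if (mode == "approx") return(acc[, 2] / GRAVITY)
  den <- sqrt(acc[, 3]^2 + acc[, 1]^2)
  bad <- which(den == 0)
  if (length(bad)) stopf("zero gravity denominator at sample %d", bad[1])
  atan(acc[, 2] / den)
}

#' Chest roll angle from gravity projections
#'
#' Roll (inclination about the longitudinal y axis): exact form
#' `alpha = arctan(Accx / sqrt(Accz^2 + Accy^2))`; approximation
#' `alpha ~ Accx / g`.
#'
#' @inheritParams adr_pitch
#' @return roll angle channel in radians.
#' @export
adr_roll <- function(acc, mode = c("exact", "approx")) {
  mode <- match.arg(mode)
  acc <- as.matrix(acc)
  adr_pitch(acc[, c(2, 1, 3), drop = FALSE], mode)
}

#' Integrate an angular rate into a tilt angle
#'
#' Cumulative trapezoidal integration (which also low-pass filters) followed
#' by drift removal: the line through the first and last samples is
#' subtracted (a least-squares line would bias sinusoid amplitudes, since a
#' sine train is not orthogonal to a ramp over a finite record) and the
#' result is centred, so the output is exactly zero-mean.
#'
#' @param rate angular rate channel (rad/s).
#' @param fs sampling rate (Hz).
#' @param detrend remove integration drift after integrating
#'   (default `TRUE`).
#' @return angle channel (rad).
#' @export
gdr_integrate <- function(rate, fs, detrend = TRUE) {
  if (any(!is.finite(rate))) stopf("non-finite samples in angular rate")
  ang <- as.numeric(pracma::cumtrapz(rate)) / fs
  if (detrend) {
    n <- length(ang)
    if (n > 1) {
      slope <- (ang[n] - ang[1]) / (n - 1)
      ang <- ang - (ang[1] + slope * (seq_len(n) - 1))
    }
    ang <- ang - mean(ang)
  }
  ang
}

#' Extract the five chest-inclination respiration channels
#'
#' Computes the accelerometer-derived roll and pitch (`adr_x`, `adr_y`), the
#' integrated gyroscope tilt angles (`gdr_x`, `gdr_y`, `gdr_z`), band-passes
#' each to the respiration band (0.1--2 Hz) and removes the mean. The
#' channels are stacked row-wise as `R = [ADRx; ADRy; GDRx; GDRy; GDRz]`.
#'
#' @param rec an [imu_recording()].
#' @param config a [preprocess_config()] (supplies `resp_band_hz`).
#' @param mode tilt formula mode passed to [adr_pitch()]/[adr_roll()].
#' @return object of class `respiration_set`: list with the five channels,
#'   `fs`, the 5 x n matrix `R`, and `polarity_flags`.
#' @export
extract_respiration <- function(rec, config = preprocess_config(),
                                mode = "exact") {
  stopifnot(inherits(rec, "imu_recording"))
  band <- config$resp_band_hz
  prep <- function(x) {
    y <- bandpass(x, rec$fs, band, config)
    y - mean(y)
  }
  chans <- list(
    adr_x = prep(adr_roll(rec$acc, mode)),
    adr_y = prep(adr_pitch(rec$acc, mode)),
    gdr_x = prep(gdr_integrate(rec$gyro[, 1], rec$fs)),
    gdr_y = prep(gdr_integrate(rec$gyro[, 2], rec$fs)),
    gdr_z = prep(gdr_integrate(rec$gyro[, 3], rec$fs)))
  R <- do.call(rbind, chans)
  rownames(R) <- names(chans)
  structure(c(chans,
              list(fs = rec$fs, R = R,
                   polarity_flags = stats::setNames(rep(1, 5), names(chans)))),
            class = "respiration_set")
}

#' Polarity correction against the dorsoventral reference
#'
#' The accelerometer z channel band-passed to the respiration band serves as
#' the polarity reference (it tracks longitudinal chest movement); any
#' inclination channel correlating negatively with it is inverted. Applying
#' the correction twice is a no-op.
#'
#' @param set a [extract_respiration()] result.
#' @param rec the [imu_recording()] the set was extracted from.
#' @param config a [preprocess_config()].
#' @return the corrected `respiration_set`, with updated `polarity_flags`
#'   and the reference stored as `reference`.
#' @export
polarity_correct <- function(set, rec, config = preprocess_config()) {
  stopifnot(inherits(set, "respiration_set"), inherits(rec, "imu_recording"))
  ref <- bandpass(rec$acc[, 3], rec$fs, config$resp_band_hz, config)
  if (stats::sd(ref) == 0) stopf("zero-variance polarity reference (acc_z)")
  nm <- c("adr_x", "adr_y", "gdr_x", "gdr_y", "gdr_z")
  for (ch in nm) {
    r <- suppressWarnings(stats::cor(set[[ch]], ref))
    if (is.finite(r) && r < 0) {
      set[[ch]] <- -set[[ch]]
      set$R[ch, ] <- -set$R[ch, ]
      set$polarity_flags[ch] <- -set$polarity_flags[ch]
    }
  }
  set$reference <- ref
  set
}

#' Fuse the respiration channels by principal component analysis
#'
#' Channels are standardized and the 5 x 5 correlation matrix is
#' eigendecomposed; the fused respiration curve is the projection onto the
#' first eigenvector (unit norm), with its sign fixed to correlate
#' positively with the polarity reference.
#'
#' @param set a polarity-corrected [extract_respiration()] result.
#' @return object of class `fused_respiration`: list with `pc1`,
#'   `explained_var_ratio`, `loadings` (named, unit Euclidean norm), `fs`.
#' @export
pca_fuse <- function(set) {
  stopifnot(inherits(set, "respiration_set"))
  nm <- rownames(set$R)
  sds <- apply(set$R, 1, stats::sd)
  keep <- which(is.finite(sds) & sds > 0)
  if (length(keep) < 2)
    stopf("need at least two finite-variance channels for PCA fusion")
  Z <- sweep(set$R[keep, , drop = FALSE] -
               rowMeans(set$R[keep, , drop = FALSE]), 1, sds[keep], "/")
  C <- Z %*% t(Z) / ncol(Z)
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1]
  pc1 <- as.numeric(t(v) %*% Z)
  evr <- eg$values[1] / sum(pmax(eg$values, 0))
  ref <- set$reference
  if (is.null(ref)) ref <- set$R[keep[1], ]
  if (stats::sd(pc1) > 0 && stats::cor(pc1, ref) < 0) {
    pc1 <- -pc1; v <- -v
  }
  loadings <- stats::setNames(rep(0, length(nm)), nm)
  loadings[keep] <- v
  structure(list(pc1 = pc1, explained_var_ratio = evr, loadings = loadings,
                 fs = set$fs),
            class = "fused_respiration")
}

#' Detect breath cycles on the fused respiration curve
#'
#' AMPD locates candidate maxima on the curve and minima on its negation;
#' candidates closer than half the median inter-peak distance to their
#' predecessor are discarded (keeping the larger-amplitude one), and strict
#' inhalation/exhalation alternation is enforced by dropping the weaker of
#' two same-kind consecutive extrema. Maxima are peak-inhalation events;
#' trigger times are refined to sub-sample precision by parabolic
#' interpolation.
#'
#' @param pc1 fused respiration samples (band-limited to the respiration
#'   band).
#' @param fs sampling rate (Hz).
#' @param max_scale_s AMPD scale cap in seconds (default 15, beyond the
#'   longest plausible breath).
#' @return list with `inhalation_peaks`, `exhalation_troughs` (times, s),
#'   `triggers` (parabolically refined inhalation times, s).
#' @export
detect_breaths <- function(pc1, fs, max_scale_s = 15) {
  n <- length(pc1)
  if (stats::sd(pc1) == 0) stopf("constant respiration signal; no breaths")
  stride <- max(1L, floor(fs / 25))
  xd <- pc1[seq(1L, n, by = stride)]
  fsd <- fs / stride
  refine <- function(idx_d) {
    idx <- (idx_d - 1L) * stride + 1L
    vapply(idx, function(i) {
      lo <- max(1L, i - stride); hi <- min(n, i + stride)
      as.integer(lo + which.max(pc1[lo:hi]) - 1L)
    }, integer(1))
  }
  max_d <- ampd_peaks(xd, fsd, max_scale_s)
  min_d <- ampd_peaks(-xd, fsd, max_scale_s)
  if (length(max_d) < 2 || length(min_d) < 2)
    stopf("fewer than two breaths detected; supply a longer recording")
  maxima <- refine(max_d)
  minima <- vapply((min_d - 1L) * stride + 1L, function(i) {
    lo <- max(1L, i - stride); hi <- min(n, i + stride)
    as.integer(lo + which.min(pc1[lo:hi]) - 1L)
  }, integer(1))

  drop_close <- function(idx, amp) {
    if (length(idx) < 2) return(idx)
    med <- stats::median(diff(idx))
    keep <- idx[1]
    for (i in idx[-1]) {
      prev <- keep[length(keep)]
      if (i - prev < 0.5 * med) {
        if (amp[as.character(i)] > amp[as.character(prev)])
          keep[length(keep)] <- i
      } else keep <- c(keep, i)
    }
    keep
  }
  amp_max <- stats::setNames(pc1[maxima], maxima)
  amp_min <- stats::setNames(-pc1[minima], minima)
  maxima <- drop_close(maxima, amp_max)
  minima <- drop_close(minima, amp_min)

  ev <- rbind(data.frame(i = maxima, kind = 1),
              data.frame(i = minima, kind = -1))
  ev <- ev[order(ev$i), ]
  keep <- rep(TRUE, nrow(ev))
  last <- 1L
  for (j in seq_len(nrow(ev))[-1]) {
    if (ev$kind[j] == ev$kind[last]) {
      a_last <- ev$kind[last] * pc1[ev$i[last]]
      a_j <- ev$kind[j] * pc1[ev$i[j]]
      if (a_j > a_last) { keep[last] <- FALSE; last <- j }
      else keep[j] <- FALSE
    } else last <- j
  }
  ev <- ev[keep, ]
  maxima <- ev$i[ev$kind == 1]
  minima <- ev$i[ev$kind == -1]
  if (length(maxima) < 2 || length(minima) < 2)
    stopf("fewer than two breaths detected; supply a longer recording")
  triggers <- vapply(maxima, function(i) (parabolic_vertex(pc1, i) - 1) / fs,
                     numeric(1))
  list(inhalation_peaks = (maxima - 1) / fs,
       exhalation_troughs = (minima - 1) / fs,
       triggers = triggers)
}

#' Respiratory gating bins
#'
#' Amplitude mode splits the 5th--95th percentile amplitude range of the
#' fused curve into `n_bins` equal bands and labels every sample; phase mode
#' maps each inhalation-to-inhalation interval onto `[0, 2*pi)` and splits it
#' into `n_bins` equal phase bins (samples outside the first/last trigger
#' are `NA`).
#'
#' @param pc1 fused respiration samples.
#' @param fs sampling rate (Hz).
#' @param breaths a [detect_breaths()] result (required for phase mode).
#' @param n_bins number of bins (>= 2).
#' @param mode `"amplitude"` or `"phase"`.
#' @return list with `mode`, `n_bins`, `labels` (per-sample bin index), and
#'   `edges` (amplitude mode only).
#' @export
make_resp_bins <- function(pc1, fs, breaths = NULL, n_bins = 4,
                           mode = c("amplitude", "phase")) {
  mode <- match.arg(mode)
  if (n_bins < 2) stopf("n_bins must be >= 2")
  n <- length(pc1)
  if (mode == "amplitude") {
    q <- stats::quantile(pc1, c(0.05, 0.95), names = FALSE)
    edges <- seq(q[1], q[2], length.out = n_bins + 1)
    lab <- findInterval(pc1, edges, rightmost.closed = TRUE)
    lab <- pmin(pmax(lab, 1L), n_bins)
    list(mode = mode, n_bins = n_bins, labels = as.integer(lab), edges = edges)
  } else {
    if (is.null(breaths)) stopf("phase mode requires detected breaths")
    trig <- breaths$inhalation_peaks
    if (length(trig) < 2) stopf("phase mode needs at least two inhalation peaks")
    tt <- (seq_len(n) - 1) / fs
    lab <- rep(NA_integer_, n)
    for (k in seq_len(length(trig) - 1)) {
      inwin <- tt >= trig[k] & tt < trig[k + 1]
      ph <- (tt[inwin] - trig[k]) / (trig[k + 1] - trig[k])  # [0, 1)
      lab[inwin] <- pmin(n_bins, floor(ph * n_bins) + 1L)
    }
    list(mode = mode, n_bins = n_bins, labels = lab)
  }
}
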