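#' Simulation configuration for synthetic chest recordings
#'
#' Defaults describe a resting supine adult: 60 bpm with mild beat-to-beat
#' variability, systolic-to-diastolic burst delay 350 ms, breathing at 0.25 Hz
#' with slow rate drift, chest tilt amplitude 0.04 rad, cardiac burst
#' amplitudes typical of sternal seismo-/gyrocardiography, sporadic
#' whole-body motion artifacts.
#'
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz.
#' @param hr_bpm mean heart rate (beats per minute).
#' @param hr_sd_bpm beat-to-beat heart-rate jitter, SD in bpm. The default
#'   keeps inter-beat jitter below ~10 ms so that successive complexes stay
#'   phase-coherent at the burst carrier frequency, as real systolic
#'   complexes (reproducible in shape beat to beat) are.
#' @param ejection_ms mean systolic-to-diastolic burst delay (ms).
#' @param ejection_sd_ms SD of the per-beat ejection time (ms).
#' @param resp_rate_hz mean breathing rate (Hz).
#' @param resp_sd_hz SD of the slowly drifting instantaneous breathing rate.
#' @param resp_incl_amp_rad chest pitch amplitude (rad); roll amplitude is
#'   0.6 of this.
#' @param cardiac_amp_acc peak systolic burst amplitude on the accelerometer
#'   z axis (m/s^2).
#' @param cardiac_amp_gyro peak systolic burst amplitude on the gyroscope
#'   y axis (rad/s).
#' @param diastolic_rel_amp diastolic burst amplitude relative to systolic.
#' @param noise_sd white-noise SD as a fraction of each channel's
#'   (mean-removed) signal SD.
#' @param artifact_rate_per_min expected motion-artifact bursts per minute.
#' @param artifact_amp_factor artifact amplitude as a multiple of the
#'   channel's signal RMS.
#' @param seed integer RNG seed; identical seeds give identical recordings.
#' @return a `sim_config` list.
#' @export
sim_config <- function(duration_s = 120, fs = 800,
                       hr_bpm = 60, hr_sd_bpm = 0.5,
                       ejection_ms = 350, ejection_sd_ms = 5,
                       resp_rate_hz = 0.25, resp_sd_hz = 0.02,
                       resp_incl_amp_rad = 0.04,
                       cardiac_amp_acc = 0.1, cardiac_amp_gyro = 0.02,
                       diastolic_rel_amp = 0.4,
                       noise_sd = 0.05,
                       artifact_rate_per_min = 1,
                       artifact_amp_factor = 8,
                       seed = 1) {
  cfg <- as.list(environment())
  for (nm in c("duration_s", "fs", "hr_bpm", "resp_rate_hz"))
    if (!is_scalar_num(cfg[[nm]]) || cfg[[nm]] <= 0) stopf("%s must be positive", nm)
  for (nm in c("hr_sd_bpm", "ejection_sd_ms", "resp_sd_hz", "resp_incl_amp_rad",
               "cardiac_amp_acc", "cardiac_amp_gyro", "diastolic_rel_amp",
               "noise_sd", "artifact_rate_per_min", "artifact_amp_factor"))
    if (!is_scalar_num(cfg[[nm]]) || cfg[[nm]] < 0) stopf("%s must be >= 0", nm)
  if (fs <= 2 * 25) stopf("fs must exceed twice the highest simulated frequency")
  structure(cfg, class = "sim_config")
}

# Gabor-like damped-oscillation burst kernel, symmetric support so the
# kernel centre falls on a sample; unit peak amplitude.
gabor_burst <- function(fs, f_center, sigma_s = 0.013) {
  half <- round(4 * sigma_s * fs)
  tt <- (-half:half) / fs
  k <- exp(-tt^2 / (2 * sigma_s^2)) * sin(2 * pi * f_center * tt)
  k / max(abs(k))
}

# Place kernel k (centred) at fractional sample positions `at` with weights.
place_bursts <- function(n, fs, at_s, weights, kernel) {
  x <- numeric(n)
  half <- (length(kernel) - 1) %/% 2
  for (j in seq_along(at_s)) {
    c_idx <- round(at_s[j] * fs) + 1L
    lo <- c_idx - half; hi <- c_idx + half
    klo <- max(1L, 1L + (1L - lo)); khi <- length(kernel) - max(0L, hi - n)
    lo <- max(1L, lo); hi <- min(n, hi)
    if (lo <= hi) x[lo:hi] <- x[lo:hi] + weights[j] * kernel[klo:khi]
  }
  x
}

#' Simulate a six-axis chest recording with ground truth
#'
#' Generates quasi-periodic cardiac micro-vibration complexes (a systolic
#' burst per beat plus a weaker diastolic burst at the per-beat ejection
#' delay) mixed with channel-specific weights onto the accelerometer z and
#' gyroscope y axes; a slow pitch/roll breathing trajectory projected through
#' gravity onto the accelerometer axes with matching angular rates on the
#' gyroscope; white measurement noise; and sporadic raised-cosine motion
#' artifacts common to all channels.
#'
#' @param config a [sim_config()].
#' @return list with elements `recording` (an [imu_recording()]) and `truth`
#'   (list: `beat_times`, `ejection_times`, `resp_phase`, `pitch`, `roll`,
#'   `inhalation_peaks`, `artifact_windows`, `cardiac_source`).
#' @export
simulate_chest_motion <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    fs <- config$fs
    n <- round(config$duration_s * fs)
    t <- (seq_len(n) - 1) / fs
    if (config$duration_s < 30)
      warnf("duration %.1f s < 30 s: cardiac cycle segmentation needs 20-s segments",
            config$duration_s)

    ## --- cardiac beat train -------------------------------------------------
    ibi_mean <- 60 / config$hr_bpm
    ibi_sd <- config$hr_sd_bpm * 60 / config$hr_bpm^2
    max_beats <- ceiling(config$duration_s / ibi_mean) + 10L
    ibis <- pmax(0.3, stats::rnorm(max_beats, ibi_mean, ibi_sd))
    beats <- 0.5 + cumsum(c(0, ibis))
    # keep only beats whose full complex (diastolic burst + kernel tails)
    # fits inside the record; a truncated boundary complex has no complete
    # signature to detect
    beats <- beats[beats < config$duration_s - 0.8]
    eject <- pmin(0.6, pmax(0.2,
      stats::rnorm(length(beats), config$ejection_ms / 1000,
                   config$ejection_sd_ms / 1000)))

    # Systolic complexes are broader oscillatory bursts; diastolic complexes
    # are weaker, quicker, sharper spikes, so they get a shorter kernel with
    # higher centre frequency.
    k_acc <- gabor_burst(fs, 15, 0.013)
    k_acc_dia <- gabor_burst(fs, 25, 0.006)
    k_gyro <- gabor_burst(fs, 8, 0.013)
    k_gyro_dia <- gabor_burst(fs, 13, 0.006)
    w_sys <- rep(1, length(beats))
    w_dia <- rep(config$diastolic_rel_amp, length(beats))
    s_m <- place_bursts(n, fs, beats, w_sys, k_acc) +
      place_bursts(n, fs, beats + eject, w_dia, k_acc_dia)
    s_b <- place_bursts(n, fs, beats + 0.04, w_sys, k_gyro) +
      place_bursts(n, fs, beats + eject + 0.04, w_dia, k_gyro_dia)
    # Eq-1-style fixed mixing of the two latent sources onto the two cardiac
    # carrying channels.
    acc_card <- config$cardiac_amp_acc * (1.0 * s_m + 0.35 * s_b)
    gyro_card <- config$cardiac_amp_gyro * (0.4 * s_m + 1.0 * s_b)

    ## --- respiration --------------------------------------------------------
    # Instantaneous rate = mean + slow drift (smoothed noise, phase jitter);
    # smoothing runs on a padded draw so edge samples keep the nominal SD.
    w <- round(10 * fs)
    raw <- stats::rnorm(n + w, 0, 1)
    cs <- c(0, cumsum(raw))
    drift <- config$resp_sd_hz * sqrt(w) * (cs[(w + 1):(w + n)] - cs[1:n]) / w
    f_inst <- pmax(0.05, config$resp_rate_hz + drift)
    phase <- 2 * pi * cumsum(f_inst) / fs
    pitch <- config$resp_incl_amp_rad * sin(phase)
    roll <- 0.6 * config$resp_incl_amp_rad * sin(phase - 0.3)
    # inhalation peaks: crests of the pitch trajectory
    pk <- local_maxima(pitch)
    inhal <- t[pk]

    g <- 9.80665
    acc_x <- g * sin(roll) * cos(pitch)
    acc_y <- g * sin(pitch) * cos(roll)
    acc_z <- sqrt(pmax(0, g^2 - acc_x^2 - acc_y^2))
    # dorsoventral chest displacement contributes a respiratory proper
    # acceleration on z, in phase with inhalation (chest rise)
    acc_z <- acc_z + 0.05 * sin(phase) + acc_card
    dpitch <- diff(pitch) * fs; dpitch <- c(dpitch[1], dpitch)
    droll <- diff(roll) * fs; droll <- c(droll[1], droll)
    gyro_x <- dpitch
    gyro_y <- droll + gyro_card
    gyro_z <- 0.4 * dpitch

    acc <- cbind(acc_x, acc_y, acc_z)
    gyro <- cbind(gyro_x, gyro_y, gyro_z)

    ## --- noise and artifacts ------------------------------------------------
    chans <- cbind(acc, gyro)
    sds <- apply(chans, 2, stats::sd)
    if (config$noise_sd > 0)
      chans <- chans + sapply(sds, function(s)
        stats::rnorm(n, 0, config$noise_sd * s))

    art_windows <- NULL
    n_art <- stats::rpois(1, config$artifact_rate_per_min * config$duration_s / 60)
    if (n_art > 0 && config$artifact_amp_factor > 0) {
      art_dur <- 0.4
      starts <- sort(stats::runif(n_art, 1, config$duration_s - 1 - art_dur))
      art_windows <- cbind(start = starts, end = starts + art_dur)
      w_len <- round(art_dur * fs)
      bump <- 0.5 * (1 - cos(2 * pi * seq_len(w_len) / (w_len + 1)))
      rms <- apply(chans, 2, function(v) sqrt(mean((v - mean(v))^2)))
      for (s0 in starts) {
        i0 <- round(s0 * fs) + 1L
        idx <- i0:(i0 + w_len - 1L)
        idx <- idx[idx >= 1 & idx <= n]
        sgn <- sample(c(-1, 1), 6, replace = TRUE)
        for (ch in 1:6)
          chans[idx, ch] <- chans[idx, ch] +
            sgn[ch] * config$artifact_amp_factor * rms[ch] * bump[seq_along(idx)]
      }
    }

    rec <- imu_recording(chans[, 1:3], chans[, 4:6], fs = fs)
    truth <- list(beat_times = beats, ejection_times = eject,
                  resp_phase = phase, pitch = pitch, roll = roll,
                  inhalation_peaks = inhal,
                  artifact_windows = art_windows,
                  cardiac_source = s_m)
    list(recording = rec, truth = truth)
  })
}

#' Add white noise at a requested per-channel SNR
#'
#' Signal power is the variance of each channel about its mean (the static
#' gravity component therefore does not count as signal).
#'
#' @param rec an [imu_recording()].
#' @param snr_db target signal-to-noise ratio in dB (`Inf` returns the
#'   recording unchanged).
#' @param seed RNG seed.
#' @return a degraded [imu_recording()].
#' @export
degrade <- function(rec, snr_db, seed = 1) {
  stopifnot(inherits(rec, "imu_recording"))
  if (is.na(snr_db)) stopf("snr_db must not be NA")
  if (is.infinite(snr_db) && snr_db > 0) return(rec)
  with_seed(seed, {
    add_noise <- function(m) {
      for (j in 1:3) {
        p_sig <- stats::var(m[, j])
        m[, j] <- m[, j] + stats::rnorm(nrow(m), 0,
                                        sqrt(p_sig / 10^(snr_db / 10)))
      }
      m
    }
    imu_recording(add_noise(rec$acc), add_noise(rec$gyro),
                  fs = rec$fs, t0 = rec$t0)
  })
}

#' Simulate a five-channel chest-inclination respiration set
#'
#' Generates the situation the PCA fusion addresses: five inclination
#' channels (two accelerometer-derived, three gyroscope-derived) that all
#' follow one common breathing trajectory but with axis-dependent coupling
#' gain, random polarity, and independent band-limited noise of
#' axis-dependent strength. Which axis is cleanest varies from recording to
#' recording, as it does from subject to subject in practice.
#'
#' @param duration_s record length (s).
#' @param fs sampling rate (Hz); the respiration band needs only ~25 Hz.
#' @param resp_rate_hz mean breathing rate (Hz).
#' @param resp_sd_hz SD of the slow breathing-rate drift.
#' @param snr_db mean per-channel in-band signal-to-noise ratio (dB).
#' @param snr_spread_db SD of the per-channel SNR around `snr_db` (dB).
#' @param seed RNG seed.
#' @return list with `set` (a `respiration_set` ready for [pca_fuse()]),
#'   `truth` (the common breathing trajectory), `snr_db` (per channel),
#'   and `gains`.
#' @export
simulate_respiration_set <- function(duration_s = 60, fs = 25,
                                     resp_rate_hz = 0.25, resp_sd_hz = 0.02,
                                     snr_db = 3, snr_spread_db = 3,
                                     seed = 1) {
  with_seed(seed, {
    n <- round(duration_s * fs)
    w <- round(10 * fs)
    raw <- stats::rnorm(n + w)
    cs <- c(0, cumsum(raw))
    drift <- resp_sd_hz * sqrt(w) * (cs[(w + 1):(w + n)] - cs[1:n]) / w
    phase <- 2 * pi * cumsum(pmax(0.05, resp_rate_hz + drift)) / fs
    truth <- sin(phase)

    nm <- c("adr_x", "adr_y", "gdr_x", "gdr_y", "gdr_z")
    band <- c(0.1, 2)
    gains <- stats::runif(5, 0.3, 1) * sample(c(-1, 1), 5, replace = TRUE)
    snrs <- stats::rnorm(5, snr_db, snr_spread_db)
    chans <- lapply(seq_len(5), function(i) {
      noise <- bp_filter(stats::rnorm(n), fs, band)
      noise <- noise / stats::sd(noise)
      sig <- gains[i] * truth
      y <- sig + stats::sd(sig) * 10^(-snrs[i] / 20) * noise
      y - mean(y)
    })
    names(chans) <- nm
    R <- do.call(rbind, chans)
    rownames(R) <- nm
    set <- structure(c(chans,
                       list(fs = fs, R = R,
                            polarity_flags = stats::setNames(rep(1, 5), nm),
                            reference = truth)),
                     class = "respiration_set")
    list(set = set, truth = truth,
         snr_db = stats::setNames(snrs, nm),
         gains = stats::setNames(gains, nm))
  })
}
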