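#' Pearson correlation with validity checks
#'
#' @param a,b numeric vectors of equal length, each with non-zero variance.
#' @return the product-moment correlation in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b)) stopf("inputs must have equal length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stopf("correlation undefined for a constant input")
  stats::cor(a, b)
}

#' Mean absolute trigger offset
#'
#' Each test trigger is matched to its nearest reference trigger; matches
#' farther than half the median reference inter-trigger interval are
#' discarded (reported as counts) and the mean and SD of the absolute offsets
#' are computed over the remainder.
#'
#' @param test detected trigger times (s), sorted.
#' @param ref reference trigger times (s), sorted.
#' @return list with `mean_abs_offset_s`, `sd_abs_offset_s`, `n_matched`,
#'   `n_unmatched_test`.
#' @export
trigger_offset <- function(test, ref) {
  if (!length(test) || !length(ref)) stopf("trigger lists must be non-empty")
  half_med <- if (length(ref) > 1) stats::median(diff(ref)) / 2 else Inf
  dt <- vapply(test, function(x) min(abs(x - ref)), numeric(1))
  matched <- dt <= half_med
  if (!any(matched)) stopf("no trigger matched within %.3f s", half_med)
  d <- dt[matched]
  list(mean_abs_offset_s = mean(d),
       sd_abs_offset_s = if (length(d) > 1) stats::sd(d) else 0,
       n_matched = sum(matched),
       n_unmatched_test = sum(!matched))
}

#' Match detected beats against reference annotations
#'
#' Greedy nearest-first one-to-one matching within a tolerance window,
#' followed by sensitivity (TPR), precision (PPV), F1, and the RMS of the
#' matched time differences in milliseconds.
#'
#' @param detected detected beat times (s), sorted.
#' @param reference reference beat times (s), sorted, non-empty.
#' @param tolerance_ms matching window (ms), default 150.
#' @return object of class `beat_match`: list with `tp`, `fp`, `fn`,
#'   `matched_pairs` (two-column matrix detected/reference), `tpr`, `ppv`,
#'   `f1`, `rmse_ms`, `tolerance_ms`.
#' @export
match_beats <- function(detected, reference, tolerance_ms = 150) {
  if (!length(reference)) stopf("reference beat list must be non-empty")
  tol <- tolerance_ms / 1000
  nd <- length(detected); nr <- length(reference)
  pairs <- NULL
  if (nd) {
    cand <- do.call(rbind, lapply(seq_len(nd), function(i) {
      j <- which(abs(reference - detected[i]) <= tol)
      if (!length(j)) return(NULL)
      cbind(i = i, j = j, d = abs(reference[j] - detected[i]))
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(cand[, "d"]), , drop = FALSE]
      used_d <- logical(nd); used_r <- logical(nr)
      sel <- logical(nrow(cand))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, "i"]; j <- cand[k, "j"]
        if (!used_d[i] && !used_r[j]) {
          used_d[i] <- used_r[j] <- TRUE
          sel[k] <- TRUE
        }
      }
      pairs <- cand[sel, , drop = FALSE]
    }
  }
  tp <- if (is.null(pairs)) 0L else nrow(pairs)
  fp <- nd - tp; fn <- nr - tp
  tpr <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  ppv <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (is.finite(tpr) && is.finite(ppv) && (tpr + ppv) > 0)
    2 * tpr * ppv / (tpr + ppv) else 0
  rmse <- if (tp > 0) sqrt(mean((pairs[, "d"] * 1000)^2)) else NA_real_
  structure(list(tp = tp, fp = fp, fn = fn,
                 matched_pairs = if (is.null(pairs)) NULL else
                   cbind(detected_s = detected[pairs[, "i"]],
                         reference_s = reference[pairs[, "j"]]),
                 tpr = tpr, ppv = ppv, f1 = f1, rmse_ms = rmse,
                 tolerance_ms = tolerance_ms),
            class = "beat_match")
}

#' @export
print.beat_match <- function(x, ...) {
  cat(sprintf("<beat_match> TP %d FP %d FN %d | TPR %.3f PPV %.3f F1 %.3f | RMSE %.1f ms\n",
              x$tp, x$fp, x$fn, x$tpr, x$ppv, x$f1, x$rmse_ms))
  invisible(x)
}

#' Average heart rate from a beat set
#'
#' @param beats a [beat_set()] (or numeric beat times) with at least two
#'   beats.
#' @return heart rate in beats per minute, `60 / mean(IBI)`.
#' @export
heart_rate <- function(beats) {
  bt <- if (inherits(beats, "beat_set")) beats$beat_times else as.numeric(beats)
  if (length(bt) < 2) stopf("need at least two beats to estimate heart rate")
  60 / mean(diff(bt))
}

#' Cardiac cycle percentage
#'
#' The summed per-beat systolic (ejection) intervals divided by the summed
#' cycle lengths, as a percentage. Each beat takes the ejection and cycle
#' length of the segment containing it.
#'
#' @param beats a [beat_set()].
#' @param seg a [segment_cycles()] result with at least one valid segment.
#' @return CCP in percent.
#' @export
ccp <- function(beats, seg) {
  segs <- seg$segments[seg$segments$valid, , drop = FALSE]
  if (!nrow(segs)) stopf("no valid cycle segments")
  bt <- beats$beat_times
  tot_e <- 0; tot_c <- 0; n_used <- 0L
  for (b in bt) {
    row <- which(segs$start_s <= b & b < segs$end_s)
    if (!length(row)) next
    tot_e <- tot_e + segs$ejection_s[row[1]]
    tot_c <- tot_c + segs$cycle_len_s[row[1]]
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stopf("no beats fall inside valid segments")
  100 * tot_e / tot_c
}

#' Assemble a gating evaluation report
#'
#' @param beat_match a [match_beats()] result (or `NULL`).
#' @param hr_bpm estimated heart rate (bpm, or `NA`).
#' @param ccp_percent cardiac cycle percentage (or `NA`).
#' @param pearson_r named list/vector of respiration correlations.
#' @param trigger a [trigger_offset()] result (or `NULL`).
#' @return a `gating_report` list suitable for JSON serialization.
#' @export
gating_report <- function(beat_match = NULL, hr_bpm = NA_real_,
                          ccp_percent = NA_real_, pearson_r = NULL,
                          trigger = NULL) {
  structure(list(
    tpr = if (!is.null(beat_match)) beat_match$tpr else NA_real_,
    ppv = if (!is.null(beat_match)) beat_match$ppv else NA_real_,
    f1 = if (!is.null(beat_match)) beat_match$f1 else NA_real_,
    rmse_ms = if (!is.null(beat_match)) beat_match$rmse_ms else NA_real_,
    hr_bpm = hr_bpm,
    ccp_percent = ccp_percent,
    pearson_r = pearson_r,
    mean_abs_trigger_offset_s =
      if (!is.null(trigger)) trigger$mean_abs_offset_s else NA_real_,
    sd_abs_trigger_offset_s =
      if (!is.null(trigger)) trigger$sd_abs_offset_s else NA_real_),
    class = "gating_report")
}
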