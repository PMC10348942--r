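# Clubhead accelerometer processing: resampling, filtering, putt
# detection, pre-contact extraction, per-putt metrics and time
# normalization.

#' Resample an IMU trace onto a uniform grid
#'
#' Linear interpolation from the first to the last timestamp; no
#' extrapolation beyond the recorded span.
#'
#' @param trace an [imu_trace()].
#' @param target_rate target sampling rate, Hz.
#' @return An `imu_trace` at `target_rate`.
#' @export
resample_uniform <- function(trace, target_rate) {
  stopifnot(inherits(trace, "imu_trace"), target_rate > 0)
  t <- trace$time
  if (length(t) < 2) stop("need at least 2 samples", call. = FALSE)
  if (any(diff(t) <= 0))
    stop("time vector must be strictly increasing", call. = FALSE)
  n_out <- floor((t[length(t)] - t[1]) * target_rate + 1e-9) + 1
  grid <- t[1] + (seq_len(n_out) - 1) / target_rate
  acc <- apply(trace$acc, 2, function(ch) approx(t, ch, xout = grid)$y)
  imu_trace(grid, acc, target_rate)
}

#' Detect putts from vertical-channel impact spikes
#'
#' Impact instants are located on the raw (unfiltered) vertical channel
#' as samples whose absolute deviation from the channel median exceeds
#' `threshold_k` robust standard deviations (1.4826 x MAD) and which are
#' local maxima of that deviation.  Detections closer than
#' `min_separation_s` are resolved in favour of the larger spike.
#'
#' @param trace an [imu_trace()] (resampled; detection runs on the raw
#'   vertical channel).
#' @param threshold_k robust-SD multiplier (default 6).
#' @param min_separation_s minimum separation between putts, seconds.
#' @return Integer vector of impact sample indices (empty when no spike
#'   qualifies; the caller is expected to log and skip such trials).
#' @export
detect_putts <- function(trace, threshold_k = 6, min_separation_s = 2) {
  stopifnot(inherits(trace, "imu_trace"))
  v <- trace$acc[, "vertical"]
  dev <- abs(v - median(v))
  rsd <- mad(v)
  thr <- max(threshold_k * rsd, .Machine$double.eps)
  n <- length(dev)
  cand <- which(dev > thr)
  cand <- cand[cand > 1 & cand < n]
  cand <- cand[dev[cand] >= dev[cand - 1] & dev[cand] >= dev[cand + 1]]
  if (!length(cand)) return(integer(0))
  cand <- cand[order(dev[cand], decreasing = TRUE)]
  keep <- integer(0)
  min_gap <- min_separation_s * trace$rate
  for (i in cand) {
    if (!length(keep) || all(abs(keep - i) >= min_gap)) keep <- c(keep, i)
  }
  sort(keep)
}

#' Extract the pre-contact phase of a putt
#'
#' Backtracks from the impact sample to the movement onset: the last
#' sample before impact at which the low-pass-filtered transverse
#' acceleration magnitude stays below `onset_frac` of its pre-impact peak
#' for at least `hold_s` seconds.  The returned segment carries the
#' filtered channels (metrics are read from the filtered signal), spans
#' `[onset, impact]` inclusive, and must be at least 10 samples long.
#'
#' @param trace an [imu_trace()] (raw).
#' @param impact_index impact sample from [detect_putts()].
#' @param filtered optional pre-filtered copy of `trace`; computed with
#'   the default 3 Hz/2nd-order zero-phase filter when missing.
#' @param onset_frac onset threshold as a fraction of the pre-impact peak.
#' @param hold_s minimum quiet duration qualifying as pre-movement stance.
#' @param lookback_s how far before impact the onset is searched for.
#' @param onset_cutoff cutoff (Hz) of the dedicated onset-detection
#'   smoother.  This is deliberately milder than the 3 Hz analysis
#'   filter: a zero-phase 3 Hz pass smears movement energy ~50 ms ahead
#'   of the true onset, while 10 Hz keeps the onset sharp and still sits
#'   far above the sensor-noise floor.
#' @return A `swing_segment`: list with `time`, `acc` (filtered slice),
#'   `onset_index`, `impact_index` (indices into the source trace) and
#'   `rate`.
#' @export
extract_pre_contact <- function(trace, impact_index, filtered = NULL,
                                onset_frac = 0.05, hold_s = 0.15,
                                lookback_s = 5, onset_cutoff = 10) {
  stopifnot(inherits(trace, "imu_trace"))
  n <- length(trace$time)
  if (impact_index < 2 || impact_index > n)
    stop("trial rejected: impact index at trace boundary", call. = FALSE)
  if (is.null(filtered)) filtered <- filter_imu(trace)
  w0 <- max(1L, impact_index - round(lookback_s * trace$rate))
  win <- seq(w0, impact_index)
  smooth_t <- lowpass_butterworth(trace$acc[, "transverse"],
                                  cutoff = onset_cutoff, order = 2,
                                  rate = trace$rate)
  mag <- abs(smooth_t[win])
  below <- mag < onset_frac * max(mag)
  hold_n <- max(2L, ceiling(hold_s * trace$rate))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= hold_n)
  ok <- ok[ends[ok] < length(win)]  # movement must follow the quiet run
  if (!length(ok))
    stop("trial rejected: no movement onset found within lookback",
         call. = FALSE)
  onset_index <- w0 + ends[max(ok)] - 1L
  if (impact_index - onset_index + 1L < 10L)
    stop("trial rejected: pre-contact segment shorter than 10 samples",
         call. = FALSE)
  idx <- seq(onset_index, impact_index)
  structure(list(time = trace$time[idx],
                 acc = filtered$acc[idx, , drop = FALSE],
                 onset_index = onset_index, impact_index = impact_index,
                 rate = trace$rate),
            class = "swing_segment")
}

# filter all three channels of an IMU trace (3 Hz, 2nd order, zero phase)
filter_imu <- function(trace, cutoff = 3, order = 2) {
  acc <- apply(trace$acc, 2, lowpass_butterworth, cutoff = cutoff,
               order = order, rate = trace$rate)
  imu_trace(trace$time, acc, trace$rate)
}

#' Jerk of a swing segment
#'
#' First difference of acceleration divided by the sampling interval
#' (jerk as the discrete time derivative of acceleration).
#'
#' @param segment a `swing_segment`.
#' @return Matrix of length `nrow(segment$acc) - 1` with one jerk series
#'   per plane, m/s^3.
#' @export
compute_jerk <- function(segment) {
  stopifnot(inherits(segment, "swing_segment"), nrow(segment$acc) >= 2)
  apply(segment$acc, 2, diff) / (1 / segment$rate)
}

#' Per-putt scalar swing metrics
#'
#' Impact-instant transverse and sagittal accelerations (read from the
#' filtered channels at the impact sample), sample variance of the
#' sagittal channel over the pre-contact segment, and mean absolute jerk
#' per plane.  Mean jerk is computed on magnitudes: a signed mean over a
#' near-symmetric swing would cancel to zero, which is incompatible with
#' the positive values this summary is meant to carry.
#'
#' @param segment a `swing_segment`.
#' @return A one-row data frame with columns `acc_impact_transverse`,
#'   `acc_impact_sagittal`, `var_sagittal`, `jerk_mean_transverse`,
#'   `jerk_mean_sagittal`, `n_samples`.
#' @export
swing_metrics <- function(segment) {
  stopifnot(inherits(segment, "swing_segment"))
  jerk <- compute_jerk(segment)
  n <- nrow(segment$acc)
  data.frame(
    acc_impact_transverse = segment$acc[n, "transverse"],
    acc_impact_sagittal = segment$acc[n, "sagittal"],
    var_sagittal = var(segment$acc[, "sagittal"]),
    jerk_mean_transverse = mean(abs(jerk[, "transverse"])),
    jerk_mean_sagittal = mean(abs(jerk[, "sagittal"])),
    n_samples = n
  )
}

#' Time-normalize a swing segment to a fixed number of nodes
#'
#' Linear interpolation of each plane onto `n_nodes` equally spaced
#' fractions of `[onset, impact]`; node 1 carries the onset value and
#' node `n_nodes` the impact value exactly.  101 nodes (0-100% in 1%
#' steps) is the field convention for curve analysis.
#'
#' @param segment a `swing_segment`.
#' @param n_nodes number of nodes (>= 2).
#' @return Matrix `n_nodes` x 3 (planes in columns).
#' @export
time_normalize <- function(segment, n_nodes = 101) {
  stopifnot(inherits(segment, "swing_segment"), n_nodes >= 2)
  grid <- seq(segment$time[1], segment$time[length(segment$time)],
              length.out = n_nodes)
  out <- apply(segment$acc, 2, function(ch)
    approx(segment$time, ch, xout = grid)$y)
  out[1, ] <- segment$acc[1, ]
  out[n_nodes, ] <- segment$acc[nrow(segment$acc), ]
  out
}

#' Process one putt recording end to end
#'
#' Resample, filter, detect the putt, extract the pre-contact phase and
#' compute metrics and the normalized curves.  A trial whose spike or
#' onset cannot be identified is returned with a `rejected_reason`
#' instead of metrics, mirroring how unreliable laboratory trials are
#' logged and skipped.
#'
#' @param trace an [imu_trace()].
#' @param target_rate resampling rate, Hz.
#' @param cutoff,order low-pass design (defaults 3 Hz, 2nd order).
#' @param n_nodes nodes for time normalization.
#' @param threshold_k,min_separation_s putt-detection parameters.
#' @return List with `metrics` (one-row data frame or `NULL`), `curves`
#'   (`n_nodes` x 3 matrix or `NULL`), `impact_index`, `onset_index`,
#'   `rejected_reason` (`NA` when processed).
#' @export
process_swing <- function(trace, target_rate = 1125, cutoff = 3, order = 2,
                          n_nodes = 101, threshold_k = 6,
                          min_separation_s = 2) {
  trace <- resample_uniform(trace, target_rate)
  peaks <- detect_putts(trace, threshold_k, min_separation_s)
  if (!length(peaks))
    return(list(metrics = NULL, curves = NULL, impact_index = NA,
                onset_index = NA, rejected_reason = "no impact spike"))
  impact <- peaks[which.max(abs(trace$acc[peaks, "vertical"] -
                                  median(trace$acc[, "vertical"])))]
  filtered <- filter_imu(trace, cutoff, order)
  seg <- tryCatch(extract_pre_contact(trace, impact, filtered),
                  error = function(e) conditionMessage(e))
  if (is.character(seg))
    return(list(metrics = NULL, curves = NULL, impact_index = impact,
                onset_index = NA, rejected_reason = seg))
  list(metrics = swing_metrics(seg),
       curves = time_normalize(seg, n_nodes),
       impact_index = impact, onset_index = seg$onset_index,
       rejected_reason = NA_character_)
}
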