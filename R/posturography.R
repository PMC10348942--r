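# Centre-of-pressure posturography: filtering, trial segmentation, sway
# amplitude, sample entropy, path length and the 95% prediction ellipse.

#' Low-pass filter a COP trace
#'
#' Both coordinates are filtered (5 Hz, 2nd order, zero phase by
#' default); events are preserved.
#'
#' @param trace a [cop_trace()].
#' @param cutoff,order Butterworth design.
#' @return A filtered `cop_trace`.
#' @export
filter_cop <- function(trace, cutoff = 5, order = 2) {
  stopifnot(inherits(trace, "cop_trace"))
  cop_trace(trace$time,
            lowpass_butterworth(trace$x, cutoff, order, trace$rate),
            lowpass_butterworth(trace$y, cutoff, order, trace$rate),
            trace$rate, events = trace$events)
}

#' Segment the putt window of a COP trace
#'
#' In `markers` mode the putt window runs from the foot-lift event plus a
#' settling margin to the next foot-lift (or the end of the trace).  In
#' `detect` mode the foot-lift is found as an excursion of the (filtered)
#' COP speed above `speed_thr` sustained for more than `min_dur_s`.
#'
#' @param trace a [cop_trace()].
#' @param mode `"markers"` or `"detect"`.
#' @param settle_s settling margin after the foot-lift, seconds.
#' @param speed_thr COP speed threshold for `detect` mode, mm/s; speed is
#'   estimated over a 50 ms lag of the filtered trace, which separates
#'   the foot-lift excursion from sample-scale sway velocity.
#' @param min_dur_s minimum sustained duration above threshold, seconds.
#' @return The windowed `cop_trace`.
#' @export
segment_trial <- function(trace, mode = c("markers", "detect"),
                          settle_s = 0.5, speed_thr = 150,
                          min_dur_s = 0.1) {
  stopifnot(inherits(trace, "cop_trace"))
  mode <- match.arg(mode)
  if (mode == "markers") {
    fl <- trace$events$time[trace$events$label == "footlift"]
    if (!length(fl))
      stop("no footlift event in markers mode", call. = FALSE)
    fl <- sort(fl)
    start <- fl[1] + settle_s
    end <- if (length(fl) > 1) fl[2] else trace$time[length(trace$time)]
  } else {
    f <- filter_cop(trace)
    lag <- max(1L, round(0.05 * trace$rate))
    n <- length(f$x)
    dx <- f$x[seq(lag + 1, n)] - f$x[seq(1, n - lag)]
    dy <- f$y[seq(lag + 1, n)] - f$y[seq(1, n - lag)]
    speed <- c(rep(0, lag), sqrt(dx^2 + dy^2) / (lag / trace$rate))
    over <- speed > speed_thr
    r <- rle(over)
    ends <- cumsum(r$lengths)
    ok <- which(r$values & r$lengths > min_dur_s * trace$rate)
    if (!length(ok))
      stop("no footlift excursion detected", call. = FALSE)
    # the foot-lift is the largest sustained excursion of the recording
    peak <- vapply(ok, function(i)
      max(speed[(ends[i] - r$lengths[i] + 1):ends[i]]), numeric(1))
    run <- ok[which.max(peak)]
    mid <- ends[run] - r$lengths[run] / 2
    start <- trace$time[round(mid)] + settle_s
    end <- trace$time[length(trace$time)]
  }
  keep <- trace$time >= start & trace$time <= end
  if (sum(keep) < 2) stop("empty putt window", call. = FALSE)
  ev <- trace$events[trace$events$time >= start &
                       trace$events$time <= end, , drop = FALSE]
  cop_trace(trace$time[keep], trace$x[keep], trace$y[keep], trace$rate,
            events = ev)
}

#' RMS sway amplitude
#'
#' Root-mean-square of a coordinate series about its own mean position.
#'
#' @param series numeric vector (>= 2 samples).
#' @return RMS amplitude in the series' units.
#' @export
rms_amplitude <- function(series) {
  stopifnot(length(series) >= 2)
  sqrt(mean((series - mean(series))^2))
}

#' Decimate a series by an integer factor
#'
#' Keeps every `from_rate / to_rate`-th sample (the series is expected to
#' be low-pass filtered already, as in the 300 Hz to 100 Hz entropy
#' chain).
#'
#' @param series numeric vector.
#' @param from_rate,to_rate rates in Hz; their ratio must be an integer.
#' @return Decimated series of length `ceiling(n / factor)`.
#' @export
downsample <- function(series, from_rate, to_rate) {
  factor <- from_rate / to_rate
  if (abs(factor - round(factor)) > 1e-9)
    stop("from_rate must be an integer multiple of to_rate", call. = FALSE)
  series[seq(1, length(series), by = round(factor))]
}

#' Sample entropy
#'
#' `SampEn(m, r) = -ln(A / B)` where `B` counts pairs of length-`m`
#' templates within Chebyshev distance `r` and `A` the same for length
#' `m + 1`; self-matches are excluded and both counts run over the
#' `n - m` templates for which the `m + 1` extension exists.  Lower
#' values indicate a more regular signal.  When no `m + 1` template pair
#' matches (`A = 0`) the entropy is unbounded and `Inf` is returned with
#' a warning; `NA` (with a warning) signals the degenerate `B = 0` case.
#'
#' @param series numeric vector of length >= `m + 2`.
#' @param m template length (default 2).
#' @param r tolerance; defaults to `0.2 * sd(series)` computed from the
#'   analysed series itself.
#' @return Sample entropy (unitless).
#' @examples
#' sample_entropy(rep(1, 50), r = 0.1)  # 0: fully regular
#' @export
sample_entropy <- function(series, m = 2, r = 0.2 * sd(series)) {
  n <- length(series)
  if (n < m + 2) stop("series shorter than m + 2", call. = FALSE)
  if (!is.finite(r) || r <= 0)
    stop("tolerance r must be positive", call. = FALSE)
  counts <- .sampen_counts(as.numeric(series), as.integer(m), r)
  A <- counts[1]; B <- counts[2]
  if (B == 0) {
    warning("no template matches at length m; SampEn undefined")
    return(NA_real_)
  }
  if (A == 0) {
    warning("no template matches at length m + 1; SampEn unbounded")
    return(Inf)
  }
  -log(A / B)
}

#' COP path length
#'
#' Total distance travelled in the 2D plane of the plate: the cumulative
#' sum of consecutive-sample displacements of the (filtered) COP signal.
#'
#' @param trace a [cop_trace()] (or list with `x`, `y`).
#' @return Path length in mm.
#' @export
path_length <- function(trace) {
  stopifnot(length(trace$x) >= 2)
  sum(sqrt(diff(trace$x)^2 + diff(trace$y)^2))
}

#' 95% prediction ellipse of the COP cloud
#'
#' Principal-components ellipse: eigen-decomposition of the 2 x 2 sample
#' covariance of `(x, y)`; the ellipse semi-axes are
#' `sqrt(chi2_{0.95,2} * lambda_i)` and its area
#' `pi * chi2_{0.95,2} * sqrt(lambda_1 * lambda_2)`, the region expected
#' to contain 95% of bivariate-normal COP positions.
#'
#' @param trace a [cop_trace()], or a two-column matrix of positions.
#' @return List with `area` (mm^2), `center`, `semi_axes`, `angle`
#'   (radians of the first principal axis) and `chisq` (the quantile
#'   constant, 5.991).
#' @export
ellipse_area_95 <- function(trace) {
  xy <- if (inherits(trace, "cop_trace")) cbind(trace$x, trace$y)
        else as.matrix(trace)
  stopifnot(ncol(xy) == 2, nrow(xy) >= 3)
  q <- stats::qchisq(0.95, df = 2)  # 5.991
  S <- stats::cov(xy)
  e <- eigen(S, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (min(lam) <= 1e-12 * max(lam, 1e-300)) {
    warning("degenerate (collinear) COP cloud; ellipse area 0")
    return(list(area = 0, center = colMeans(xy),
                semi_axes = sqrt(q * lam), angle = atan2(e$vectors[2, 1],
                                                         e$vectors[1, 1]),
                chisq = q))
  }
  list(area = pi * q * sqrt(lam[1] * lam[2]),
       center = colMeans(xy),
       semi_axes = sqrt(q * lam),
       angle = atan2(e$vectors[2, 1], e$vectors[1, 1]),
       chisq = q)
}

#' All posturographic outcomes of one trial
#'
#' Bundles the processing chain: 5 Hz zero-phase filtering, putt-window
#' segmentation, RMS sway per axis, decimation to 100 Hz followed by
#' sample entropy per axis, and path length and 95% ellipse area on the
#' filtered 2D window.
#'
#' @param trace a raw [cop_trace()].
#' @param cutoff,order COP filter design (defaults 5 Hz, 2nd order).
#' @param mode segmentation mode, see [segment_trial()].
#' @param sampen_m,sampen_r_factor sample-entropy parameters; the
#'   tolerance is `sampen_r_factor * sd` of each decimated axis series.
#' @param sampen_rate decimation target for entropy, Hz.
#' @param settle_s settling margin after the foot-lift.
#' @return One-row data frame: `rms_t`, `rms_s`, `sampen_t`, `sampen_s`,
#'   `path_length_mm`, `ellipse_area_mm2` (transverse = y, sagittal = x).
#' @export
posture_metrics <- function(trace, cutoff = 5, order = 2,
                            mode = "markers", sampen_m = 2,
                            sampen_r_factor = 0.2, sampen_rate = 100,
                            settle_s = 0.5) {
  f <- filter_cop(trace, cutoff, order)
  w <- segment_trial(f, mode = mode, settle_s = settle_s)
  x100 <- downsample(w$x, trace$rate, sampen_rate)
  y100 <- downsample(w$y, trace$rate, sampen_rate)
  data.frame(
    rms_t = rms_amplitude(w$y),
    rms_s = rms_amplitude(w$x),
    sampen_t = sample_entropy(y100, sampen_m,
                              sampen_r_factor * sd(y100)),
    sampen_s = sample_entropy(x100, sampen_m,
                              sampen_r_factor * sd(x100)),
    path_length_mm = path_length(w),
    ellipse_area_mm2 = ellipse_area_95(w)$area
  )
}
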