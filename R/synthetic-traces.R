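# Synthetic swing and centre-of-pressure traces with recorded ground truth.
#
# The swing model is deliberately simple but smooth: the transverse
# (forward) channel is built from two opposed minimum-jerk acceleration
# lobes (backswing, then downswing), scaled so the value at the impact
# sample equals the per-trial "true" impact acceleration exactly.  The
# paper-gap here is explicit: laboratory swings are measured, not
# modelled; this profile only needs to be smooth, parameterisable and
# morphologically putt-like.

# minimum-jerk acceleration profile on normalized phase time [0, 1]
mj_acc <- function(tau) {
  out <- 60 * tau - 180 * tau^2 + 120 * tau^3
  out[tau < 0 | tau > 1] <- 0
  out
}
MJ_TAU_STAR <- (1 - 1 / sqrt(3)) / 2      # phase of the first accel peak
MJ_PEAK <- 60 * MJ_TAU_STAR - 180 * MJ_TAU_STAR^2 + 120 * MJ_TAU_STAR^3
MJ_TAU_REV <- (1 + 1 / sqrt(3)) / 2       # phase of the reversal peak

# swing phase durations: the backswing reversal peak (at 0.7887 * B after
# onset) is placed at 50% of the pre-contact swing, and impact falls on
# the rising downswing lobe peak, giving the classic negative-positive-
# positive transverse morphology.
swing_timing <- function(swing) {
  B <- swing$backswing_s
  t_pre <- MJ_TAU_REV * B / 0.5       # pre-contact duration
  d_full <- (t_pre - B) / MJ_TAU_STAR # full downswing phase duration
  list(backswing = B, pre_contact = t_pre, downswing = d_full)
}

# compactly supported raised-cosine bump centred at c with half-width hw,
# on normalized swing time.  Compact support (instead of a Gaussian tail)
# keeps the condition-specific shape effects away from the impact sample
# even after the 3 Hz zero-phase filter smears energy by ~100 ms.
shape_bump <- function(s, centre, hw) {
  out <- numeric(length(s))
  inside <- abs(s - centre) < hw
  out[inside] <- 0.5 * (1 + cos(pi * (s[inside] - centre) / hw))
  out
}

#' Generate one synthetic putt recording (clubhead IMU)
#'
#' Produces a triaxial accelerometer trace containing exactly one putt:
#' a minimum-jerk backswing/downswing profile in the transverse channel,
#' a 20 ms half-cosine impact spike in the vertical channel, band-limited
#' sagittal fluctuation with the configured per-condition variance, plus
#' white sensor noise.  Condition effects shift the impact-instant
#' accelerations, the sagittal variance and the swing shape (localized
#' bumps at ~50% and ~80% of the pre-contact swing).
#'
#' @param cfg a [study_config()].
#' @param participant integer participant index.
#' @param condition condition label present in `cfg$conditions`.
#' @param trial integer trial index.
#' @param seed optional integer; defaults to a stable hash of
#'   (root seed, participant, condition, trial).
#' @return A list with elements `trace` (an `imu_trace`: `time`, `acc`
#'   matrix with columns transverse/vertical/sagittal, `rate`) and
#'   `truth` (the generating parameters: true onset/impact times, impact
#'   index, impact accelerations, sagittal SD and realized pre-contact
#'   sagittal variance).
#' @examples
#' cfg <- study_config(n_participants = 2, n_trials = 1, seed = 3)
#' sw <- generate_swing_trace(cfg, 1, "Real", 1)
#' sw$trace$acc[sw$truth$impact_index, "transverse"]
#' sw$truth$acc_impact_transverse  # identical before noise
#' @export
generate_swing_trace <- function(cfg, participant, condition, trial,
                                 seed = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (!condition %in% cfg$conditions)
    stop("unknown condition '", condition, "'", call. = FALSE)
  if (cfg$imu_duration_s <= 0) stop("non-positive duration", call. = FALSE)
  if (is.null(seed))
    seed <- derive_seed(cfg$seed, "swing", participant, condition, trial)
  tm <- swing_timing(cfg$swing)
  onset <- cfg$swing$onset_s
  if (cfg$imu_duration_s < onset + tm$pre_contact + 0.25)
    stop("imu_duration_s too short for the configured swing", call. = FALSE)

  rate <- cfg$imu_rate
  n <- round(cfg$imu_duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  impact_idx <- round((onset + tm$pre_contact) * rate) + 1L
  t_imp <- t[impact_idx]

  local_seed(seed, {
    a_t <- effect_value(cfg, "acc_impact_transverse", condition, participant) +
      rnorm(1, 0, cfg$effects$acc_impact_transverse$residual_sd)
    # a putt must strike the ball moving forward: censor tail draws at a
    # positive floor (recorded as the trial's truth)
    a_t <- max(a_t, cfg$swing$impact_floor)
    a_s <- effect_value(cfg, "acc_impact_sagittal", condition, participant) +
      rnorm(1, 0, cfg$effects$acc_impact_sagittal$residual_sd)
    lv <- effect_value(cfg, "log_var_sagittal", condition, participant) +
      rnorm(1, 0, cfg$effects$log_var_sagittal$residual_sd)
    sag_sd <- sqrt(exp(lv))

    # transverse: backswing lobe (negative then braking), downswing lobe
    trans <- numeric(n)
    bs <- t > onset & t <= onset + tm$backswing
    tau_b <- (t[bs] - onset) / tm$backswing
    scale_b <- cfg$swing$backswing_rel * a_t / MJ_PEAK
    trans[bs] <- -scale_b * mj_acc(tau_b)
    ds <- t > onset + tm$backswing &
      t <= onset + tm$backswing + tm$downswing
    tau_d <- (t[ds] - onset - tm$backswing) / tm$downswing
    mj_imp <- mj_acc((t_imp - onset - tm$backswing) / tm$downswing)
    trans[ds] <- (a_t / mj_imp) * mj_acc(tau_d)

    # condition-specific shape bumps (compact support, zero at impact)
    s_frac <- (t - onset) / (t_imp - onset)
    amp <- cfg$swing$bump_amp[[condition]]
    if (is.null(amp)) amp <- rep(0, length(cfg$swing$bump_centers))
    for (j in seq_along(cfg$swing$bump_centers)) {
      trans <- trans + amp[j] *
        shape_bump(s_frac, cfg$swing$bump_centers[j],
                   cfg$swing$bump_halfwidth)
    }

    # vertical: half-cosine impact spike
    vert <- numeric(n)
    half <- cfg$swing$spike_ms / 2000
    sp <- abs(t - t_imp) <= half
    vert[sp] <- cfg$swing$spike_amp *
      0.5 * (1 + cos(pi * (t[sp] - t_imp) / half))

    # sagittal: band-limited fluctuation (0.2-1.0 Hz, survives the 3 Hz
    # low-pass) scaled to the true SD over the pre-contact window, plus an
    # impact-locked bump pinning the value at the impact sample
    seg <- seq(round(onset * rate) + 1L, impact_idx)
    fl_freq <- runif(6, 0.2, 1.0)
    fl_phase <- runif(6, 0, 2 * pi)
    fl_amp <- runif(6, 0.5, 1)
    sag <- numeric(n)
    if (sag_sd > 0) {
      raw <- colSums(fl_amp * sin(outer(2 * pi * fl_freq, t) + fl_phase))
      sag <- raw * (sag_sd / sd(raw[seg]))
    }
    sag <- sag + (a_s - sag[impact_idx]) *
      exp(-(t - t_imp)^2 / (2 * 0.35^2))
    var_sag_true <- var(sag[seg])

    acc <- cbind(transverse = trans, vertical = vert, sagittal = sag)
    if (cfg$imu_noise_sd > 0)
      acc <- acc + matrix(rnorm(3 * n, 0, cfg$imu_noise_sd), ncol = 3)

    list(
      trace = imu_trace(t, acc, rate),
      truth = list(participant = participant, condition = condition,
                   trial = trial, seed = seed,
                   onset_s = onset, impact_s = t_imp,
                   impact_index = impact_idx,
                   acc_impact_transverse = a_t,
                   acc_impact_sagittal = a_s,
                   sagittal_sd = sag_sd,
                   var_sagittal = var_sag_true)
    )
  })
}

#' Generate one synthetic centre-of-pressure recording
#'
#' The 2D COP series is the sum of a slow quasi-periodic drift (amplitude
#' set per condition; controls RMS sway, path length and ellipse area) and
#' a regularity-controlled fluctuation
#' `lambda * oscillation + (1 - lambda) * white noise`, rescaled to a
#' fixed SD so that `lambda` tunes sample entropy without moving the sway
#' amplitude.  A foot-lift before the putt is encoded both as an event
#' timestamp and as a brief large sagittal excursion, so segmentation can
#' be exercised in marker mode and in detection mode.
#'
#' @inheritParams generate_swing_trace
#' @return A list with elements `trace` (a `cop_trace`: `time`, `x`
#'   sagittal mm, `y` transverse mm, `rate`, `events`) and `truth`
#'   (drift amplitude, lambda, foot-lift time).
#' @export
generate_cop_trace <- function(cfg, participant, condition, trial,
                               seed = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  if (!condition %in% cfg$conditions)
    stop("unknown condition '", condition, "'", call. = FALSE)
  if (is.null(seed))
    seed <- derive_seed(cfg$seed, "cop", participant, condition, trial)
  rate <- cfg$cop_rate
  n <- round(cfg$cop_duration_s * rate)
  t <- (seq_len(n) - 1) / rate
  t_fl <- cfg$cop$footlift_s
  win <- t >= t_fl + 0.5

  local_seed(seed, {
    drift_mm <- effect_value(cfg, "cop_drift_mm", condition, participant) +
      rnorm(1, 0, cfg$effects$cop_drift_mm$residual_sd)
    drift_mm <- max(drift_mm, 0)
    lambda <- effect_value(cfg, "cop_lambda", condition, participant) +
      rnorm(1, 0, cfg$effects$cop_lambda$residual_sd)
    lambda <- min(max(lambda, 0), 1)

    one_axis <- function(amp_mm) {
      fr <- runif(4, cfg$cop$drift_band[1], cfg$cop$drift_band[2])
      ph <- runif(4, 0, 2 * pi)
      aw <- runif(4, 0.5, 1)
      drift <- colSums(aw * sin(outer(2 * pi * fr, t) + ph))
      if (sd(drift[win]) > 0 && amp_mm > 0) {
        drift <- drift * (amp_mm / sd(drift[win]))
      } else drift <- drift * 0
      # regularity mixture of a unit-SD oscillation and unit-SD white
      # noise; the mixture is calibrated by its SD in the analysis band
      # (below the 5 Hz plate filter) so the regularity dial stays
      # visible after filtering while the sway-amplitude outcomes remain
      # drift-dominated
      osc <- sin(2 * pi * cfg$cop$osc_hz * t + runif(1, 0, 2 * pi))
      osc <- osc / sd(osc[win])
      wn <- rnorm(n)
      mix <- lambda * osc + (1 - lambda) * wn
      smix <- sd(lowpass_butterworth(mix, 5, 2, rate)[win])
      if (smix > 0) mix <- mix * (cfg$cop$fluct_mm / smix)
      drift + mix
    }
    x <- one_axis(drift_mm * cfg$cop$sagittal_gain)  # sagittal
    y <- one_axis(drift_mm)                          # transverse

    # foot-lift artifact: Hann-window excursion centred on the event
    fl <- abs(t - t_fl) <= cfg$cop$footlift_dur_s / 2
    x[fl] <- x[fl] + cfg$cop$footlift_amp_mm *
      0.5 * (1 + cos(2 * pi * (t[fl] - t_fl) / cfg$cop$footlift_dur_s))

    list(
      trace = cop_trace(t, x, y, rate,
                        events = data.frame(time = t_fl,
                                            label = "footlift")),
      truth = list(participant = participant, condition = condition,
                   trial = trial, seed = seed,
                   drift_mm = drift_mm, lambda = lambda,
                   footlift_s = t_fl)
    )
  })
}

#' Generate questionnaire item scores for one condition
#'
#' Six conscious-movement-processing items per participant, drawn from a
#' discretized latent normal whose mean shifts by condition, rounded and
#' clamped to the 1-5 Likert range.
#'
#' @param cfg a [study_config()].
#' @param condition condition label.
#' @return A list with `scores` (data frame: `participant_id`,
#'   `condition`, `item_1` ... `item_6`) and `truth` (latent means).
#' @export
generate_cmp_scores <- function(cfg, condition) {
  stopifnot(inherits(cfg, "study_config"))
  if (!condition %in% cfg$conditions)
    stop("unknown condition '", condition, "'", call. = FALSE)
  rows <- lapply(seq_len(cfg$n_participants), function(p) {
    latent <- effect_value(cfg, "cmp_latent", condition, p)
    items <- local_seed(derive_seed(cfg$seed, "cmp", p, condition), {
      raw <- latent + rnorm(6, 0, cfg$cmp_item_sd)
      pmin(pmax(round(raw), 1), 5)
    })
    list(scores = c(participant = p, items), latent = latent)
  })
  scores <- do.call(rbind, lapply(rows, `[[`, "scores"))
  scores_df <- data.frame(
    participant_id = participant_label(scores[, 1]),
    condition = condition,
    matrix(as.integer(scores[, -1]), ncol = 6,
           dimnames = list(NULL, paste0("item_", 1:6)))
  )
  truth <- data.frame(
    participant_id = participant_label(seq_len(cfg$n_participants)),
    condition = condition,
    latent_mean = vapply(rows, `[[`, numeric(1), "latent")
  )
  list(scores = scores_df, truth = truth)
}

participant_label <- function(i) sprintf("P%02d", as.integer(i))
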