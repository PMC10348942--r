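#' Configuration of a synthetic putting study
#'
#' Builds the configuration object that drives the synthetic study
#' generator.  Defaults emulate the design of a within-subject real-vs-VR
#' putting experiment: 21 participants, three conditions
#' (`Real`, `VR`, `VRHaptic`) in a Latin-square order, 20 putts per
#' condition, a clubhead accelerometer sampled at 1125 Hz and a pressure
#' plate sampled at 300 Hz.
#'
#' Condition effects are expressed on the `Real` baseline.  The default
#' effect table injects:
#' \describe{
#'   \item{`acc_impact_transverse`}{intercept 3.69 m/s^2, VR -1.47,
#'     VRHaptic -0.42 (slower forward contact in VR).}
#'   \item{`acc_impact_sagittal`}{intercept 0.95 m/s^2, VR +0.90,
#'     VRHaptic +0.78 (more sideways contact in VR).}
#'   \item{`log_var_sagittal`}{intercept -2.21 on the log (m/s^2)^2 scale,
#'     VR +1.20, VRHaptic +0.95 (noisier swing path in VR).}
#'   \item{`cop_drift_mm`}{postural drift amplitude, intercept 10 mm,
#'     VR +4, VRHaptic +3 (drives RMS sway, path length and ellipse area).}
#'   \item{`cop_lambda`}{regularity mixing weight in `[0, 1]` of the
#'     centre-of-pressure fluctuation, intercept 0.35, VR +0.35,
#'     VRHaptic +0.30; a larger weight means a more deterministic
#'     (regular) signal and hence lower sample entropy.}
#'   \item{`cmp_latent`}{latent mean of the 5-point conscious-movement
#'     items, intercept 3.4, VR -0.40, VRHaptic -0.35.}
#' }
#'
#' Each effect row also carries `participant_sd` (SD of the per-participant
#' random intercept) and `residual_sd` (trial-to-trial SD).  Swing-shape
#' parameters place condition-specific acceleration differences at ~50%
#' (backswing reversal) and ~80% (downswing) of the pre-contact swing;
#' the two VR conditions receive identical shape bumps so that their
#' continua differ from `Real` but not from each other.
#'
#' @param n_participants number of participants.
#' @param n_trials putts per participant per condition.
#' @param conditions ordered condition labels; first label is the baseline.
#' @param imu_rate,cop_rate sampling rates in Hz.
#' @param imu_duration_s,cop_duration_s trace durations in seconds.
#' @param effects named list of effect rows; see Details.  Entries given
#'   here are merged over the defaults field by field.
#' @param swing named list of swing-shape parameters (merged over
#'   defaults): `onset_s`, `backswing_s`, `spike_amp`, `spike_ms`,
#'   `backswing_rel`, `bump_centers`, `bump_halfwidth`, `bump_amp`.
#' @param cop named list of centre-of-pressure parameters (merged over
#'   defaults): `footlift_s`, `footlift_amp_mm`, `footlift_dur_s`,
#'   `fluct_mm`, `osc_hz`, `drift_band`, `sagittal_gain`.
#' @param imu_noise_sd white sensor-noise SD on every accelerometer
#'   channel, m/s^2.
#' @param cmp_item_sd item-level latent noise SD of questionnaire items.
#' @param seed integer root seed; all per-trace streams derive from it.
#' @return An object of class `study_config`.
#' @examples
#' cfg <- study_config(n_participants = 3, n_trials = 2, seed = 7)
#' cfg$effects$acc_impact_transverse$VR
#' @export
study_config <- function(n_participants = 21,
                         n_trials = 20,
                         conditions = c("Real", "VR", "VRHaptic"),
                         imu_rate = 1125,
                         cop_rate = 300,
                         imu_duration_s = 6,
                         cop_duration_s = 10,
                         effects = list(),
                         swing = list(),
                         cop = list(),
                         imu_noise_sd = 0.05,
                         cmp_item_sd = 0.6,
                         seed = 1L) {
  eff_default <- list(
    acc_impact_transverse = list(intercept = 3.69, VR = -1.47,
                                 VRHaptic = -0.42,
                                 participant_sd = 1.0, residual_sd = 1.2),
    acc_impact_sagittal   = list(intercept = 0.95, VR = 0.90,
                                 VRHaptic = 0.78,
                                 participant_sd = 0.45, residual_sd = 0.6),
    log_var_sagittal      = list(intercept = -2.21, VR = 1.20,
                                 VRHaptic = 0.95,
                                 participant_sd = 0.5, residual_sd = 0.3),
    cop_drift_mm          = list(intercept = 10, VR = 4, VRHaptic = 3,
                                 participant_sd = 2.0, residual_sd = 1.0),
    cop_lambda            = list(intercept = 0.35, VR = 0.35,
                                 VRHaptic = 0.30,
                                 participant_sd = 0.04, residual_sd = 0.03),
    cmp_latent            = list(intercept = 3.4, VR = -0.40,
                                 VRHaptic = -0.35,
                                 participant_sd = 0.5, residual_sd = 0)
  )
  swing_default <- list(
    onset_s = 2.0,          # quiet stance before the backswing starts
    backswing_s = 0.75,     # minimum-jerk backswing duration
    spike_amp = 40,         # vertical impact spike amplitude, m/s^2
    spike_ms = 20,          # impact spike duration
    backswing_rel = 0.9,    # backswing braking peak relative to |impact acc|
    impact_floor = 0.5,     # minimum true impact acceleration, m/s^2
    bump_centers = c(0.50, 0.76),  # fractions of the pre-contact swing
    bump_halfwidth = 0.09,         # raised-cosine half-width, fraction
    bump_amp = list(Real = c(0, 0), VR = c(1.5, 1.5),
                    VRHaptic = c(1.5, 1.5))
  )
  cop_default <- list(
    footlift_s = 2.0,       # foot-lift event before the putt
    footlift_amp_mm = 40,   # excursion amplitude of the foot-lift artifact
    footlift_dur_s = 0.4,
    fluct_mm = 2.5,         # in-band SD of the regularity fluctuation
    osc_hz = 2.2,           # deterministic oscillation frequency
    drift_band = c(0.1, 0.5),  # slow drift frequency band, Hz
    sagittal_gain = 1.2     # sagittal drift relative to transverse
  )
  cfg <- list(
    n_participants = as.integer(n_participants),
    n_trials = as.integer(n_trials),
    conditions = as.character(conditions),
    imu_rate = imu_rate, cop_rate = cop_rate,
    imu_duration_s = imu_duration_s, cop_duration_s = cop_duration_s,
    effects = merge_spec(eff_default, effects),
    swing = merge_spec(swing_default, swing),
    cop = merge_spec(cop_default, cop),
    imu_noise_sd = imu_noise_sd,
    cmp_item_sd = cmp_item_sd,
    seed = as.integer(seed)
  )
  class(cfg) <- "study_config"
  validate_study_config(cfg)
  cfg
}

# recursive defaults <- overrides merge for nested parameter lists
merge_spec <- function(defaults, overrides) {
  if (length(overrides) == 0) return(defaults)
  stopifnot(is.list(overrides), !is.null(names(overrides)))
  for (nm in names(overrides)) {
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      defaults[[nm]] <- merge_spec(defaults[[nm]], overrides[[nm]])
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  defaults
}

validate_study_config <- function(cfg) {
  stopifnot(cfg$n_participants >= 1, cfg$n_trials >= 1,
            cfg$imu_rate > 0, cfg$cop_rate > 0,
            cfg$imu_duration_s > 0, cfg$cop_duration_s > 0,
            cfg$imu_noise_sd >= 0, cfg$cmp_item_sd >= 0,
            length(cfg$conditions) >= 2)
  for (nm in names(cfg$effects)) {
    e <- cfg$effects[[nm]]
    if (e$participant_sd < 0 || e$residual_sd < 0)
      stop("negative SD in effect row '", nm, "'", call. = FALSE)
    missing_cond <- setdiff(setdiff(cfg$conditions, cfg$conditions[1]),
                            names(e))
    if (length(missing_cond))
      stop("effect row '", nm, "' lacks condition(s): ",
           paste(missing_cond, collapse = ", "), call. = FALSE)
  }
  lam <- cfg$effects$cop_lambda
  lam_max <- lam$intercept + max(0, unlist(lam[cfg$conditions[-1]]))
  if (lam$intercept < 0 || lam_max > 1 + 1e-9)
    stop("cop_lambda baseline + effects must stay in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.study_config <- function(x, ...) {
  cat("<study_config> ", x$n_participants, " participants x ",
      length(x$conditions), " conditions x ", x$n_trials, " trials\n",
      sep = "")
  cat("  conditions:", paste(x$conditions, collapse = ", "), "\n")
  cat("  IMU ", x$imu_rate, " Hz / ", x$imu_duration_s, " s;  COP ",
      x$cop_rate, " Hz / ", x$cop_duration_s, " s;  seed ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Read or write a study configuration as YAML
#'
#' Round-trips the `study_config` fields through a plain YAML file so a
#' run can be described entirely by a text artifact.
#'
#' @param cfg a `study_config`.
#' @param path file path.
#' @return `read_study_config()` returns a `study_config`;
#'   `write_study_config()` returns `path` invisibly.
#' @export
write_study_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "study_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_study_config
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(study_config, raw)
}

# linear predictor of an effect row: intercept + condition offset
# + optional participant intercept (drawn reproducibly from the root seed)
effect_value <- function(cfg, outcome, condition, participant = NULL) {
  e <- cfg$effects[[outcome]]
  if (is.null(e)) stop("unknown outcome '", outcome, "'", call. = FALSE)
  if (!condition %in% cfg$conditions)
    stop("unknown condition '", condition, "'", call. = FALSE)
  val <- e$intercept
  if (condition != cfg$conditions[1]) val <- val + e[[condition]]
  if (!is.null(participant))
    val <- val + participant_intercept(cfg, outcome, participant)
  val
}

#' Participant random intercept for one outcome
#'
#' Drawn once per (outcome, participant) from a stream derived from the
#' root seed, so every trace and table of a study sees the same draw.
#'
#' @param cfg a `study_config`.
#' @param outcome name of an effect row in `cfg$effects`.
#' @param participant integer participant index.
#' @return A single numeric value.
#' @export
participant_intercept <- function(cfg, outcome, participant) {
  psd <- cfg$effects[[outcome]]$participant_sd
  if (psd == 0) return(0)
  local_seed(derive_seed(cfg$seed, "intercept", outcome, participant),
             rnorm(1, 0, psd))
}
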