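#' Generate a complete synthetic study
#'
#' Produces every swing and COP trace of an
#' `n_participants x conditions x n_trials` design, the trial metadata
#' table, questionnaire scores, and the ground-truth tables that
#' downstream parameter-recovery tests compare against.  Condition order
#' per participant follows a 3 x 3 Latin square cycled over participants.
#'
#' Traces are kept in memory; for the full default design this is a few
#' hundred MB, so [run_all()] regenerates traces trial-by-trial instead of
#' calling this function.  Use `write_study()` to export a study to the
#' on-disk CSV layout.
#'
#' @param cfg a [study_config()].
#' @param traces one of `"both"`, `"swing"`, `"cop"`, `"none"`: which
#'   trace families to generate (truth tables are always complete).
#' @return An object of class `motor_study`: list with `config`,
#'   `metadata` (one row per trial: `participant_id`, `condition`,
#'   `trial`, `block`, `imu_file`, `cop_file`), `swings`, `cops` (named
#'   lists of `trace`/`truth` pairs keyed `P01_Real_T01`), `cmp`
#'   (`scores` and `truth`), `swing_truth` and `cop_truth` (data frames).
#' @examples
#' st <- generate_study(study_config(n_participants = 2, n_trials = 2,
#'                                   seed = 9))
#' nrow(st$metadata)  # 2 x 3 x 2 = 12
#' @export
generate_study <- function(cfg, traces = c("both", "swing", "cop", "none")) {
  stopifnot(inherits(cfg, "study_config"))
  traces <- match.arg(traces)
  meta <- study_metadata(cfg)
  key <- trial_key(meta$participant_id, meta$condition, meta$trial)

  swings <- cops <- NULL
  if (traces %in% c("both", "swing")) {
    swings <- lapply(seq_len(nrow(meta)), function(i)
      generate_swing_trace(cfg, meta$participant[i], meta$condition[i],
                           meta$trial[i]))
    names(swings) <- key
  }
  if (traces %in% c("both", "cop")) {
    cops <- lapply(seq_len(nrow(meta)), function(i)
      generate_cop_trace(cfg, meta$participant[i], meta$condition[i],
                         meta$trial[i]))
    names(cops) <- key
  }

  swing_truth <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    tr <- if (!is.null(swings)) swings[[i]]$truth else
      generate_swing_trace(cfg, meta$participant[i], meta$condition[i],
                           meta$trial[i])$truth
    as.data.frame(tr)
  }))
  swing_truth$participant_id <- participant_label(swing_truth$participant)
  cop_truth <- do.call(rbind, lapply(seq_len(nrow(meta)), function(i) {
    tr <- if (!is.null(cops)) cops[[i]]$truth else
      generate_cop_trace(cfg, meta$participant[i], meta$condition[i],
                         meta$trial[i])$truth
    as.data.frame(tr)
  }))
  cop_truth$participant_id <- participant_label(cop_truth$participant)

  cmp <- lapply(cfg$conditions, function(cc) generate_cmp_scores(cfg, cc))
  cmp <- list(scores = do.call(rbind, lapply(cmp, `[[`, "scores")),
              truth = do.call(rbind, lapply(cmp, `[[`, "truth")))

  structure(list(config = cfg, metadata = meta, swings = swings,
                 cops = cops, cmp = cmp, swing_truth = swing_truth,
                 cop_truth = cop_truth),
            class = "motor_study")
}

#' @export
print.motor_study <- function(x, ...) {
  cat("<motor_study> ", nrow(x$metadata), " trials (",
      x$config$n_participants, " x ", length(x$config$conditions), " x ",
      x$config$n_trials, ")\n", sep = "")
  invisible(x)
}

# trial metadata with Latin-square condition order
study_metadata <- function(cfg) {
  k <- length(cfg$conditions)
  square <- outer(seq_len(k) - 1, seq_len(k) - 1, `+`) %% k + 1
  rows <- lapply(seq_len(cfg$n_participants), function(p) {
    order_p <- cfg$conditions[square[(p - 1) %% k + 1, ]]
    do.call(rbind, lapply(seq_len(k), function(b) {
      data.frame(participant = p,
                 participant_id = participant_label(p),
                 condition = order_p[b], block = b,
                 trial = seq_len(cfg$n_trials))
    }))
  })
  meta <- do.call(rbind, rows)
  meta$imu_file <- file.path("imu", paste0(
    trial_key(meta$participant_id, meta$condition, meta$trial), ".csv"))
  meta$cop_file <- file.path("cop", paste0(
    trial_key(meta$participant_id, meta$condition, meta$trial), ".csv"))
  rownames(meta) <- NULL
  meta
}

trial_key <- function(pid, condition, trial) {
  sprintf("%s_%s_T%02d", pid, condition, as.integer(trial))
}

#' Write a synthetic study to disk
#'
#' Exports the CSV layout consumed by [validate_inputs()]: `meta.csv`
#' (`participant_id`, `condition`, `trial`, `imu_file`, `cop_file`),
#' `config.yaml`, and one CSV per trace under `imu/` and `cop/`.
#'
#' @param study a `motor_study` generated with traces.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "motor_study"))
  dir.create(file.path(dir, "imu"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "cop"), recursive = TRUE, showWarnings = FALSE)
  meta <- study$metadata
  write.csv(meta[c("participant_id", "condition", "trial",
                   "imu_file", "cop_file")],
            file.path(dir, "meta.csv"), row.names = FALSE)
  write_study_config(study$config, file.path(dir, "config.yaml"))
  key <- trial_key(meta$participant_id, meta$condition, meta$trial)
  for (i in seq_len(nrow(meta))) {
    if (!is.null(study$swings))
      write_imu_csv(study$swings[[key[i]]]$trace,
                    file.path(dir, meta$imu_file[i]))
    if (!is.null(study$cops))
      write_cop_csv(study$cops[[key[i]]]$trace,
                    file.path(dir, meta$cop_file[i]))
  }
  if (!is.null(study$cmp))
    write.csv(study$cmp$scores, file.path(dir, "cmp.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Generate subject-level time-normalized swing curves directly
#'
#' Evaluates the analytic swing acceleration profile of each subject and
#' condition on `n_nodes` equally spaced fractions of the pre-contact
#' swing and adds smooth within-subject noise, emulating the average of
#' `n_trials` processed putts without running trace extraction.  This is
#' the light-weight entry point for statistical-parametric-mapping
#' simulations.
#'
#' Each subject's profile amplitude is their condition-independent
#' swing scale (outcome intercept plus participant intercept plus a
#' trial-mean residual); conditions differ only through the localized
#' shape bumps, so the continuum carries exactly the injected
#' topographical effects (the two VR conditions receive equal bumps and
#' their pairwise map is null by construction).
#'
#' @param cfg a [study_config()].
#' @param plane `"transverse"` or `"sagittal"`.
#' @param n_nodes number of curve nodes (default 101, i.e. 0-100%).
#' @param noise_sd SD of the smooth subject-by-condition noise curves
#'   before averaging over trials (divided by `sqrt(n_trials)`).
#' @param noise_fwhm smoothness of the noise curves, in nodes.
#' @param seed optional root seed override.
#' @return A `curve_set`: list with `curves`
#'   (matrix `n_participants * conditions` x `n_nodes`), `condition`,
#'   `participant_id`.
#' @export
generate_curve_set <- function(cfg, plane = c("transverse", "sagittal"),
                               n_nodes = 101, noise_sd = 0.15,
                               noise_fwhm = 15, seed = NULL) {
  stopifnot(inherits(cfg, "study_config"))
  plane <- match.arg(plane)
  if (is.null(seed)) seed <- cfg$seed
  s <- seq(0, 1, length.out = n_nodes)
  tm <- swing_timing(cfg$swing)
  grid <- list()
  lab_cond <- character(); lab_pid <- character()
  i <- 0
  for (p in seq_len(cfg$n_participants)) {
    for (cond in cfg$conditions) {
      i <- i + 1
      outcome <- paste0("acc_impact_", plane)
      mean_resid <- local_seed(
        derive_seed(seed, "curve-resid", plane, p, cond),
        rnorm(1, 0, cfg$effects[[outcome]]$residual_sd /
                sqrt(cfg$n_trials)))
      a_star <- cfg$effects[[outcome]]$intercept +
        participant_intercept(cfg, outcome, p) + mean_resid
      if (plane == "transverse")
        a_star <- max(a_star, cfg$swing$impact_floor)
      base <- if (plane == "transverse") {
        swing_profile(s, a_star, cfg, cond, tm)
      } else {
        a_star * exp(-((s - 1) * tm$pre_contact)^2 / (2 * 0.35^2))
      }
      noise <- local_seed(
        derive_seed(seed, "curve-noise", plane, p, cond),
        drop(smooth_noise_1d(1, n_nodes, fwhm = noise_fwhm,
                             sd = noise_sd / sqrt(cfg$n_trials))))
      grid[[i]] <- base + noise
      lab_cond[i] <- cond; lab_pid[i] <- participant_label(p)
    }
  }
  curve_set(do.call(rbind, grid), lab_cond, lab_pid)
}

# analytic transverse profile on normalized pre-contact time [0, 1]
swing_profile <- function(s, a_star, cfg, condition, tm = NULL) {
  if (is.null(tm)) tm <- swing_timing(cfg$swing)
  t <- s * tm$pre_contact
  out <- numeric(length(s))
  bs <- t <= tm$backswing
  out[bs] <- -(cfg$swing$backswing_rel * a_star / MJ_PEAK) *
    mj_acc(t[bs] / tm$backswing)
  out[!bs] <- (a_star / MJ_PEAK) *
    mj_acc((t[!bs] - tm$backswing) / tm$downswing)
  amp <- cfg$swing$bump_amp[[condition]]
  if (is.null(amp)) amp <- rep(0, length(cfg$swing$bump_centers))
  for (j in seq_along(cfg$swing$bump_centers)) {
    out <- out + amp[j] *
      shape_bump(s, cfg$swing$bump_centers[j], cfg$swing$bump_halfwidth)
  }
  out
}
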