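# End-to-end orchestration: generate -> process -> model -> report.

# outcome -> model specification used for the per-outcome mixed models
outcome_model_specs <- function() {
  list(
    list(outcome = "acc_impact_transverse", family = "gaussian",
         transform = "none", slopes = FALSE),
    list(outcome = "acc_impact_sagittal", family = "gaussian",
         transform = "none", slopes = FALSE),
    list(outcome = "var_sagittal", family = "gaussian",
         transform = "log", slopes = FALSE),
    list(outcome = "jerk_mean_transverse", family = "gaussian",
         transform = "none", slopes = TRUE),
    list(outcome = "jerk_mean_sagittal", family = "gaussian",
         transform = "none", slopes = TRUE),
    list(outcome = "rms_t", family = "gaussian", transform = "none",
         slopes = FALSE),
    list(outcome = "rms_s", family = "gaussian", transform = "none",
         slopes = FALSE),
    list(outcome = "sampen_t", family = "gamma", transform = "none",
         slopes = FALSE),
    list(outcome = "sampen_s", family = "gamma", transform = "none",
         slopes = FALSE),
    list(outcome = "path_length_mm", family = "gaussian",
         transform = "none", slopes = FALSE),
    list(outcome = "ellipse_area_mm2", family = "gaussian",
         transform = "log", slopes = FALSE),
    list(outcome = "cmp", family = "gaussian", transform = "none",
         slopes = FALSE)
  )
}

#' Run the full analysis pipeline on a synthetic study
#'
#' Executes the whole chain for one study configuration: trace
#' generation, swing processing, posturography, pooled Winsorizing,
#' questionnaire scoring, the twelve per-outcome mixed models with
#' Bonferroni pairwise contrasts, and the SPM comparison of the
#' time-normalized swing continua per plane.  Traces are regenerated
#' trial-by-trial from the root seed (never held in memory all at once),
#' so a rerun with the same configuration reproduces every output
#' byte for byte.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional output directory; when given, all metric
#'   tables, the model table, contrast table, SPM cluster tables,
#'   subject-mean curves and a JSON report are written there.
#' @param params named list overriding processing parameters:
#'   `imu_cutoff` (3 Hz), `imu_order` (2), `cop_cutoff` (5 Hz),
#'   `cop_order` (2), `sampen_m` (2), `sampen_r_factor` (0.2),
#'   `sampen_rate` (100 Hz), `n_nodes` (101), `alpha` (0.05),
#'   `winsor_z` (3), `cmp_mode` ("sum").
#' @param seed optional override of `cfg$seed`.
#' @param quiet suppress progress messages.
#' @return An object of class `motor_report`: trial metrics
#'   (Winsorized), raw metrics, rejected trials, model table, contrasts,
#'   SPM results per plane, subject-mean curve sets, provenance
#'   (config hash, seed, package version) and the processing parameters.
#' @export
run_all <- function(cfg = study_config(), out_dir = NULL, params = list(),
                    seed = NULL, quiet = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  if (!is.null(seed)) {
    cfg$seed <- as.integer(seed)
  }
  p <- merge_spec(list(imu_cutoff = 3, imu_order = 2, cop_cutoff = 5,
                       cop_order = 2, sampen_m = 2, sampen_r_factor = 0.2,
                       sampen_rate = 100, n_nodes = 101, alpha = 0.05,
                       winsor_z = 3, cmp_mode = "sum"), params)
  say <- function(...) if (!quiet) message(...)
  meta <- study_metadata(cfg)
  n <- nrow(meta)

  say("processing ", n, " trials (swing + COP) ...")
  swing_rows <- vector("list", n)
  posture_rows <- vector("list", n)
  rejected <- list()
  curves_t <- matrix(NA_real_, n, p$n_nodes)
  curves_s <- matrix(NA_real_, n, p$n_nodes)
  for (i in seq_len(n)) {
    id <- meta[i, c("participant_id", "condition", "trial")]
    sw <- generate_swing_trace(cfg, meta$participant[i], meta$condition[i],
                               meta$trial[i])
    ps <- process_swing(sw$trace, target_rate = cfg$imu_rate,
                        cutoff = p$imu_cutoff, order = p$imu_order,
                        n_nodes = p$n_nodes)
    if (is.na(ps$rejected_reason)) {
      swing_rows[[i]] <- cbind(id, ps$metrics)
      curves_t[i, ] <- ps$curves[, "transverse"]
      curves_s[i, ] <- ps$curves[, "sagittal"]
    } else {
      rejected[[length(rejected) + 1]] <-
        cbind(id, stage = "swing", reason = ps$rejected_reason)
    }
    cp <- generate_cop_trace(cfg, meta$participant[i], meta$condition[i],
                             meta$trial[i])
    pm <- tryCatch(
      posture_metrics(cp$trace, cutoff = p$cop_cutoff,
                      order = p$cop_order, sampen_m = p$sampen_m,
                      sampen_r_factor = p$sampen_r_factor,
                      sampen_rate = p$sampen_rate),
      error = function(e) conditionMessage(e))
    if (is.character(pm)) {
      rejected[[length(rejected) + 1]] <-
        cbind(id, stage = "cop", reason = pm)
    } else {
      posture_rows[[i]] <- cbind(id, pm)
    }
  }
  swing_metrics <- do.call(rbind, swing_rows)
  posture_metrics <- do.call(rbind, posture_rows)
  rejected <- if (length(rejected)) do.call(rbind, rejected) else
    data.frame()

  say("scoring questionnaire ...")
  cmp_scores <- do.call(rbind, lapply(cfg$conditions, function(cc) {
    sc <- generate_cmp_scores(cfg, cc)$scores
    sc$cmp <- apply(sc[paste0("item_", 1:6)], 1, score_cmp,
                    mode = p$cmp_mode)
    sc
  }))

  trial_metrics <- merge(swing_metrics, posture_metrics,
                         by = c("participant_id", "condition", "trial"),
                         all = TRUE)
  raw_metrics <- trial_metrics
  outcome_cols <- c("acc_impact_transverse", "acc_impact_sagittal",
                    "var_sagittal", "jerk_mean_transverse",
                    "jerk_mean_sagittal", "rms_t", "rms_s", "sampen_t",
                    "sampen_s", "path_length_mm", "ellipse_area_mm2")
  for (cn in outcome_cols) {
    v <- trial_metrics[[cn]]
    ok <- is.finite(v)
    if (sum(ok) >= 3)
      trial_metrics[[cn]][ok] <- winsorize_outliers(v[ok], p$winsor_z)
  }
  cmp_scores$cmp <- winsorize_outliers(cmp_scores$cmp, p$winsor_z)

  say("fitting mixed models ...")
  specs <- outcome_model_specs()
  fits <- lapply(specs, function(sp) {
    tab <- if (sp$outcome == "cmp") cmp_scores else trial_metrics
    tryCatch(
      suppressMessages(suppressWarnings(
        fit_lmm(tab, sp$outcome, family = sp$family,
                transform = sp$transform, random_slopes = sp$slopes,
                reference = cfg$conditions[1]))),
      error = function(e) conditionMessage(e))
  })
  names(fits) <- vapply(specs, `[[`, "", "outcome")
  model_table <- do.call(rbind, lapply(seq_along(fits), function(i)
    model_table_row(specs[[i]], fits[[i]])))
  contrasts <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    if (!inherits(f, "lmm_result")) return(NULL)
    ct <- suppressMessages(pairwise_bonferroni(f))
    cbind(outcome = nm, ct)
  }))

  say("SPM over swing continua ...")
  spm <- list()
  curve_sets <- list()
  for (plane in c("transverse", "sagittal")) {
    curves <- if (plane == "transverse") curves_t else curves_s
    cs <- subject_mean_curves(curves, meta)
    curve_sets[[plane]] <- cs
    spm[[plane]] <- spm_compare_conditions(cs, alpha = p$alpha)
  }

  provenance <- list(config_hash = config_hash(cfg), seed = cfg$seed,
                     package_version =
                       as.character(utils::packageVersion("motorlab")),
                     n_trials = n, n_rejected = nrow(rejected))
  report <- structure(list(
    config = cfg, params = p, trial_metrics = trial_metrics,
    raw_metrics = raw_metrics, cmp_scores = cmp_scores,
    rejected = rejected, fits = fits, model_table = model_table,
    contrasts = contrasts, spm = spm, curve_sets = curve_sets,
    provenance = provenance), class = "motor_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

subject_mean_curves <- function(curves, meta) {
  ok <- rowSums(is.na(curves)) == 0
  key <- interaction(meta$participant_id, meta$condition, drop = TRUE)
  agg <- rowsum(curves[ok, , drop = FALSE], key[ok]) /
    as.vector(table(key[ok]))
  parts <- strsplit(rownames(agg), ".", fixed = TRUE)
  curve_set(agg,
            condition = vapply(parts, `[`, "", 2),
            participant_id = vapply(parts, `[`, "", 1))
}

model_table_row <- function(sp, fit) {
  base <- data.frame(outcome = sp$outcome, family = sp$family,
                     transform = sp$transform,
                     random_slopes = sp$slopes)
  if (!inherits(fit, "lmm_result"))
    return(cbind(base, total_r2 = NA, marginal_r2 = NA, intercept = NA,
                 intercept_lo = NA, intercept_hi = NA, beta_VR = NA,
                 beta_VR_lo = NA, beta_VR_hi = NA, beta_VRHaptic = NA,
                 beta_VRHaptic_lo = NA, beta_VRHaptic_hi = NA,
                 std_beta_VR = NA, std_beta_VRHaptic = NA,
                 label_VR = NA, label_VRHaptic = NA, singular = NA,
                 note = as.character(fit)))
  fx <- fit$fixed
  g <- function(term, col) {
    i <- match(term, fx$term)
    if (is.na(i)) NA_real_ else fx[[col]][i]
  }
  cbind(base, data.frame(
    total_r2 = fit$total_r2, marginal_r2 = fit$marginal_r2,
    intercept = g("(Intercept)", "estimate"),
    intercept_lo = g("(Intercept)", "ci_lower"),
    intercept_hi = g("(Intercept)", "ci_upper"),
    beta_VR = g("conditionVR", "estimate"),
    beta_VR_lo = g("conditionVR", "ci_lower"),
    beta_VR_hi = g("conditionVR", "ci_upper"),
    beta_VRHaptic = g("conditionVRHaptic", "estimate"),
    beta_VRHaptic_lo = g("conditionVRHaptic", "ci_lower"),
    beta_VRHaptic_hi = g("conditionVRHaptic", "ci_upper"),
    std_beta_VR = unname(fit$std_beta["conditionVR"]),
    std_beta_VRHaptic = unname(fit$std_beta["conditionVRHaptic"]),
    label_VR = unname(fit$std_label["conditionVR"]),
    label_VRHaptic = unname(fit$std_label["conditionVRHaptic"]),
    singular = fit$singular, note = NA_character_))
}

#' @export
print.motor_report <- function(x, ...) {
  cat("<motor_report> seed ", x$provenance$seed, ", ",
      x$provenance$n_trials, " trials, ", x$provenance$n_rejected,
      " rejected\n", sep = "")
  cat("-- model table --\n")
  print(x$model_table[c("outcome", "family", "total_r2", "marginal_r2",
                        "intercept", "beta_VR", "beta_VRHaptic")],
        row.names = FALSE, digits = 3)
  for (plane in names(x$spm)) {
    omn <- x$spm[[plane]]$omnibus
    cat("-- SPM{F} ", plane, ": ", nrow(omn$clusters),
        " cluster(s)\n", sep = "")
  }
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, nm) if (!is.null(df) && nrow(df))
    write.csv(df, file.path(out_dir, nm), row.names = FALSE)
  wcsv(report$trial_metrics, "trial_metrics.csv")
  wcsv(report$raw_metrics, "trial_metrics_raw.csv")
  wcsv(report$cmp_scores, "cmp_scores.csv")
  wcsv(report$rejected, "rejected_trials.csv")
  wcsv(report$model_table, "model_table.csv")
  wcsv(report$contrasts, "contrasts.csv")
  for (plane in names(report$spm)) {
    sp <- report$spm[[plane]]
    tag <- function(nm, df) if (nrow(df)) cbind(map = nm, df) else NULL
    cl <- do.call(rbind, c(
      list(tag("omnibus_F", sp$omnibus$clusters)),
      lapply(names(sp$pairwise), function(nm)
        tag(nm, sp$pairwise[[nm]]$clusters))))
    wcsv(cl, paste0("spm_clusters_", plane, ".csv"))
    cs <- report$curve_sets[[plane]]
    cdf <- data.frame(participant_id = cs$participant_id,
                      condition = cs$condition)
    colnames(cs$curves) <- sprintf("node_%03d",
                                   seq_len(ncol(cs$curves)) - 1)
    wcsv(cbind(cdf, cs$curves), paste0("curves_", plane, ".csv"))
  }
  write_study_config(report$config, file.path(out_dir, "config.yaml"))
  summary_list <- list(
    provenance = report$provenance,
    params = report$params,
    models = report$model_table,
    n_spm_clusters = lapply(report$spm, function(sp)
      list(omnibus = nrow(sp$omnibus$clusters),
           pairwise = lapply(sp$pairwise, function(z)
             nrow(z$clusters))))
  )
  jsonlite::write_json(summary_list, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(out_dir)
}

# FNV-1a hash of the YAML form of the configuration
config_hash <- function(cfg) {
  bytes <- utf8ToInt(yaml::as.yaml(unclass(cfg)))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Validate an on-disk study before processing
#'
#' Checks the metadata schema, trace-file presence, CSV schemas,
#' strictly increasing time vectors, and condition labels.  Missing or
#' invalid files are tolerated and listed (such trials are simply absent
#' from downstream models); nothing is thrown.
#'
#' @param meta_csv path to the metadata CSV (`participant_id`,
#'   `condition`, `trial`, `imu_file`, `cop_file`).
#' @param trace_dir directory that trace paths are relative to.
#' @param conditions expected condition labels.
#' @return A list of class `validation_report`: `ok` (logical), `issues`
#'   (data frame with `participant_id`, `condition`, `trial`, `file`,
#'   `problem`) and `summary` counts.
#' @export
validate_inputs <- function(meta_csv, trace_dir,
                            conditions = c("Real", "VR", "VRHaptic")) {
  issues <- list()
  add <- function(pid, cond, trial, file, problem)
    issues[[length(issues) + 1]] <<- data.frame(
      participant_id = pid, condition = cond, trial = trial,
      file = file, problem = problem)
  meta <- tryCatch(read.csv(meta_csv), error = function(e) NULL)
  need <- c("participant_id", "condition", "trial", "imu_file",
            "cop_file")
  if (is.null(meta) || !all(need %in% names(meta))) {
    return(structure(list(ok = FALSE, issues = data.frame(
      participant_id = NA, condition = NA, trial = NA, file = meta_csv,
      problem = "metadata unreadable or missing required columns"),
      summary = c(trials = 0, missing = 0, invalid = 0)),
      class = "validation_report"))
  }
  bad_cond <- !meta$condition %in% conditions
  for (i in which(bad_cond))
    add(meta$participant_id[i], meta$condition[i], meta$trial[i], NA,
        "unknown condition label")
  check_trace <- function(i, file, reader) {
    path <- file.path(trace_dir, file)
    if (!file.exists(path)) {
      add(meta$participant_id[i], meta$condition[i], meta$trial[i],
          file, "file missing")
      return(invisible())
    }
    tr <- tryCatch(reader(path), error = function(e)
      conditionMessage(e))
    if (is.character(tr))
      add(meta$participant_id[i], meta$condition[i], meta$trial[i],
          file, paste("invalid:", tr))
    invisible()
  }
  for (i in seq_len(nrow(meta))) {
    check_trace(i, meta$imu_file[i], read_imu_csv)
    check_trace(i, meta$cop_file[i], read_cop_csv)
  }
  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(participant_id = character(), condition = character(),
               trial = integer(), file = character(),
               problem = character())
  structure(list(
    ok = nrow(issues) == 0, issues = issues,
    summary = c(trials = nrow(meta),
                missing = sum(issues$problem == "file missing"),
                invalid = sum(grepl("^invalid", issues$problem)))),
    class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> ", x$summary["trials"], " trials; ",
      x$summary["missing"], " missing file(s), ", x$summary["invalid"],
      " invalid file(s)\n", sep = "")
  if (nrow(x$issues)) print(head(x$issues, 20), row.names = FALSE)
  invisible(x)
}
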