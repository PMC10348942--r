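test_that("study metadata has the full crossed design in Latin-square order", {
  cfg <- study_config(n_participants = 21, n_trials = 20)
  meta <- motorlab:::study_metadata(cfg)
  expect_equal(nrow(meta), 21 * 3 * 20)
  expect_equal(as.integer(table(meta$condition)), rep(21L * 20L, 3))
  # each condition appears in each block position equally often (cycled square)
  tab <- table(meta$condition[meta$trial == 1], meta$block[meta$trial == 1])
  expect_true(all(tab == 7))
  st <- generate_study(study_config(n_participants = 2, n_trials = 2,
                                    seed = 9))
  expect_equal(nrow(st$metadata), 12)
  expect_length(st$swings, 12)
})

test_that("trace generation is bit-deterministic in (config, seed)", {
  cfg <- quick_config(seed = 31)
  a <- generate_swing_trace(cfg, 2, "VR", 1)
  b <- generate_swing_trace(cfg, 2, "VR", 1)
  expect_identical(a, b)
  ca <- generate_cop_trace(cfg, 2, "VR", 1)
  cb <- generate_cop_trace(cfg, 2, "VR", 1)
  expect_identical(ca, cb)
  # different trials get different streams
  expect_false(identical(a$trace$acc,
                         generate_swing_trace(cfg, 2, "VR", 2)$trace$acc))
})

test_that("transverse channel equals the true impact acceleration at the impact sample", {
  cfg <- study_config(seed = 77, imu_noise_sd = 0)
  for (cond in c("Real", "VR", "VRHaptic")) {
    sw <- generate_swing_trace(cfg, 3, cond, 5)
    expect_lt(abs(sw$trace$acc[sw$truth$impact_index, "transverse"] -
                    sw$truth$acc_impact_transverse), 1e-9)
  }
})

test_that("zero-noise zero-sagittal configuration leaves the sagittal channel silent", {
  cfg <- study_config(seed = 1, imu_noise_sd = 0, effects = list(
    acc_impact_sagittal = deterministic_effects(0, 0, 0),
    log_var_sagittal = deterministic_effects(-Inf, 0, 0)))
  sw <- generate_swing_trace(cfg, 1, "Real", 1)
  expect_equal(max(abs(sw$trace$acc[, "sagittal"])), 0)
  # vertical channel is silent everywhere except the impact spike
  pre <- seq_len(sw$truth$impact_index - round(0.02 * cfg$imu_rate))
  expect_equal(max(abs(sw$trace$acc[pre, "vertical"])), 0)
})

test_that("with all variance sources off, condition mean differences equal the programmed effects", {
  cfg <- study_config(seed = 1, imu_noise_sd = 0, effects = list(
    acc_impact_transverse = deterministic_effects(3.69, -1.47, -0.42)))
  real <- sapply(1:5, function(i)
    generate_swing_trace(cfg, i, "Real", i)$truth$acc_impact_transverse)
  vr <- sapply(1:5, function(i)
    generate_swing_trace(cfg, i, "VR", i)$truth$acc_impact_transverse)
  expect_equal(mean(real) - mean(vr), 1.47, tolerance = 1e-12)
})

test_that("participant intercept draws recover the configured SD", {
  cfg <- study_config(n_participants = 200, seed = 17, effects = list(
    acc_impact_transverse = list(intercept = 3.69, VR = -1.47,
                                 VRHaptic = -0.42, participant_sd = 2.0,
                                 residual_sd = 1.2)))
  ints <- sapply(1:200, function(p)
    participant_intercept(cfg, "acc_impact_transverse", p))
  expect_lt(abs(sd(ints) - 2.0) / 2.0, 0.1)
  # zero participant SD means zero between-participant variance
  cfg0 <- study_config(seed = 17)
  cfg0$effects$acc_impact_transverse$participant_sd <- 0
  expect_equal(sd(sapply(1:20, function(p)
    participant_intercept(cfg0, "acc_impact_transverse", p))), 0)
})

test_that("doubling COP drift amplitude strictly increases path length", {
  mk <- function(drift) study_config(seed = 5, effects = list(
    cop_drift_mm = deterministic_effects(drift, 0, 0)))
  a <- generate_cop_trace(mk(8), 1, "Real", 1)$trace
  b <- generate_cop_trace(mk(16), 1, "Real", 1)$trace
  pl <- function(tr) path_length(segment_trial(filter_cop(tr)))
  expect_gt(pl(b), pl(a))
})

test_that("fully regular COP trace (lambda 1, no drift) has near-zero entropy downstream", {
  cfg <- study_config(seed = 4, effects = list(
    cop_drift_mm = deterministic_effects(0, 0, 0),
    cop_lambda = deterministic_effects(1, 0, 0)))
  cp <- generate_cop_trace(cfg, 1, "Real", 1)
  pm <- suppressWarnings(posture_metrics(cp$trace))
  # a clean sine sampled at ~45 samples/cycle has a SampEn floor of ~0.2
  # (continuous phase spreads template edges); "near zero" means an order
  # of magnitude below the white-noise level of ~2.2
  expect_lt(pm$sampen_t, 0.35)
  expect_lt(pm$sampen_s, 0.35)
})

test_that("questionnaire scores are integer, clamped, and shift with condition", {
  cfg <- study_config(seed = 3, cmp_item_sd = 0, effects = list(
    cmp_latent = deterministic_effects(3, 0, 0)))
  sc <- generate_cmp_scores(cfg, "Real")$scores
  expect_true(all(as.matrix(sc[paste0("item_", 1:6)]) == 3))
  # clamping holds for extreme latent parameters
  cfg2 <- study_config(seed = 3, cmp_item_sd = 4, effects = list(
    cmp_latent = list(intercept = 9, VR = -12, VRHaptic = 0,
                      participant_sd = 2, residual_sd = 0)))
  for (cc in c("Real", "VR")) {
    items <- as.matrix(generate_cmp_scores(cfg2, cc)$scores[paste0("item_", 1:6)])
    expect_true(all(items >= 1 & items <= 5))
  }
  # Monte Carlo: +1 latent unit for Real shows up in the mean item score
  cfg3 <- study_config(n_participants = 300, seed = 8, effects = list(
    cmp_latent = list(intercept = 3.5, VR = -1, VRHaptic = 0,
                      participant_sd = 0.3, residual_sd = 0)))
  m_real <- mean(as.matrix(
    generate_cmp_scores(cfg3, "Real")$scores[paste0("item_", 1:6)]))
  m_vr <- mean(as.matrix(
    generate_cmp_scores(cfg3, "VR")$scores[paste0("item_", 1:6)]))
  expect_gt(m_real, m_vr)
})

test_that("config validation rejects inconsistent parameters", {
  expect_error(study_config(effects = list(
    acc_impact_transverse = list(intercept = 1, VR = 0, VRHaptic = 0,
                                 participant_sd = -1, residual_sd = 1))),
    "negative SD")
  expect_error(study_config(effects = list(
    cop_lambda = list(intercept = 0.8, VR = 0.5, VRHaptic = 0,
                      participant_sd = 0, residual_sd = 0))),
    "lambda")
  expect_error(generate_swing_trace(quick_config(), 1, "Mars", 1),
               "unknown condition")
  # YAML round trip preserves the configuration
  cfg <- quick_config(seed = 12)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_study_config(cfg, path)
  expect_equal(read_study_config(path), cfg)
})
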