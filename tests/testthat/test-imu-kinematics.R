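test_that("resampling is exact for uniform and linear inputs and accurate for jittered sines", {
  t <- seq(0, 1, by = 1 / 500)
  ramp <- 2 + 3 * t
  tr <- imu_trace(t, cbind(ramp, ramp, ramp), 500)
  same <- resample_uniform(tr, 500)
  expect_equal(same$acc, tr$acc, tolerance = 1e-12)
  up <- resample_uniform(tr, 1125)
  expect_equal(up$acc[, 1], 2 + 3 * up$time, tolerance = 1e-12)

  set.seed(2)
  tj <- sort(t + runif(length(t), -2e-4, 2e-4))
  s <- sin(2 * pi * 2 * tj)
  trj <- imu_trace(tj, cbind(s, s, s), 500)
  re <- resample_uniform(trj, 1125)
  expect_lt(max(abs(re$acc[, 1] - sin(2 * pi * 2 * re$time))), 1e-3)

  bad <- tr; bad$time[5] <- bad$time[3]
  expect_error(resample_uniform(bad, 500), "increasing")
})

test_that("zero-phase Butterworth matches its magnitude response", {
  expect_lt(max(abs(lowpass_butterworth(rep(7, 2000), 3, 2, 1125) - 7)),
            1e-9)
  t <- seq(0, 4, by = 1 / 1125)
  mid <- 1500:3000
  pass <- lowpass_butterworth(sin(2 * pi * 0.5 * t), 3, 2, 1125)
  expect_lt(abs(max(abs(pass[mid])) - 1), 0.02)
  stop_band <- lowpass_butterworth(sin(2 * pi * 30 * t), 3, 2, 1125)
  expect_lt(max(abs(stop_band[mid])), 0.02)
  expect_error(lowpass_butterworth(1:10, 600, 2, 1125), "cutoff")
})

test_that("putt detection finds the spike, skips noise, and enforces separation", {
  cfg <- study_config(seed = 42)
  for (i in 1:6) {
    sw <- generate_swing_trace(cfg, i, c("Real", "VR", "VRHaptic")[(i %% 3) + 1], i)
    peaks <- detect_putts(sw$trace)
    expect_length(peaks, 1)
    expect_lte(abs(peaks - sw$truth$impact_index), 3)
  }
  n <- 6 * 1125
  t <- (seq_len(n) - 1) / 1125
  set.seed(3)
  noise <- imu_trace(t, cbind(0, rnorm(n, 0, 0.05), 0), 1125)
  expect_length(detect_putts(noise), 0)
  # two spikes 0.5 s apart with 2 s separation: keep the larger
  v <- rnorm(n, 0, 0.05)
  v[3000] <- v[3000] + 20
  v[3562] <- v[3562] + 35
  two <- imu_trace(t, cbind(0, v, 0), 1125)
  expect_equal(detect_putts(two), 3562L)
})

test_that("pre-contact extraction recovers the movement onset", {
  cfg <- study_config(seed = 42)
  for (i in 1:6) {
    cond <- c("Real", "VR", "VRHaptic")[(i %% 3) + 1]
    sw <- generate_swing_trace(cfg, i, cond, i)
    ps <- process_swing(sw$trace)
    expect_true(is.na(ps$rejected_reason))
    expect_lt(abs(sw$trace$time[ps$onset_index] - sw$truth$onset_s), 0.05)
  }
  # degenerate impact index is rejected, not silently processed
  sw <- generate_swing_trace(cfg, 1, "Real", 1)
  expect_error(extract_pre_contact(sw$trace, 1), "rejected")
})

test_that("doubling the pre-swing quiet period leaves the segment unchanged", {
  base <- study_config(seed = 9, imu_noise_sd = 0)
  padded <- study_config(seed = 9, imu_noise_sd = 0, imu_duration_s = 8,
                         swing = list(onset_s = 4))
  pa <- process_swing(generate_swing_trace(base, 1, "Real", 1)$trace)
  pb <- process_swing(generate_swing_trace(padded, 1, "Real", 1)$trace)
  expect_lte(abs(pa$metrics$n_samples - pb$metrics$n_samples), 2)
})

test_that("jerk is the exact discrete derivative of acceleration", {
  mk_seg <- function(acc, rate = 1000) {
    n <- nrow(acc)
    structure(list(time = (seq_len(n) - 1) / rate, acc = acc,
                   onset_index = 1L, impact_index = n, rate = rate),
              class = "swing_segment")
  }
  t <- seq(0, 1, by = 1e-3)
  ramp <- mk_seg(cbind(transverse = 3 * t, vertical = 0 * t,
                       sagittal = 5 + 0 * t))
  j <- compute_jerk(ramp)
  expect_equal(unname(j[, "transverse"]), rep(3, length(t) - 1),
               tolerance = 1e-9)
  expect_equal(max(abs(j[, "sagittal"])), 0)
  quad <- mk_seg(cbind(transverse = t^2, vertical = 0 * t, sagittal = 0 * t))
  jq <- compute_jerk(quad)[, "transverse"]
  mid_t <- (t[-1] + t[-length(t)]) / 2
  expect_lt(max(abs(jq - 2 * mid_t)), 1e-3)
  # cumulative sum of jerk reconstructs acceleration differences exactly
  cfg <- study_config(seed = 6)
  sw <- generate_swing_trace(cfg, 1, "VR", 1)
  ps <- process_swing(sw$trace)
  seg <- extract_pre_contact(resample_uniform(sw$trace, 1125),
                             ps$impact_index)
  jj <- compute_jerk(seg)
  recon <- seg$acc[1, "transverse"] +
    cumsum(jj[, "transverse"]) / seg$rate
  expect_equal(recon, unname(seg$acc[-1, "transverse"]), tolerance = 1e-9)
})

test_that("swing metrics recover programmed values and match brute-force variance", {
  cfg <- study_config(seed = 1, imu_noise_sd = 0, effects = list(
    acc_impact_transverse = deterministic_effects(3.69, -1.47, -0.42)))
  ps <- process_swing(generate_swing_trace(cfg, 1, "Real", 1)$trace)
  expect_lt(abs(ps$metrics$acc_impact_transverse - 3.69), 0.05)
  # silent sagittal channel gives exactly zero variance and jerk
  cfg0 <- study_config(seed = 1, imu_noise_sd = 0, effects = list(
    acc_impact_sagittal = deterministic_effects(0, 0, 0),
    log_var_sagittal = deterministic_effects(-Inf, 0, 0)))
  ps0 <- process_swing(generate_swing_trace(cfg0, 1, "Real", 1)$trace)
  expect_equal(ps0$metrics$var_sagittal, 0)
  expect_equal(ps0$metrics$jerk_mean_sagittal, 0)
  # two-pass variance oracle
  sw <- generate_swing_trace(study_config(seed = 14), 2, "VR", 3)
  ps2 <- process_swing(sw$trace)
  seg <- extract_pre_contact(resample_uniform(sw$trace, 1125),
                             ps2$impact_index)
  expect_equal(ps2$metrics$var_sagittal, var_brute(seg$acc[, "sagittal"]),
               tolerance = 1e-12)
})

test_that("transverse metrics are unaffected by the sagittal channel", {
  cfg <- study_config(seed = 23, imu_noise_sd = 0)
  sw <- generate_swing_trace(cfg, 1, "Real", 1)
  ps1 <- process_swing(sw$trace)
  noisy <- sw$trace
  set.seed(99)
  noisy$acc[, "sagittal"] <- noisy$acc[, "sagittal"] +
    rnorm(nrow(noisy$acc), 0, 0.5)
  ps2 <- process_swing(noisy)
  expect_lt(abs(ps1$metrics$acc_impact_transverse -
                  ps2$metrics$acc_impact_transverse), 1e-9)
  expect_lt(abs(ps1$metrics$jerk_mean_transverse -
                  ps2$metrics$jerk_mean_transverse), 1e-9)
})

test_that("time normalization preserves endpoints and linear structure", {
  n <- 101
  t <- seq(0, 1, length.out = n)
  seg <- structure(list(time = t,
                        acc = cbind(transverse = 1 + 2 * t,
                                    vertical = t^3, sagittal = -t),
                        onset_index = 1L, impact_index = n, rate = 100),
                   class = "swing_segment")
  out <- time_normalize(seg, n)
  expect_equal(out, seg$acc, tolerance = 1e-12)
  out51 <- time_normalize(seg, 51)
  expect_equal(out51[1, ], seg$acc[1, ])
  expect_equal(out51[51, ], seg$acc[n, ])
  expect_equal(out51[, "transverse"],
               1 + 2 * seq(0, 1, length.out = 51), tolerance = 1e-12)
})

test_that("Winsorizing implements the 1%-beyond-next-extreme rule", {
  x <- c(rep(1, 30), 100)
  w <- winsorize_outliers(x)
  expect_equal(w[31], 1.01)
  expect_equal(w[1:30], rep(1, 30))
  expect_equal(w, winsorize_brute(x))
  # no outliers: untouched; idempotence on fixtures
  set.seed(4)
  y <- rnorm(50)
  expect_equal(winsorize_outliers(y), y)
  expect_equal(winsorize_outliers(w), w)
  # negative scale: sign-consistent replacement
  xn <- c(rep(-1, 30), -100)
  wn <- winsorize_outliers(xn)
  expect_equal(wn[31], -1.01)
  expect_equal(wn, winsorize_brute(xn))
  # randomized fixtures against the brute-force oracle
  for (i in 1:5) {
    set.seed(i)
    v <- c(rnorm(40), rnorm(2, 0, 25))
    expect_equal(winsorize_outliers(v), winsorize_brute(v))
  }
  expect_equal(winsorize_outliers(rep(2, 10)), rep(2, 10))
})
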