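test_that("pointwise repeated-measures F matches a scalar ANOVA oracle", {
  set.seed(31)
  S <- 10; C <- 3; N <- 60
  curves <- smooth_noise_1d(S * C, N, fwhm = 10) +
    rep(rnorm(S, 0, 0.5), each = C)  # subject offsets
  cond <- rep(c("A", "B", "C"), S)
  subj <- rep(sprintf("S%02d", 1:S), each = C)
  cs <- curve_set(curves, cond, subj)
  fit <- pointwise_f(cs)
  expect_equal(fit$df, c(2, 18))
  for (node in c(1, 17, 30, 45, 60)) {
    expect_equal(fit$stat[node],
                 rm_anova_f_oracle(curves[, node], cond, subj),
                 tolerance = 1e-9)
  }
  # degenerate zero-variance input errors out
  flat <- curve_set(matrix(1, 6, 10), rep(c("A", "B"), 3),
                    rep(sprintf("S%d", 1:3), each = 2))
  expect_error(pointwise_f(flat), "zero within-cell variance")
})

test_that("pointwise paired t matches t.test and squares to the F map", {
  set.seed(12)
  S <- 14; N <- 40
  curves <- smooth_noise_1d(2 * S, N, fwhm = 8)
  cond <- rep(c("A", "B"), each = S)
  subj <- rep(sprintf("S%02d", 1:S), 2)
  cs <- curve_set(curves, cond, subj)
  fit_t <- pointwise_t_paired(cs)
  for (node in c(1, 10, 20, 30, 40)) {
    a <- curves[cond == "A", node][order(subj[cond == "A"])]
    b <- curves[cond == "B", node][order(subj[cond == "B"])]
    expect_equal(unname(fit_t$stat[node]),
                 unname(stats::t.test(b, a, paired = TRUE)$statistic),
                 tolerance = 1e-9)
  }
  fit_f <- pointwise_f(cs)
  expect_equal(fit_f$stat, fit_t$stat^2, tolerance = 1e-9)
  # identical condition curves give t = 0 everywhere
  same <- curve_set(rbind(curves[1:S, ], curves[1:S, ]), cond, subj)
  expect_true(all(pointwise_t_paired(same)$stat == 0))
  # constant offset with zero variance hits the signed-Inf sentinel
  # (dyadic values keep the offset exactly representable)
  dy <- matrix(sample(-8:8, 2 * S * N, replace = TRUE) / 4, 2 * S, N)
  off <- curve_set(rbind(dy[1:S, ], dy[1:S, ] + 1), cond, subj)
  expect_true(all(pointwise_t_paired(off)$stat == Inf))
})

test_that("FWHM estimation is calibrated, bounded for white noise, and scale-free", {
  set.seed(77)
  ests <- replicate(100, estimate_fwhm(smooth_noise_1d(50, 101, fwhm = 20)))
  expect_lt(abs(mean(ests) - 20) / 20, 0.2)
  set.seed(78)
  expect_lt(estimate_fwhm(smooth_noise_1d(50, 101, fwhm = 0)), 3)
  set.seed(79)
  r <- smooth_noise_1d(20, 101, fwhm = 12)
  expect_equal(estimate_fwhm(r), estimate_fwhm(10 * r), tolerance = 1e-12)
  expect_error(estimate_fwhm(matrix(0, 5, 20)), "all-zero")
})

test_that("RFT threshold has the right limits and monotonicities", {
  df <- c(1, 19)
  z_smooth <- rft_threshold(0.05, df, 101, fwhm = 1e5, "t")
  expect_lt(abs(z_smooth - qt(0.95, 19)) / qt(0.95, 19), 0.01)
  zz <- sapply(c(5, 10, 20, 40, 80), function(fw)
    rft_threshold(0.05, df, 101, fw, "t"))
  expect_true(all(diff(zz) < 0))
  aa <- sapply(c(0.1, 0.05, 0.01, 0.001), function(a)
    rft_threshold(a, df, 101, 20, "t"))
  expect_true(all(diff(aa) > 0))
  nn <- sapply(c(51, 101, 201, 401), function(n)
    rft_threshold(0.05, df, n, 20, "t"))
  expect_true(all(diff(nn) > 0))
})

test_that("the F-field threshold honours the F(1, nu) = t^2 excursion identity", {
  # EC densities: clusters of {F(1, nu) > u} are clusters of {|t| > sqrt(u)},
  # so the F threshold at alpha must equal the squared |t| threshold
  z_t2 <- rft_threshold(0.025, c(1, 19), 101, 15, "t")^2
  z_f <- rft_threshold(0.05, c(1, 19), 101, 15, "F")
  expect_equal(z_f, z_t2, tolerance = 1e-4)
})

test_that("cluster inference localizes effects and orders p by extent and height", {
  stat <- rep(0.5, 101)
  expect_equal(nrow(cluster_inference(stat, 3, 10, c(1, 19), "t")), 0)
  stat[45:55] <- 6
  cl <- cluster_inference(stat, 3, 10, c(1, 19), "t")
  expect_equal(nrow(cl), 1)
  expect_equal(c(cl$start_node, cl$end_node), c(45, 55))
  expect_lt(cl$p_value, 0.05)
  # wider cluster at the same height is less probable under the null
  stat2 <- rep(0.5, 101); stat2[40:60] <- 6
  cl2 <- cluster_inference(stat2, 3, 10, c(1, 19), "t")
  expect_lt(cl2$p_value, cl$p_value)
})

test_that("condition comparison recovers the injected topography", {
  cfg <- study_config(seed = 5)
  cs <- generate_curve_set(cfg, "transverse")
  sp <- spm_compare_conditions(cs, alpha = 0.05)
  hw <- cfg$swing$bump_halfwidth
  lo <- round((cfg$swing$bump_centers - hw) * 100) + 1
  hi <- round((cfg$swing$bump_centers + hw) * 100) + 1
  omn <- sp$omnibus$clusters
  expect_equal(nrow(omn), 2)
  for (j in 1:2) {
    expect_lt(omn$start_node[j], hi[j])
    expect_gt(omn$end_node[j], lo[j])
    expect_lt(omn$p_value[j], 0.05)
  }
  expect_equal(nrow(sp$pairwise$Real_vs_VR$clusters), 2)
  expect_equal(nrow(sp$pairwise$VR_vs_VRHaptic$clusters), 0)
  # sagittal continua carry no condition effects
  sp_s <- spm_compare_conditions(generate_curve_set(cfg, "sagittal"))
  expect_equal(nrow(sp_s$omnibus$clusters), 0)
  # cluster p falls as the injected amplitude grows
  amp_p <- sapply(c(0.8, 1.6, 3.2), function(a) {
    cfg_a <- study_config(seed = 5, swing = list(
      bump_amp = list(Real = c(0, 0), VR = c(a, a), VRHaptic = c(a, a))))
    spa <- spm_compare_conditions(generate_curve_set(cfg_a, "transverse"))
    min(spa$omnibus$clusters$p_value)
  })
  expect_true(all(diff(amp_p) < 0))
})

test_that("identical condition curves produce an empty pairwise map", {
  set.seed(3)
  base <- smooth_noise_1d(9, 101, fwhm = 15)
  curves <- rbind(base, base, base)
  cs <- curve_set(curves + smooth_noise_1d(27, 101, fwhm = 15, sd = 0.2),
                  rep(c("Real", "VR", "VRHaptic"), each = 9),
                  rep(sprintf("S%02d", 1:9), 3))
  sp <- spm_compare_conditions(cs)
  expect_equal(nrow(sp$omnibus$clusters), 0)
})
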