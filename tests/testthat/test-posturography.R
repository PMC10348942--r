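test_that("COP filtering follows the Butterworth response and preserves events", {
  n <- 3000
  t <- (seq_len(n) - 1) / 300
  ev <- data.frame(time = 2, label = "footlift")
  const <- cop_trace(t, rep(3, n), rep(-2, n), 300, events = ev)
  fc <- filter_cop(const)
  expect_lt(max(abs(fc$x - 3)), 1e-9)
  expect_identical(fc$events, ev)
  mid <- 1000:2000
  s1 <- filter_cop(cop_trace(t, sin(2 * pi * 1 * t), rep(0, n), 300))
  expect_lt(abs(max(abs(s1$x[mid])) - 1), 0.02)
  s25 <- filter_cop(cop_trace(t, sin(2 * pi * 25 * t), rep(0, n), 300))
  expect_lt(max(abs(s25$x[mid])), 0.05)
})

test_that("marker segmentation applies the settle margin and next-footlift bound", {
  n <- 3000
  t <- (seq_len(n) - 1) / 300
  tr <- cop_trace(t, t, t, 300,
                  events = data.frame(time = 2, label = "footlift"))
  w <- segment_trial(tr)
  expect_equal(w$time[1], 2.5, tolerance = 1 / 300)
  expect_equal(w$time[length(w$time)], t[n])
  tr2 <- cop_trace(t, t, t, 300,
                   events = data.frame(time = c(2, 7),
                                       label = c("footlift", "footlift")))
  w2 <- segment_trial(tr2)
  expect_equal(range(w2$time), c(2.5, 7), tolerance = 1 / 300)
  bare <- cop_trace(t, t, t, 300)
  expect_error(segment_trial(bare), "footlift")
})

test_that("detect-mode segmentation recovers the foot-lift time", {
  cfg <- study_config(seed = 2)
  for (i in 1:6) {
    cp <- generate_cop_trace(cfg, i, c("Real", "VR", "VRHaptic")[(i %% 3) + 1], i)
    w <- segment_trial(cp$trace, mode = "detect")
    expect_lt(abs(w$time[1] - 0.5 - cp$truth$footlift_s), 0.2)
  }
})

test_that("RMS amplitude matches closed forms and the brute-force definition", {
  expect_equal(rms_amplitude(rep(5, 100)), 0)
  t <- seq(0, 10, by = 1 / 300)[-1]
  expect_equal(rms_amplitude(sin(2 * pi * t)), 1 / sqrt(2),
               tolerance = 1e-3)
  set.seed(8)
  v <- rnorm(500, 3, 2)
  expect_equal(rms_amplitude(v), sqrt(mean((v - mean(v))^2)),
               tolerance = 1e-12)
  # invariant to mean shifts
  expect_equal(rms_amplitude(v + 100), rms_amplitude(v), tolerance = 1e-9)
})

test_that("decimation keeps every k-th sample", {
  x <- sin(2 * pi * 1.3 * (seq_len(900) - 1) / 300)
  d <- downsample(x, 300, 100)
  expect_length(d, 300)
  expect_equal(d, x[seq(1, 900, by = 3)], tolerance = 1e-12)
  expect_equal(downsample(rep(2, 10), 300, 100), rep(2, 4))
  expect_error(downsample(x, 300, 140), "integer")
})

test_that("sample entropy matches the brute-force oracle and its closed cases", {
  expect_equal(sample_entropy(rep(1, 60), 2, 0.1), 0)
  set.seed(5)
  for (k in 1:20) {
    n <- sample(50:200, 1)
    lam <- runif(1)
    x <- lam * sin(2 * pi * 2 * seq_len(n) / 50) + (1 - lam) * rnorm(n)
    r <- 0.2 * sd(x)
    fast <- suppressWarnings(sample_entropy(x, 2, r))
    slow <- sampen_brute(x, 2, r)
    if (is.finite(fast)) {
      expect_equal(fast, slow, tolerance = 1e-10)
    } else {
      expect_true(is.infinite(fast) && is.infinite(slow))
    }
  }
  expect_error(sample_entropy(1:3, 2, 0.1), "shorter")
  expect_error(sample_entropy(1:50, 2, 0), "positive")
})

test_that("white noise carries more sample entropy than a matched-SD sine", {
  s <- sin(2 * pi * 2 * seq_len(1000) / 100)
  s <- s / sd(s)
  for (i in 1:20) {
    set.seed(i)
    w <- rnorm(1000)
    expect_gt(sample_entropy(w, 2, 0.2 * sd(w)),
              sample_entropy(s, 2, 0.2 * sd(s)))
  }
})

test_that("path length matches geometry and the per-step oracle", {
  n <- 100
  still <- cop_trace((seq_len(n) - 1) / 300, rep(1, n), rep(2, n), 300)
  expect_equal(path_length(still), 0)
  square <- cop_trace((0:4) / 300, c(0, 10, 10, 0, 0), c(0, 0, 10, 10, 0),
                      300)
  expect_equal(path_length(square), 40)
  set.seed(10)
  x <- cumsum(rnorm(200)); y <- cumsum(rnorm(200))
  tr <- cop_trace((seq_len(200) - 1) / 300, x, y, 300)
  expect_equal(path_length(tr), path_brute(x, y), tolerance = 1e-12)
  # translation invariance and linear scaling
  tr2 <- cop_trace(tr$time, x + 50, y - 20, 300)
  expect_equal(path_length(tr2), path_length(tr), tolerance = 1e-9)
  tr3 <- cop_trace(tr$time, 3 * x, 3 * y, 300)
  expect_equal(path_length(tr3), 3 * path_length(tr), tolerance = 1e-9)
})

test_that("95% prediction ellipse matches the bivariate-normal closed form", {
  set.seed(123)
  xy <- matrix(rnorm(20000), ncol = 2)
  e <- ellipse_area_95(xy)
  expect_lt(abs(e$area - pi * stats::qchisq(0.95, 2)) /
              (pi * stats::qchisq(0.95, 2)), 0.05)
  # coverage: the ellipse contains ~95% of the points
  centred <- sweep(xy, 2, e$center)
  S <- stats::cov(xy)
  d2 <- rowSums((centred %*% solve(S)) * centred)
  expect_lt(abs(mean(d2 <= e$chisq) - 0.95), 0.01)
  # rotation and translation invariance; quadratic scaling
  th <- 30 * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_lt(abs(ellipse_area_95(xy %*% R)$area - e$area), 1e-9 * e$area)
  expect_equal(ellipse_area_95(sweep(xy, 2, c(10, -4), "+"))$area, e$area,
               tolerance = 1e-9)
  expect_equal(ellipse_area_95(2.5 * xy)$area, 2.5^2 * e$area,
               tolerance = 1e-9)
  expect_warning(a0 <- ellipse_area_95(cbind(1:50, 2 * (1:50))), "degenerate")
  expect_equal(a0$area, 0)
  expect_warning(ellipse_area_95(matrix(1, 10, 2)), "degenerate")
})

test_that("posture metrics respond monotonically to drift and are deterministic", {
  mk <- function(drift) study_config(seed = 44, effects = list(
    cop_drift_mm = deterministic_effects(drift, 0, 0)))
  a <- posture_metrics(generate_cop_trace(mk(6), 1, "Real", 1)$trace)
  b <- posture_metrics(generate_cop_trace(mk(12), 1, "Real", 1)$trace)
  expect_gt(b$rms_t, a$rms_t)
  expect_gt(b$rms_s, a$rms_s)
  expect_gt(b$path_length_mm, a$path_length_mm)
  expect_gt(b$ellipse_area_mm2, a$ellipse_area_mm2)
  cp <- generate_cop_trace(study_config(seed = 45), 2, "VR", 3)
  expect_identical(posture_metrics(cp$trace), posture_metrics(cp$trace))
})
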