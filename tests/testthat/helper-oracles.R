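# Independent brute-force oracles used across the suite.  These stay
# deliberately naive: each one re-derives the quantity from its
# definition, sharing no code path with the implementation it checks.

# Richman-Moorman sample entropy by explicit double loop
sampen_brute <- function(x, m = 2, r) {
  n <- length(x)
  nt <- n - m
  A <- 0; B <- 0
  for (i in seq_len(nt - 1)) {
    for (j in seq(i + 1, nt)) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= r) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1
      }
    }
  }
  if (B == 0) return(NA_real_)
  -log(A / B)
}

# two-pass sample variance from the definition
var_brute <- function(x) {
  m <- sum(x) / length(x)
  sum((x - m)^2) / (length(x) - 1)
}

# per-step path length
path_brute <- function(x, y) {
  total <- 0
  for (i in seq(2, length(x)))
    total <- total + sqrt((x[i] - x[i - 1])^2 + (y[i] - y[i - 1])^2)
  total
}

# z-score screen + 1%-beyond-next-extreme replacement, element by element
winsorize_brute <- function(v, z = 3) {
  m <- mean(v); s <- sd(v)
  out <- v
  for (i in seq_along(v)) {
    zi <- (v[i] - m) / s
    if (zi > z) {
      nxt <- max(v[(v - m) / s <= z])
      out[i] <- nxt + 0.01 * abs(nxt)
    } else if (zi < -z) {
      nxt <- min(v[(v - m) / s >= -z])
      out[i] <- nxt - 0.01 * abs(nxt)
    }
  }
  out
}

# scalar repeated-measures ANOVA F via a two-way fixed-effects fit
# (condition + subject), whose residual term equals the RM error stratum
rm_anova_f_oracle <- function(y, cond, subj) {
  fit <- stats::lm(y ~ factor(cond) + factor(subj))
  stats::anova(fit)["factor(cond)", "F value"]
}

# a small study configuration that keeps unit tests fast
quick_config <- function(seed = 1, ...) {
  study_config(n_participants = 3, n_trials = 2, seed = seed, ...)
}

# configuration with every stochastic component switched off except the
# programmed condition effects
deterministic_effects <- function(intercept, vr, vrh) {
  list(intercept = intercept, VR = vr, VRHaptic = vrh,
       participant_sd = 0, residual_sd = 0)
}
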