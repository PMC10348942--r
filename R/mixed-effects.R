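# Per-outcome mixed-effects condition models: participant random
# intercepts (random slopes for the jerk outcomes), Gamma family for
# entropy, standardized betas, Nakagawa-style marginal/conditional R2 and
# Bonferroni pairwise contrasts.

#' Fit a condition mixed model for one outcome
#'
#' Fits `outcome ~ condition + (1 | participant_id)` (or
#' `(condition | participant_id)` with `random_slopes = TRUE`) with the
#' first condition level (`Real`) as reference.  Gaussian models use
#' REML via `lmerTest`; the Gamma family uses a log-link GLMM via
#' `lme4::glmer`.  `transform = "log"` models the natural log of the
#' outcome with a Gaussian family.
#'
#' Variance explained follows the fixed/random/residual decomposition:
#' marginal `R2 = var_f / (var_f + var_r + var_e)` measures the fixed
#' effects alone and conditional (total) `R2` adds the random-effect
#' variance to the numerator.  `var_f` is the variance of the fixed-
#' effect linear predictor, `var_r` the mean diagonal of `Z Sigma Z'`,
#' and `var_e` the residual variance (for the Gamma log link, the
#' trigamma-based latent-scale variance `psigamma(1/phi, 1)`).
#'
#' Standardized betas use the standardize-both convention
#' `beta * sd(dummy) / sd(response)` on the modeling scale by default;
#' `std_convention = "response"` divides by the response SD only.
#'
#' @param table data frame of per-trial outcomes with columns
#'   `participant_id`, `condition` and the outcome.
#' @param outcome name of the outcome column.
#' @param family `"gaussian"` or `"gamma"`.
#' @param transform `"none"` or `"log"` (gaussian only).
#' @param random_slopes random condition slopes per participant.
#' @param std_convention `"dummy-sd"` (default) or `"response"`.
#' @param reference reference condition label (default `"Real"`).
#' @return An object of class `lmm_result`: fixed-effect table
#'   (estimate, 95% CI, p), standardized betas with interpretive labels,
#'   variance components, `marginal_r2`, `total_r2`, `singular` flag and
#'   the fitted model.
#' @export
fit_lmm <- function(table, outcome, family = c("gaussian", "gamma"),
                    transform = c("none", "log"), random_slopes = FALSE,
                    std_convention = c("dummy-sd", "response"),
                    reference = "Real") {
  family <- match.arg(family)
  transform <- match.arg(transform)
  std_convention <- match.arg(std_convention)
  stopifnot(all(c("participant_id", "condition", outcome) %in%
                  names(table)))
  d <- table[stats::complete.cases(table[c("participant_id", "condition",
                                           outcome)]), , drop = FALSE]
  d$condition <- stats::relevel(factor(d$condition), ref = reference)
  if (length(unique(d$participant_id)) < 2 ||
      nlevels(d$condition) < 2)
    stop("need >= 2 participants and >= 2 conditions", call. = FALSE)
  y <- d[[outcome]]
  if ((family == "gamma" || transform == "log") && any(y <= 0))
    stop("non-positive outcome values under log/gamma", call. = FALSE)
  d$.y <- if (transform == "log") log(y) else y
  re_term <- if (random_slopes) "(condition | participant_id)"
             else "(1 | participant_id)"
  fml <- stats::as.formula(paste(".y ~ condition +", re_term))

  if (family == "gaussian") {
    model <- lmerTest::lmer(fml, data = d, REML = TRUE)
    coefs <- summary(model)$coefficients
    pvals <- coefs[, "Pr(>|t|)"]
    var_e <- stats::sigma(model)^2
  } else {
    model <- lme4::glmer(fml, data = d, family = stats::Gamma("log"))
    coefs <- summary(model)$coefficients
    pvals <- coefs[, "Pr(>|z|)"]
    # latent-scale residual variance of a Gamma log-link model
    var_e <- psigamma(1 / stats::sigma(model)^2, deriv = 1)
  }
  singular <- lme4::isSingular(model)
  est <- coefs[, "Estimate"]
  se <- coefs[, "Std. Error"]
  ci <- cbind(lower = est - 1.96 * se, upper = est + 1.96 * se)

  X <- stats::model.matrix(model)
  var_f <- var(as.numeric(X %*% lme4::fixef(model)))
  var_r <- mean(ranef_variance_diag(model))
  denom <- var_f + var_r + var_e
  marginal_r2 <- var_f / denom
  total_r2 <- (var_f + var_r) / denom

  sd_y <- if (family == "gamma") sd(log(y)) else sd(d$.y)
  dummy_cols <- setdiff(colnames(X), "(Intercept)")
  std_beta <- vapply(dummy_cols, function(cn) {
    scale <- if (std_convention == "dummy-sd") sd(X[, cn]) else 1
    est[cn] * scale / sd_y
  }, numeric(1))

  fixed <- data.frame(term = rownames(coefs), estimate = est,
                      ci_lower = ci[, 1], ci_upper = ci[, 2],
                      p_value = pvals, row.names = NULL)
  structure(list(
    outcome = outcome, family = family, transform = transform,
    random_slopes = random_slopes, fixed = fixed,
    std_beta = std_beta,
    std_label = vapply(std_beta, interpret_std_beta, ""),
    var_fixed = var_f, var_random = var_r, var_residual = var_e,
    marginal_r2 = marginal_r2, total_r2 = total_r2,
    singular = singular, n_obs = nrow(d),
    n_participants = length(unique(d$participant_id)),
    model = model
  ), class = "lmm_result")
}

# per-observation random-effect variance: diag(Z Sigma Z')
ranef_variance_diag <- function(model) {
  Z <- lme4::getME(model, "Z")
  Lambda <- lme4::getME(model, "Lambda")
  Matrix::rowSums((Z %*% Lambda)^2) * stats::sigma(model)^2
}

#' @export
print.lmm_result <- function(x, ...) {
  cat("<lmm_result> ", x$outcome, " [", x$family,
      if (x$transform != "none") paste0(", ", x$transform),
      if (x$random_slopes) ", random slopes",
      if (x$singular) ", SINGULAR FIT", "]\n", sep = "")
  df <- x$fixed
  df$std_beta <- c(NA, x$std_beta)
  df$label <- c(NA, x$std_label)
  print(df, row.names = FALSE, digits = 3)
  cat(sprintf("  marginal R2 = %.3f, total R2 = %.3f (n = %d)\n",
              x$marginal_r2, x$total_r2, x$n_obs))
  invisible(x)
}

#' Bonferroni-corrected pairwise condition contrasts
#'
#' Estimated marginal mean differences for all condition pairs from a
#' fitted model, with p-values multiplied by the number of contrasts and
#' capped at 1.
#'
#' @param result an `lmm_result` (or a fitted merMod).
#' @return Data frame with `contrast`, `estimate`, `se`, `p_raw`,
#'   `p_bonferroni`.
#' @export
pairwise_bonferroni <- function(result) {
  model <- if (inherits(result, "lmm_result")) result$model else result
  em <- emmeans::emmeans(model, "condition")
  ct <- summary(emmeans::contrast(em, method = "pairwise"),
                adjust = "none", infer = c(FALSE, TRUE))
  data.frame(contrast = as.character(ct$contrast),
             estimate = ct$estimate, se = ct$SE,
             p_raw = ct$p.value,
             p_bonferroni = pmin(1, nrow(ct) * ct$p.value))
}

#' Score the conscious-movement-processing items
#'
#' Six 5-point items are summarized per participant and condition.  The
#' `mean` mode is the arithmetic item mean (range 1-5); the `sum` mode
#' (range 6-30) is also provided since summed scores are common for this
#' scale, and the scoring mode is recorded alongside the value.
#'
#' @param items numeric vector of exactly 6 integers in `[1, 5]`.
#' @param mode `"mean"` or `"sum"`.
#' @return Scalar score with attribute `mode`.
#' @export
score_cmp <- function(items, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  if (length(items) != 6)
    stop("expected exactly 6 items", call. = FALSE)
  if (any(items < 1 | items > 5))
    stop("items must lie in [1, 5]", call. = FALSE)
  out <- if (mode == "mean") mean(items) else sum(items)
  attr(out, "mode") <- mode
  out
}

#' Interpret a standardized beta
#'
#' Effect-size labels analogous to correlation rules of thumb:
#' `|beta| < 0.2` weak, `0.2 <= |beta| <= 0.5` moderate (boundaries
#' inclusive), `> 0.5` strong.
#'
#' @param beta_std finite standardized beta.
#' @return `"weak"`, `"moderate"` or `"strong"`.
#' @export
interpret_std_beta <- function(beta_std) {
  stopifnot(is.finite(beta_std))
  b <- abs(beta_std)
  if (b < 0.2) "weak" else if (b <= 0.5) "moderate" else "strong"
}

#' Simulate a trial-metrics table from known mixed-model parameters
#'
#' Direct simulation harness for parameter-recovery studies: outcome =
#' intercept + condition effect + participant intercept + residual, with
#' optional exponentiation for positive (Gamma-type) outcomes.
#'
#' @param n_participants,n_trials design size.
#' @param intercept,effects fixed effects (`effects` named by non-
#'   reference condition).
#' @param participant_sd,residual_sd variance components.
#' @param conditions condition labels (first = reference).
#' @param exp_link exponentiate the linear predictor and draw Gamma
#'   noise (shape `1/residual_sd^2`) instead of additive Gaussian noise.
#' @param seed integer seed.
#' @return Data frame `participant_id`, `condition`, `trial`, `y`.
#' @export
simulate_lmm_table <- function(n_participants = 21, n_trials = 20,
                               intercept = 3.69,
                               effects = c(VR = -1.47, VRHaptic = -0.42),
                               participant_sd = 1.0, residual_sd = 1.2,
                               conditions = c("Real", "VR", "VRHaptic"),
                               exp_link = FALSE, seed = 1) {
  local_seed(seed, {
    p_int <- rnorm(n_participants, 0, participant_sd)
    rows <- expand.grid(trial = seq_len(n_trials), condition = conditions,
                        participant = seq_len(n_participants))
    eff <- c(setNames(0, conditions[1]), effects)
    lp <- intercept + eff[as.character(rows$condition)] +
      p_int[rows$participant]
    y <- if (exp_link) {
      shape <- 1 / residual_sd^2
      exp(lp) * stats::rgamma(nrow(rows), shape = shape, rate = shape)
    } else {
      lp + rnorm(nrow(rows), 0, residual_sd)
    }
    data.frame(participant_id = participant_label(rows$participant),
               condition = as.character(rows$condition),
               trial = rows$trial, y = y)
  })
}
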