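# One-dimensional statistical parametric mapping: pointwise statistic
# continua over time-normalized swing curves, random-field-theory (RFT)
# family-wise error control via the 1D expected-Euler-characteristic
# expansion, and supra-threshold cluster p-values.

#' Curve dataset for SPM
#'
#' @param curves numeric matrix, one curve per row, no missing nodes.
#' @param condition factor/character condition label per curve.
#' @param participant_id subject identifier per curve (one curve per
#'   subject per condition for repeated-measures statistics).
#' @return An object of class `curve_set`.
#' @export
curve_set <- function(curves, condition, participant_id) {
  curves <- as.matrix(curves)
  stopifnot(nrow(curves) == length(condition),
            length(condition) == length(participant_id),
            !anyNA(curves))
  structure(list(curves = curves, condition = as.character(condition),
                 participant_id = as.character(participant_id)),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat("<curve_set> ", nrow(x$curves), " curves x ", ncol(x$curves),
      " nodes; conditions: ",
      paste(unique(x$condition), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# curves as a subjects x conditions x nodes array; errors if unbalanced
curve_array <- function(cs) {
  subj <- sort(unique(cs$participant_id))
  cond <- unique(cs$condition)
  tab <- table(cs$participant_id, cs$condition)
  if (any(tab != 1))
    stop("unbalanced design: need exactly one curve per subject per ",
         "condition", call. = FALSE)
  n_nodes <- ncol(cs$curves)
  arr <- array(NA_real_, c(length(subj), length(cond), n_nodes),
               dimnames = list(subj, cond, NULL))
  for (i in seq_len(nrow(cs$curves)))
    arr[cs$participant_id[i], cs$condition[i], ] <- cs$curves[i, ]
  arr
}

#' Pointwise repeated-measures F continuum
#'
#' At every node, a one-way repeated-measures ANOVA F statistic across
#' conditions with subject as blocking factor.  The error-term residual
#' curves (`y - cond mean - subject mean + grand mean`) are returned for
#' smoothness estimation.
#'
#' @param cs a [curve_set()] with >= 2 conditions, one curve per subject
#'   per condition.
#' @return List with `stat` (F per node), `df` (numerator, denominator),
#'   `residuals` (curves x nodes matrix).
#' @export
pointwise_f <- function(cs) {
  arr <- curve_array(cs)
  S <- dim(arr)[1]; C <- dim(arr)[2]; N <- dim(arr)[3]
  stopifnot(C >= 2, S >= 2)
  grand <- apply(arr, 3, mean)
  cond_m <- apply(arr, c(2, 3), mean)   # C x N
  subj_m <- apply(arr, c(1, 3), mean)   # S x N
  ss_cond <- S * colSums((cond_m - rep(grand, each = C))^2)
  resid <- arr
  for (s in seq_len(S)) for (cc in seq_len(C))
    resid[s, cc, ] <- arr[s, cc, ] - cond_m[cc, ] - subj_m[s, ] + grand
  ss_err <- apply(resid^2, 3, sum)
  df <- c(C - 1, (C - 1) * (S - 1))
  if (any(ss_err <= 0))
    stop("zero within-cell variance at some node; F undefined",
         call. = FALSE)
  f <- (ss_cond / df[1]) / (ss_err / df[2])
  res_mat <- matrix(aperm(resid, c(3, 1, 2)), nrow = S * C, ncol = N,
                    byrow = TRUE)
  list(stat = f, df = df, residuals = res_mat)
}

#' Pointwise paired-t continuum for two conditions
#'
#' Node-wise paired t statistic on subject difference curves
#' (`second condition - first`).  Nodes with zero difference variance
#' yield `0` when the mean difference is also zero and a signed `Inf`
#' sentinel otherwise.
#'
#' @param cs a [curve_set()] restricted to exactly 2 conditions.
#' @return List with `stat` (t per node), `df`, `residuals`
#'   (subjects x nodes difference residuals).
#' @export
pointwise_t_paired <- function(cs) {
  cond <- unique(cs$condition)
  stopifnot(length(cond) == 2)
  arr <- curve_array(cs)
  S <- dim(arr)[1]
  if (S < 2) stop("need >= 2 subjects", call. = FALSE)
  D <- arr[, 2, ] - arr[, 1, ]          # S x N difference curves
  if (is.null(dim(D))) D <- matrix(D, nrow = S)
  mn <- colMeans(D)
  sdev <- apply(D, 2, sd)
  t_stat <- ifelse(sdev > 0, mn / (sdev / sqrt(S)),
                   ifelse(mn == 0, 0, sign(mn) * Inf))
  list(stat = t_stat, df = c(1, S - 1),
       residuals = sweep(D, 2, mn), conditions = cond)
}

#' Estimate field smoothness (FWHM) from residual curves
#'
#' Residual curves are normalized node-wise to unit variance; the mean
#' squared gradient of the normalized residuals estimates the field
#' roughness, converted to the full width at half maximum of the
#' equivalent Gaussian kernel: `fwhm = sqrt(4 log 2 / mean(grad^2))`,
#' in node units.  Scale-invariant by construction.
#'
#' @param residuals matrix of residual curves (>= 2 rows, >= 3 nodes).
#' @return Estimated FWHM in nodes.
#' @export
estimate_fwhm <- function(residuals) {
  residuals <- as.matrix(residuals)
  stopifnot(nrow(residuals) >= 2, ncol(residuals) >= 3)
  sdn <- apply(residuals, 2, sd)
  keep <- sdn > 0
  if (!any(keep)) stop("all-zero residuals", call. = FALSE)
  rn <- sweep(residuals[, keep, drop = FALSE], 2, sdn[keep], "/")
  grad <- t(diff(t(rn)))
  msg <- mean(grad^2)
  sqrt(4 * log(2) / msg)
}

# 1D Euler-characteristic densities (unit-roughness resel units).
# t field, nu df:   rho1 = sqrt(4 log 2)/(2 pi) (1 + u^2/nu)^(-(nu-1)/2)
# F field, (k, nu): prefactor sqrt(4 log 2)/sqrt(2 pi) with the
# gamma-ratio normalization; fixed so that the excursion-set identity
# EC{F(1, nu) > u} = 2 EC{t(nu) > sqrt(u)} holds exactly.
ec_density_1d <- function(u, df, stat_family = c("t", "F")) {
  stat_family <- match.arg(stat_family)
  if (stat_family == "t") {
    nu <- df[2]
    sqrt(4 * log(2)) / (2 * pi) * (1 + u^2 / nu)^(-(nu - 1) / 2)
  } else {
    k <- df[1]; nu <- df[2]
    lg <- lgamma((nu + k - 1) / 2) - lgamma(nu / 2) - lgamma(k / 2)
    sqrt(4 * log(2)) / sqrt(2 * pi) * sqrt(2) * exp(lg) *
      (k * u / nu)^((k - 1) / 2) * (1 + k * u / nu)^(-(nu + k - 2) / 2)
  }
}

ec_p0 <- function(u, df, stat_family) {
  if (stat_family == "t") pt(u, df[2], lower.tail = FALSE)
  else pf(u, df[1], df[2], lower.tail = FALSE)
}

# expected Euler characteristic of the excursion set above u
expected_ec <- function(u, df, resels, stat_family) {
  ec_p0(u, df, stat_family) + resels * ec_density_1d(u, df, stat_family)
}

#' RFT critical threshold for a 1D statistic field
#'
#' The smallest height `u` at which the expected number of
#' supra-threshold features of a smooth random field of the given
#' smoothness equals `alpha`, using the 1D expected-Euler-characteristic
#' expansion `E[EC] = P0(u) + resels * rho1(u)` with
#' `resels = (n_nodes - 1)/fwhm`, solved by bisection to 1e-6.  In the
#' very smooth limit (`fwhm >> n_nodes`) the threshold approaches the
#' ordinary uncorrected critical value.
#'
#' @param alpha family-wise error rate (one threshold crossing anywhere
#'   along the continuum).
#' @param df degrees of freedom pair `(df1, df2)`; `df1` is ignored for
#'   `t` fields.
#' @param n_nodes number of nodes of the continuum.
#' @param fwhm field smoothness in nodes, from [estimate_fwhm()].
#' @param stat_family `"t"` or `"F"`.
#' @return Critical threshold `z_star`.
#' @export
rft_threshold <- function(alpha, df, n_nodes, fwhm,
                          stat_family = c("t", "F")) {
  stat_family <- match.arg(stat_family)
  stopifnot(alpha > 0, alpha < 1, fwhm > 0, n_nodes >= 2)
  resels <- (n_nodes - 1) / fwhm
  lo <- if (stat_family == "t") qt(1 - alpha, df[2])
        else qf(1 - alpha, df[1], df[2])
  hi <- lo + 20
  f_lo <- expected_ec(lo, df, resels, stat_family) - alpha
  if (f_lo < 0) return(lo)  # already below alpha at the uncorrected value
  # the +20 bracket suffices for t fields; heavy-tailed F fields with few
  # denominator df can need a far larger ceiling, so grow it as required
  tries <- 0
  while (expected_ec(hi, df, resels, stat_family) - alpha > 0) {
    hi <- lo + (hi - lo) * 4
    tries <- tries + 1
    if (tries > 30) stop("no root in threshold search bracket",
                         call. = FALSE)
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (hi - lo < 1e-6) break
    if (expected_ec(mid, df, resels, stat_family) - alpha > 0) lo <- mid
    else hi <- mid
  }
  (lo + hi) / 2
}

#' Supra-threshold cluster inference
#'
#' Contiguous runs of nodes with the statistic above `z_star` (on `|t|`
#' for two-tailed t maps).  Each cluster's p-value is the RFT
#' cluster-extent approximation: with expected cluster count
#' `E_c = E[EC](u)` and expected extent (in resels)
#' `eta = resels * P0(u) / E_c`, the extent survival is modelled as
#' `P(extent >= k) = exp(-pi k^2 / (4 eta^2))` and
#' `p = 1 - exp(-E_c * P(extent >= k))`.  Cluster extents use integer
#' node boundaries (no interpolated crossings), which is conservative.
#'
#' @param stat_curve statistic continuum.
#' @param z_star critical threshold from [rft_threshold()].
#' @param fwhm field smoothness in nodes.
#' @param df degrees-of-freedom pair.
#' @param stat_family `"t"` or `"F"`.
#' @param two_tailed cluster on `|stat|` (t maps only).
#' @return Data frame with one row per cluster: `start_node`, `end_node`
#'   (1-based), `extent_nodes`, `extent_resels`, `max_stat`, `p_value`;
#'   zero rows when nothing crosses the threshold.
#' @export
cluster_inference <- function(stat_curve, z_star, fwhm, df,
                              stat_family = c("t", "F"),
                              two_tailed = FALSE) {
  stat_family <- match.arg(stat_family)
  n_nodes <- length(stat_curve)
  height <- if (two_tailed && stat_family == "t") abs(stat_curve)
            else stat_curve
  over <- height > z_star
  out <- data.frame(start_node = integer(), end_node = integer(),
                    extent_nodes = integer(), extent_resels = numeric(),
                    max_stat = numeric(), p_value = numeric())
  if (!any(over)) return(out)
  r <- rle(over)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  resels <- (n_nodes - 1) / fwhm
  e_c <- expected_ec(z_star, df, resels, stat_family)
  if (two_tailed && stat_family == "t") e_c <- 2 * e_c
  p0 <- ec_p0(z_star, df, stat_family)
  if (two_tailed && stat_family == "t") p0 <- 2 * p0
  eta <- max(resels * p0 / e_c, 1e-12)
  for (i in which(r$values)) {
    k <- r$lengths[i] / fwhm
    p_ext <- exp(-pi * k^2 / (4 * eta^2))
    p <- max(-expm1(-e_c * p_ext), 1e-300)  # guard underflow; p stays > 0
    out <- rbind(out, data.frame(
      start_node = starts[i], end_node = ends[i],
      extent_nodes = r$lengths[i], extent_resels = k,
      max_stat = max(height[starts[i]:ends[i]]), p_value = p))
  }
  out[order(out$start_node), , drop = FALSE]
}

#' Omnibus and pairwise SPM over condition curves
#'
#' Runs the repeated-measures SPM{F} map across all conditions and the
#' pairwise SPM{t} maps for every condition pair (pairwise maps are
#' computed regardless of the omnibus outcome, and no alpha adjustment
#' is applied across the pairwise maps unless requested).
#'
#' @param cs a [curve_set()] of subject-level curves (typically each
#'   subject's mean of 20 trials per condition).
#' @param alpha family-wise error rate per map.
#' @param two_tailed two-tailed pairwise t maps (default `TRUE`).
#' @param adjust_pairs divide alpha by the number of pairwise maps.
#' @return List of class `spm_comparison` with `omnibus` (an
#'   `spm1d_result`) and `pairwise` (named list of `spm1d_result`).
#' @export
spm_compare_conditions <- function(cs, alpha = 0.05, two_tailed = TRUE,
                                   adjust_pairs = FALSE) {
  stopifnot(inherits(cs, "curve_set"))
  fit <- pointwise_f(cs)
  fwhm <- estimate_fwhm(fit$residuals)
  n_nodes <- ncol(cs$curves)
  z_f <- rft_threshold(alpha, fit$df, n_nodes, fwhm, "F")
  omnibus <- spm1d_result(fit$stat, fit$df, fwhm, z_f,
                          cluster_inference(fit$stat, z_f, fwhm, fit$df,
                                            "F"),
                          alpha, "F", two_tailed = FALSE)
  conds <- unique(cs$condition)
  pairs <- utils::combn(conds, 2, simplify = FALSE)
  a_pair <- if (adjust_pairs) alpha / length(pairs) else alpha
  pairwise <- lapply(pairs, function(pr) {
    sub <- cs$condition %in% pr
    ord <- order(match(cs$condition[sub], pr))
    cs2 <- curve_set(cs$curves[sub, , drop = FALSE][ord, , drop = FALSE],
                     cs$condition[sub][ord], cs$participant_id[sub][ord])
    fit2 <- pointwise_t_paired(cs2)
    fw2 <- estimate_fwhm(fit2$residuals)
    a_eff <- if (two_tailed) a_pair / 2 else a_pair
    z_t <- rft_threshold(a_eff, fit2$df, n_nodes, fw2, "t")
    spm1d_result(fit2$stat, fit2$df, fw2, z_t,
                 cluster_inference(fit2$stat, z_t, fw2, fit2$df, "t",
                                   two_tailed = two_tailed),
                 a_pair, "t", two_tailed = two_tailed)
  })
  names(pairwise) <- vapply(pairs, paste, "", collapse = "_vs_")
  structure(list(omnibus = omnibus, pairwise = pairwise),
            class = "spm_comparison")
}

spm1d_result <- function(stat_curve, df, fwhm, z_star, clusters, alpha,
                         stat_family, two_tailed) {
  stopifnot(fwhm > 0, all(clusters$p_value > 0 | !nrow(clusters)),
            all(clusters$p_value <= 1))
  structure(list(stat_curve = stat_curve, df = df, fwhm = fwhm,
                 z_star = z_star, clusters = clusters, alpha = alpha,
                 stat_family = stat_family, two_tailed = two_tailed,
                 resels = (length(stat_curve) - 1) / fwhm),
            class = "spm1d_result")
}

#' @export
print.spm1d_result <- function(x, ...) {
  cat("<spm1d_result> SPM{", x$stat_family, "} over ",
      length(x$stat_curve), " nodes\n", sep = "")
  cat("  df = (", paste(signif(x$df, 4), collapse = ", "),
      "), FWHM = ", round(x$fwhm, 2), " nodes, resels = ",
      round(x$resels, 2), "\n", sep = "")
  cat("  z* = ", round(x$z_star, 3), " at alpha = ", x$alpha,
      if (x$two_tailed) " (two-tailed)", "\n", sep = "")
  if (nrow(x$clusters)) {
    cat("  clusters:\n")
    print(x$clusters, row.names = FALSE)
  } else cat("  no supra-threshold clusters\n")
  invisible(x)
}

#' @export
print.spm_comparison <- function(x, ...) {
  cat("<spm_comparison>\n-- omnibus --\n")
  print(x$omnibus)
  for (nm in names(x$pairwise)) {
    cat("-- ", nm, " --\n", sep = "")
    print(x$pairwise[[nm]])
  }
  invisible(x)
}

#' Smooth Gaussian noise curves of known smoothness
#'
#' White Gaussian noise convolved with a Gaussian kernel whose FWHM (in
#' nodes) equals the target field smoothness; the kernel is normalized to
#' unit sum of squares so the field has unit variance.  Used to validate
#' the smoothness estimator and the family-wise error control by
#' simulation.
#'
#' @param n_curves number of curves.
#' @param n_nodes nodes per curve.
#' @param fwhm target smoothness in nodes; values below 0.1 return white
#'   noise.
#' @param sd marginal standard deviation.
#' @return Matrix `n_curves` x `n_nodes`.
#' @export
smooth_noise_1d <- function(n_curves, n_nodes, fwhm, sd = 1) {
  if (fwhm < 0.1)
    return(matrix(rnorm(n_curves * n_nodes, 0, sd), n_curves))
  s <- fwhm / (2 * sqrt(2 * log(2)))
  h <- ceiling(4 * s)
  kern <- exp(-(seq(-h, h))^2 / (2 * s^2))
  kern <- kern / sqrt(sum(kern^2))
  wide <- n_nodes + 2 * h
  W <- matrix(rnorm(n_curves * wide), n_curves, wide)
  K <- matrix(0, wide, n_nodes)
  for (j in seq_len(n_nodes)) K[j:(j + 2 * h), j] <- kern
  (W %*% K) * sd
}
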