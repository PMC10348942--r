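#' Winsorize values beyond a z-score screen
#'
#' Screens a vector for values more than `z` standard deviations from the
#' mean (mean and SD of the original vector) and replaces each outlier
#' with a value 1% more extreme than the next most extreme non-outlying
#' value on the same side: `v + 0.01 * |v|` on the high side,
#' `v - 0.01 * |v|` on the low side, which reduces to `1.01 * v` /
#' `0.99 * v` for positive scales and to the sign-consistent equivalent
#' for negative values.  Non-outliers are untouched, and applying the
#' rule twice gives the same result as applying it once.
#'
#' @param values numeric vector (>= 3 values).
#' @param z z-score screen (default 3).
#' @return Vector of the same length.
#' @examples
#' x <- c(rep(1, 30), 100)
#' winsorize_outliers(x)[31]  # 1.01
#' @export
winsorize_outliers <- function(values, z = 3) {
  stopifnot(length(values) >= 3, z > 0)
  keep <- is.finite(values)
  m <- mean(values[keep])
  s <- sd(values[keep])
  if (!is.finite(s) || s == 0) return(values)
  hi <- keep & values > m + z * s
  lo <- keep & values < m - z * s
  inliers <- values[keep & !hi & !lo]
  if (!length(inliers)) return(values)
  out <- values
  if (any(hi)) {
    v <- max(inliers)
    out[hi] <- v + 0.01 * abs(v)
  }
  if (any(lo)) {
    v <- min(inliers)
    out[lo] <- v - 0.01 * abs(v)
  }
  out
}
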