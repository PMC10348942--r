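# Lightweight S3 containers for the two trace types, plus CSV round-trips
# matching the interchange schemas (header row mandatory):
#   IMU: time_s, acc_x, acc_y, acc_z  (x transverse, y vertical, z sagittal)
#   COP: time_s, cop_x_mm, cop_y_mm, event ("" or "footlift")

#' Triaxial accelerometer trace
#'
#' @param time numeric vector of timestamps, seconds, strictly increasing.
#' @param acc numeric matrix with columns `transverse`, `vertical`,
#'   `sagittal`, in m/s^2.
#' @param rate nominal sampling rate, Hz.
#' @return An object of class `imu_trace`.
#' @export
imu_trace <- function(time, acc, rate) {
  acc <- as.matrix(acc)
  stopifnot(length(time) == nrow(acc), ncol(acc) == 3, rate > 0)
  if (any(diff(time) <= 0))
    stop("time vector must be strictly increasing", call. = FALSE)
  colnames(acc) <- c("transverse", "vertical", "sagittal")
  structure(list(time = as.numeric(time), acc = acc, rate = rate),
            class = "imu_trace")
}

#' @export
print.imu_trace <- function(x, ...) {
  cat("<imu_trace> ", length(x$time), " samples @ ", x$rate, " Hz (",
      round(diff(range(x$time)), 3), " s)\n", sep = "")
  invisible(x)
}

#' Centre-of-pressure trace
#'
#' @param time numeric timestamps, seconds.
#' @param x,y COP coordinates in mm; `x` is the sagittal direction,
#'   `y` the transverse direction.
#' @param rate sampling rate, Hz.
#' @param events data frame with columns `time`, `label` (may be empty).
#' @return An object of class `cop_trace`.
#' @export
cop_trace <- function(time, x, y, rate,
                      events = data.frame(time = numeric(),
                                          label = character())) {
  stopifnot(length(time) == length(x), length(x) == length(y), rate > 0,
            all(is.finite(x)), all(is.finite(y)))
  structure(list(time = as.numeric(time), x = as.numeric(x),
                 y = as.numeric(y), rate = rate, events = events),
            class = "cop_trace")
}

#' @export
print.cop_trace <- function(x, ...) {
  cat("<cop_trace> ", length(x$time), " samples @ ", x$rate, " Hz, ",
      nrow(x$events), " event(s)\n", sep = "")
  invisible(x)
}

#' Read and write trace CSV files
#'
#' @param trace an `imu_trace` or `cop_trace`.
#' @param path file path.
#' @param rate sampling rate to attach on read (IMU rate is otherwise
#'   inferred from the median sampling interval).
#' @return Readers return the trace object; writers return `path`
#'   invisibly.
#' @export
write_imu_csv <- function(trace, path) {
  stopifnot(inherits(trace, "imu_trace"))
  df <- data.frame(time_s = trace$time,
                   acc_x = trace$acc[, "transverse"],
                   acc_y = trace$acc[, "vertical"],
                   acc_z = trace$acc[, "sagittal"])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_imu_csv <- function(path, rate = NULL) {
  df <- read.csv(path)
  need <- c("time_s", "acc_x", "acc_y", "acc_z")
  if (!all(need %in% names(df)))
    stop("IMU CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(rate)) rate <- 1 / median(diff(df$time_s))
  imu_trace(df$time_s,
            cbind(transverse = df$acc_x, vertical = df$acc_y,
                  sagittal = df$acc_z),
            rate)
}

#' @rdname write_imu_csv
#' @export
write_cop_csv <- function(trace, path) {
  stopifnot(inherits(trace, "cop_trace"))
  ev <- character(length(trace$time))
  if (nrow(trace$events)) {
    idx <- vapply(trace$events$time,
                  function(tt) which.min(abs(trace$time - tt)), integer(1))
    ev[idx] <- trace$events$label
  }
  df <- data.frame(time_s = trace$time, cop_x_mm = trace$x,
                   cop_y_mm = trace$y, event = ev)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_imu_csv
#' @export
read_cop_csv <- function(path, rate = NULL) {
  df <- read.csv(path)
  need <- c("time_s", "cop_x_mm", "cop_y_mm")
  if (!all(need %in% names(df)))
    stop("COP CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (is.null(rate)) rate <- 1 / median(diff(df$time_s))
  ev <- data.frame(time = numeric(), label = character())
  if ("event" %in% names(df)) {
    hit <- !is.na(df$event) & nzchar(df$event)
    ev <- data.frame(time = df$time_s[hit], label = df$event[hit])
  }
  cop_trace(df$time_s, df$cop_x_mm, df$cop_y_mm, rate, events = ev)
}
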