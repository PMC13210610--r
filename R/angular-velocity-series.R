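#' Uniformly sampled single-axis angular-velocity record
#'
#' The central data container of the package: an ordered sequence of
#' angular-velocity samples (rad/s) on a uniform time grid, together with
#' trial metadata (participant id, measurement-stage label, ergometer power
#' grade, source path).
#'
#' @param values numeric vector of angular-velocity samples (rad/s); length
#'   at least 2, all finite.
#' @param dt sampling step in seconds (nominal 0.001 for a 1 kHz gyroscope).
#' @param t0 start time in seconds of the first sample.
#' @param meta named list of free-form metadata; recognized fields are
#'   `participant`, `stage`, `grade`, `source`.
#'
#' @return An object of class `angular_velocity_series`.
#' @examples
#' s <- angular_velocity_series(sin(2 * pi * seq(0, 10, by = 0.001)), dt = 0.001)
#' s
#' @export
angular_velocity_series <- function(values, dt, t0 = 0, meta = list()) {
  values <- as.numeric(values)
  if (length(values) < 2L)
    stop("an angular-velocity series needs at least 2 samples", call. = FALSE)
  if (!all(is.finite(values)))
    stop("all angular-velocity samples must be finite", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("'dt' must be a single positive number (seconds)", call. = FALSE)
  if (!is.numeric(t0) || length(t0) != 1L || !is.finite(t0))
    stop("'t0' must be a single finite number (seconds)", call. = FALSE)
  stopifnot(is.list(meta))
  structure(
    list(t0 = as.numeric(t0), dt = as.numeric(dt), values = values, meta = meta),
    class = "angular_velocity_series"
  )
}

#' Sample times of a series
#'
#' @param series an [angular_velocity_series()].
#' @return numeric vector `t0 + (0:(n-1)) * dt`.
#' @export
series_times <- function(series) {
  stopifnot(inherits(series, "angular_velocity_series"))
  series$t0 + (seq_along(series$values) - 1) * series$dt
}

#' @export
length.angular_velocity_series <- function(x) length(x$values)

#' @export
print.angular_velocity_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<angular_velocity_series> %d samples, dt = %g s, span %.3f s\n",
    n, x$dt, (n - 1) * x$dt
  ))
  m <- x$meta
  lab <- c(
    if (!is.null(m$participant)) paste0("participant=", m$participant),
    if (!is.null(m$stage)) paste0("stage=", m$stage),
    if (!is.null(m$grade)) paste0("grade=", m$grade)
  )
  if (length(lab)) cat(" ", paste(lab, collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.data.frame.angular_velocity_series <- function(x, ...) {
  data.frame(time = series_times(x), omega_x = x$values)
}
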