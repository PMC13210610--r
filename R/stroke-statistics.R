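#' Per-trial duration summary
#'
#' Arithmetic means and sample standard deviations (n - 1 denominator) of
#' the full-stroke period and the drive (phase 1) and recovery (phase 2)
#' durations over the strokes of one trial. With a single stroke the means
#' are defined but the SDs are reported as `NA` (not zero).
#'
#' @param ensemble a `stroke_ensemble` from [segment_strokes()].
#' @return a `duration_summary`: a one-row data frame with columns `scope`,
#'   `n`, `full_mean`, `full_sd`, `phase1_mean`, `phase1_sd`, `phase2_mean`,
#'   `phase2_sd`, carrying the ensemble's `meta` attribute.
#' @export
summarize_durations <- function(ensemble) {
  stopifnot(inherits(ensemble, "stroke_ensemble"))
  n <- nrow(ensemble)
  if (n < 1L) stop("empty stroke ensemble", call. = FALSE)
  sd_or_na <- function(x) if (length(x) >= 2L) stats::sd(x) else NA_real_
  out <- data.frame(
    scope = "trial", n = n,
    full_mean = mean(ensemble$period), full_sd = sd_or_na(ensemble$period),
    phase1_mean = mean(ensemble$phase1), phase1_sd = sd_or_na(ensemble$phase1),
    phase2_mean = mean(ensemble$phase2), phase2_sd = sd_or_na(ensemble$phase2)
  )
  structure(out, meta = attr(ensemble, "meta"),
            class = c("duration_summary", "data.frame"))
}

#' Group-level duration summary
#'
#' Aggregates per-trial summaries of several participants measured at the
#' same stage and grade: the group mean and SD are computed over the
#' participants' per-trial mean values (n = number of participants), not
#' over pooled strokes. This is the aggregation behind group tables of
#' stroke time characteristics and matches the participant-level samples
#' used by the longitudinal rank tests.
#'
#' @param per_trial list of `duration_summary` objects, one per participant.
#' @return a `duration_summary` with `scope = "group"`.
#' @export
group_summary <- function(per_trial) {
  stopifnot(is.list(per_trial), length(per_trial) >= 2L)
  if (!all(vapply(per_trial, inherits, logical(1), "duration_summary")))
    stop("'per_trial' must be a list of duration_summary objects", call. = FALSE)
  metas <- lapply(per_trial, attr, "meta")
  key <- vapply(metas, function(m)
    paste(m$stage %||% "", m$grade %||% "", sep = "\r"), character(1))
  if (length(unique(key)) != 1L)
    stop("mixed stages/grades in group input; aggregate one cell at a time",
         call. = FALSE)
  col <- function(nm) vapply(per_trial, function(s) s[[nm]], numeric(1))
  out <- data.frame(
    scope = "group", n = length(per_trial),
    full_mean = mean(col("full_mean")), full_sd = stats::sd(col("full_mean")),
    phase1_mean = mean(col("phase1_mean")), phase1_sd = stats::sd(col("phase1_mean")),
    phase2_mean = mean(col("phase2_mean")), phase2_sd = stats::sd(col("phase2_mean"))
  )
  structure(out, meta = metas[[1]][c("stage", "grade")],
            class = c("duration_summary", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Ensemble mean stroke profile with point-wise dispersion
#'
#' Builds the mean stroke curve and its point-wise standard deviation from
#' the aligned individual strokes of one trial. Alignment uses fixed-length
#' windows of duration equal to the mean period `<T>`: for each stroke
#' onset, a window of `round(<T>/dt) + 1` samples starting at the
#' (fractional, linearly interpolated) onset is extracted, so every grid
#' point is covered by the full ensemble of windows. Windows that would run
#' past the end of the record are dropped. The profile's `mean_curve` and
#' `std_curve` are the point-wise mean and sample SD (n - 1) across windows.
#'
#' @param series the smoothed [angular_velocity_series()] the ensemble was
#'   segmented from.
#' @param ensemble the `stroke_ensemble` from [segment_strokes()].
#' @return a `mean_stroke_profile`: list with `grid` (time offsets from
#'   stroke onset, step `dt`, spanning `[0, <T>]`), `mean_curve`,
#'   `std_curve`, `mean_period`, `n_strokes`, `dt` and `meta`.
#' @export
mean_profile <- function(series, ensemble) {
  stopifnot(inherits(series, "angular_velocity_series"),
            inherits(ensemble, "stroke_ensemble"))
  if (nrow(ensemble) < 2L)
    stop("at least 2 strokes are needed for a mean profile", call. = FALSE)
  dt <- series$dt
  tbar <- mean(ensemble$period)
  L <- round(tbar / dt) + 1L
  t <- series_times(series)
  t_end <- t[length(t)]

  onsets <- ensemble$onset
  onsets <- onsets[onsets + (L - 1L) * dt <= t_end + 1e-12]
  m <- length(onsets)
  if (m < 2L)
    stop("fewer than 2 usable stroke windows fit inside the record", call. = FALSE)

  offs <- (0:(L - 1L)) * dt
  xout <- rep(onsets, each = L) + rep(offs, times = m)
  w <- matrix(stats::approx(t, series$values, xout = xout, rule = 2)$y,
              nrow = L, ncol = m)
  mu <- rowMeans(w)
  dev <- w - mu
  sdv <- sqrt(rowSums(dev * dev) / (m - 1L))
  structure(
    list(grid = offs, mean_curve = mu, std_curve = sdv,
         mean_period = tbar, n_strokes = m, dt = dt,
         meta = attr(ensemble, "meta")),
    class = "mean_stroke_profile"
  )
}

#' @export
print.mean_stroke_profile <- function(x, ...) {
  cat(sprintf("<mean_stroke_profile> %d strokes, <T> = %.3f s, %d grid points\n",
              x$n_strokes, x$mean_period, length(x$grid)))
  invisible(x)
}

#' @export
as.data.frame.mean_stroke_profile <- function(x, ...) {
  data.frame(t = x$grid, mean = x$mean_curve, std = x$std_curve)
}

#' @export
plot.mean_stroke_profile <- function(x, ...) {
  graphics::plot(x$grid, x$mean_curve, type = "l", lwd = 2,
                 xlab = "time from stroke onset (s)",
                 ylab = expression(omega[x] ~ (rad/s)), ...)
  graphics::lines(x$grid, x$mean_curve + x$std_curve, col = "grey50", lty = 2)
  graphics::lines(x$grid, x$mean_curve - x$std_curve, col = "grey50", lty = 2)
  graphics::abline(h = 0, col = "grey80")
  invisible(x)
}
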