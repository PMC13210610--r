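#' Whole-stroke instability index
#'
#' Computes the period-normalized integral criterion of stroke stability
#'
#' \deqn{\frac{1}{\langle T\rangle} \int_0^{\langle T\rangle}
#'       \frac{STD(\omega_x)(t)}{|\langle\omega_x\rangle(t)|}\, dt
#'       \times 100\%,}
#'
#' the average, over the mean stroke period, of the point-wise standard
#' deviation of the individual stroke curves divided by the absolute value
#' of the mean curve. Larger values mean the individual strokes scatter
#' more around the mean pattern, i.e. less stable technique.
#'
#' The integrand is undefined where the mean curve crosses zero. Both grid
#' endpoints are zeros by construction (stroke boundaries are zero
#' crossings), and a typical two-phase stroke has exactly one interior
#' zero, giving the canonical three excluded points. The exclusion is
#' implemented generally: the first and last grid points are removed, and
#' for every interior sign change of the mean curve the two samples
#' bracketing it are removed (grid points where the mean is exactly zero
#' are removed as well), so profiles with ripple-induced extra zeros remain
#' computable. Each removed point splits the integration domain, and the
#' trapezoidal rule is applied piecewise over the remaining contiguous
#' sub-intervals. Normalization is by the full mean period, not by the
#' retained measure, following the printed form of the criterion.
#'
#' No regularization floor is applied to small mean values: values of the
#' index well above 100% near phase boundaries are meaningful and are never
#' clipped.
#'
#' @param profile a `mean_stroke_profile` from [mean_profile()].
#' @return a `stability_index`: list with `value` (percent),
#'   `excluded_points` (grid times removed), `mean_period` and `meta`.
#' @export
stability_index <- function(profile) {
  stopifnot(inherits(profile, "mean_stroke_profile"))
  if (profile$n_strokes < 2L)
    stop("stability index requires a profile built from at least 2 strokes",
         call. = FALSE)
  mu <- profile$mean_curve
  sdv <- profile$std_curve
  grid <- profile$grid
  L <- length(grid)
  if (all(mu == 0)) stop("degenerate mean profile: mean curve identically zero",
                         call. = FALSE)

  drop <- c(1L, L, which(mu == 0))
  sign_chg <- which(mu[-L] * mu[-1] < 0)
  drop <- sort(unique(c(drop, sign_chg, sign_chg + 1L)))
  # changes in the first/last sample pair belong to the boundary zeros of
  # the stroke cycle, not to the interior phase transition
  n_interior <- sum(sign_chg >= 2L & sign_chg <= L - 2L)
  if (n_interior != 1L)
    warning(sprintf("mean curve has %d interior sign change(s); a two-phase stroke has 1",
                    n_interior), call. = FALSE)

  keep <- setdiff(seq_len(L), drop)
  g <- sdv[keep] / abs(mu[keep])
  tk <- grid[keep]

  # piecewise trapezoidal rule over contiguous runs of retained grid points
  runs <- cumsum(c(TRUE, diff(keep) != 1L))
  total <- 0
  for (r in unique(runs)) {
    idx <- which(runs == r)
    if (length(idx) < 2L) next
    gi <- g[idx]; ti <- tk[idx]
    total <- total + sum((gi[-1] + gi[-length(gi)]) / 2 * diff(ti))
  }
  structure(
    list(value = 100 * total / profile$mean_period,
         excluded_points = grid[drop],
         mean_period = profile$mean_period,
         meta = profile$meta),
    class = "stability_index"
  )
}

#' @export
print.stability_index <- function(x, ...) {
  cat(sprintf("<stability_index> %.2f%% over <T> = %.3f s (%d grid points excluded)\n",
              x$value, x$mean_period, length(x$excluded_points)))
  invisible(x)
}
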