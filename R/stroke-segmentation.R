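#' Locate negative-to-positive zero crossings
#'
#' Finds every transition of the angular velocity from negative to positive
#' values between successive samples. These up-crossings mark stroke onsets:
#' the body tilt reverses from the drive (negative angular velocity) into
#' the recovery (positive). Crossing times are located by linear
#' interpolation between the bracketing samples, giving sub-sample
#' precision; a sample exactly equal to 0 terminates the preceding sign run,
#' so a 0 sample lying between a negative and a positive sample yields one
#' crossing at the 0 sample's own time.
#'
#' @param series an [angular_velocity_series()] (normally smoothed first
#'   with [lowpass_fourier()]).
#' @return numeric vector of crossing times in seconds (possibly empty).
#' @export
find_upcrossings <- function(series) {
  stopifnot(inherits(series, "angular_velocity_series"))
  v <- series$values
  t <- series_times(series)
  n <- length(v)

  # strict sign-change pairs
  i <- which(v[-n] < 0 & v[-1] > 0)
  tc <- t[i] + series$dt * (-v[i]) / (v[i + 1] - v[i])

  # zero runs separating a negative run from a positive run: the crossing
  # sits at the first zero sample (it terminates the preceding sign run)
  if (any(v == 0)) {
    r <- rle(sign(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    zr <- which(r$values == 0)
    zr <- zr[zr > 1L & zr < length(r$values)]
    zr <- zr[r$values[zr - 1L] == -1 & r$values[zr + 1L] == 1]
    tc <- c(tc, t[starts[zr]])
  }
  sort(tc)
}

#' Segment a smoothed record into individual strokes
#'
#' Partitions the record at successive negative-to-positive zero crossings
#' (see [find_upcrossings()]). Each stroke spans one full cycle from one
#' up-crossing to the next; data before the first and after the last
#' crossing are incomplete strokes and are discarded. Within each stroke the
#' recovery (phase 2) duration is the total time the signal is positive,
#' measured between linearly interpolated sign-change points, and the drive
#' (phase 1) duration is the remainder, so the two always sum exactly to the
#' stroke period. Note the chronology: because boundaries are the
#' negative-to-positive crossings, the positive (recovery) sub-interval
#' comes first within a segmented stroke; phase labels follow the sign
#' convention (negative = phase 1/drive), not chronological order. Runs of
#' samples exactly equal to zero have zero measure under the interpolation
#' and are absorbed into phase 1.
#'
#' Strokes shorter than `min_period` (the period of the smoothing cut-off
#' frequency, 0.45 s by default) are physically implausible; they are
#' flagged via a message and the `short_strokes` attribute but retained - no
#' stroke is silently deleted.
#'
#' @param series a smoothed [angular_velocity_series()].
#' @param min_period flagging threshold in seconds (default 0.45).
#' @return a `stroke_ensemble`: a data frame with one row per stroke and
#'   columns `onset`, `period`, `phase1`, `phase2`, `slice_start`,
#'   `slice_end` (sample-index range into the parent series), carrying
#'   attributes `dt`, `meta` and `short_strokes`.
#' @export
segment_strokes <- function(series, min_period = 0.45) {
  stopifnot(inherits(series, "angular_velocity_series"))
  crossings <- find_upcrossings(series)
  if (length(crossings) < 2L)
    stop("no complete stroke: fewer than 2 negative-to-positive zero crossings",
         call. = FALSE)

  t <- series_times(series)
  v <- series$values
  ns <- length(crossings) - 1L
  onset <- crossings[-length(crossings)]
  period <- diff(crossings)
  phase2 <- numeric(ns)
  slice_start <- integer(ns)
  slice_end <- integer(ns)

  ci <- findInterval(crossings, t)  # last sample index with t <= crossing
  for (k in seq_len(ns)) {
    a <- crossings[k]
    b <- crossings[k + 1L]
    i0 <- ci[k] + 1L                       # first sample with t > a
    i1 <- ci[k + 1L]                       # last sample with t <= b
    if (i1 >= 1L && t[i1] >= b) i1 <- i1 - 1L
    inside <- if (i0 <= i1) i0:i1 else integer(0)
    bt <- c(a, t[inside], b)
    bv <- c(0, v[inside], 0)
    phase2[k] <- .positive_measure(bt, bv)
    slice_start[k] <- if (length(inside)) inside[1] else NA_integer_
    slice_end[k] <- if (length(inside)) inside[length(inside)] else NA_integer_
  }
  phase1 <- period - phase2

  ens <- data.frame(onset = onset, period = period,
                    phase1 = phase1, phase2 = phase2,
                    slice_start = slice_start, slice_end = slice_end)
  short <- which(period < min_period)
  if (length(short))
    message(sprintf("%d stroke(s) shorter than %.2f s flagged (retained)",
                    length(short), min_period))
  structure(ens,
            dt = series$dt, meta = series$meta, short_strokes = short,
            class = c("stroke_ensemble", "data.frame"))
}

# total time a piecewise-linear signal through (bt, bv) is positive
.positive_measure <- function(bt, bv) {
  ta <- bt[-length(bt)]; tb <- bt[-1]
  va <- bv[-length(bv)]; vb <- bv[-1]
  len <- tb - ta
  pos <- numeric(length(len))

  both_pos <- va >= 0 & vb >= 0 & (va > 0 | vb > 0)
  pos[both_pos] <- len[both_pos]
  # sign change inside the segment: split at the interpolated root
  chg <- va * vb < 0
  if (any(chg)) {
    frac <- va[chg] / (va[chg] - vb[chg])  # position of the root in [0,1]
    pos[chg] <- ifelse(va[chg] > 0, frac * len[chg], (1 - frac) * len[chg])
  }
  sum(pos)
}

#' @export
print.stroke_ensemble <- function(x, ...) {
  cat(sprintf("<stroke_ensemble> %d strokes, mean period %.3f s (phase1 %.3f, phase2 %.3f)\n",
              nrow(x), mean(x$period), mean(x$phase1), mean(x$phase2)))
  ns <- length(attr(x, "short_strokes"))
  if (ns) cat(" ", ns, "stroke(s) flagged shorter than the cut-off period\n")
  invisible(x)
}
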