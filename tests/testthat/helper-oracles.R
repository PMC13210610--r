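# Independent oracles and small builders used across the suite.

# Brute-force DFT by direct summation (O(n^2)); oracle for the FFT path.
dft_direct <- function(x) {
  n <- length(x)
  k <- 0:(n - 1)
  vapply(k, function(kk)
    sum(x * exp(-2i * pi * kk * k / n)), complex(1))
}

# Brute-force low-pass: zero direct-DFT bins above the cut-off, invert by
# direct summation.
lowpass_direct <- function(x, dt, f_cutoff) {
  n <- length(x)
  X <- dft_direct(x)
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * dt)
  X[f > f_cutoff * (1 + 1e-12)] <- 0
  k <- 0:(n - 1)
  out <- vapply(k, function(kk)
    sum(X * exp(2i * pi * kk * k / n)) / n, complex(1))
  Re(out)
}

# Exact two-sided rank-sum p-value by full enumeration of all
# choose(n1+n2, n1) group assignments (mid-ranks).
ranksum_enum <- function(a, b) {
  n1 <- length(a)
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)])
  combs <- utils::combn(length(r), n1)
  ws <- apply(combs, 2, function(idx) sum(r[idx]))
  pl <- mean(ws <= w + 1e-9)
  pg <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pl, pg))
}

# Exact two-sided signed-rank p-value by enumeration of all 2^m sign
# assignments of the non-zero differences (mid-ranks of |d|).
signed_enum <- function(a, b) {
  d <- (b - a)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) return(1)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  ws <- signs %*% r
  pl <- mean(ws <= w + 1e-9)
  pg <- mean(ws >= w - 1e-9)
  min(1, 2 * min(pl, pg))
}

# Series holding sin(2*pi*f*t) on a bin-aligned grid of length span seconds.
sine_series <- function(freq, span = 10, dt = 0.001, phase = 0) {
  t <- seq(0, span, by = dt)
  t <- t[-length(t)]
  angular_velocity_series(sin(2 * pi * freq * t + phase), dt = dt)
}

# Stroke ensemble built directly from stated durations (documented
# data-frame contract of segment_strokes()).
ensemble_of <- function(periods, phase1, meta = list()) {
  onset <- cumsum(c(0, periods[-length(periods)]))
  structure(
    data.frame(onset = onset, period = periods,
               phase1 = phase1, phase2 = periods - phase1,
               slice_start = NA_integer_, slice_end = NA_integer_),
    dt = 0.001, meta = meta, short_strokes = integer(0),
    class = c("stroke_ensemble", "data.frame"))
}

# Mean-stroke profile built directly from curves (documented contract of
# mean_profile()).
profile_of <- function(mean_curve, std_curve, dt, mean_period,
                       n_strokes = 2) {
  structure(
    list(grid = (seq_along(mean_curve) - 1) * dt,
         mean_curve = mean_curve, std_curve = std_curve,
         mean_period = mean_period, n_strokes = n_strokes, dt = dt,
         meta = list()),
    class = "mean_stroke_profile")
}

# One-row trial duration summary for building per-trial tables by hand.
trial_row <- function(participant, stage, grade, full, p1, p2,
                      full_sd = 0.1, p1_sd = 0.08, p2_sd = 0.06) {
  data.frame(participant = participant, stage = stage, grade = grade,
             n = 20, full_mean = full, full_sd = full_sd,
             phase1_mean = p1, phase1_sd = p1_sd,
             phase2_mean = p2, phase2_sd = p2_sd)
}
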