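# Default 3-harmonic stroke template. The constants were fixed once by
# truncating an asymmetric two-lobe reference shape to its first three
# Fourier harmonics and root-finding the lobe split so that the truncated
# waveform's negative (drive) lobe occupies exactly 2.1/3.3 of the period,
# the typical drive/recovery split of a 3.3 s ergometer stroke. The
# waveform has exactly one negative-to-positive zero crossing per period,
# located at the period boundary.
.default_amplitudes <- c(1.294361732055158, 0.480126744843594, 0.232707429210940)
.default_phases     <- c(0.428398998310751, -0.713998330437995, -1.856395657676259)

#' Configuration of the synthetic angular-velocity generator
#'
#' Bundles the parameters of the synthetic stroke signal: a periodic
#' template built from the fundamental plus second and third harmonics,
#' stroke-to-stroke period and amplitude jitter, and additive band-limited
#' Gaussian noise confined to frequencies above the smoothing cut-off.
#' Defaults emulate a steady ergometer bout: mean stroke period 3.3 s with
#' a 2.1 s drive / 1.2 s recovery split, 0.08 s stroke-to-stroke period
#' jitter, 5% amplitude jitter, and 0.15 rad/s of sensor noise in the
#' 3-40 Hz band, sampled at 1 kHz.
#'
#' @param mean_period mean stroke period in seconds (1 to 10; default 3.3).
#' @param harmonic_amplitudes amplitudes (rad/s) of harmonics 1-3.
#' @param harmonic_phases phase offsets (rad) of harmonics 1-3.
#' @param period_jitter_sd SD (s) of the per-stroke period jitter.
#' @param amplitude_jitter_rel relative SD of the per-stroke amplitude scale.
#' @param noise_sd SD (rad/s) of the additive band-limited noise.
#' @param noise_band frequency interval (Hz) the noise is confined to;
#'   must sit above the intended smoothing cut-off for the noise to be
#'   fully removable.
#' @param n_strokes number of strokes to generate (default 72, about a
#'   4-minute bout at a 3.3 s period).
#' @param dt sampling step in seconds (default 0.001).
#' @param seed integer seed for reproducibility, or `NULL`.
#' @param phase_durations optional `c(phase1, phase2)` target drive and
#'   recovery durations in seconds; overrides `mean_period` with their sum
#'   and reshapes the template by piecewise-linear time warping of its two
#'   lobes.
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(mean_period = 3.3,
                             harmonic_amplitudes = .default_amplitudes,
                             harmonic_phases = .default_phases,
                             period_jitter_sd = 0.08,
                             amplitude_jitter_rel = 0.05,
                             noise_sd = 0.15,
                             noise_band = c(3, 40),
                             n_strokes = 72,
                             dt = 0.001,
                             seed = NULL,
                             phase_durations = NULL) {
  if (!is.null(phase_durations)) {
    stopifnot(length(phase_durations) == 2, all(phase_durations > 0))
    mean_period <- sum(phase_durations)
  }
  stopifnot(
    is.numeric(mean_period), length(mean_period) == 1,
    mean_period >= 1, mean_period <= 10,
    length(harmonic_amplitudes) == 3, all(is.finite(harmonic_amplitudes)),
    length(harmonic_phases) == 3, all(is.finite(harmonic_phases)),
    period_jitter_sd >= 0, amplitude_jitter_rel >= 0, noise_sd >= 0,
    length(noise_band) == 2, noise_band[1] > 0, noise_band[2] > noise_band[1],
    n_strokes >= 1, dt > 0
  )
  structure(
    list(mean_period = mean_period,
         harmonic_amplitudes = harmonic_amplitudes,
         harmonic_phases = harmonic_phases,
         period_jitter_sd = period_jitter_sd,
         amplitude_jitter_rel = amplitude_jitter_rel,
         noise_sd = noise_sd, noise_band = noise_band,
         n_strokes = as.integer(n_strokes), dt = dt, seed = seed,
         phase_durations = phase_durations),
    class = "synthetic_config"
  )
}

#' Build the periodic stroke template
#'
#' Evaluates the 3-harmonic waveform
#' `s(theta) = sum_m A_m sin(m theta + phi_m)` (zero mean over one period
#' by construction), anchors it so that `theta = 0` is a
#' negative-to-positive zero crossing, and measures the exact drive
#' (negative) and recovery (positive) fractions of the period by
#' root-finding on the analytic waveform.
#'
#' @param config a [synthetic_config()].
#' @return a `stroke_template`: list with the anchored `amplitudes` and
#'   `phases`, analytic evaluator `fun(theta)`, `theta_down` (interior
#'   down-crossing, radians; `NA` when the waveform has more than two
#'   crossings per period), `phase1_frac`, `phase2_frac`, `period`, `dt`
#'   and `values` (one period sampled at `dt`).
#' @export
make_template <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  A <- config$harmonic_amplitudes
  if (all(A == 0)) stop("template amplitudes are all zero", call. = FALSE)
  ph <- config$harmonic_phases
  f0 <- function(th) A[1] * sin(th + ph[1]) + A[2] * sin(2 * th + ph[2]) +
    A[3] * sin(3 * th + ph[3])

  # locate all zero crossings on a dense grid, refine by root-finding
  ng <- 4096L
  th <- 2 * pi * (0:(ng - 1)) / ng
  s <- f0(th)
  s2 <- c(s[-1], s[1])
  idx <- which(s * s2 < 0 | (s == 0 & s2 != 0))
  if (length(idx) == 0L)
    stop("template has no sign change; adjust amplitudes/phases", call. = FALSE)
  roots <- vapply(idx, function(i) {
    lo <- th[i]; hi <- th[i] + 2 * pi / ng
    if (f0(lo) == 0) lo else stats::uniroot(f0, c(lo, hi), tol = 1e-14)$root
  }, numeric(1))
  up <- roots[f0(roots - 1e-9) < 0 & f0(roots + 1e-9) > 0]
  if (length(up) == 0L)
    stop("template has no negative-to-positive crossing", call. = FALSE)

  # anchor at an up-crossing (prefer one already at the period boundary)
  th0 <- up[1]
  if (any(pmin(up, 2 * pi - up) < 1e-6)) th0 <- 0
  ph_anchored <- ph + (1:3) * th0
  f <- function(theta) {
    A[1] * sin(theta + ph_anchored[1]) + A[2] * sin(2 * theta + ph_anchored[2]) +
      A[3] * sin(3 * theta + ph_anchored[3])
  }

  # negative-measure fraction over one period (drive fraction)
  cross <- sort(((roots - th0) %% (2 * pi)))
  cross <- cross[cross > 1e-9 & cross < 2 * pi - 1e-9]
  bounds <- c(0, cross, 2 * pi)
  mids <- (bounds[-1] + bounds[-length(bounds)]) / 2
  neg <- sum((bounds[-1] - bounds[-length(bounds)])[f(mids) < 0])
  phase1_frac <- neg / (2 * pi)
  theta_down <- if (length(cross) == 1L) cross else NA_real_

  n1 <- round(config$mean_period / config$dt)
  theta_grid <- 2 * pi * (0:(n1 - 1)) / n1
  structure(
    list(amplitudes = A, phases = ph_anchored, fun = f,
         theta_down = theta_down,
         phase1_frac = phase1_frac, phase2_frac = 1 - phase1_frac,
         period = config$mean_period, dt = config$dt,
         values = f(theta_grid)),
    class = "stroke_template"
  )
}

#' @export
print.stroke_template <- function(x, ...) {
  cat(sprintf("<stroke_template> period %.3f s, drive fraction %.4f (%s-lobe)\n",
              x$period, x$phase1_frac,
              if (is.na(x$theta_down)) "multi" else "two"))
  invisible(x)
}

#' Generate a synthetic angular-velocity record with ground truth
#'
#' Concatenates `n_strokes` template cycles. Each stroke k gets a period
#' `T_k = mean_period + N(0, period_jitter_sd)` (the whole cycle is
#' time-rescaled, keeping the waveform continuous at stroke boundaries,
#' where the template is zero) and an amplitude scale
#' `1 + N(0, amplitude_jitter_rel)`. Band-limited Gaussian noise of SD
#' `noise_sd`, synthesized in the frequency domain and confined to
#' `noise_band`, is added last; its power below the band is exactly zero,
#' so brick-wall smoothing at a cut-off under the band removes it entirely.
#' Output is deterministic under a fixed `config$seed`.
#'
#' When `config$phase_durations` is set, the template's positive and
#' negative lobes are piecewise-linearly time-warped to the requested
#' drive/recovery durations (requires a two-lobe template); period jitter
#' then rescales both phases proportionally.
#'
#' @param config a [synthetic_config()].
#' @param meta metadata list attached to the generated series.
#' @return list with `series` (an [angular_velocity_series()]) and `truth`
#'   (data frame of per-stroke `onset`, `period`, `phase1`, `phase2`,
#'   `amplitude_scale`), plus the `template` used.
#' @export
generate_record <- function(config, meta = list()) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  tpl <- make_template(config)
  n <- config$n_strokes
  tb <- config$mean_period

  # per-stroke periods; reject non-physical draws
  periods <- tb + stats::rnorm(n, 0, config$period_jitter_sd)
  for (tries in seq_len(1000L)) {
    bad <- periods <= 0.25 * tb
    if (!any(bad)) break
    periods[bad] <- tb + stats::rnorm(sum(bad), 0, config$period_jitter_sd)
  }
  if (any(periods <= 0.25 * tb))
    stop("period jitter keeps producing non-positive periods", call. = FALSE)

  scales <- 1 + stats::rnorm(n, 0, config$amplitude_jitter_rel)
  for (tries in seq_len(1000L)) {
    bad <- scales <= 0.05
    if (!any(bad)) break
    scales[bad] <- 1 + stats::rnorm(sum(bad), 0, config$amplitude_jitter_rel)
  }

  if (!is.null(config$phase_durations)) {
    if (is.na(tpl$theta_down))
      stop("phase warping requires a two-lobe template", call. = FALSE)
    p1b <- config$phase_durations[1]
    p2b <- config$phase_durations[2]
  } else {
    p1b <- tpl$phase1_frac * tb
    p2b <- tpl$phase2_frac * tb
  }
  # per-stroke phase durations: period jitter rescales both proportionally
  p1 <- p1b * periods / tb
  p2 <- p2b * periods / tb

  onsets <- cumsum(c(0, periods[-n]))
  total <- sum(periods)
  N <- floor(total / config$dt) + 1L
  t <- (0:(N - 1)) * config$dt
  k <- findInterval(t, c(onsets, total), rightmost.closed = TRUE)
  k[k > n] <- n
  tau <- t - onsets[k]

  thd <- if (is.na(tpl$theta_down)) 2 * pi * tpl$phase2_frac else tpl$theta_down
  in_pos <- tau < p2[k]
  theta <- ifelse(in_pos,
                  thd * tau / p2[k],
                  thd + (2 * pi - thd) * (tau - p2[k]) / p1[k])
  v <- scales[k] * tpl$fun(theta)

  if (config$noise_sd > 0)
    v <- v + .bandlimited_noise(N, config$dt, config$noise_band, config$noise_sd)

  series <- angular_velocity_series(v, dt = config$dt, t0 = 0, meta = meta)
  truth <- data.frame(onset = onsets, period = periods,
                      phase1 = p1, phase2 = p2, amplitude_scale = scales)
  list(series = series, truth = truth, template = tpl)
}

# zero-mean Gaussian noise with spectral support confined to band (Hz)
.bandlimited_noise <- function(n, dt, band, sd_target) {
  z <- stats::rnorm(n)
  zf <- .dft(z)
  f <- .fft_freqs(n, dt)
  zf[f < band[1] | f > band[2]] <- 0 + 0i
  y <- Re(.dft(zf, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("noise band contains no frequency bins for this record",
                   call. = FALSE)
  y * (sd_target / s)
}

#' Generate a synthetic longitudinal cohort
#'
#' Emulates the measurement design of a longitudinal ergometer study:
#' `n_participants` athletes measured at each `stage` and power `grade`.
#' Each participant gets a random baseline stroke period
#' (`N(mean_period, between_sd)`); higher grades shorten the period by
#' `grade_period_step` per grade, and each stage can add the
#' phase-duration shifts in `stage_effects` - e.g. opposing drive/recovery
#' shifts with the full period held constant.
#'
#' @param n_participants number of participants (default 7).
#' @param stages chronological stage labels.
#' @param grades vector of grade indices.
#' @param stage_effects `NULL` (no effects) or a data frame with columns
#'   `stage`, `phase1_shift`, `phase2_shift` (seconds, added to the
#'   baseline phase durations at that stage).
#' @param between_sd between-participant SD (s) of the baseline period
#'   (default 0.15).
#' @param grade_period_step change (s) of the stroke period per grade
#'   above the first (default -0.1: higher power, faster strokes).
#' @param config base [synthetic_config()] for the per-trial records.
#' @param seed integer seed for the whole cohort, or `NULL`.
#' @return a `synthetic_cohort`: list with `manifest` (data frame
#'   `participant`, `stage`, `grade`) and `trials` (list of
#'   `list(meta, series, truth)` in manifest order).
#' @export
generate_cohort <- function(n_participants = 7,
                            stages = c("March", "April", "June"),
                            grades = 1:3,
                            stage_effects = NULL,
                            between_sd = 0.15,
                            grade_period_step = -0.1,
                            config = synthetic_config(),
                            seed = NULL) {
  stopifnot(n_participants >= 1, length(stages) >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(stage_effects))
    stage_effects <- data.frame(stage = stages, phase1_shift = 0, phase2_shift = 0)
  if (!all(stages %in% stage_effects$stage))
    stop("stage_effects must cover every stage", call. = FALSE)

  tpl <- make_template(config)
  baselines <- config$mean_period + stats::rnorm(n_participants, 0, between_sd)
  participants <- sprintf("P%02d", seq_len(n_participants))

  manifest <- expand.grid(participant = participants, stage = stages,
                          grade = grades, stringsAsFactors = FALSE,
                          KEEP.OUT.ATTRS = FALSE)
  manifest <- manifest[order(match(manifest$stage, stages),
                             manifest$grade, manifest$participant), ]
  rownames(manifest) <- NULL

  trials <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    pid <- match(manifest$participant[i], participants)
    eff <- stage_effects[stage_effects$stage == manifest$stage[i], ][1, ]
    tb_i <- baselines[pid] + grade_period_step * (manifest$grade[i] - grades[1])
    p1 <- tpl$phase1_frac * tb_i + eff$phase1_shift
    p2 <- tpl$phase2_frac * tb_i + eff$phase2_shift
    if (p1 < 0.2 || p2 < 0.2)
      stop(sprintf("infeasible stage effects: phase durations %.3f/%.3f s for %s/%s",
                   p1, p2, manifest$participant[i], manifest$stage[i]),
           call. = FALSE)
    cfg_i <- config
    cfg_i$seed <- NULL                      # RNG stream continues
    cfg_i$phase_durations <- c(p1, p2)
    cfg_i$mean_period <- p1 + p2
    meta <- list(participant = manifest$participant[i],
                 stage = manifest$stage[i], grade = manifest$grade[i])
    rec <- generate_record(cfg_i, meta = meta)
    trials[[i]] <- c(list(meta = meta), rec[c("series", "truth")])
  }
  structure(list(manifest = manifest, trials = trials),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("<synthetic_cohort> %d trials: %d participants x %d stages x %d grades\n",
              nrow(m), length(unique(m$participant)),
              length(unique(m$stage)), length(unique(m$grade))))
  invisible(x)
}
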