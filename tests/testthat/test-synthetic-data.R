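test_that("template phase split matches dense root-finding", {
  # pure fundamental: symmetric 50/50 split
  cfg <- synthetic_config(harmonic_amplitudes = c(1, 0, 0),
                          harmonic_phases = c(0, 0, 0))
  tpl <- make_template(cfg)
  expect_equal(tpl$phase1_frac, 0.5, tolerance = 1e-9)

  # default asymmetric template: drive fraction in the documented window,
  # verified against an independent dense-sampling measure of the waveform
  tpl2 <- make_template(synthetic_config())
  expect_gt(tpl2$phase1_frac, 0.62)
  expect_lt(tpl2$phase1_frac, 0.66)
  th <- 2 * pi * (0:999999) / 1e6
  expect_equal(mean(tpl2$fun(th) < 0), tpl2$phase1_frac, tolerance = 1e-5)
  # exactly one negative-to-positive crossing per period
  sv <- tpl2$fun(th)
  expect_equal(sum(sv < 0 & c(sv[-1], sv[1]) > 0), 1)

  expect_error(make_template(synthetic_config(
    harmonic_amplitudes = c(0, 0, 0))), "all zero")
})

test_that("records are deterministic under a seed and vary across seeds", {
  cfg1 <- synthetic_config(n_strokes = 5, dt = 0.002, seed = 42)
  r1 <- generate_record(cfg1)
  r2 <- generate_record(cfg1)
  expect_identical(r1$series$values, r2$series$values)
  expect_identical(r1$truth, r2$truth)
  cfg2 <- synthetic_config(n_strokes = 5, dt = 0.002, seed = 43)
  r3 <- generate_record(cfg2)
  expect_false(identical(r1$series$values, r3$series$values))
})

test_that("ground-truth phases sum to periods exactly", {
  cfg <- synthetic_config(n_strokes = 40, dt = 0.002, seed = 9)
  tr <- generate_record(cfg)$truth
  expect_lt(max(abs(tr$phase1 + tr$phase2 - tr$period)), 1e-12)
})

test_that("noiseless records are recovered by segmentation to the millisecond", {
  cfg <- synthetic_config(period_jitter_sd = 0, amplitude_jitter_rel = 0,
                          noise_sd = 0, n_strokes = 10, seed = 1)
  rec <- generate_record(cfg)
  ens <- segment_strokes(rec$series)
  # strokes 2..n are complete (the record starts at an up-crossing)
  truth <- rec$truth[-1, ][seq_len(nrow(ens)), ]
  expect_lt(max(abs(ens$period - truth$period)), 0.002)
})

test_that("band-limited noise is fully removed by the smoothing stage", {
  cfg <- synthetic_config(period_jitter_sd = 0, amplitude_jitter_rel = 0,
                          noise_sd = 0.2, n_strokes = 12, seed = 2)
  rec <- generate_record(cfg)
  sm <- lowpass_fourier(rec$series)
  ens <- segment_strokes(sm)
  truth <- rec$truth[-1, ][seq_len(nrow(ens)), ]
  expect_lt(max(abs(ens$period - truth$period)), 0.01)

  # noise spectral power below the cut-off is negligible (< 1%)
  clean <- generate_record(synthetic_config(
    period_jitter_sd = 0, amplitude_jitter_rel = 0, noise_sd = 0,
    n_strokes = 12, seed = 2))
  noise <- rec$series$values - clean$series$values
  spec <- Mod(stats::fft(noise))^2
  f <- pmin(0:(length(noise) - 1), length(noise) - (0:(length(noise) - 1))) /
    (length(noise) * cfg$dt)
  expect_lt(sum(spec[f <= 2.23]) / sum(spec), 0.01)
})

test_that("the full pipeline recovers generator parameters end to end", {
  cfg <- synthetic_config(period_jitter_sd = 0.05, amplitude_jitter_rel = 0.03,
                          noise_sd = 0.15, n_strokes = 200, dt = 0.002,
                          seed = 21)
  rec <- generate_record(cfg)
  sm <- lowpass_fourier(rec$series)
  d <- summarize_durations(segment_strokes(sm))
  expect_lt(abs(d$full_mean - 3.3) / 3.3, 0.01)
  expect_lt(abs(d$full_sd - 0.05) / 0.05, 0.2)
})

test_that("cohorts honour stage effects and reject infeasible ones", {
  # jitter off: the shift bookkeeping itself is deterministic
  cfg <- synthetic_config(n_strokes = 6, dt = 0.005, period_jitter_sd = 0,
                          amplitude_jitter_rel = 0, noise_sd = 0)
  eff <- data.frame(stage = c("A", "B"),
                    phase1_shift = c(0, 0.3), phase2_shift = c(0, -0.3))
  coh <- generate_cohort(3, stages = c("A", "B"), grades = 1,
                         stage_effects = eff, config = cfg, seed = 3)
  expect_equal(nrow(coh$manifest), 6)
  tB <- coh$trials[[which(coh$manifest$stage == "B")[1]]]$truth
  tA <- coh$trials[[which(coh$manifest$stage == "A")[1]]]$truth
  # same participant: phase 1 grew and phase 2 shrank by exactly the shift
  expect_equal(mean(tB$phase1) - mean(tA$phase1), 0.3, tolerance = 1e-9)
  expect_equal(mean(tB$phase2) - mean(tA$phase2), -0.3, tolerance = 1e-9)
  expect_equal(mean(tB$period), mean(tA$period), tolerance = 1e-9)

  bad <- data.frame(stage = c("A", "B"),
                    phase1_shift = c(0, 0), phase2_shift = c(0, -1.2))
  expect_error(
    generate_cohort(3, stages = c("A", "B"), grades = 1, stage_effects = bad,
                    config = cfg, seed = 3),
    "infeasible")
  expect_error(
    generate_cohort(3, stages = c("A", "B"), grades = 1,
                    stage_effects = eff[1, ], config = cfg, seed = 3),
    "cover every stage")
})
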