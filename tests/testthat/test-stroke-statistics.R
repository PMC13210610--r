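test_that("trial summaries use the n-1 standard deviation", {
  ens <- ensemble_of(rep(2, 4), rep(1, 4))
  d <- summarize_durations(ens)
  expect_equal(c(d$full_mean, d$phase1_mean, d$phase2_mean), c(2, 1, 1))
  expect_equal(c(d$full_sd, d$phase1_sd, d$phase2_sd), c(0, 0, 0))

  d2 <- summarize_durations(ensemble_of(c(3.0, 3.2, 3.4), c(2, 2, 2)))
  expect_equal(d2$full_mean, 3.2)
  expect_equal(d2$full_sd, 0.2)

  # single stroke: means defined, SDs reported as missing (not zero)
  d3 <- summarize_durations(ensemble_of(3.3, 2.1))
  expect_equal(d3$full_mean, 3.3)
  expect_true(is.na(d3$full_sd))
})

test_that("trial summaries are invariant to stroke order", {
  set.seed(401)
  p <- runif(10, 2, 4)
  ph1 <- p * runif(10, 0.5, 0.7)
  d1 <- summarize_durations(ensemble_of(p, ph1))
  o <- sample(10)
  d2 <- summarize_durations(ensemble_of(p[o], ph1[o]))
  expect_equal(d1, d2, ignore_attr = TRUE)
})

test_that("group summaries aggregate participant means", {
  mk <- function(full) {
    structure(data.frame(scope = "trial", n = 20,
                         full_mean = full, full_sd = 0.1,
                         phase1_mean = full * 0.64, phase1_sd = 0.08,
                         phase2_mean = full * 0.36, phase2_sd = 0.06),
              meta = list(stage = "March", grade = 1),
              class = c("duration_summary", "data.frame"))
  }
  same <- lapply(rep(3.3, 7), mk)
  g <- group_summary(same)
  expect_equal(g$n, 7)
  expect_equal(g$full_mean, 3.3)
  expect_equal(g$full_sd, 0)

  g2 <- group_summary(lapply(seq(3.0, 4.2, by = 0.2), mk))
  expect_equal(g2$full_mean, 3.6)
  expect_equal(g2$full_sd, 0.4320494, tolerance = 1e-6)

  mixed <- c(same[1:3], list(structure(same[[4]],
                                       meta = list(stage = "April", grade = 1))))
  expect_error(group_summary(mixed), "mixed stages/grades")
})

test_that("mean profile of identical strokes has zero dispersion", {
  cfg <- synthetic_config(period_jitter_sd = 0, amplitude_jitter_rel = 0,
                          noise_sd = 0, n_strokes = 8)
  rec <- generate_record(cfg)
  ens <- segment_strokes(rec$series)
  pr <- mean_profile(rec$series, ens)
  expect_lt(max(pr$std_curve), 1e-9)
  # the mean curve reproduces one stroke's waveform
  tpl <- make_template(cfg)
  theta <- 2 * pi * pr$grid / 3.3
  expect_lt(max(abs(pr$mean_curve - tpl$fun(pmin(theta, 2 * pi)))), 1e-6)
})

test_that("two scaled windows give the closed-form point-wise SD", {
  cfg <- synthetic_config(period_jitter_sd = 0, amplitude_jitter_rel = 0,
                          noise_sd = 0, n_strokes = 2)
  tpl <- make_template(cfg)
  n1 <- round(3.3 / cfg$dt)
  w <- tpl$values
  # lead-in negative sample so the first cycle boundary is a detected crossing
  v <- c(-0.01, 1.1 * w, 0.9 * w, 0.01)
  s <- angular_velocity_series(v, cfg$dt)
  ens <- segment_strokes(s)
  pr <- mean_profile(s, ens)
  expect_equal(pr$n_strokes, 2)
  # the final grid point falls on the window boundary; compare the interior
  want <- 0.1 * sqrt(2) * abs(w)
  expect_lt(max(abs(pr$std_curve[seq_len(n1)] - want)), 1e-9)
})

test_that("period jitter concentrates dispersion near the interior crossing", {
  # the window tail overlaps the next stroke, so dispersion is also high at
  # the very end of the grid; the property concerns the interior
  cfg <- synthetic_config(period_jitter_sd = 0.05, amplitude_jitter_rel = 0,
                          noise_sd = 0, n_strokes = 200, dt = 0.002, seed = 7)
  rec <- generate_record(cfg)
  ens <- segment_strokes(rec$series)
  pr <- mean_profile(rec$series, ens)
  fr <- pr$grid / pr$mean_period
  interior <- fr > 0.05 & fr < 0.9
  am <- fr[which.max(pr$std_curve * interior)]
  L <- length(pr$grid)
  ic <- which(pr$mean_curve[-L] > 0 & pr$mean_curve[-1] < 0)[1]
  expect_lt(abs(am - fr[ic]), 0.15)
})

test_that("jittered-period SD is recovered from synthetic ensembles", {
  for (sigma in c(0.02, 0.05, 0.1)) {
    cfg <- synthetic_config(period_jitter_sd = sigma, amplitude_jitter_rel = 0,
                            noise_sd = 0, n_strokes = 200, dt = 0.002,
                            seed = 11)
    rec <- generate_record(cfg)
    d <- summarize_durations(segment_strokes(rec$series))
    expect_lt(abs(d$full_sd - sigma) / sigma, 0.2)
    expect_lt(abs(d$full_mean - 3.3) / 3.3, 0.01)
  }
})

test_that("profiles require at least two usable windows", {
  cfg <- synthetic_config(period_jitter_sd = 0, amplitude_jitter_rel = 0,
                          noise_sd = 0, n_strokes = 3)
  rec <- generate_record(cfg)
  ens <- segment_strokes(rec$series)
  # 7.0 s covers the crossings at 3.3 and 6.6 s: exactly one complete stroke
  short <- angular_velocity_series(
    rec$series$values[1:(round(7.0 / cfg$dt))], cfg$dt)
  ens_short <- segment_strokes(short)
  expect_equal(nrow(ens_short), 1)
  expect_error(mean_profile(short, ens_short), "2 strokes")
})
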