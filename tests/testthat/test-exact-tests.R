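test_that("rank-sum worked examples match full enumeration", {
  # complete separation of two samples of 7
  expect_equal(ranksum_exact(1:7, 8:14), 2 / choose(14, 7))
  # identical samples sit at the centre of the null
  expect_equal(ranksum_exact(1:5, 1:5), 1)
  # tied overlapping samples against the enumeration oracle
  expect_equal(ranksum_exact(c(1, 2, 3), c(2, 3, 4)),
               ranksum_enum(c(1, 2, 3), c(2, 3, 4)))
})

test_that("signed-rank worked examples match full enumeration", {
  expect_equal(signed_rank_exact(rep(0, 7), 1:7), 2 / 2^7)
  # differences symmetric about zero
  expect_warning(p0 <- signed_rank_exact(rep(0, 7), rep(0, 7)), "degenerate")
  expect_equal(p0, 1)
  expect_equal(signed_rank_exact(rep(0, 7), c(1, -1, 2, -2, 3, -3, 0)), 1)
  # 5 positive, 2 negative smallest-magnitude differences
  a <- rep(0, 7); b <- c(5, 6, 7, 8, 9, -1, -2)
  expect_equal(signed_rank_exact(a, b), signed_enum(a, b))
})

test_that("both tests agree with enumeration oracles on random small samples", {
  set.seed(501)
  for (i in 1:100) {
    n1 <- sample(2:8, 1); n2 <- sample(2:8, 1)
    # half the instances get heavy ties via rounding
    gen <- function(n) if (i %% 2) rnorm(n) else round(rnorm(n), 0)
    a <- gen(n1); b <- gen(n2)
    expect_equal(ranksum_exact(a, b), ranksum_enum(a, b), tolerance = 1e-12)
    x <- gen(n1); y <- gen(n1)
    expect_equal(suppressWarnings(signed_rank_exact(x, y)),
                 signed_enum(x, y), tolerance = 1e-12)
  }
})

test_that("both tests agree with stats::wilcox.test exact p-values without ties", {
  set.seed(502)
  for (i in 1:25) {
    a <- rnorm(7); b <- rnorm(7)
    expect_equal(ranksum_exact(a, b),
                 stats::wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(signed_rank_exact(a, b),
                 stats::wilcox.test(b, a, paired = TRUE, exact = TRUE)$p.value)
  }
})

test_that("rank tests are invariant under monotone transforms and swaps", {
  set.seed(503)
  for (i in 1:20) {
    a <- rnorm(6); b <- rnorm(7)
    f <- function(x) exp(2 * x) + 1   # strictly increasing
    expect_equal(ranksum_exact(a, b), ranksum_exact(f(a), f(b)))
    expect_equal(ranksum_exact(a, b), ranksum_exact(b, a))
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(signed_rank_exact(x, y), signed_rank_exact(y, x))
    p <- ranksum_exact(a, b)
    expect_gt(p, 0); expect_lte(p, 1)
  }
})

test_that("rejection under the null stays at or below the nominal level", {
  set.seed(504)
  nrep <- 2000
  rej_rs <- 0; rej_sr <- 0
  for (i in seq_len(nrep)) {
    a <- rnorm(7); b <- rnorm(7)
    if (ranksum_exact(a, b) < 0.05) rej_rs <- rej_rs + 1
    if (signed_rank_exact(a, b) < 0.05) rej_sr <- rej_sr + 1
  }
  se <- sqrt(0.05 * 0.95 / nrep)
  expect_lte(rej_rs / nrep, 0.05 + 3 * se)
  expect_lte(rej_sr / nrep, 0.05 + 3 * se)
})

test_that("test matrices flag constructed effects and ignore stable quantities", {
  set.seed(505)
  rows <- list()
  for (p in sprintf("P%d", 1:7)) {
    base <- 3.3 + rnorm(1, 0, 0.05)
    rows[[length(rows) + 1L]] <-
      trial_row(p, "March", 1, base, base * 0.64, base * 0.36)
    # phase 1 up, phase 2 down by 0.3 s; full period unchanged
    rows[[length(rows) + 1L]] <-
      trial_row(p, "April", 1, base, base * 0.64 + 0.3, base * 0.36 - 0.3)
  }
  tm <- build_test_matrix(do.call(rbind, rows), stages = c("March", "April"))
  sr <- tm$signed_rank
  expect_equal(sr$sig_duration[sr$quantity == "phase1"], 1)
  expect_equal(sr$sig_duration[sr$quantity == "phase2"], 1)
  expect_equal(sr$sig_duration[sr$quantity == "full"], 0)
  rs <- tm$ranksum
  expect_equal(rs$sig_duration[rs$quantity == "phase1"], 1)
  expect_equal(rs$sig_duration[rs$quantity == "full"], 0)
})

test_that("identical stages give all-zero matrices with p = 1", {
  rows <- list()
  for (p in sprintf("P%d", 1:7)) {
    v <- trial_row(p, "March", 1, 3.3 + as.numeric(substring(p, 2)) / 10,
                   2.1, 1.2)
    rows[[length(rows) + 1L]] <- v
    v$stage <- "April"
    rows[[length(rows) + 1L]] <- v
  }
  tm <- suppressWarnings(
    build_test_matrix(do.call(rbind, rows), stages = c("March", "April")))
  for (d in list(tm$ranksum, tm$signed_rank)) {
    expect_true(all(d$sig_duration == 0))
    expect_true(all(d$p_duration == 1))
  }
})

test_that("incomplete participant grids are rejected with the missing cells", {
  rows <- do.call(rbind, lapply(sprintf("P%d", 1:7), function(p)
    trial_row(p, "March", 1, 3.3, 2.1, 1.2)))
  rows <- rbind(rows, trial_row("P1", "April", 1, 3.3, 2.1, 1.2))
  expect_error(build_test_matrix(rows, stages = c("March", "April")),
               "missing per-trial cells")
})

test_that("matrix layout matches the stage-pair by quantity grid", {
  set.seed(506)
  rows <- list()
  for (p in sprintf("P%d", 1:7)) for (st in c("March", "April", "June"))
    for (g in 1:3) {
      base <- 3.3 + rnorm(1, 0, 0.05)
      rows[[length(rows) + 1L]] <- trial_row(p, st, g, base, base * 0.64,
                                             base * 0.36)
    }
  tm <- build_test_matrix(do.call(rbind, rows),
                          stages = c("March", "April", "June"))
  # 3 stage pairs x 3 grades x 3 quantities
  expect_equal(nrow(tm$ranksum), 27)
  wide <- format_test_matrix(tm, "ranksum")
  expect_equal(nrow(wide), 9)
  expect_named(wide, c("stage_pair", "grade", "full", "phase1", "phase2"))
  counts <- significance_counts(tm)
  expect_equal(counts$n_comparisons, c(12, 12))
})
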