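#' Exact two-sided Wilcoxon rank-sum test
#'
#' Exact two-sided p-value of the rank-sum statistic, suitable for the very
#' small samples of a longitudinal cohort study (e.g. 7 participants per
#' stage), where normal approximations can flip borderline significance
#' calls. The full null distribution of the rank-sum of sample `a` is
#' computed by a subset-sum counting recursion over the (mid-)ranks, which
#' is equivalent to complete enumeration of all `choose(n1 + n2, n1)`
#' group assignments and remains exact in the presence of ties (mid-ranks
#' are used and the permutation distribution is computed on them).
#'
#' The two-sided p-value is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param a,b numeric vectors (each of length >= 2, finite).
#' @return the exact two-sided p-value.
#' @examples
#' ranksum_exact(1:7, 8:14)  # complete separation: 2 / choose(14, 7)
#' @export
ranksum_exact <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L)
    stop("both samples must contain at least 2 values", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("samples must be finite", call. = FALSE)
  n1 <- length(a)
  r <- rank(c(a, b))            # mid-ranks for ties
  d <- as.integer(round(2 * r)) # doubled ranks are integers
  w <- sum(d[seq_len(n1)])
  dist <- .ranksum_null(d, n1)
  pl <- sum(dist[seq_len(w + 1L)])
  pg <- sum(dist[(w + 1L):length(dist)])
  min(1, 2 * min(pl, pg))
}

# exact null pmf of the doubled rank-sum of a size-n1 subset of d
# (counting DP; identical to enumerating all subsets)
.ranksum_null <- function(d, n1) {
  S <- sum(d)
  counts <- matrix(0, nrow = n1 + 1L, ncol = S + 1L)
  counts[1L, 1L] <- 1
  for (x in d) {
    jmax <- min(n1, nrow(counts) - 1L)
    for (j in jmax:1) {
      shifted <- c(numeric(x), counts[j, seq_len(S + 1L - x)])
      counts[j + 1L, ] <- counts[j + 1L, ] + shifted
    }
  }
  counts[n1 + 1L, ] / choose(length(d), n1)
}

#' Paired sample for a pre/post comparison
#'
#' Light container pairing each participant's value at an earlier stage
#' (`a`) with the value at a later stage (`b`).
#'
#' @param a,b numeric vectors of equal length (>= 2), finite.
#' @param labels optional participant identifiers.
#' @return a `paired_sample` object.
#' @export
paired_sample <- function(a, b, labels = NULL) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) != length(b)) stop("'a' and 'b' must have equal length", call. = FALSE)
  if (length(a) < 2L) stop("at least 2 pairs are required", call. = FALSE)
  if (!all(is.finite(a)) || !all(is.finite(b)))
    stop("paired values must be finite", call. = FALSE)
  if (is.null(labels)) labels <- as.character(seq_along(a))
  structure(list(labels = labels, a = a, b = b), class = "paired_sample")
}

#' Exact two-sided Wilcoxon signed-rank test
#'
#' Exact two-sided p-value of the signed-rank statistic for paired
#' (pre/post) measurements on the same subjects. Zero differences are
#' dropped before ranking (the classical convention; at n = 7 the
#' alternative zero-handling rules can change the p-value, so the choice is
#' documented here). Tied absolute differences receive mid-ranks and the
#' null distribution - the distribution of the positive-rank sum over all
#' `2^m` equally likely sign assignments of the m non-zero differences - is
#' computed exactly by convolution, equivalent to full enumeration.
#'
#' @param a a numeric vector of earlier-stage values, or a
#'   [paired_sample()].
#' @param b numeric vector of later-stage values (ignored when `a` is a
#'   `paired_sample`).
#' @return the exact two-sided p-value. If all differences are zero the
#'   test is degenerate: returns 1 with a warning.
#' @examples
#' signed_rank_exact(rep(0, 7), 1:7)  # all positive: 2 / 2^7
#' @export
signed_rank_exact <- function(a, b = NULL) {
  if (inherits(a, "paired_sample")) {
    d <- a$b - a$a
  } else {
    if (is.null(b)) stop("supply 'b' or a paired_sample", call. = FALSE)
    a <- as.numeric(a); b <- as.numeric(b)
    if (length(a) != length(b)) stop("'a' and 'b' must have equal length", call. = FALSE)
    if (length(a) < 2L) stop("at least 2 pairs are required", call. = FALSE)
    if (!all(is.finite(a)) || !all(is.finite(b)))
      stop("paired values must be finite", call. = FALSE)
    d <- b - a
  }
  d <- d[d != 0]
  m <- length(d)
  if (m == 0L) {
    warning("all paired differences are zero; signed-rank test is degenerate",
            call. = FALSE)
    return(1)
  }
  r <- rank(abs(d))
  dr <- as.integer(round(2 * r))
  w <- sum(dr[d > 0])
  S <- sum(dr)
  ways <- numeric(S + 1L)
  ways[1L] <- 1
  for (x in dr)
    ways <- ways + c(numeric(x), ways[seq_len(S + 1L - x)])
  dist <- ways / 2^m
  pl <- sum(dist[seq_len(w + 1L)])
  pg <- sum(dist[(w + 1L):length(dist)])
  min(1, 2 * min(pl, pg))
}

#' Longitudinal significance matrices
#'
#' Applies both exact tests to participant-level stroke statistics for
#' every combination of stage pair, power grade and quantity (full stroke,
#' phase 1, phase 2), separately for the mean durations and for their
#' per-trial standard deviations. The rank-sum test compares the two
#' stages' participant samples as two groups; the signed-rank test pairs
#' values by participant. Stage pairs are the consecutive stages plus, when
#' three or more stages are present, the first-to-last comparison.
#'
#' No multiple-testing correction is applied; the matrices report raw
#' per-comparison p-values and 0/1 calls at `alpha`, and carry an
#' `mt_correction = "none"` attribute to make that explicit.
#'
#' @param per_trial data frame of per-trial summaries with columns
#'   `participant`, `stage`, `grade`, `full_mean`, `full_sd`,
#'   `phase1_mean`, `phase1_sd`, `phase2_mean`, `phase2_sd` (one row per
#'   participant x stage x grade; see [summarize_durations()]).
#' @param alpha significance level for the 0/1 calls (default 0.05).
#' @param stages stage labels in chronological order; default: order of
#'   first appearance in `per_trial$stage`.
#' @return a `test_matrix`: list with elements `ranksum` and `signed_rank`,
#'   each a long-format data frame with columns `stage_from`, `stage_to`,
#'   `grade`, `quantity`, `p_duration`, `sig_duration`, `p_sd`, `sig_sd`,
#'   plus the `alpha` used.
#' @export
build_test_matrix <- function(per_trial, alpha = 0.05, stages = NULL) {
  per_trial <- as.data.frame(per_trial)
  need <- c("participant", "stage", "grade", "full_mean", "full_sd",
            "phase1_mean", "phase1_sd", "phase2_mean", "phase2_sd")
  miss <- setdiff(need, names(per_trial))
  if (length(miss))
    stop("per_trial is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (is.null(stages)) stages <- unique(as.character(per_trial$stage))
  grades <- sort(unique(per_trial$grade))
  participants <- sort(unique(as.character(per_trial$participant)))
  if (length(stages) < 2L) stop("at least 2 stages are required", call. = FALSE)
  if (length(participants) < 2L)
    stop("group tests require at least 2 participants", call. = FALSE)

  # completeness check: every participant x stage x grade cell present once
  key <- with(per_trial, paste(participant, stage, grade, sep = "\r"))
  want <- as.vector(outer(
    as.vector(outer(participants, stages, paste, sep = "\r")),
    grades, paste, sep = "\r"))
  missing_cells <- setdiff(want, key)
  if (length(missing_cells))
    stop("missing per-trial cells: ",
         paste(gsub("\r", "/", utils::head(missing_cells, 10L)), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(key))
    stop("duplicated per-trial cells", call. = FALSE)

  pairs <- cbind(stages[-length(stages)], stages[-1])
  if (length(stages) >= 3L)
    pairs <- rbind(pairs, c(stages[1], stages[length(stages)]))

  quantities <- c("full", "phase1", "phase2")
  grab <- function(stage, grade, colname) {
    sub <- per_trial[per_trial$stage == stage & per_trial$grade == grade, ]
    sub <- sub[match(participants, as.character(sub$participant)), ]
    sub[[colname]]
  }

  run <- function(testfun) {
    rows <- list()
    for (p in seq_len(nrow(pairs))) for (g in grades) for (q in quantities) {
      xd <- grab(pairs[p, 1], g, paste0(q, "_mean"))
      yd <- grab(pairs[p, 2], g, paste0(q, "_mean"))
      xs <- grab(pairs[p, 1], g, paste0(q, "_sd"))
      ys <- grab(pairs[p, 2], g, paste0(q, "_sd"))
      pd <- suppressWarnings(testfun(xd, yd))
      ps <- suppressWarnings(testfun(xs, ys))
      rows[[length(rows) + 1L]] <- data.frame(
        stage_from = pairs[p, 1], stage_to = pairs[p, 2], grade = g,
        quantity = q,
        p_duration = pd, sig_duration = as.integer(pd < alpha),
        p_sd = ps, sig_sd = as.integer(ps < alpha)
      )
    }
    do.call(rbind, rows)
  }

  structure(
    list(ranksum = run(ranksum_exact),
         signed_rank = run(signed_rank_exact),
         alpha = alpha),
    mt_correction = "none",
    class = "test_matrix"
  )
}

#' Format a significance matrix as a compact grid
#'
#' Renders one test's results as a grid with one row per (stage pair,
#' grade) and one column per quantity, each cell in the
#' `duration/standard-deviation` format, e.g. `"0/1"`.
#'
#' @param tm a `test_matrix` from [build_test_matrix()].
#' @param test `"ranksum"` or `"signed_rank"`.
#' @return a data frame with columns `stage_pair`, `grade`, `full`,
#'   `phase1`, `phase2`.
#' @export
format_test_matrix <- function(tm, test = c("ranksum", "signed_rank")) {
  stopifnot(inherits(tm, "test_matrix"))
  test <- match.arg(test)
  d <- tm[[test]]
  d$cell <- paste(d$sig_duration, d$sig_sd, sep = "/")
  wide <- stats::reshape(
    d[, c("stage_from", "stage_to", "grade", "quantity", "cell")],
    idvar = c("stage_from", "stage_to", "grade"),
    timevar = "quantity", direction = "wide")
  names(wide) <- sub("^cell\\.", "", names(wide))
  data.frame(stage_pair = paste(wide$stage_from, wide$stage_to, sep = " -> "),
             grade = wide$grade,
             full = wide$full, phase1 = wide$phase1, phase2 = wide$phase2)
}

#' Headline significance counts over sequential stage pairs
#'
#' Counts significant phase-duration (and phase-SD) cells over the
#' comparison universe of the sequential stage pairs only (first-to-last
#' comparisons excluded), all grades, phases 1 and 2 - with 3 grades this
#' is the familiar "x of 12" summary.
#'
#' @param tm a `test_matrix`.
#' @return data frame with one row per test and columns `sig_duration`,
#'   `sig_sd`, `n_comparisons`.
#' @export
significance_counts <- function(tm) {
  stopifnot(inherits(tm, "test_matrix"))
  one <- function(d) {
    # sequential pairs are all pairs except the first-to-last comparison
    stages <- unique(c(d$stage_from, d$stage_to))
    keep <- d$quantity %in% c("phase1", "phase2") &
      !(d$stage_from == stages[1] & d$stage_to == stages[length(stages)] &
          length(stages) >= 3)
    sub <- d[keep, ]
    data.frame(sig_duration = sum(sub$sig_duration), sig_sd = sum(sub$sig_sd),
               n_comparisons = nrow(sub))
  }
  out <- rbind(one(tm$ranksum), one(tm$signed_rank))
  cbind(test = c("ranksum", "signed_rank"), out)
}

#' @export
print.test_matrix <- function(x, ...) {
  cat("<test_matrix> alpha =", x$alpha,
      "(cells: duration/SD; no multiple-testing correction)\n")
  cat("\nRank-sum test:\n")
  print(format_test_matrix(x, "ranksum"), row.names = FALSE)
  cat("\nWilcoxon signed-rank test:\n")
  print(format_test_matrix(x, "signed_rank"), row.names = FALSE)
  invisible(x)
}
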