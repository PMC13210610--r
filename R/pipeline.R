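#' Trial manifest
#'
#' Validates a table describing one recording file per (participant,
#' stage, grade) cell. The ergometer power corresponding to a grade
#' (110 W + 40 W per grade above the first) is carried as metadata only.
#'
#' @param df data frame with columns `participant`, `stage`, `grade`,
#'   `path`.
#' @param check_files verify at construction that the files exist.
#' @return a `trial_manifest` data frame.
#' @export
trial_manifest <- function(df, check_files = TRUE) {
  df <- as.data.frame(df)
  need <- c("participant", "stage", "grade", "path")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("manifest is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  key <- with(df, paste(participant, stage, grade))
  if (anyDuplicated(key))
    stop("duplicate (participant, stage, grade) keys in manifest", call. = FALSE)
  if (check_files) {
    gone <- !file.exists(df$path)
    if (any(gone))
      stop("manifest references missing files: ",
           paste(utils::head(df$path[gone], 5L), collapse = ", "), call. = FALSE)
  }
  df$power_w <- 110 + 40 * (df$grade - min(df$grade))
  structure(df, class = c("trial_manifest", "data.frame"))
}

#' Run the full analysis pipeline
#'
#' Orchestrates read -> smooth -> segment -> summarize -> stability ->
#' longitudinal tests over a set of trials, either a [trial_manifest()] of
#' recording files or an in-memory [generate_cohort()] result. Trials that
#' fail segmentation are recorded in the failure table with their reason
#' and the pipeline continues; group-level stages require at least 2
#' participants per (stage, grade) cell and the test matrices require a
#' complete participant x stage x grade grid.
#'
#' @param x a `trial_manifest` or a `synthetic_cohort`.
#' @param f_cutoff smoothing cut-off frequency in Hz (default 2.23).
#' @param alpha significance level for the test matrices (default 0.05).
#' @param outdir optional directory; when given, every output table is
#'   written there as delimited text.
#' @param column_map passed to [read_gyro_export()] for file manifests.
#' @return a `pipeline_result`: list with `durations` (per-trial summary
#'   table), `group` (group-level summaries per stage x grade),
#'   `stability` (per-trial instability index table), `tests` (a
#'   `test_matrix`, or `NULL` if the grid is incomplete), `ensembles`
#'   (per-trial stroke tables), `profiles`, `failures` and `log`.
#' @export
run_pipeline <- function(x, f_cutoff = 2.23, alpha = 0.05, outdir = NULL,
                         column_map = c(time = "Time (s)",
                                        omega_x = "Gyroscope x (rad/s)")) {
  if (inherits(x, "synthetic_cohort")) {
    meta_df <- x$manifest
    loaders <- lapply(x$trials, function(tr) {
      force(tr); function() tr$series
    })
  } else if (inherits(x, "trial_manifest") || is.data.frame(x)) {
    x <- trial_manifest(x, check_files = FALSE)
    meta_df <- x[, c("participant", "stage", "grade")]
    paths <- x$path
    loaders <- lapply(seq_len(nrow(x)), function(i) {
      function() {
        s <- read_gyro_export(paths[i], column_map = column_map)
        s$meta <- c(list(participant = meta_df$participant[i],
                         stage = meta_df$stage[i],
                         grade = meta_df$grade[i]), s$meta)
        s
      }
    })
  } else stop("'x' must be a trial_manifest or a synthetic_cohort", call. = FALSE)

  n <- nrow(meta_df)
  dur_rows <- vector("list", n)
  stab_rows <- vector("list", n)
  ensembles <- vector("list", n)
  profiles <- vector("list", n)
  failures <- list()
  notes <- list()
  counts <- integer(n)
  shorts <- integer(n)

  for (i in seq_len(n)) {
    notes_i <- character(0)
    res <- tryCatch(withCallingHandlers({
      series <- loaders[[i]]()
      smooth <- lowpass_fourier(series, f_cutoff = f_cutoff)
      ens <- suppressMessages(segment_strokes(smooth))
      summ <- summarize_durations(ens)
      prof <- mean_profile(smooth, ens)
      stab <- stability_index(prof)
      list(ens = ens, summ = summ, prof = prof, stab = stab)
    }, warning = function(w) {
      notes_i <<- c(notes_i, conditionMessage(w))
      invokeRestart("muffleWarning")
    }), error = function(e) e)
    if (length(notes_i))
      notes[[length(notes) + 1L]] <- cbind(meta_df[i, , drop = FALSE],
                                           note = notes_i)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1L]] <- cbind(
        meta_df[i, , drop = FALSE], reason = conditionMessage(res))
      next
    }
    counts[i] <- nrow(res$ens)
    shorts[i] <- length(attr(res$ens, "short_strokes"))
    ensembles[[i]] <- res$ens
    profiles[[i]] <- res$prof
    dur_rows[[i]] <- cbind(meta_df[i, , drop = FALSE],
                           res$summ[, -1, drop = FALSE])  # drop 'scope'
    stab_rows[[i]] <- cbind(meta_df[i, , drop = FALSE],
                            data.frame(index_percent = res$stab$value,
                                       mean_period = res$stab$mean_period,
                                       n_strokes = res$prof$n_strokes))
  }

  durations <- do.call(rbind, dur_rows[!vapply(dur_rows, is.null, logical(1))])
  stability <- do.call(rbind, stab_rows[!vapply(stab_rows, is.null, logical(1))])
  n_failed <- length(failures)
  failures <- if (n_failed) do.call(rbind, failures) else NULL

  # group-level summaries per (stage, grade)
  group <- NULL
  if (!is.null(durations) && nrow(durations)) {
    cells <- unique(durations[, c("stage", "grade")])
    grp_rows <- list()
    for (j in seq_len(nrow(cells))) {
      sub <- durations[durations$stage == cells$stage[j] &
                         durations$grade == cells$grade[j], ]
      if (nrow(sub) < 2L) next
      per <- lapply(seq_len(nrow(sub)), function(r) {
        structure(data.frame(scope = "trial", n = sub$n[r],
                             full_mean = sub$full_mean[r], full_sd = sub$full_sd[r],
                             phase1_mean = sub$phase1_mean[r], phase1_sd = sub$phase1_sd[r],
                             phase2_mean = sub$phase2_mean[r], phase2_sd = sub$phase2_sd[r]),
                  meta = list(stage = cells$stage[j], grade = cells$grade[j]),
                  class = c("duration_summary", "data.frame"))
      })
      g <- group_summary(per)
      grp_rows[[length(grp_rows) + 1L]] <-
        cbind(data.frame(stage = cells$stage[j], grade = cells$grade[j]),
              g[, -1, drop = FALSE])
    }
    if (length(grp_rows)) group <- do.call(rbind, grp_rows)
  }

  tests <- NULL
  if (!is.null(durations)) {
    tests <- tryCatch(
      build_test_matrix(durations, alpha = alpha,
                        stages = unique(as.character(meta_df$stage))),
      error = function(e) NULL)
  }

  out <- structure(
    list(durations = durations, group = group, stability = stability,
         tests = tests, ensembles = ensembles, profiles = profiles,
         failures = failures,
         log = list(f_cutoff = f_cutoff, alpha = alpha,
                    stroke_counts = counts, short_strokes = shorts,
                    notes = if (length(notes)) do.call(rbind, notes) else NULL,
                    n_trials = n, n_failed = n_failed)),
    class = "pipeline_result"
  )

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(d, f) if (!is.null(d) && nrow(d))
      write_table(d, file.path(outdir, f))
    wt(durations, "durations.csv")
    wt(group, "group_summary.csv")
    wt(stability, "stability.csv")
    if (!is.null(tests)) {
      wt(rbind(cbind(test = "ranksum", tests$ranksum),
               cbind(test = "signed_rank", tests$signed_rank)),
         "test_pvalues.csv")
      wt(cbind(test = "ranksum", format_test_matrix(tests, "ranksum")),
         "test_matrix_ranksum.csv")
      wt(cbind(test = "signed_rank", format_test_matrix(tests, "signed_rank")),
         "test_matrix_signed_rank.csv")
    }
    if (!is.null(failures)) wt(failures, "failures.csv")
  }
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d trials (%d failed), cut-off %.2f Hz\n",
              x$log$n_trials, x$log$n_failed, x$log$f_cutoff))
  if (!is.null(x$group)) {
    cat("\nGroup duration summary (s):\n")
    print(x$group, row.names = FALSE, digits = 4)
  }
  if (!is.null(x$tests)) print(x$tests)
  invisible(x)
}
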