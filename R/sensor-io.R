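#' Read a delimited gyroscope export
#'
#' Reads a sensor-app text export (phyphox-style CSV and similar dialects)
#' holding a time column and at least one angular-velocity column, and
#' returns the x-axis channel as a uniformly sampled
#' [angular_velocity_series()]. The field delimiter (comma, semicolon or tab)
#' is auto-detected from the header row. Any columns other than the two
#' mapped ones are ignored.
#'
#' If the source timestamps deviate from uniformity by more than 10% of the
#' median step (dropped samples are common in real sensor streams), the
#' values are linearly interpolated onto a uniform grid of step
#' `resample_dt` (default: the median source step). Otherwise the samples
#' pass through unchanged and `dt` is the median step.
#'
#' @param path path to the delimited text file; must have a header row.
#' @param column_map named character vector mapping the roles `time` and
#'   `omega_x` to column names in the file.
#' @param resample_dt uniform grid step (s) used when resampling is
#'   triggered; `NULL` (default) uses the median source step.
#'
#' @return an [angular_velocity_series()] with `meta$source = path`.
#' @export
read_gyro_export <- function(path,
                             column_map = c(time = "Time (s)",
                                            omega_x = "Gyroscope x (rad/s)"),
                             resample_dt = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!all(c("time", "omega_x") %in% names(column_map)))
    stop("'column_map' must name both 'time' and 'omega_x' columns", call. = FALSE)

  header <- readLines(path, n = 1L)
  sep <- .detect_delimiter(header)
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          comment.char = "", quote = "\"")

  for (role in c("time", "omega_x")) {
    cn <- unname(column_map[[role]])
    if (!cn %in% names(df))
      stop(sprintf("format error: column '%s' (role '%s') not found in %s",
                   cn, role, path), call. = FALSE)
  }
  t <- as.numeric(df[[column_map[["time"]]]])
  v <- as.numeric(df[[column_map[["omega_x"]]]])
  if (length(t) < 2L)
    stop("data error: fewer than 2 rows in ", path, call. = FALSE)
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("data error: time not strictly increasing at row %d of %s",
                 bad[1] + 1L, path), call. = FALSE)
  if (!all(is.finite(t)) || !all(is.finite(v)))
    stop("data error: non-finite values in ", path, call. = FALSE)

  steps <- diff(t)
  med <- stats::median(steps)
  if (any(abs(steps - med) > 0.1 * med)) {
    dt <- if (is.null(resample_dt)) med else as.numeric(resample_dt)
    n_out <- round((t[length(t)] - t[1]) / dt) + 1L
    grid <- t[1] + (seq_len(n_out) - 1L) * dt
    v <- stats::approx(t, v, xout = grid, rule = 2)$y
    t0 <- t[1]
  } else {
    dt <- med
    t0 <- t[1]
  }
  angular_velocity_series(v, dt = dt, t0 = t0, meta = list(source = path))
}

# pick the candidate delimiter splitting the header into the most fields
.detect_delimiter <- function(header) {
  cands <- c(",", ";", "\t")
  counts <- vapply(cands, function(s)
    length(strsplit(header, s, fixed = TRUE)[[1]]), integer(1))
  if (max(counts) < 2L)
    stop("format error: could not detect a delimiter in the header row",
         call. = FALSE)
  cands[which.max(counts)]
}

#' Write a series as delimited text
#'
#' Writes a two-column (time, angular velocity) text file with a header,
#' round-trippable through [read_gyro_export()] to within formatting
#' precision (values printed with 10 significant digits).
#'
#' @param series an [angular_velocity_series()].
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @param column_names character vector of length 2: time and omega_x
#'   column headers.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path, sep = ",",
                         column_names = c("Time (s)", "Gyroscope x (rad/s)")) {
  stopifnot(inherits(series, "angular_velocity_series"))
  df <- data.frame(
    t = sprintf("%.10g", series_times(series)),
    v = sprintf("%.10g", series$values)
  )
  names(df) <- column_names
  write_table(df, path, sep = sep)
}

#' Write any pipeline table as delimited text
#'
#' @param artifact a data frame with at least one row.
#' @param path output file path.
#' @param sep field delimiter (default comma).
#' @return `path`, invisibly.
#' @export
write_table <- function(artifact, path, sep = ",") {
  artifact <- as.data.frame(artifact)
  if (nrow(artifact) == 0L)
    stop("refusing to write an empty artifact", call. = FALSE)
  tryCatch(
    utils::write.table(artifact, path, sep = sep, row.names = FALSE,
                       quote = TRUE),
    error = function(e) {
      stop("I/O error writing ", path, ": ", conditionMessage(e), call. = FALSE)
    })
  invisible(path)
}
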