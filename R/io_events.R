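#' Read a MEMS-style event log
#'
#' Reads a delimited text file of medication-container opening events. Each row
#' is one opening with a subject identifier and an ISO 8601 timestamp; openings
#' are treated downstream as a proxy for dose-taking.
#'
#' @param path Path to a delimited text file.
#' @param delim Field delimiter (default comma).
#' @param subject_col,timestamp_col Column names holding the subject identifier
#'   and the opening timestamp.
#' @return A tibble with columns `subject_id` (character) and `timestamp`
#'   (POSIXct, parsed at face value in UTC — no timezone conversion is applied,
#'   since calendar day within a single study region is what matters).
#'   Rows whose timestamp cannot be parsed raise an error that lists the
#'   offending lines; they are never silently dropped.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c(
#'   "subject_id,timestamp",
#'   "S01,2015-01-05 08:10:00",
#'   "S01,2015-01-05 20:55:00",
#'   "S02,2015-01-06 07:30:00"
#' ), f)
#' read_event_log(f)
#' @export
read_event_log <- function(path, delim = ",", subject_col = "subject_id",
                           timestamp_col = "timestamp") {
  assert_that(file.exists(path), paste0("event log not found: ", path))
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  missing_cols <- setdiff(c(subject_col, timestamp_col), names(raw))
  assert_that(length(missing_cols) == 0,
              paste0("event log ", path, " lacks column(s): ",
                     paste(missing_cols, collapse = ", ")))
  if (nrow(raw) == 0) {
    warning("event log ", path, " contains no events", call. = FALSE)
    return(tibble::tibble(subject_id = character(), timestamp = as.POSIXct(character(), tz = "UTC")))
  }
  subject <- as.character(raw[[subject_col]])
  assert_that(!anyNA(subject) && all(nzchar(subject)),
              "event log has empty subject identifiers")
  ts <- parse_timestamp(raw[[timestamp_col]])
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stop("unparseable timestamp(s) in ", path, " at data line(s) ",
         paste(utils::head(bad, 10), collapse = ", "),
         ": ", paste(utils::head(raw[[timestamp_col]][bad], 5), collapse = "; "),
         call. = FALSE)
  }
  tibble::tibble(subject_id = subject, timestamp = ts)
}

# ISO 8601 date-times, with or without a time part; face value, no tz shifts.
parse_timestamp <- function(x) {
  x <- trimws(x)
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  date_only <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[date_only] <- as.POSIXct(x[date_only], tz = "UTC", format = "%Y-%m-%d")
  no_sec <- is.na(out) & grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}$", x)
  out[no_sec] <- as.POSIXct(x[no_sec], tz = "UTC", format = "%Y-%m-%d %H:%M")
  out
}

#' Read a follow-up window file
#'
#' @param path CSV with columns `subject_id`, `start_date`, `end_date`
#'   (ISO dates). The window defines the observed calendar days per subject;
#'   typically it runs from first dispensation to 12 months of follow-up.
#' @param max_days Truncate each window to at most this many days from its
#'   start (default 365, mirroring a 12-month covariate-analysis window).
#'   Use `Inf` to keep windows as given.
#' @return A tibble `subject_id`, `start_date`, `end_date` (Date).
#' @export
read_window_file <- function(path, max_days = 365) {
  assert_that(file.exists(path), paste0("window file not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  missing_cols <- setdiff(c("subject_id", "start_date", "end_date"), names(raw))
  assert_that(length(missing_cols) == 0,
              paste0("window file lacks column(s): ", paste(missing_cols, collapse = ", ")))
  out <- tibble::tibble(
    subject_id = as.character(raw$subject_id),
    start_date = as.Date(raw$start_date),
    end_date = as.Date(raw$end_date)
  )
  assert_that(!anyNA(out$start_date) && !anyNA(out$end_date),
              "window file has unparseable dates")
  assert_that(all(out$start_date <= out$end_date),
              "window file has start_date after end_date")
  trunc_end <- out$start_date + (max_days - 1)
  out$end_date <- pmin(out$end_date, trunc_end)
  out
}

#' Reduce opening events to daily binary adherence states
#'
#' A day is coded 1 ("dose taken") when at least one container opening falls on
#' that calendar date inside the subject's follow-up window, 0 ("dose missed")
#' otherwise. Multiple openings in one day count as a single dose-taking event.
#' Days with no events — including whole gaps between device downloads — are
#' coded 0; subjects with broken or lost devices should be excluded upstream
#' via the window file rather than imputed.
#'
#' @param events Tibble of events as returned by [read_event_log()].
#' @param windows Tibble `subject_id`, `start_date`, `end_date` as returned by
#'   [read_window_file()]. Every subject listed here gets a series, even with
#'   no events (all-zero series).
#' @return A tibble with one row per subject-day: `subject_id`, `date`, `day`
#'   (1-based study day) and `state` (0/1). Events outside any window are
#'   dropped; their count is attached as attribute `n_outside` and reported
#'   with a message when positive.
#' @export
daily_states <- function(events, windows) {
  assert_that(all(c("subject_id", "timestamp") %in% names(events)),
              "events must have subject_id and timestamp columns")
  assert_that(all(c("subject_id", "start_date", "end_date") %in% names(windows)),
              "windows must have subject_id, start_date, end_date columns")
  assert_that(!anyDuplicated(windows$subject_id),
              "windows must list each subject once")
  assert_that(all(windows$start_date <= windows$end_date),
              "window start_date must not exceed end_date")

  grid <- windows |>
    dplyr::rowwise() |>
    dplyr::mutate(date = list(seq(.data$start_date, .data$end_date, by = "day"))) |>
    dplyr::ungroup() |>
    tidyr::unnest("date") |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::mutate(day = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::select("subject_id", "date", "day")

  ev <- events |>
    dplyr::mutate(date = as.Date(.data$timestamp)) |>
    dplyr::distinct(.data$subject_id, .data$date) |>
    dplyr::mutate(.hit = 1L)

  n_total <- nrow(ev)
  out <- grid |>
    dplyr::left_join(ev, by = c("subject_id", "date")) |>
    dplyr::mutate(state = ifelse(is.na(.data$.hit), 0L, 1L)) |>
    dplyr::select("subject_id", "date", "day", "state")

  n_inside <- sum(out$state)
  n_outside <- n_total - n_inside
  if (n_outside > 0) {
    message(n_outside, " event day(s) fell outside the follow-up windows and were ignored")
  }
  attr(out, "n_outside") <- n_outside
  out
}

#' Read a covariate table
#'
#' Two layouts are supported. Wide: one row per subject, `subject_id` plus one
#' numeric 0/1 indicator column per covariate (categorical covariates coded as
#' indicators against a declared reference level). Long (time-varying):
#' columns `subject_id`, `covariate`, `value`, `interval_start_day`,
#' `interval_end_day` with 1-based closed intervals in study days.
#'
#' @param path CSV file in either layout.
#' @return A tibble; long layout is detected by the presence of the
#'   `covariate`/`value`/interval columns.
#' @export
read_covariate_table <- function(path) {
  assert_that(file.exists(path), paste0("covariate table not found: ", path))
  raw <- readr::read_csv(path, col_types = readr::cols(subject_id = "c", .default = "?"),
                         progress = FALSE)
  assert_that("subject_id" %in% names(raw), "covariate table lacks subject_id column")
  long_cols <- c("covariate", "value", "interval_start_day", "interval_end_day")
  if (all(long_cols %in% names(raw))) {
    return(tibble::as_tibble(raw)[, c("subject_id", long_cols)])
  }
  tibble::as_tibble(raw)
}

#' Attach per-day covariate vectors to a daily state series
#'
#' Subject-constant covariates (wide table) are broadcast to every day of the
#' subject's series. Time-varying covariates (long interval table) must cover
#' every observed day exactly once per covariate; uncovered days or overlapping
#' intervals are errors naming the subject, day and covariate.
#'
#' @param states Per-day tibble from [daily_states()].
#' @param covariates Wide covariate tibble (`subject_id` + indicator columns),
#'   or `NULL`.
#' @param intervals Long time-varying tibble (`subject_id`, `covariate`,
#'   `value`, `interval_start_day`, `interval_end_day`), or `NULL`. A row with
#'   subject_id `".all"` applies to every subject (useful for covariates that
#'   are pure functions of study day, such as being beyond six months of
#'   follow-up).
#' @return `states` with one extra numeric column per covariate.
#' @export
resolve_covariates <- function(states, covariates = NULL, intervals = NULL) {
  out <- states
  if (!is.null(covariates)) {
    assert_that("subject_id" %in% names(covariates),
                "covariates must have a subject_id column")
    missing_subj <- setdiff(unique(states$subject_id), covariates$subject_id)
    assert_that(length(missing_subj) == 0,
                paste0("no covariate row for subject(s): ",
                       paste(utils::head(missing_subj, 5), collapse = ", ")))
    out <- dplyr::left_join(out, covariates, by = "subject_id")
  }
  if (!is.null(intervals) && nrow(intervals) > 0) {
    for (cv in unique(intervals$covariate)) {
      iv <- intervals[intervals$covariate == cv, ]
      out[[cv]] <- resolve_one_interval(out, iv, cv)
    }
  }
  out
}

resolve_one_interval <- function(states, iv, cv) {
  val <- rep(NA_real_, nrow(states))
  n_cover <- rep(0L, nrow(states))
  for (r in seq_len(nrow(iv))) {
    sel <- states$day >= iv$interval_start_day[r] & states$day <= iv$interval_end_day[r]
    if (iv$subject_id[r] != ".all") sel <- sel & states$subject_id == iv$subject_id[r]
    if (any(n_cover[sel] > 0)) {
      stop("overlapping intervals for covariate '", cv, "' (subject ",
           states$subject_id[which(sel & n_cover > 0)[1]], ")", call. = FALSE)
    }
    n_cover[sel] <- n_cover[sel] + 1L
    val[sel] <- as.numeric(iv$value[r])
  }
  if (anyNA(val)) {
    i <- which(is.na(val))[1]
    stop("day ", states$day[i], " of subject ", states$subject_id[i],
         " is not covered by any interval of covariate '", cv, "'", call. = FALSE)
  }
  val
}

#' Write and re-read a daily adherence series
#'
#' Round-trip helpers for the package's delimited per-day format
#' (`subject_id,date,day,state`).
#'
#' @param states Per-day tibble from [daily_states()].
#' @param path Output CSV path.
#' @return `write_states()` returns `path` invisibly; `read_states()` returns
#'   the per-day tibble.
#' @export
write_states <- function(states, path) {
  readr::write_csv(states[, c("subject_id", "date", "day", "state")], path)
  invisible(path)
}

#' @rdname write_states
#' @export
read_states <- function(path) {
  readr::read_csv(path, col_types = readr::cols(
    subject_id = "c", date = "D", day = "i", state = "i"
  ), progress = FALSE)
}
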