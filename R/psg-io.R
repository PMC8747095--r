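sleep_stages <- c("WAKE", "REM", "N1", "N2", "N3")

#' Epoch length of clinical sleep staging, in seconds
#' @export
epoch_length_sec <- 30

#' Construct a hypnogram
#'
#' A hypnogram is the ordered sequence of sleep-stage labels across a night,
#' one label per 30 s epoch. Epoch `i` (1-based) covers the half-open
#' interval `[30 * (i - 1), 30 * i)` seconds, anchored at recording time 0.
#'
#' @param stages Character vector over `WAKE, REM, N1, N2, N3`.
#' @return A tibble with columns `epoch` (1-based index), `stage` (factor)
#'   and `onset_sec` (epoch start time).
#' @export
#' @examples
#' hypnogram(c("WAKE", "N1", "N2", "REM"))
hypnogram <- function(stages) {
  stages <- toupper(as.character(stages))
  bad <- setdiff(unique(stages), sleep_stages)
  if (length(stages) == 0L) {
    abort("A hypnogram needs at least one epoch.",
          class = "hflf_error_empty_hypnogram")
  }
  if (length(bad) > 0L) {
    abort(paste0("Unknown sleep stage label(s): ",
                 paste(bad, collapse = ", "),
                 ". Expected WAKE, REM, N1, N2 or N3."),
          class = "hflf_error_unknown_stage")
  }
  tibble::tibble(
    epoch = seq_along(stages),
    stage = factor(stages, levels = sleep_stages),
    onset_sec = (seq_along(stages) - 1) * epoch_length_sec
  )
}

#' Read a hypnogram from CSV
#'
#' Expects a headered delimited file with a `stage` column holding one of
#' `WAKE, REM, N1, N2, N3` per row, one row per 30 s epoch in temporal order.
#'
#' @param path Path to the CSV file.
#' @return A hypnogram tibble (see [hypnogram()]).
#' @export
read_hypnogram <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Hypnogram file not found: ", path),
          class = "hflf_error_missing_file")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"stage" %in% names(df)) {
    abort("Hypnogram file must have a `stage` column.",
          class = "hflf_error_bad_hypnogram")
  }
  if (nrow(df) == 0L) {
    abort("Hypnogram file has no epochs.",
          class = "hflf_error_empty_hypnogram")
  }
  hypnogram(df$stage)
}

#' Write a hypnogram to CSV
#' @param hyp A hypnogram tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  readr::write_csv(tibble::tibble(stage = as.character(hyp$stage)), path,
                   progress = FALSE)
  invisible(path)
}

#' Construct a phasic-event table
#'
#' Visually scored phasic RSWA events: onset (seconds from recording start)
#' and duration of each transient EMG activation during REM sleep. Rows are
#' sorted by onset.
#'
#' @param onset_sec Numeric vector of onsets (seconds, non-negative).
#' @param duration_sec Numeric vector of durations (seconds, positive).
#' @param label Event label(s); recycled (default `"phasic"`).
#' @return A tibble with columns `event_id`, `onset_sec`, `duration_sec`,
#'   `label`, sorted by onset.
#' @export
event_table <- function(onset_sec = double(), duration_sec = double(),
                        label = "phasic") {
  if (length(onset_sec) != length(duration_sec)) {
    abort("`onset_sec` and `duration_sec` must have the same length.",
          class = "hflf_error_bad_events")
  }
  if (any(onset_sec < 0, na.rm = TRUE) || anyNA(onset_sec)) {
    abort("Event onsets must be non-negative and non-missing.",
          class = "hflf_error_bad_events")
  }
  if (any(duration_sec <= 0, na.rm = TRUE) || anyNA(duration_sec)) {
    abort("Event durations must be positive and non-missing.",
          class = "hflf_error_bad_events")
  }
  out <- tibble::tibble(
    onset_sec = as.double(onset_sec),
    duration_sec = as.double(duration_sec),
    label = if (length(onset_sec)) as.character(label) else character()
  )
  out <- dplyr::arrange(out, .data$onset_sec)
  dplyr::mutate(out, event_id = dplyr::row_number(), .before = 1L)
}

#' Read a phasic-event table from CSV
#'
#' Expects a headered CSV with columns `onset_sec`, `duration_sec` and
#' optionally `label`. An empty table (header only) is valid and represents
#' a recording with no scored events.
#'
#' @param path Path to the CSV file.
#' @return An event tibble (see [event_table()]).
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Events file not found: ", path),
          class = "hflf_error_missing_file")
  }
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("onset_sec", "duration_sec")
  if (!all(need %in% names(df))) {
    abort("Events file must have `onset_sec` and `duration_sec` columns.",
          class = "hflf_error_bad_events")
  }
  event_table(df$onset_sec, df$duration_sec,
              label = if ("label" %in% names(df) && nrow(df))
                df$label else "phasic")
}

#' Write a phasic-event table to CSV
#' @param events An event tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  readr::write_csv(events[, c("onset_sec", "duration_sec", "label")], path,
                   progress = FALSE)
  invisible(path)
}

#' Record-level eligibility screen
#'
#' Applies the study-entry exclusions used for RSWA quantification: a record
#' is eligible when it has at least 4 h of sleep (time in any non-WAKE
#' stage) and at least 10 epochs of REM sleep.
#'
#' @param hyp A hypnogram tibble.
#' @param min_sleep_hours Minimum total sleep time in hours (default 4).
#' @param min_rem_epochs Minimum number of REM epochs (default 10).
#' @return A one-row tibble: `eligible`, `total_sleep_hours`,
#'   `rem_epoch_count`, and `reasons` (list-column of failure reasons,
#'   empty when eligible).
#' @export
#' @examples
#' check_eligibility(hypnogram(rep("REM", 480)))
check_eligibility <- function(hyp, min_sleep_hours = 4,
                              min_rem_epochs = 10) {
  sleep_epochs <- sum(hyp$stage != "WAKE")
  tst_hours <- sleep_epochs * epoch_length_sec / 3600
  rem_count <- sum(hyp$stage == "REM")
  reasons <- character()
  if (tst_hours < min_sleep_hours) {
    reasons <- c(reasons, sprintf(
      "total sleep time %.2f h below the %g h minimum",
      tst_hours, min_sleep_hours))
  }
  if (rem_count < min_rem_epochs) {
    reasons <- c(reasons, sprintf(
      "%d REM epochs below the %d-epoch minimum", rem_count,
      min_rem_epochs))
  }
  tibble::tibble(
    eligible = length(reasons) == 0L,
    total_sleep_hours = tst_hours,
    rem_epoch_count = rem_count,
    reasons = list(reasons)
  )
}
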