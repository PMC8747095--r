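# Epoch-based and window-based grouping of the per-second HF:LF ratio
# against visually scored phasic events.
#
# Epoch groups (REM epochs only): E1 = no scored event, E2 = exactly one,
# E3 = two or more; the epoch value is the sum of its per-second ratios.
# Window groups: W2 = one sample per event, the mean ratio over the event's
# window (1 s before the event through 1 s after it); W1 = every valid REM
# second not inside any event's window.

epoch_of_second <- function(second) as.integer(floor(second / epoch_length_sec)) + 1L

#' Seconds covered by an event's analysis window
#'
#' An event with onset `o` and duration `d` claims the integer seconds
#' `floor(o) - 1` through `ceiling(o + d)`: the second before onset, every
#' second the event touches, and the second after offset. For a typical
#' ~1 s phasic event this is the 3 s window around it.
#'
#' @param onset_sec,duration_sec Event onset and duration (seconds).
#' @param max_second Largest valid second index; windows extending past it
#'   (or below 0) are truncated.
#' @return Integer vector of seconds.
#' @export
event_window_seconds <- function(onset_sec, duration_sec, max_second = Inf) {
  lo <- floor(onset_sec) - 1
  hi <- ceiling(onset_sec + duration_sec)
  seq.int(max(0, lo), min(max_second, hi))
}

#' Count phasic events per REM epoch and assign epoch groups
#'
#' Each event is assigned to the 30 s epoch containing its onset. Only REM
#' epochs are grouped; events whose onset falls in a non-REM epoch, or past
#' the end of the hypnogram, are excluded with a warning.
#'
#' @param hyp A hypnogram tibble ([hypnogram()]).
#' @param events An event tibble ([event_table()]).
#' @return A tibble with one row per REM epoch: `epoch`, `event_count`,
#'   and `group` (factor `E1`/`E2`/`E3` for 0 / 1 / >= 2 events).
#' @export
count_events_per_epoch <- function(hyp, events) {
  ev_epoch <- epoch_of_second(events$onset_sec)
  beyond <- ev_epoch > nrow(hyp)
  if (any(beyond)) {
    warn(sprintf("%d event(s) start after the hypnogram ends; dropped.",
                 sum(beyond)))
  }
  in_range <- events[!beyond, , drop = FALSE]
  ev_epoch <- ev_epoch[!beyond]
  non_rem <- hyp$stage[ev_epoch] != "REM"
  if (any(non_rem)) {
    warn(sprintf(
      "%d event(s) have onsets in non-REM epochs; excluded from grouping.",
      sum(non_rem)))
  }
  rem <- dplyr::filter(hyp, .data$stage == "REM")
  counts <- table(factor(ev_epoch[!non_rem], levels = rem$epoch))
  tibble::tibble(
    epoch = rem$epoch,
    event_count = as.integer(counts),
    group = epoch_group(as.integer(counts))
  )
}

epoch_group <- function(event_count) {
  factor(dplyr::case_when(event_count == 0L ~ "E1",
                          event_count == 1L ~ "E2",
                          TRUE ~ "E3"),
         levels = c("E1", "E2", "E3"))
}

#' Per-REM-epoch HF:LF summaries (epoch-based analysis)
#'
#' For every REM epoch, aggregates the non-degenerate per-second HF:LF
#' values over the epoch's 30 s interval (by default their sum) and attaches
#' the phasic-event count and E1/E2/E3 group label.
#'
#' @param hflf_tbl Per-second ratio tibble from [compute_hflf()].
#' @param hyp A hypnogram tibble.
#' @param events An event tibble.
#' @param aggregate `"sum"` (default) or `"mean"` of the epoch's valid
#'   per-second values.
#' @return A tibble with one row per REM epoch: `epoch`, `event_count`,
#'   `group`, `epoch_hflf` and `n_valid_seconds`.
#' @export
summarize_epochs <- function(hflf_tbl, hyp, events,
                             aggregate = c("sum", "mean")) {
  aggregate <- match.arg(aggregate)
  counts <- count_events_per_epoch(hyp, events)
  agg_fun <- if (aggregate == "sum") sum else mean
  per_epoch <- hflf_tbl |>
    dplyr::mutate(epoch = epoch_of_second(.data$second)) |>
    dplyr::filter(.data$epoch %in% counts$epoch, !is.na(.data$hflf)) |>
    dplyr::group_by(.data$epoch) |>
    dplyr::summarise(epoch_hflf = agg_fun(.data$hflf),
                     n_valid_seconds = dplyr::n(), .groups = "drop")
  counts |>
    dplyr::left_join(per_epoch, by = "epoch") |>
    dplyr::mutate(
      n_valid_seconds = dplyr::coalesce(.data$n_valid_seconds, 0L),
      epoch_hflf = dplyr::if_else(.data$n_valid_seconds > 0L,
                                  .data$epoch_hflf, NA_real_)
    )
}

#' Window samples for the second-based analysis (W1/W2)
#'
#' Produces the two second-level sample groups: `W2`, one sample per
#' REM-epoch event holding the mean per-second HF:LF over the event's
#' window (see [event_window_seconds()]); and `W1`, one sample per valid
#' REM second that lies inside no event window. Windows of all scored
#' events (including any outside REM) are excluded from W1, so a second
#' with scored activity never counts as activity-free baseline.
#'
#' @inheritParams summarize_epochs
#' @return A tibble with columns `kind` (factor `W1`/`W2`), `value`, and
#'   `source` (the second index for W1, the event id for W2).
#' @export
collect_window_samples <- function(hflf_tbl, hyp, events) {
  max_second <- max(hflf_tbl$second)
  ratio <- setNames(hflf_tbl$hflf, hflf_tbl$second)

  windows <- purrr::map2(events$onset_sec, events$duration_sec,
                         function(o, d) {
    secs <- event_window_seconds(o, d)
    if (max(secs) > max_second) {
      warn(sprintf(
        "Event window at %.1f s extends past the recording; truncated.", o))
      secs <- secs[secs <= max_second]
    }
    secs
  })

  ev_epoch <- epoch_of_second(events$onset_sec)
  is_rem_event <- ev_epoch <= nrow(hyp) & hyp$stage[pmin(ev_epoch, nrow(hyp))] == "REM"
  w2 <- tibble::tibble(
    kind = factor("W2", levels = c("W1", "W2")),
    value = vapply(windows, function(secs) {
      v <- ratio[as.character(secs)]
      if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, double(1)),
    source = events$event_id
  )[is_rem_event, , drop = FALSE]
  w2 <- dplyr::filter(w2, !is.na(.data$value))

  rem_epochs <- hyp$epoch[hyp$stage == "REM"]
  rem_secs <- hflf_tbl$second[
    epoch_of_second(hflf_tbl$second) %in% rem_epochs &
      !is.na(hflf_tbl$hflf)]
  excluded <- unique(unlist(windows, use.names = FALSE))
  w1_secs <- setdiff(rem_secs, excluded)
  w1 <- tibble::tibble(
    kind = factor("W1", levels = c("W1", "W2")),
    value = as.numeric(ratio[as.character(w1_secs)]),
    source = as.integer(w1_secs)
  )
  dplyr::bind_rows(w1, w2)
}

#' Descriptive statistics for a sample group
#'
#' @param x Numeric vector (NAs dropped); must leave at least one value.
#' @return A one-row tibble: `n`, `mean`, `sd`, `median`, `p5`, `p25`,
#'   `p75`, `p95`, and `sd_defined` (FALSE when n = 1, where the sample SD
#'   is undefined and reported as 0). Percentiles use linear interpolation
#'   between order statistics.
#' @export
group_statistics <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) {
    abort("Cannot summarise an empty sample.",
          class = "hflf_error_empty_sample")
  }
  q <- quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), type = 7, names = FALSE)
  tibble::tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1L) sd(x) else 0,
    median = q[3], p5 = q[1], p25 = q[2], p75 = q[4], p95 = q[5],
    sd_defined = length(x) > 1L
  )
}

#' Descriptive statistics by group
#'
#' Tidy wrapper applying [group_statistics()] within groups of a data
#' frame, e.g. the E1/E2/E3 epoch groups or the W1/W2 window groups.
#'
#' @param data A data frame.
#' @param value Column holding the sample values (tidy-eval).
#' @param group Grouping column (tidy-eval).
#' @return A tibble with one row per group level present in the data.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b"), each = 5), v = 1:10)
#' summarize_groups(df, v, g)
summarize_groups <- function(data, value, group) {
  data |>
    dplyr::filter(!is.na({{ value }})) |>
    dplyr::group_by({{ group }}) |>
    dplyr::reframe(group_statistics({{ value }}))
}

#' Locate the crossover of two spectral curves
#'
#' Scans two per-frequency curves on a shared grid and returns the first
#' adjacent bin pair within the search range where their order changes
#' (the sign of `curve_a - curve_b` differs between the two bins). Applied
#' to the median relative spectra of activity-free REM seconds and of
#' phasic-event windows, the crossover interval is the empirical basis for
#' placing the HF/LF band boundary near 20 Hz.
#'
#' @param curve_a,curve_b Tibbles with columns `frequency` and `power` on
#'   the same grid (e.g. from [median_spectrum()]).
#' @param search_lo,search_hi Frequency range to scan (defaults: the whole
#'   shared grid).
#' @return A one-row tibble: `found` (logical), `lower_hz`, `upper_hz`
#'   (the bracketing grid frequencies; `NA` when no crossover is found).
#' @export
find_crossover <- function(curve_a, curve_b, search_lo = -Inf,
                           search_hi = Inf) {
  joined <- dplyr::inner_join(curve_a, curve_b, by = "frequency",
                              suffix = c("_a", "_b")) |>
    dplyr::arrange(.data$frequency) |>
    dplyr::filter(.data$frequency >= search_lo,
                  .data$frequency <= search_hi)
  if (nrow(joined) < 2L) {
    abort("Search range must contain at least two shared grid frequencies.",
          class = "hflf_error_bad_search_range")
  }
  s <- sign(joined$power_a - joined$power_b)
  k <- which(s[-length(s)] != s[-1] &
               !(s[-length(s)] == 0 & s[-1] == 0))
  if (length(k) == 0L) {
    return(tibble::tibble(found = FALSE, lower_hz = NA_real_,
                          upper_hz = NA_real_))
  }
  tibble::tibble(found = TRUE,
                 lower_hz = joined$frequency[k[1]],
                 upper_hz = joined$frequency[k[1] + 1L])
}
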