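# End-to-end pipeline: read inputs, screen eligibility, compute per-second
# spectra and HF:LF, group against scored events, run the inferential
# statistics, and serialize CSV outputs plus a structured JSON report.

#' Analyse one polysomnography recording end to end
#'
#' Reads the EMG channel, hypnogram and (optional) event table, screens
#' eligibility (a failure is flagged and warned, not fatal), computes the
#' per-second HF:LF series, the epoch-based (E1/E2/E3) and window-based
#' (W1/W2) analyses, the median relative-spectrum crossover, and the
#' associated statistics, and writes four outputs into `out_dir`:
#' `hflf.csv` (per-second ratio), `epochs.csv`, `windows.csv`, and
#' `report.json`.
#'
#' @param edf Path to the EDF file.
#' @param channel EMG channel label in the EDF.
#' @param hypnogram_path Path to the hypnogram CSV.
#' @param events_path Path to the events CSV, or `NULL` for a recording
#'   with no scored events.
#' @param out_dir Output directory (created if missing).
#' @param band An [hflf_band()].
#' @param epoch_aggregate `"sum"` (default) or `"mean"` per-epoch
#'   aggregation.
#' @return The report as a list (invisibly), with attribute `paths` naming
#'   the written files.
#' @export
run_hflf <- function(edf, channel, hypnogram_path, events_path = NULL,
                     out_dir, band = hflf_band(),
                     epoch_aggregate = c("sum", "mean")) {
  epoch_aggregate <- match.arg(epoch_aggregate)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rec <- read_emg_edf(edf, channel)
  hyp <- read_hypnogram(hypnogram_path)
  events <- if (is.null(events_path)) {
    warn("No events file supplied; analysing with an empty event table.")
    event_table()
  } else {
    read_events(events_path)
  }

  elig <- check_eligibility(hyp)
  if (!elig$eligible) {
    warn(paste0("Recording fails eligibility screen: ",
                paste(elig$reasons[[1]], collapse = "; "),
                ". Analyses are still emitted."))
  }

  res <- analyse_recording(rec, hyp, events, band = band,
                           epoch_aggregate = epoch_aggregate)

  paths <- c(
    hflf = file.path(out_dir, "hflf.csv"),
    epochs = file.path(out_dir, "epochs.csv"),
    windows = file.path(out_dir, "windows.csv"),
    report = file.path(out_dir, "report.json")
  )
  write_hflf_series(res$hflf, paths[["hflf"]])
  readr::write_csv(res$epochs, paths[["epochs"]], progress = FALSE)
  readr::write_csv(res$windows, paths[["windows"]], progress = FALSE)

  report <- c(
    list(
      eligibility = as.list(dplyr::mutate(
        elig, reasons = paste(reasons[[1]], collapse = "; "))),
      provenance = list(
        edf = unname(tools::md5sum(edf)),
        hypnogram = unname(tools::md5sum(hypnogram_path)),
        events = if (is.null(events_path)) NA else
          unname(tools::md5sum(events_path)),
        channel = channel,
        band = unclass(band),
        epoch_aggregate = epoch_aggregate
      )
    ),
    res$report
  )
  jsonlite::write_json(report, paths[["report"]], auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE, na = "null")
  out <- structure(report, paths = paths)
  invisible(out)
}

# Core in-memory analysis shared by run_hflf(), run_batch() and the
# validation experiments: everything downstream of I/O.
#' Analyse an in-memory recording
#'
#' The computational core of [run_hflf()], operating on in-memory objects:
#' per-second spectra, HF:LF, epoch and window grouping, group statistics,
#' crossover, ANOVA/Tukey across E1/E2/E3 and Welch-t / variance-F for
#' W1/W2 (each statistic computed only where its sample-size preconditions
#' hold).
#'
#' @param rec An [emg_recording()].
#' @param hyp A hypnogram tibble.
#' @param events An event tibble.
#' @inheritParams run_hflf
#' @return A list with tibbles `hflf`, `epochs`, `windows`, `rel_psd`
#'   (median spectra inputs are recomputed lazily), and `report` (list).
#' @export
analyse_recording <- function(rec, hyp, events, band = hflf_band(),
                              epoch_aggregate = "sum") {
  psd <- psd_welch(rec)
  hflf_tbl <- compute_hflf(psd, band)
  epochs <- summarize_epochs(hflf_tbl, hyp, events,
                             aggregate = epoch_aggregate)
  windows <- collect_window_samples(hflf_tbl, hyp, events)

  epoch_stats <- summarize_groups(epochs, epoch_hflf, group)
  window_stats <- summarize_groups(windows, value, kind)

  anova_res <- NULL
  sizes <- table(epochs$group[!is.na(epochs$epoch_hflf)])
  if (sum(sizes >= 2L) >= 2L) {
    anova_res <- anova_tukey(
      dplyr::filter(epochs, .data$group %in% names(sizes)[sizes >= 2L]),
      epoch_hflf, group)
  }
  two_res <- NULL
  if (sum(windows$kind == "W1") >= 2L && sum(windows$kind == "W2") >= 2L) {
    two_res <- two_sample_tests(windows, value, kind,
                                numerator = "W2")
  }

  crossover <- tibble::tibble(found = FALSE, lower_hz = NA_real_,
                              upper_hz = NA_real_)
  if (any(windows$kind == "W2")) {
    rel <- psd_relative(psd)
    w1_secs <- windows$source[windows$kind == "W1"]
    w2_secs <- unique(unlist(purrr::map2(
      events$onset_sec, events$duration_sec, event_window_seconds,
      max_second = max(hflf_tbl$second)), use.names = FALSE))
    if (length(w1_secs) && length(w2_secs)) {
      crossover <- find_crossover(median_spectrum(rel, w1_secs),
                                  median_spectrum(rel, w2_secs))
    }
  }

  list(
    hflf = hflf_tbl, epochs = epochs, windows = windows,
    report = list(
      n_rem_epochs = nrow(epochs),
      n_degenerate_seconds = sum(hflf_tbl$degenerate),
      epoch_groups = epoch_stats,
      window_groups = window_stats,
      anova_tukey = if (!is.null(anova_res))
        c(as.list(glance(anova_res)), list(pairwise = tidy(anova_res))),
      two_sample = if (!is.null(two_res)) as.list(glance(two_res)),
      crossover = as.list(crossover)
    )
  )
}

#' Run the pipeline over a batch manifest, optionally stratified
#'
#' Processes every recording listed in a manifest (one row per recording
#' with columns `edf`, `channel`, `hypnogram`, `events`, plus any logical
#' metadata flags). Recordings failing the eligibility screen are excluded
#' from the pooled analyses (the study-entry rule), with their status
#' recorded. When `stratify` names a flag column, the pooled epoch and
#' window analyses are repeated within each stratum and a comparison block
#' reports the per-stratum E1/E2/E3 and W1/W2 counts; counts across strata
#' sum to the unstratified counts.
#'
#' @param manifest A data frame or path to a manifest CSV.
#' @param out_dir Output directory.
#' @param stratify Optional name of a logical metadata column.
#' @param band An [hflf_band()].
#' @param epoch_aggregate Per-epoch aggregation rule.
#' @param apply_eligibility Apply the record-level exclusions before pooling
#'   (default TRUE); set FALSE to pool every recording regardless, e.g. for
#'   short exploratory runs.
#' @return The batch report list (invisibly); written to
#'   `<out_dir>/batch_report.json` along with pooled `epochs.csv` and
#'   `windows.csv`.
#' @export
run_batch <- function(manifest, out_dir, stratify = NULL,
                      band = hflf_band(), epoch_aggregate = "sum",
                      apply_eligibility = TRUE) {
  if (is.character(manifest)) {
    manifest <- readr::read_csv(manifest, show_col_types = FALSE,
                                progress = FALSE)
  }
  need <- c("edf", "channel", "hypnogram", "events")
  if (!all(need %in% names(manifest))) {
    abort("Manifest needs columns edf, channel, hypnogram, events.",
          class = "hflf_error_bad_manifest")
  }
  if (!is.null(stratify) && !stratify %in% names(manifest)) {
    abort(paste0("Unknown stratification flag: ", stratify),
          class = "hflf_error_unknown_flag")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  per_rec <- purrr::map(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    rec <- read_emg_edf(row$edf, row$channel)
    hyp <- read_hypnogram(row$hypnogram)
    events <- if (is.na(row$events) || !nzchar(row$events)) event_table()
      else read_events(row$events)
    elig <- check_eligibility(hyp)
    res <- analyse_recording(rec, hyp, events, band = band,
                             epoch_aggregate = epoch_aggregate)
    list(id = i, eligible = elig$eligible, elig = elig,
         epochs = dplyr::mutate(res$epochs, recording = i),
         windows = dplyr::mutate(res$windows, recording = i))
  })

  eligible <- vapply(per_rec, `[[`, logical(1), "eligible")
  included <- if (apply_eligibility) eligible else rep(TRUE, length(per_rec))
  if (apply_eligibility && !all(eligible)) {
    warn(sprintf("%d recording(s) failed eligibility; excluded from pooling.",
                 sum(!eligible)))
  }
  pooled_epochs <- dplyr::bind_rows(
    purrr::map(per_rec[included], "epochs"))
  pooled_windows <- dplyr::bind_rows(
    purrr::map(per_rec[included], "windows"))

  pool_block <- function(ep, wi) {
    if (nrow(ep) == 0L && nrow(wi) == 0L) {
      return(list(n_recordings = 0L, note = "no pooled data"))
    }
    list(
      n_recordings = length(unique(c(ep$recording, wi$recording))),
      epoch_group_counts = as.list(table(ep$group)),
      window_group_counts = as.list(table(wi$kind)),
      epoch_groups = summarize_groups(ep, epoch_hflf, group),
      window_groups = summarize_groups(wi, value, kind)
    )
  }
  report <- list(
    eligibility = tibble::tibble(
      recording = vapply(per_rec, `[[`, integer(1), "id"),
      eligible = eligible),
    pooled = pool_block(pooled_epochs, pooled_windows)
  )
  if (!is.null(stratify)) {
    flag <- as.logical(manifest[[stratify]])
    strata <- list(`TRUE` = which(flag), `FALSE` = which(!flag))
    report$strata <- purrr::imap(strata, function(ids, nm) {
      ids <- intersect(ids, which(included))
      if (length(ids) == 0L) {
        return(list(n_recordings = 0L, note = "empty stratum"))
      }
      pool_block(
        dplyr::filter(pooled_epochs, .data$recording %in% ids),
        dplyr::filter(pooled_windows, .data$recording %in% ids))
    })
    report$stratified_by <- stratify
  }

  readr::write_csv(pooled_epochs, file.path(out_dir, "epochs.csv"),
                   progress = FALSE)
  readr::write_csv(pooled_windows, file.path(out_dir, "windows.csv"),
                   progress = FALSE)
  jsonlite::write_json(report, file.path(out_dir, "batch_report.json"),
                       auto_unbox = TRUE, digits = I(17), pretty = TRUE,
                       na = "null")
  invisible(report)
}
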