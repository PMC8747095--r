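#' Define the high- and low-frequency bands
#'
#' The HF:LF ratio divides summed spectral power in a high band by summed
#' power in a low band. The defaults are LF 2-20 Hz and HF 20-55 Hz. As the
#' two sums are written, the 20 Hz bin would belong to both bands; the
#' `boundary_rule` resolves the shared edge:
#'
#' * `"lf_half_open"` (default): LF bins are `[lf_lo, lf_hi)`, HF bins are
#'   `[hf_lo, hf_hi]`, so 20.0 Hz counts as HF only. On the 0.5 Hz grid the
#'   default bands then hold 36 and 71 bins. This matches the empirical
#'   observation that the relative-spectrum crossover between quiet REM and
#'   phasic-event windows sits just above 20 Hz.
#' * `"hf_half_open"`: LF bins are `[lf_lo, lf_hi]`, HF bins are
#'   `(hf_lo, hf_hi]`, assigning the shared edge to LF instead.
#'
#' @param lf_lo,lf_hi Low-band edges in Hz (defaults 2 and 20).
#' @param hf_lo,hf_hi High-band edges in Hz (defaults 20 and 55).
#' @param boundary_rule `"lf_half_open"` or `"hf_half_open"`.
#' @return An object of class `hflf_band`.
#' @export
#' @examples
#' hflf_band()
hflf_band <- function(lf_lo = 2, lf_hi = 20, hf_lo = 20, hf_hi = 55,
                      boundary_rule = c("lf_half_open", "hf_half_open")) {
  boundary_rule <- match.arg(boundary_rule)
  if (!(lf_lo < lf_hi && lf_hi <= hf_lo && hf_lo < hf_hi)) {
    abort("Band edges must satisfy lf_lo < lf_hi <= hf_lo < hf_hi.",
          class = "hflf_error_bad_band")
  }
  structure(
    list(lf_lo = lf_lo, lf_hi = lf_hi, hf_lo = hf_lo, hf_hi = hf_hi,
         boundary_rule = boundary_rule),
    class = "hflf_band"
  )
}

#' @export
print.hflf_band <- function(x, ...) {
  lf_br <- if (x$boundary_rule == "lf_half_open") ")" else "]"
  hf_br <- if (x$boundary_rule == "lf_half_open") "[" else "("
  cat(sprintf("<hflf_band> LF [%g, %g%s Hz : HF %s%g, %g] Hz\n",
              x$lf_lo, x$lf_hi, lf_br, hf_br, x$hf_lo, x$hf_hi))
  invisible(x)
}

band_membership <- function(frequency, band) {
  eps <- 1e-9
  if (band$boundary_rule == "lf_half_open") {
    lf <- frequency >= band$lf_lo - eps & frequency < band$lf_hi - eps
    hf <- frequency >= band$hf_lo - eps & frequency <= band$hf_hi + eps
  } else {
    lf <- frequency >= band$lf_lo - eps & frequency <= band$lf_hi + eps
    hf <- frequency > band$hf_lo + eps & frequency <= band$hf_hi + eps
  }
  dplyr::case_when(lf ~ "lf", hf ~ "hf", TRUE ~ NA_character_)
}

#' Per-second HF:LF spectral power ratio
#'
#' For every second `t` of a spectral series, computes
#' `HF:LF(t) = sum of power in the high band / sum of power in the low
#' band`. Because the ratio divides two sums over the same second, it is
#' invariant to the per-second normalization: absolute and relative input
#' give identical values. Seconds whose low-band power is zero are marked
#' degenerate and carry `NA` rather than a number; they are excluded from
#' all downstream group statistics.
#'
#' @param psd A long-format spectral tibble from [psd_welch()] or
#'   [psd_relative()].
#' @param band An [hflf_band()] (defaults to LF 2-20 / HF 20-55 Hz with the
#'   20 Hz bin assigned to HF).
#' @return A tibble with columns `second`, `hflf` (`NA` when degenerate)
#'   and `degenerate` (logical), one row per second of the input.
#' @export
#' @examples
#' rec <- emg_recording(rnorm(2000), 200)
#' psd_welch(rec) |> compute_hflf()
compute_hflf <- function(psd, band = hflf_band()) {
  fmax <- max(psd$frequency)
  fmin <- min(psd$frequency)
  if (band$hf_hi > fmax + 1e-9 || band$lf_lo < fmin - 1e-9) {
    abort(sprintf(
      "Band [%g, %g] Hz lies outside the spectral grid [%g, %g] Hz.",
      band$lf_lo, band$hf_hi, fmin, fmax),
      class = "hflf_error_band_outside_grid")
  }
  out <- psd |>
    dplyr::mutate(.band = band_membership(.data$frequency, band)) |>
    dplyr::filter(!is.na(.data$.band)) |>
    dplyr::group_by(.data$second) |>
    dplyr::summarise(
      .lf = sum(.data$power[.data$.band == "lf"]),
      .hf = sum(.data$power[.data$.band == "hf"]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      degenerate = .data$.lf <= 0,
      hflf = dplyr::if_else(.data$degenerate, NA_real_,
                            .data$.hf / .data$.lf)
    ) |>
    dplyr::select("second", "hflf", "degenerate")
  attr(out, "band") <- band
  out
}

#' Number of frequency bins in each band
#'
#' @param band An [hflf_band()].
#' @param frequencies Frequency grid (default the 0-55 Hz grid in 0.5 Hz
#'   steps).
#' @return A named list with integer elements `lf` and `hf`.
#' @export
band_bin_counts <- function(band = hflf_band(),
                            frequencies = seq(0, 55, by = 0.5)) {
  m <- band_membership(frequencies, band)
  list(lf = sum(m == "lf", na.rm = TRUE), hf = sum(m == "hf", na.rm = TRUE))
}

#' Write an HF:LF series with a band-definition sidecar
#'
#' Exports the per-second ratio as CSV (`second, hflf, degenerate_flag`)
#' and the band definition that produced it as an adjacent `.json` sidecar
#' for provenance.
#'
#' @param hflf_tbl Output of [compute_hflf()].
#' @param path CSV output path; the sidecar is `<path>.band.json`.
#' @return A character vector of the two paths, invisibly.
#' @export
write_hflf_series <- function(hflf_tbl, path) {
  readr::write_csv(
    dplyr::transmute(hflf_tbl, .data$second, .data$hflf,
                     degenerate_flag = .data$degenerate),
    path, progress = FALSE)
  band <- attr(hflf_tbl, "band") %||% hflf_band()
  sidecar <- paste0(path, ".band.json")
  jsonlite::write_json(unclass(band), sidecar, auto_unbox = TRUE)
  invisible(c(path, sidecar))
}
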