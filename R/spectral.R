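# Per-second spectral decomposition of the EMG.
#
# Each integer second t gets one power spectral density estimate from the
# 2 s window [t, t + 2): the window is mean-detrended, Hann-tapered, and
# transformed in one segment, which is Welch's method with the averaging
# segment equal to the full window (a modified periodogram). A 2 s window
# fixes the frequency resolution at 0.5 Hz; consecutive windows overlap by
# 1 s, so a recording of duration D seconds yields floor(D) - 1 spectra.

hann_window <- function(n) {
  0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
}

#' Per-second Welch power spectral density series
#'
#' Computes one PSD per integer second of the recording from 2 s sliding
#' windows overlapped by 1 s, on a 0.5 Hz frequency grid truncated at
#' `max_freq` (111 bins for the default 0-55 Hz). Each window is
#' mean-detrended and Hann-tapered; the density scaling is
#' Parseval-consistent, i.e. `sum(power) * 0.5 Hz` over the full 0-Nyquist
#' grid equals the tapered window's mean-square amplitude.
#'
#' @param recording An [emg_recording()]; sampling rate must be at least
#'   `2 * max_freq` and duration at least 2 s.
#' @param max_freq Highest retained frequency in Hz (default 55; use
#'   `recording$sampling_rate / 2` to keep the full grid).
#' @return A tibble in long format with columns `second` (window start time,
#'   0-based), `frequency` (Hz) and `power` (uV^2/Hz), carrying attribute
#'   `mode = "absolute"`. Seconds run from 0 to `floor(duration) - 2`.
#' @export
#' @examples
#' rec <- emg_recording(rnorm(2000), 200)
#' psd <- psd_welch(rec)
#' dplyr::n_distinct(psd$second) # floor(10) - 1 = 9 spectra
psd_welch <- function(recording, max_freq = 55) {
  stopifnot(inherits(recording, "emg_recording"))
  fs <- recording$sampling_rate
  if (abs(fs - round(fs)) > 1e-9) {
    abort("Sampling rate must be an integer number of Hz.",
          class = "hflf_error_bad_sampling_rate")
  }
  fs <- as.integer(round(fs))
  if (fs < 2 * max_freq) {
    abort(sprintf(
      "Sampling rate %d Hz is too low for a %g Hz band (need >= %g Hz).",
      fs, max_freq, 2 * max_freq), class = "hflf_error_bad_sampling_rate")
  }
  dur <- emg_duration(recording)
  if (dur < 2) {
    abort("Recording must be at least 2 s long.",
          class = "hflf_error_recording_too_short")
  }
  win_len <- 2L * fs
  n_sec <- as.integer(floor(dur)) - 1L
  w <- hann_window(win_len)
  wnorm <- fs * sum(w^2)
  nf <- win_len %/% 2L + 1L
  freqs <- (seq_len(nf) - 1) * fs / win_len  # 0.5 Hz steps
  keep <- which(freqs <= max_freq + 1e-9)

  pow <- matrix(0, nrow = length(keep), ncol = n_sec)
  chunk <- 4096L
  for (lo in seq(1L, n_sec, by = chunk)) {
    hi <- min(lo + chunk - 1L, n_sec)
    starts <- (lo:hi) - 1L
    idx <- outer(seq_len(win_len), starts * fs, `+`)
    xm <- matrix(recording$samples[idx], nrow = win_len)
    xm <- sweep(xm, 2L, colMeans(xm))
    ft <- mvfft(xm * w)
    p <- Mod(ft[seq_len(nf), , drop = FALSE])^2 / wnorm
    # one-sided density: double all bins except DC and (even-length) Nyquist
    dbl <- setdiff(seq_len(nf), c(1L, if (win_len %% 2L == 0L) nf))
    p[dbl, ] <- 2 * p[dbl, ]
    pow[, lo:hi] <- p[keep, , drop = FALSE]
  }

  out <- tibble::tibble(
    second = rep(0:(n_sec - 1L), each = length(keep)),
    frequency = rep(freqs[keep], times = n_sec),
    power = as.vector(pow)
  )
  attr(out, "mode") <- "absolute"
  attr(out, "sampling_rate") <- fs
  out
}

#' Convert an absolute spectral series to relative spectra
#'
#' Divides each second's spectrum by that second's total power over the
#' retained frequency bins, so every second with nonzero power sums to 1
#' and spectral shape becomes comparable across amplitude levels. Seconds
#' with zero total power are left all-zero and flagged.
#'
#' @param psd A long-format spectral tibble from [psd_welch()].
#' @return A tibble of the same shape with normalized `power`, attribute
#'   `mode = "relative"`, and attribute `zero_power_seconds` listing the
#'   degenerate seconds.
#' @export
psd_relative <- function(psd) {
  out <- psd |>
    dplyr::group_by(.data$second) |>
    dplyr::mutate(.total = sum(.data$power)) |>
    dplyr::ungroup() |>
    dplyr::mutate(power = dplyr::if_else(.data$.total > 0,
                                         .data$power / .data$.total, 0))
  zero <- unique(out$second[out$.total <= 0])
  out <- dplyr::select(out, -".total")
  attr(out, "mode") <- "relative"
  attr(out, "zero_power_seconds") <- zero
  if (length(zero) > 0L) {
    warn(sprintf("%d second(s) had zero total power; left all-zero.",
                 length(zero)))
  }
  out
}

#' Median spectrum across a set of seconds
#'
#' For each frequency bin, the median across the selected seconds of the
#' (typically relative) spectral power. With relative input this is the
#' "median relative spectral power" curve used to compare activity-free
#' REM sleep with phasic-event windows.
#'
#' @param psd A long-format spectral tibble.
#' @param seconds Optional integer vector of seconds to include (default:
#'   all seconds present). Must select at least one second.
#' @return A tibble with columns `frequency` and `power` (per-bin median).
#' @export
median_spectrum <- function(psd, seconds = NULL) {
  if (!is.null(seconds)) {
    psd <- dplyr::filter(psd, .data$second %in% seconds)
  }
  if (nrow(psd) == 0L) {
    abort("No seconds selected for the median spectrum.",
          class = "hflf_error_empty_selection")
  }
  psd |>
    dplyr::group_by(.data$frequency) |>
    dplyr::summarise(power = median(.data$power), .groups = "drop")
}
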