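#' Construct an EMG recording
#'
#' A single-channel surface EMG trace with its sampling rate, channel label
#' and offset from the start of the polysomnography recording. Amplitudes are
#' in microvolts; for REM atonia assessment the conventional channel is the
#' mentalis (chin) EMG sampled at 200 Hz.
#'
#' @param samples Numeric vector of samples (microvolts).
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param channel_label Channel name, e.g. `"Chin1-Chin2"`.
#' @param start_offset Seconds from the start of the recording (default 0).
#'
#' @return An object of class `emg_recording`.
#' @export
#' @examples
#' rec <- emg_recording(sin(2 * pi * 30 * seq(0, 10, by = 1 / 200)), 200)
#' emg_duration(rec)
emg_recording <- function(samples, sampling_rate, channel_label = "EMG",
                          start_offset = 0) {
  if (!is.numeric(samples) || length(samples) < 1L) {
    abort("`samples` must be a non-empty numeric vector.",
          class = "hflf_error_invalid_recording")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz).",
          class = "hflf_error_invalid_recording")
  }
  structure(
    list(
      samples = as.double(samples),
      sampling_rate = as.double(sampling_rate),
      channel_label = as.character(channel_label),
      start_offset = as.double(start_offset)
    ),
    class = "emg_recording"
  )
}

#' Duration of an EMG recording in seconds
#'
#' @param recording An [emg_recording()].
#' @return Duration in seconds (`length(samples) / sampling_rate`).
#' @export
emg_duration <- function(recording) {
  stopifnot(inherits(recording, "emg_recording"))
  length(recording$samples) / recording$sampling_rate
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording> channel '%s': %d samples @ %g Hz (%.1f s)\n",
    x$channel_label, length(x$samples), x$sampling_rate, emg_duration(x)
  ))
  invisible(x)
}
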