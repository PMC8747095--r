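# Synthetic polysomnography generator.
#
# Emulates the three inputs the pipeline consumes: a chin-EMG trace whose
# REM baseline is low-amplitude 1/f^alpha-shaped noise (atonia), with
# superimposed broadband phasic bursts whose energy is concentrated above
# ~20 Hz; a staged hypnogram with REM placed in contiguous periods; and a
# ground-truth event table. The generator is calibrated only to the
# qualitative structure of real data (orderings, spectral concentration),
# never to any reported group mean.

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

saved_seed <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
}

#' Configuration for the synthetic polysomnography generator
#'
#' @param seed Integer RNG seed; the whole simulation is deterministic
#'   given the seed.
#' @param sampling_rate EMG sampling rate in Hz (default 200, the
#'   conventional clinical rate for chin EMG).
#' @param n_epochs Number of 30 s epochs (default 960, an 8 h night).
#' @param rem_fraction Fraction of epochs staged REM, placed in contiguous
#'   REM periods (default 0.2, a typical adult share of the night).
#' @param baseline_amplitude_uV RMS amplitude of the atonia baseline in
#'   microvolts (default 2, i.e. near the noise floor).
#' @param baseline_spectral_exponent Exponent alpha of the 1/(1 + f)^alpha
#'   baseline spectral shaping (default 2), concentrating baseline power at
#'   low frequencies.
#' @param burst_rate_per_rem_epoch Poisson rate of phasic bursts per REM
#'   epoch (default 1, populating all three of the 0 / 1 / >= 2 event
#'   groups).
#' @param burst_duration_s Length-2 range of burst durations in seconds
#'   (default 0.5 to 2, the phasic time scale).
#' @param burst_amplitude_ratio Burst RMS as a multiple of the baseline RMS
#'   (default 5).
#' @param burst_band_hz Length-2 band of the burst noise in Hz (default
#'   20 to 90).
#' @param baseline_psd,burst_psd Optional vectorized functions
#'   `f(frequency_hz) -> relative density` overriding the default spectral
#'   shapes (used for controlled crossover experiments).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(seed = 1L,
                         sampling_rate = 200,
                         n_epochs = 960L,
                         rem_fraction = 0.2,
                         baseline_amplitude_uV = 2,
                         baseline_spectral_exponent = 2,
                         burst_rate_per_rem_epoch = 1,
                         burst_duration_s = c(0.5, 2),
                         burst_amplitude_ratio = 5,
                         burst_band_hz = c(20, 90),
                         baseline_psd = NULL,
                         burst_psd = NULL) {
  cfg <- list(
    seed = as.integer(seed), sampling_rate = sampling_rate,
    n_epochs = as.integer(n_epochs), rem_fraction = rem_fraction,
    baseline_amplitude_uV = baseline_amplitude_uV,
    baseline_spectral_exponent = baseline_spectral_exponent,
    burst_rate_per_rem_epoch = burst_rate_per_rem_epoch,
    burst_duration_s = as.double(burst_duration_s),
    burst_amplitude_ratio = burst_amplitude_ratio,
    burst_band_hz = as.double(burst_band_hz),
    baseline_psd = baseline_psd, burst_psd = burst_psd
  )
  ok <- cfg$sampling_rate > 0 && cfg$n_epochs >= 1L &&
    cfg$rem_fraction > 0 && cfg$rem_fraction < 1 &&
    cfg$baseline_amplitude_uV > 0 &&
    cfg$burst_rate_per_rem_epoch >= 0 &&
    length(cfg$burst_duration_s) == 2L &&
    all(cfg$burst_duration_s > 0) &&
    diff(cfg$burst_duration_s) >= 0 &&
    cfg$burst_amplitude_ratio > 0 &&
    length(cfg$burst_band_hz) == 2L &&
    cfg$burst_band_hz[1] > 0 &&
    cfg$burst_band_hz[2] <= cfg$sampling_rate / 2 &&
    cfg$burst_band_hz[1] < cfg$burst_band_hz[2]
  if (!ok) {
    abort("Invalid synthetic-recording configuration.",
          class = "hflf_error_bad_config")
  }
  structure(cfg, class = "synth_config")
}

# Gaussian noise with a prescribed spectral shape, via frequency-domain
# filtering: whiten -> multiply amplitudes by sqrt(shape) -> invert.
shaped_noise <- function(n, fs, shape_fun) {
  z <- rnorm(n)
  k <- 0:(n - 1)
  freq <- pmin(k, n - k) * fs / n
  h <- sqrt(pmax(shape_fun(freq), 0))
  x <- Re(fft(fft(z) * h, inverse = TRUE)) / n
  x
}

scale_rms <- function(x, rms) {
  cur <- sqrt(mean(x^2))
  if (cur > 0) x * (rms / cur) else x
}

synth_hypnogram_stages <- function(n_epochs, rem_fraction) {
  n_rem <- max(1L, round(n_epochs * rem_fraction))
  n_wake <- max(1L, round(0.02 * n_epochs))
  if (n_wake + n_rem >= n_epochs) n_wake <- max(0L, n_epochs - n_rem - 1L)
  n_fill <- n_epochs - n_wake - n_rem
  k <- max(1L, min(4L, n_rem %/% 10L, n_fill))
  # REM period sizes: near-equal split
  rem_sizes <- diff(round(seq(0, n_rem, length.out = k + 1L)))
  fill_sizes <- diff(round(seq(0, n_fill, length.out = k + 2L)))
  nrem_cycle <- c("N1", "N2", "N2", "N3", "N3", "N2")
  stages <- rep("WAKE", n_wake)
  used <- 0L
  for (i in seq_len(k)) {
    blk <- rep(nrem_cycle, length.out = fill_sizes[i])
    stages <- c(stages, blk, rep("REM", rem_sizes[i]))
    used <- used + fill_sizes[i]
  }
  c(stages, rep(nrem_cycle, length.out = n_fill - used))
}

#' Simulate a synthetic polysomnography recording
#'
#' Generates an EMG signal, hypnogram, phasic-event table and ground-truth
#' per-second burst mask under the configured conditions: shaped-noise
#' atonia baseline over the whole night; within REM epochs, bursts arrive
#' as a Poisson process at the configured rate, each a band-limited noise
#' burst with 50 ms cosine on/off ramps added onto the baseline; events are
#' recorded with their exact onset and duration. Deterministic given
#' `config$seed`.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_psg` with elements `recording`
#'   ([emg_recording()]), `hypnogram`, `events`, `burst_mask` (tibble
#'   `second`, `burst`), and `config`.
#' @export
#' @examples
#' sim <- simulate_recording(synth_config(seed = 7, n_epochs = 20))
#' nrow(sim$events)
simulate_recording <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- saved_seed()
  on.exit(restore_seed(old_seed), add = TRUE)
  set.seed(config$seed)
  fs <- config$sampling_rate
  n_epochs <- config$n_epochs
  total_sec <- n_epochs * epoch_length_sec
  n <- as.integer(total_sec * fs)

  hyp <- hypnogram(synth_hypnogram_stages(n_epochs, config$rem_fraction))

  alpha <- config$baseline_spectral_exponent
  base_shape <- config$baseline_psd %||%
    (function(f) 1 / (1 + f)^alpha)
  signal <- scale_rms(shaped_noise(n, fs, base_shape),
                      config$baseline_amplitude_uV)

  lo <- config$burst_band_hz[1]
  hi <- config$burst_band_hz[2]
  burst_shape <- config$burst_psd %||%
    (function(f) as.numeric(f >= lo & f <= hi))

  onsets <- numeric()
  durations <- numeric()
  rem_epochs <- hyp$epoch[hyp$stage == "REM"]
  if (config$burst_rate_per_rem_epoch > 0) {
    for (e in rem_epochs) {
      n_ev <- rpois(1L, config$burst_rate_per_rem_epoch)
      if (n_ev == 0L) next
      e_start <- (e - 1L) * epoch_length_sec
      ons <- sort(runif(n_ev, e_start, e_start + epoch_length_sec))
      dur <- runif(n_ev, config$burst_duration_s[1],
                   config$burst_duration_s[2])
      dur <- pmin(dur, total_sec - ons)
      keep <- dur > 0.05
      onsets <- c(onsets, ons[keep])
      durations <- c(durations, dur[keep])
    }
  }
  burst_rms <- config$burst_amplitude_ratio * config$baseline_amplitude_uV
  for (i in seq_along(onsets)) {
    m <- max(8L, as.integer(round(durations[i] * fs)))
    burst <- scale_rms(shaped_noise(m, fs, burst_shape), burst_rms)
    ramp <- min(as.integer(0.05 * fs), m %/% 4L)
    if (ramp > 0L) {
      env <- rep(1, m)
      up <- 0.5 * (1 - cos(pi * seq_len(ramp) / ramp))
      env[seq_len(ramp)] <- up
      env[m - ramp + seq_len(ramp)] <- rev(up)
      burst <- burst * env
    }
    at <- as.integer(floor(onsets[i] * fs))
    span <- seq_len(min(m, n - at))
    signal[at + span] <- signal[at + span] + burst[span]
  }

  events <- event_table(onsets, durations)
  burst_sec <- unique(unlist(purrr::map2(onsets, durations, function(o, d) {
    seq.int(floor(o), min(total_sec - 1, ceiling(o + d) - 1))
  }), use.names = FALSE))
  mask <- tibble::tibble(second = 0:(total_sec - 1L),
                         burst = (0:(total_sec - 1L)) %in% burst_sec)

  structure(
    list(
      recording = emg_recording(signal, fs, channel_label = "Chin1-Chin2"),
      hypnogram = hyp,
      events = events,
      burst_mask = mask,
      config = config
    ),
    class = "synth_psg"
  )
}

#' Write a simulated recording to disk as a pipeline fixture
#'
#' Writes the EMG as EDF, the hypnogram and events as the CSV dialects read
#' by [read_hypnogram()] / [read_events()], and the scalar configuration
#' fields as YAML, into `directory`.
#'
#' @param sim A `synth_psg` from [simulate_recording()].
#' @param directory Output directory (created if missing).
#' @return Named character vector of the written paths (`edf`, `hypnogram`,
#'   `events`, `config`), invisibly.
#' @export
write_fixture <- function(sim, directory) {
  stopifnot(inherits(sim, "synth_psg"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    edf = file.path(directory, "recording.edf"),
    hypnogram = file.path(directory, "hypnogram.csv"),
    events = file.path(directory, "events.csv"),
    config = file.path(directory, "config.yaml")
  )
  write_edf(sim$recording, paths[["edf"]])
  write_hypnogram(sim$hypnogram, paths[["hypnogram"]])
  write_events(sim$events, paths[["events"]])
  scalar_cfg <- sim$config[!vapply(sim$config, is.function, logical(1))]
  yaml::write_yaml(scalar_cfg, paths[["config"]])
  invisible(paths)
}

#' Read a generator configuration from YAML
#'
#' @param path YAML file whose fields mirror [synth_config()] arguments.
#' @return A [synth_config()].
#' @export
read_synth_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path),
          class = "hflf_error_missing_file")
  }
  do.call(synth_config, yaml::read_yaml(path))
}
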