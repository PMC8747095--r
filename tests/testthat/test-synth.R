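test_that("simulation is deterministic given the seed", {
  cfg <- synth_config(seed = 71, n_epochs = 12)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$recording$samples, b$recording$samples)
  expect_identical(a$events, b$events)
  expect_identical(a$hypnogram, b$hypnogram)
  c <- simulate_recording(synth_config(seed = 72, n_epochs = 12))
  expect_false(identical(a$recording$samples, c$recording$samples))
})

test_that("zero burst rate yields no events and burst-free REM", {
  sim <- simulate_recording(
    synth_config(seed = 73, n_epochs = 12, burst_rate_per_rem_epoch = 0))
  expect_equal(nrow(sim$events), 0)
  expect_false(any(sim$burst_mask$burst))
})

test_that("the hypnogram has the requested REM fraction in contiguous runs", {
  cfg <- synth_config(seed = 74, n_epochs = 200, rem_fraction = 0.25)
  hyp <- simulate_recording(cfg)$hypnogram
  expect_equal(sum(hyp$stage == "REM"), 50)
  runs <- rle(as.character(hyp$stage))
  rem_runs <- sum(runs$values == "REM")
  expect_lte(rem_runs, 4)
  expect_true(all(runs$lengths[runs$values == "REM"] >= 2))
})

test_that("event counts per REM epoch follow the configured Poisson rate", {
  rate <- 1.2
  cfg <- synth_config(seed = 75, n_epochs = 1430, rem_fraction = 0.7,
                      burst_rate_per_rem_epoch = rate,
                      burst_duration_s = c(0.2, 0.4))
  # short bursts keep the waveform synthesis cheap at ~1000 REM epochs
  sim <- simulate_recording(cfg)
  counts <- count_events_per_epoch(sim$hypnogram, sim$events)
  expect_gt(nrow(counts), 990)
  obs <- table(factor(pmin(counts$event_count, 4), levels = 0:4))
  p <- c(dpois(0:3, rate), ppois(3, rate, lower.tail = FALSE))
  gof <- suppressWarnings(chisq.test(as.vector(obs), p = p))
  expect_gt(gof$p.value, 0.01)
})

test_that("bursts concentrate power above 20 Hz relative to baseline", {
  cfg <- synth_config(seed = 76, n_epochs = 40, rem_fraction = 0.5,
                      burst_amplitude_ratio = 8)
  sim <- simulate_recording(cfg)
  psd <- psd_welch(sim$recording, max_freq = 100)
  frac_hf <- psd |>
    dplyr::group_by(second) |>
    dplyr::summarise(frac = sum(power[frequency >= 20]) / sum(power))
  rem_secs <- with(sim$hypnogram,
                   unlist(lapply(epoch[stage == "REM"],
                                 function(e) ((e - 1) * 30):((e - 1) * 30 + 29))))
  burst <- sim$burst_mask$second[sim$burst_mask$burst]
  quiet <- setdiff(rem_secs, burst)
  burst <- intersect(burst, frac_hf$second)
  quiet <- intersect(quiet, frac_hf$second)
  expect_gt(median(frac_hf$frac[frac_hf$second %in% burst]),
            median(frac_hf$frac[frac_hf$second %in% quiet]))
  # and the per-second ratio separates burst from quiet REM seconds
  ratio <- compute_hflf(psd_welch(sim$recording))
  expect_gt(median(ratio$hflf[ratio$second %in% burst], na.rm = TRUE),
            median(ratio$hflf[ratio$second %in% quiet], na.rm = TRUE))
})

test_that("fixtures round-trip through the EDF/CSV dialects", {
  sim <- simulate_recording(synth_config(seed = 77, n_epochs = 12))
  dir <- withr::local_tempdir()
  paths <- write_fixture(sim, dir)
  expect_true(all(file.exists(paths)))

  rec <- read_emg_edf(paths[["edf"]], "Chin1-Chin2")
  expect_equal(length(rec$samples), length(sim$recording$samples))
  tol <- 2 * max(1, ceiling(max(abs(sim$recording$samples)))) / 65535
  expect_lt(max(abs(rec$samples - sim$recording$samples)), tol)
  expect_equal(read_hypnogram(paths[["hypnogram"]]), sim$hypnogram)
  back_ev <- read_events(paths[["events"]])
  expect_equal(back_ev$onset_sec, sim$events$onset_sec, tolerance = 1e-12)

  cfg2 <- read_synth_config(paths[["config"]])
  expect_equal(cfg2$seed, sim$config$seed)
  expect_equal(cfg2$burst_band_hz, sim$config$burst_band_hz)

  # empty event table still writes a valid header-only file
  sim0 <- simulate_recording(
    synth_config(seed = 78, n_epochs = 8, burst_rate_per_rem_epoch = 0))
  paths0 <- write_fixture(sim0, withr::local_tempdir())
  expect_equal(nrow(read_events(paths0[["events"]])), 0)
})

test_that("configuration validation rejects impossible settings", {
  expect_error(synth_config(rem_fraction = 0), class = "hflf_error_bad_config")
  expect_error(synth_config(burst_band_hz = c(50, 20)),
               class = "hflf_error_bad_config")
  expect_error(synth_config(burst_band_hz = c(20, 150)),
               class = "hflf_error_bad_config")
  expect_error(synth_config(burst_duration_s = c(2, 1)),
               class = "hflf_error_bad_config")
})
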