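test_that("EDF write/read round-trips a synthetic recording", {
  set.seed(11)
  rec <- emg_recording(rnorm(200 * 60, sd = 5), 200, "Chin1-Chin2")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_emg_edf(path, "Chin1-Chin2")
  expect_length(back$samples, 12000)
  expect_equal(back$sampling_rate, 200)
  expect_equal(back$channel_label, "Chin1-Chin2")
  # quantization tolerance: physical range / 2^16
  tol <- 2 * max(1, ceiling(max(abs(rec$samples)))) / 65535
  expect_lt(max(abs(back$samples - rec$samples)), tol)
})

test_that("EDF reader extracts the requested channel of a multi-channel file", {
  set.seed(12)
  a <- emg_recording(rnorm(100 * 10), 100, "EMG-A")
  b <- emg_recording(sin(2 * pi * 5 * (0:2999) / 300), 300, "EMG-B")
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(list(a, b), path)

  chans <- read_edf_channels(path)
  expect_equal(chans$label, c("EMG-A", "EMG-B"))
  expect_equal(chans$sampling_rate_hz, c(100, 300))

  back_b <- read_emg_edf(path, "EMG-B")
  expect_equal(back_b$sampling_rate, 300)
  expect_length(back_b$samples, 3000)
  expect_lt(max(abs(back_b$samples - b$samples)), 2 / 65535 + 1e-9)

  # written digital values for the second channel decode bit-identically
  expect_identical(
    read_emg_edf(path, "EMG-B")$samples,
    back_b$samples)
})

test_that("EDF reader fails distinctly for missing file, channel, corrupt data", {
  expect_error(read_emg_edf(file.path(tempdir(), "nope.edf"), "X"),
               class = "hflf_error_missing_file")
  rec <- emg_recording(rnorm(400), 200)
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  expect_error(read_emg_edf(path, "NoSuchChannel"),
               class = "hflf_error_channel_not_found")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(charToRaw(strrep("x", 100)), bad)
  expect_error(read_emg_edf(bad, "EMG"), class = "hflf_error_bad_edf")
})

test_that("hypnogram CSV round-trips and rejects unknown labels", {
  hyp <- hypnogram(c("WAKE", "N1", "N2", "REM"))
  expect_equal(nrow(hyp), 4)
  expect_equal(hyp$onset_sec, c(0, 30, 60, 90))

  path <- withr::local_tempfile(fileext = ".csv")
  write_hypnogram(hyp, path)
  expect_equal(read_hypnogram(path), hyp)

  expect_error(hypnogram(c("N1", "N4")), class = "hflf_error_unknown_stage")
  expect_error(hypnogram(character()), class = "hflf_error_empty_hypnogram")

  big <- hypnogram(rep(c("N2", "REM"), 500))
  expect_equal(nrow(big), 1000)
  # epoch i covers [30(i-1), 30i)
  expect_equal(big$onset_sec[1000], 29970)
})

test_that("event tables sort by onset, validate, and allow empty files", {
  ev <- event_table(c(45.4, 12.0), c(0.5, 1.0))
  expect_equal(ev$onset_sec, c(12.0, 45.4))
  expect_equal(ev$event_id, 1:2)

  expect_error(event_table(1, 0), class = "hflf_error_bad_events")
  expect_error(event_table(-1, 1), class = "hflf_error_bad_events")

  path <- withr::local_tempfile(fileext = ".csv")
  write_events(ev, path)
  expect_equal(read_events(path)$onset_sec, c(12.0, 45.4))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("onset_sec,duration_sec,label", empty)
  expect_equal(nrow(read_events(empty)), 0)
})

test_that("eligibility applies the 4 h sleep and 10 REM epoch thresholds", {
  all_rem <- check_eligibility(hypnogram(rep("REM", 480)))
  expect_true(all_rem$eligible)
  expect_equal(all_rem$total_sleep_hours, 4)
  expect_equal(all_rem$rem_epoch_count, 480)

  short <- check_eligibility(
    hypnogram(c(rep("REM", 479), "WAKE")))
  expect_false(short$eligible)
  expect_match(short$reasons[[1]], "total sleep time", all = FALSE)

  low_rem <- check_eligibility(
    hypnogram(c(rep("N2", 471), rep("REM", 9))))
  expect_false(low_rem$eligible)
  expect_equal(low_rem$total_sleep_hours, 4)
  expect_match(low_rem$reasons[[1]], "REM epochs", all = FALSE)
})

test_that("eligibility matches brute-force stage counting on random hypnograms", {
  set.seed(21)
  for (i in 1:25) {
    stages <- sample(c("WAKE", "REM", "N1", "N2", "N3"),
                     sample(300:700, 1), replace = TRUE,
                     prob = c(0.1, 0.2, 0.1, 0.4, 0.2))
    res <- check_eligibility(hypnogram(stages))
    tst <- sum(stages != "WAKE") * 30 / 3600
    rem <- sum(stages == "REM")
    expect_equal(res$total_sleep_hours, tst)
    expect_equal(res$rem_epoch_count, rem)
    expect_equal(res$eligible, tst >= 4 && rem >= 10)
  }
})
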