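make_hflf_tbl <- function(values) {
  tibble::tibble(second = seq_along(values) - 1L, hflf = values,
                 degenerate = is.na(values))
}

test_that("events are counted into the REM epoch containing their onset", {
  hyp <- hypnogram(rep("REM", 4))
  ev <- event_table(c(31, 35), c(0.5, 0.5))
  counts <- count_events_per_epoch(hyp, ev)
  expect_equal(counts$event_count, c(0L, 2L, 0L, 0L))
  expect_equal(as.character(counts$group), c("E1", "E3", "E1", "E1"))

  none <- count_events_per_epoch(hyp, event_table())
  expect_true(all(none$group == "E1"))

  mixed <- hypnogram(c("N2", "REM", "REM"))
  expect_warning(
    c2 <- count_events_per_epoch(mixed, event_table(5, 1)),
    "non-REM")
  expect_equal(sum(c2$event_count), 0L)
})

test_that("epoch summaries sum valid per-second ratios over each REM epoch", {
  hyp <- hypnogram(c("REM", "REM"))
  vals <- rep(0.26, 60)
  out <- summarize_epochs(make_hflf_tbl(vals), hyp, event_table())
  expect_equal(out$epoch_hflf, c(7.8, 7.8))
  expect_equal(out$n_valid_seconds, c(30L, 30L))

  vals[c(3, 10)] <- NA # two degenerate seconds in epoch 1
  out2 <- summarize_epochs(make_hflf_tbl(vals), hyp, event_table())
  expect_equal(out2$n_valid_seconds[1], 28L)
  expect_equal(out2$epoch_hflf[1], 28 * 0.26)

  m <- summarize_epochs(make_hflf_tbl(rep(0.26, 60)), hyp, event_table(),
                        aggregate = "mean")
  expect_equal(m$epoch_hflf, c(0.26, 0.26))
})

test_that("epoch grouping and sums match brute-force loops on random inputs", {
  set.seed(51)
  for (i in 1:10) {
    n_ep <- sample(6:12, 1)
    stages <- sample(c("REM", "N2", "WAKE"), n_ep, replace = TRUE,
                     prob = c(0.5, 0.4, 0.1))
    if (!any(stages == "REM")) stages[1] <- "REM"
    hyp <- hypnogram(stages)
    vals <- rexp(n_ep * 30)
    vals[sample(length(vals), 8)] <- NA
    rem_start <- (which(stages == "REM") - 1) * 30
    onsets <- sort(runif(sample(0:6, 1),
                         min(rem_start), min(rem_start) + 29.9))
    ev <- if (length(onsets)) event_table(onsets, runif(length(onsets), 0.2, 1))
      else event_table()
    got <- summarize_epochs(make_hflf_tbl(vals), hyp, ev)
    ref <- brute_epoch_summary(make_hflf_tbl(vals), stages, ev$onset_sec)
    expect_equal(got$epoch, ref$epoch)
    expect_equal(got$event_count, ref$event_count)
    expect_equal(got$epoch_hflf, ref$epoch_hflf)
    expect_equal(got$n_valid_seconds, ref$n_valid)
  }
})

test_that("event windows span 1 s before onset through 1 s after offset", {
  expect_equal(event_window_seconds(45.4, 0.5), 44:46)
  expect_equal(event_window_seconds(45.0, 1.0), 44:46)
  expect_equal(event_window_seconds(0.2, 0.5), 0:1) # clipped at time 0
  expect_equal(event_window_seconds(10.5, 4), 9:15) # long event: whole span

  hyp <- hypnogram(rep("REM", 2))
  vals <- seq(0.1, 6.0, by = 0.1)[1:60]
  w <- collect_window_samples(make_hflf_tbl(vals), hyp,
                              event_table(45.4, 0.5))
  w2 <- dplyr::filter(w, kind == "W2")
  expect_equal(w2$value, mean(vals[c(45, 46, 47)]))
  w1 <- dplyr::filter(w, kind == "W1")
  expect_false(any(w1$source %in% 44:46))
})

test_that("W1 covers all valid REM seconds when there are no events", {
  hyp <- hypnogram(c("REM", "N2"))
  vals <- rexp(60)
  vals[5] <- NA
  w <- collect_window_samples(make_hflf_tbl(vals), hyp, event_table())
  expect_equal(sum(w$kind == "W2"), 0L)
  expect_equal(sort(w$source[w$kind == "W1"]), setdiff(0:29, 4))
})

test_that("overlapping event windows are excluded jointly but sampled per event", {
  hyp <- hypnogram("REM")
  vals <- rexp(30)
  ev <- event_table(c(10.2, 11.0), c(1.0, 0.6))
  w <- collect_window_samples(make_hflf_tbl(vals), hyp, ev)
  expect_equal(sum(w$kind == "W2"), 2L)
  union_secs <- union(event_window_seconds(10.2, 1.0),
                      event_window_seconds(11.0, 0.6))
  expect_equal(sort(w$source[w$kind == "W1"]),
               setdiff(0:29, union_secs))
})

test_that("every valid REM second is W1 or inside an event window, never both", {
  set.seed(52)
  for (i in 1:10) {
    stages <- sample(c("REM", "N2"), 8, replace = TRUE)
    if (!any(stages == "REM")) stages[3] <- "REM"
    hyp <- hypnogram(stages)
    vals <- rexp(240)
    vals[sample(240, 10)] <- NA
    rem_ep <- which(stages == "REM")
    onsets <- runif(4, (min(rem_ep) - 1) * 30, max(rem_ep) * 30 - 2)
    ev <- event_table(onsets, runif(4, 0.3, 2))
    tbl <- make_hflf_tbl(vals)
    w <- suppressWarnings(collect_window_samples(tbl, hyp, ev))
    rem_secs <- tbl$second[!is.na(tbl$hflf) &
                             (floor(tbl$second / 30) + 1) %in% rem_ep]
    win_union <- unique(unlist(purrr::map2(ev$onset_sec, ev$duration_sec,
                                           event_window_seconds,
                                           max_second = 239)))
    w1 <- w$source[w$kind == "W1"]
    expect_setequal(w1, setdiff(rem_secs, win_union))
    expect_length(intersect(w1, win_union), 0)
    expect_equal(length(w1) + length(intersect(rem_secs, win_union)),
                 length(rem_secs))
  }
})

test_that("group statistics match brute-force sorted-array computation", {
  s <- group_statistics(c(1, 2, 3, 4, 5))
  expect_equal(s$mean, 3)
  expect_equal(s$median, 3)
  expect_equal(s$p25, 2)
  expect_equal(s$p75, 4)

  one <- group_statistics(7)
  expect_equal(one$mean, 7)
  expect_equal(one$median, 7)
  expect_equal(one$sd, 0)
  expect_false(one$sd_defined)

  set.seed(53)
  x <- rexp(10000)
  g <- group_statistics(x)
  xs <- sort(x)
  # linear-interpolation percentile on the sorted array
  lin_q <- function(p) {
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(g$mean, sum(x) / length(x))
  expect_equal(g$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)))
  expect_equal(g$median, lin_q(0.5))
  expect_equal(g$p5, lin_q(0.05))
  expect_equal(g$p95, lin_q(0.95))
  expect_error(group_statistics(NA_real_), class = "hflf_error_empty_sample")
})

test_that("find_crossover returns the first adjacent sign change in range", {
  grid <- seq(0, 55, by = 0.5)
  flat <- tibble::tibble(frequency = grid, power = 1)
  below <- tibble::tibble(frequency = grid, power = 0.5)
  expect_false(find_crossover(flat, below)$found)

  # single designed change of order between 20.5 and 21.0
  a <- tibble::tibble(frequency = grid, power = ifelse(grid <= 20.5, 1, 0))
  b <- tibble::tibble(frequency = grid, power = ifelse(grid <= 20.5, 0, 1))
  x <- find_crossover(a, b)
  expect_true(x$found)
  expect_equal(x$lower_hz, 20.5)
  expect_equal(x$upper_hz, 21.0)

  # equality at exactly one bin with opposite signs either side:
  # both adjacent pairs qualify; the first is returned
  d <- ifelse(grid < 10, 1, ifelse(grid == 10, 0, -1))
  a2 <- tibble::tibble(frequency = grid, power = d)
  b2 <- tibble::tibble(frequency = grid, power = 0)
  x2 <- find_crossover(a2, b2)
  expect_equal(c(x2$lower_hz, x2$upper_hz), c(9.5, 10))

  # search range honoured
  xr <- find_crossover(a, b, search_lo = 30, search_hi = 50)
  expect_false(xr$found)
  expect_error(find_crossover(a, b, search_lo = 20.4, search_hi = 20.6),
               class = "hflf_error_bad_search_range")
})
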