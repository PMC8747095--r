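# Independent reference implementations used only to check package output.
# These are deliberately written as direct, loop-based textbook code and
# share no internals with the package.

# One-shot Hann-tapered periodogram of a single window, density scaling.
oracle_periodogram <- function(x, fs, max_freq = Inf) {
  n <- length(x)
  x <- x - sum(x) / n
  w <- 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))
  xf <- stats::fft(x * w)
  nf <- n %/% 2 + 1
  p <- Mod(xf[seq_len(nf)])^2 / (fs * sum(w^2))
  if (n %% 2 == 0) {
    p[2:(nf - 1)] <- 2 * p[2:(nf - 1)]
  } else {
    p[2:nf] <- 2 * p[2:nf]
  }
  f <- (seq_len(nf) - 1) * fs / n
  keep <- f <= max_freq + 1e-9
  data.frame(frequency = f[keep], power = p[keep])
}

# Textbook sum-of-squares one-way ANOVA.
oracle_anova <- function(groups) {
  all_v <- unlist(groups)
  k <- length(groups)
  n <- length(all_v)
  gm <- mean(all_v)
  ssb <- 0
  ssw <- 0
  for (g in groups) {
    ssb <- ssb + length(g) * (mean(g) - gm)^2
    ssw <- ssw + sum((g - mean(g))^2)
  }
  dfb <- k - 1
  dfw <- n - k
  f <- (ssb / dfb) / (ssw / dfw)
  list(f = f, df_between = dfb, df_within = dfw,
       p = stats::pf(f, dfb, dfw, lower.tail = FALSE), mse = ssw / dfw)
}

# Tukey HSD adjusted p for one pair, from the studentized range distribution.
oracle_tukey_p <- function(groups, i, j) {
  o <- oracle_anova(groups)
  ni <- length(groups[[i]])
  nj <- length(groups[[j]])
  se <- sqrt(o$mse / 2 * (1 / ni + 1 / nj))
  q <- abs(mean(groups[[i]]) - mean(groups[[j]])) / se
  stats::ptukey(q, length(groups), o$df_within, lower.tail = FALSE)
}

# Welch unequal-variance t with Welch-Satterthwaite df.
oracle_welch_t <- function(a, b) {
  va <- stats::var(a) / length(a)
  vb <- stats::var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 /
    (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Long-format spectral tibble from a seconds-by-frequency matrix.
psd_from_matrix <- function(mat, frequencies = seq(0, 55, by = 0.5),
                            seconds = seq_len(nrow(mat)) - 1L) {
  stopifnot(ncol(mat) == length(frequencies))
  tibble::tibble(
    second = rep(seconds, each = length(frequencies)),
    frequency = rep(frequencies, times = length(seconds)),
    power = as.vector(t(mat))
  )
}

# Brute-force per-epoch event counts and sums, by explicit loops.
brute_epoch_summary <- function(hflf_tbl, stages, onsets) {
  out <- NULL
  for (e in seq_along(stages)) {
    if (stages[e] != "REM") next
    lo <- (e - 1) * 30
    cnt <- 0
    for (o in onsets) if (o >= lo && o < lo + 30) cnt <- cnt + 1
    vals <- c()
    for (s in lo:(lo + 29)) {
      v <- hflf_tbl$hflf[hflf_tbl$second == s]
      if (length(v) == 1 && !is.na(v)) vals <- c(vals, v)
    }
    out <- rbind(out, data.frame(
      epoch = e, event_count = cnt,
      epoch_hflf = if (length(vals)) sum(vals) else NA_real_,
      n_valid = length(vals)))
  }
  out
}

`%||%` <- function(x, y) if (is.null(x)) y else x
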