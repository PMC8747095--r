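#' Spectral shapes that cross at a designed frequency
#'
#' Constructs a baseline/burst pair of spectral-density shapes whose
#' *relative* (unit-sum over the 0-55 Hz analysis grid) spectra cross at a
#' chosen frequency, for controlled validation of crossover recovery.
#'
#' The baseline shape is the decaying density `s1(f) = exp(-f / 30)`. The
#' burst shape is `s1(f) * (1 + kappa * sigma(f))` with a logistic step
#' `sigma` of the given width; its midpoint is solved (by root finding) so
#' that the normalized burst shape equals the normalized baseline shape
#' exactly at `target_hz`. Any additive mixture `s1 + c * burst` then has a
#' relative spectrum passing through the same point at `target_hz` for
#' every mixing weight `c >= 0`, so seconds containing any fraction of
#' burst power cross the baseline curve at the designed frequency.
#'
#' @param target_hz Designed crossing frequency (default 20.75, the
#'   midpoint of the 20.5-21 Hz bin pair).
#' @param kappa Relative strength of the high-frequency enhancement
#'   (default 8).
#' @param width Logistic transition width in Hz (default 1.5).
#' @param grid Analysis frequency grid used for the normalization
#'   (default 0-55 Hz in 0.5 Hz steps).
#' @return A list with vectorized shape functions `baseline_psd` and
#'   `burst_psd` (usable as [synth_config()] overrides), the solved
#'   logistic midpoint `mu`, and `target_hz`.
#' @export
#' @examples
#' sh <- crossover_design_shapes(20.75)
#' sh$mu
crossover_design_shapes <- function(target_hz = 20.75, kappa = 8,
                                    width = 1.5,
                                    grid = seq(0, 55, by = 0.5)) {
  s1 <- function(f) exp(-f / 30)
  r1 <- s1(grid)
  r1 <- r1 / sum(r1)
  sig <- function(f, mu) stats::plogis((f - mu) / width)
  gap <- function(mu) sig(target_hz, mu) - sum(r1 * sig(grid, mu))
  mu <- stats::uniroot(gap, c(target_hz - 15, target_hz + 15),
                       tol = 1e-10)$root
  list(
    baseline_psd = s1,
    burst_psd = function(f) s1(f) * (1 + kappa * sig(f, mu)),
    mu = mu,
    target_hz = target_hz
  )
}
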