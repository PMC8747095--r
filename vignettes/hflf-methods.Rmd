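---
title: "Quantifying phasic REM sleep without atonia with HF:LF spectral power ratios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying phasic REM sleep without atonia with HF:LF spectral power ratios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

During healthy REM sleep, skeletal muscle is paralysed: the chin (mentalis)
surface EMG sits at or near the noise floor. REM sleep without atonia
(RSWA) — the abnormal persistence of muscle activity during REM — is the
defining polysomnographic feature of REM sleep behavior disorder and an
early marker of Parkinson's disease and related synucleinopathies. In
clinical practice RSWA is still scored visually, epoch by epoch, which is
slow and subjective.

Muscle activation is spectrally distinctive: surface EMG bursts carry most
of their energy above ~20 Hz, whereas the quiescent chin channel during
atonia is dominated by low-frequency content. The package exploits this by
computing, for every second `t` of the recording, the ratio of summed
spectral power in a high band to that in a low band:

```
HF:LF(t) = sum_{f in [20, 55] Hz} P(t, f)  /  sum_{f in [2, 20) Hz} P(t, f)
```

where `P(t, f)` is the power spectral density of the 2 s window starting at
second `t`, on a 0.5 Hz grid from 0 to 55 Hz. Quiet REM yields ratios well
below 1; phasic activations push the ratio up by an order of magnitude or
more. The ratio is then validated against visually scored phasic events in
two complementary ways:

* **Epoch-based (E1/E2/E3).** The per-second ratios of each 30 s REM epoch
  are summed, and epochs are grouped by their number of scored events
  (0, 1, >= 2). A one-way ANOVA with Tukey HSD compares the groups.
* **Window-based (W1/W2).** Each scored event contributes one sample: the
  mean ratio over the event's window (1 s before onset through 1 s after
  offset). Every valid REM second outside all event windows is a baseline
  sample. A Welch t test and a variance-ratio F test compare the groups.

The continuous ratio itself is the deliverable; the package deliberately
does not threshold it into automatic event detections.

## Spectral estimation choices

Each second's spectrum is estimated from the 2 s window `[t, t + 2)` by
Welch's method with the averaging segment equal to the full window — i.e. a
single Hann-tapered, mean-detrended modified periodogram. A 2 s window is
the only transform length consistent with the stated 0.5 Hz resolution, so
no sub-segment averaging is possible. Consequences and conventions:

* **Indexing.** The value at second `t` describes the window starting at
  `t`; a recording of duration `D` seconds yields `floor(D) - 1` spectra.
  Shifting the signal by exactly 1 s shifts the series by one index.
* **Scaling.** The density normalization is Parseval-consistent:
  `sum(PSD) * 0.5 Hz` over the full 0–Nyquist grid recovers the tapered
  window's mean-square amplitude (verified on white noise in the tests).
  The HF:LF ratio divides two sums over the same second, so it is invariant
  to this choice and to any overall signal gain.
* **Detrending.** Per-window mean removal; without it a DC offset dominates
  the 0 Hz bin. The LF band starts at 2 Hz, so the ratio is unaffected, but
  relative spectra would be distorted.
* **Truncation.** The retained grid is 0–55 Hz (111 bins). With a 55 Hz cap
  there is no need for a mains notch filter (none is applied); sampling
  rates below 110 Hz are rejected.
* **Relative spectra** divide each second's spectrum by that second's total
  power *over the retained bins*, making spectral shape comparable across
  amplitude levels. The alternative (normalize over the full 0–Nyquist
  grid) would mix in content the analysis never looks at; the retained-grid
  convention keeps the relative curves self-contained. Zero-power seconds
  are left all-zero and flagged rather than made NaN.

## The band boundary at 20 Hz

As the two sums are written, the 20 Hz bin belongs to both bands. The
default `hflf_band()` resolves the tie by assigning 20.0 Hz to the high
band (LF `[2, 20)`, HF `[20, 55]`: 36 and 71 bins on the 0.5 Hz grid), so a
flat spectrum gives exactly 71/36. This resolution is consistent with the
empirical crossover of the two median relative-spectrum curves lying just
*above* the boundary (between 20.5 and 21 Hz): the bins at and just above
20 Hz behave like event content. The opposite convention is available via
`boundary_rule = "hf_half_open"`, and band edges are configurable for
sensitivity analyses.

Seconds whose low-band power is exactly zero (silent or clipped input)
would make the ratio 0/0 or x/0; they are marked degenerate, carry `NA`,
and are excluded from all group statistics, with counts reported.

## Grouping conventions

* The epoch value is the **sum** of its valid per-second ratios (a mean is
  available via `aggregate = "mean"`). Summation is what makes the epoch
  and window scales structurally related: for stationary burst-free REM,
  the mean epoch value is 30 times the mean per-second value — the tests
  verify this to within 2% on synthetic data.
* An event belongs to the epoch containing its onset; an event straddling
  an epoch boundary counts once.
* The event window runs from `floor(onset) - 1` through
  `ceiling(onset + duration)`, i.e. the classic 3 s window for a ~1 s
  event, extended over the whole event for longer ones.
* W1 excludes the seconds of *every* scored event window — including the
  flanking seconds and events whose onset fell outside REM — so no second
  with scored activity is ever counted as activity-free baseline. W2
  samples are computed for REM-epoch events only.
* Percentiles use linear interpolation between order statistics
  (`quantile` type 7). The sample SD of a single value is reported as 0
  with `sd_defined = FALSE`.
* The Welch (unequal-variance) t test is the default for W1 vs W2: the two
  groups differ in spread by construction, and the variance-ratio F test
  puts the event group in the numerator.

## Eligibility screening

A record enters pooled analyses only with at least 4 h of sleep (time in
any non-WAKE stage — the standard total-sleep-time definition; the
alternative reading, time in bed, is not derivable from a hypnogram alone)
and at least 10 REM epochs. In single-recording mode a failure warns and
flags rather than aborts, so exploratory analyses of short recordings
remain possible; batch mode applies the exclusion by default
(`apply_eligibility = FALSE` overrides it).

## What the synthetic generator emulates

`simulate_recording()` produces the three pipeline inputs with a known
ground truth:

* **Atonia baseline**: Gaussian noise spectrally shaped as
  `1/(1 + f)^alpha` (default `alpha = 2`), RMS 2 uV, concentrating relative
  power at low frequencies like the quiescent chin channel.
* **Phasic bursts**: within REM epochs only, arriving as a Poisson process
  (default 1 event per REM epoch, so that epochs with 0, 1 and >= 2 events
  are all well populated), each a band-limited (default 20–90 Hz) noise
  burst of 0.5–2 s with 50 ms cosine ramps, added at 5 times the baseline
  RMS. Onset and duration are recorded exactly.
* **Hypnogram structure**: REM epochs are placed in a few contiguous REM
  periods within an NREM backbone and a short leading wake block,
  exercising epoch-boundary logic. Defaults give an 8 h night (960 epochs)
  with a 20% REM fraction, typical of an adult recording.

The generator is calibrated only to orderings and spectral concentration,
never to any reported group mean, and it shares no spectral code with the
analysis path. It does **not** emulate motor-unit action potential trains,
ECG or movement artifacts, electrode pops, or non-stationary baseline
drift; passing tests therefore demonstrate correct recovery of the designed
spectral structure, not clinical performance on real polysomnography.

For crossover validation, `crossover_design_shapes()` constructs a
baseline/burst shape pair whose relative spectra intersect at a chosen
frequency (default 20.75 Hz, the midpoint of a bin pair). The construction
has a useful algebraic property: any additive mixture of the two shapes
passes through the same point of the relative-spectrum plane, so partially
burst-covered seconds and flanking seconds do not displace the crossing.
The designed experiment (2 h night, 50% REM, 6–10 s events) recovers the
interval (20.5, 21.0) through the full pipeline.

## Numerical and degenerate-input decisions

* Frequencies are constructed as exact multiples of 0.5, and band
  membership uses a 1e-9 guard, so bin assignment is deterministic.
* `find_crossover()` returns the *first* adjacent bin pair whose difference
  changes sign in the search range; a curve touching zero at a single bin
  with opposite signs on either side yields two adjacent candidate pairs,
  of which the first is returned.
* EDF samples are quantized to 16-bit integers over a symmetric physical
  range just covering the data; round trips are exact to range/65535.
  Hypnogram and event files are plain CSV: the vendor-native annotation
  formats of clinical systems are proprietary and not publicly specified.
* Problem sizes in the validation suite (an 8 h night at 200 Hz for the
  discrimination check, 2 h for the crossover experiment, 100-window
  oracles elsewhere) were chosen as the smallest sizes at which the
  sampling error of the checked quantities is comfortably below the
  asserted margins.

## Known limitations

* Only phasic activity is addressed; tonic RSWA (sustained elevation
  across an epoch) needs a different aggregation and is out of scope.
* Per-second and per-epoch significance tests treat samples as independent
  although they are serially correlated within a night; the test statistics
  are descriptive of separation, not calibrated inference.
* No artifact rejection: snoring, ECG bleed and movement will inflate the
  ratio on real recordings.
* The EDF reader supports continuous recordings with integer
  samples-per-record; EDF+ annotations and discontinuous files are not
  parsed.
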