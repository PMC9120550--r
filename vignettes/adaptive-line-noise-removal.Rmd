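---
title: "Adaptive removal of frequency-specific noise: the method behind zaplinr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive removal of frequency-specific noise: the method behind zaplinr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zaplinr)
```

## The problem

Continuous M/EEG recordings are contaminated by narrowband oscillatory
artifacts: mains power at 50/60 Hz and its harmonics, but also screen
refresh rates, head-mounted displays, or other lab equipment. A notch
filter destroys all information in the noise band and can ring; frequency-
domain regression struggles with amplitude and phase fluctuations; plain
spatial filtering (ICA, joint diagonalization) reduces the algebraic rank
of the data and assumes a noise topography that is stable over the whole
recording — an assumption that fails in mobile experiments whenever the
participant moves relative to the noise source.

`zaplinr` implements a fully automatic pipeline around the Zapline
operation of de Cheveigné (2020, *NeuroImage* 207:116356), which combines
the spectral and spatial approaches: the data are split into a spectrally
smooth part and a noise-band part by a period-matched smoother, only the
noise-band part is spatially filtered, and the two parts are summed back.
Power at the noise frequency is suppressed without leaving a notch and
without reducing the rank of the data matrix.

## The procedure

For a channels × samples recording $X$ with sampling rate $f_s$:

1. **Noise frequency detection.** The Welch log-spectrum (Hann taper,
   50% overlap, constant detrend) is computed per channel; the detectors
   operate on the across-channel mean of $10\log_{10}$ PSD — the log of
   the geometric mean of the linear spectra, which a few bad channels
   cannot dominate. A 6 Hz window slides from 17 to 99 Hz; the *center
   power* at a frequency is the mean log power over the outer thirds of
   its window (the middle third, where a peak would sit, is excluded). The
   first bin exceeding its center power by more than 4 (a 2.5× power
   increase) is an outlier; the detection widens to the contiguous region
   whose excess stays above 1.76 (1.5×) and the region's maximum is the
   noise frequency.
2. **Segmentation into chunks of stable topography.** The recording is
   band-passed to ±3 Hz around the noise frequency (zero-phase order-2
   Butterworth), channel covariance matrices are computed in
   non-overlapping 1 s epochs, each matrix is scaled by its Frobenius
   norm, and the Frobenius distance between successive matrices forms a
   stationarity series. Peaks of that series mark topography changes and
   become chunk boundaries, subject to a 30 s minimum chunk length (short
   chunks would starve the spatial decomposition of data and limit the
   per-chunk frequency resolution).
3. **Per-chunk cleaning.** Within each chunk the individual peak frequency
   is searched within ±0.05 Hz of the target, and a fine threshold decides
   whether the artifact is present: the deviation measure is the center
   power minus the mean of the lower 5% quantiles of the outer thirds
   (SD and MAD are avoided because an outlier peak drives them upward),
   and the presence threshold is center + 2 × deviation. The chunk is then
   cleaned with Zapline at its own peak frequency: a moving average of
   length $f_s/f$ (nulls at $f$ and all harmonics) splits the chunk;
   the residual's covariance and its harmonic-bin-filtered counterpart
   form a joint-decorrelation (DSS) problem whose leading components are
   the noise; those components are projected out and the parts are summed
   back.
4. **Component count selection.** The DSS scores are screened by an
   iterative mean + σ·SD outlier detector (remove, recompute, repeat until
   stable; starting σ = 3). The count is floored at a configurable fixed
   minimum (default 1 — even chunks where no artifact was detected lose
   one component, insurance against a missed artifact at negligible cost)
   and capped at one-fifth of the components.
5. **Evaluation and adaptation.** After all chunks are cleaned and
   re-concatenated, the cleaned spectrum is checked against the same fine
   thresholds: more than 0.5% of bins within ±0.05 Hz above the upper
   threshold means the cleaning was *too weak* (σ −0.25 down to 2.5, fixed
   minimum +1); more than 0.5% of bins within −0.4…+0.1 Hz below the lower
   threshold means *too strong* (σ +0.25 up to 4, fixed minimum −1, never
   below its initial value). Too strong takes precedence, and once seen it
   latches: the cleaning can never be strengthened again. The frequency is
   re-cleaned from the original data until no parameter changes (at most
   10 passes; the bounded σ/fixed lattice converges much earlier). The
   search then continues 0.05 Hz above the cleaned frequency, on the
   cleaned data.

Every analytic the decisions were based on — per-chunk removed component
counts, scores, peak frequencies, presence flags, removed-power
proportions, noise/surroundings ratios before and after — is returned in
the report, together with the final configuration. Because the entire
pipeline is deterministic, re-running `zap_clean()` with the emitted
`final_config` (which pins the detected frequencies) reproduces the
cleaned data bit-identically.

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `minfreq`, `maxfreq` | 17, 99 | Hz | detection range; 17 clears the alpha band and the third subharmonic of 50 Hz, 99 stays below the second 50 Hz harmonic |
| `detection_winsize` | 6 | Hz | detection window; outer thirds define the center power, leaving a 2 Hz noise bandwidth |
| `coarse_freq_detect_power_diff` | 4 | 10·log₁₀ | coarse outlier threshold (2.5× power) |
| `coarse_freq_detect_lower_power_diff` | 1.76 | 10·log₁₀ | end of the outlier region (1.5×) |
| `freq_detect_mult_fine` | 2 | — | multiplier on the quantile deviation for presence/evaluation thresholds |
| `noise_comp_detect_sigma` | 3 | SD | initial outlier σ for component selection, adapted within [2.5, 4] |
| `fixed_nremove` | 1 | count | minimum components removed per chunk |
| `chunk_length` | 0 | s | fixed chunking; 0 = adaptive covariance segmentation |
| `min_chunk_length` | 30 | s | shortest admissible chunk |
| `win_size_complete_spectrum` | 0 | samples | Welch window; 0 = `srate` × (chunk length), long windows for fine resolution |
| `nkeep` | 0 | count | optional PCA rank cap inside the decomposition |

## Numerical choices

* All thresholds compare strictly (`>`), and spectral argmax ties break
  toward the lower frequency; quantiles are linear-interpolation empirical
  quantiles.
* The period-matched smoother uses a centered moving average (symmetric
  half-weight kernel for even lengths) with reflection padding, so
  `smoothed + residual` reproduces the input exactly over the full chunk —
  this identity is what preserves rank. Fractional periods interpolate
  linearly between the two flanking integer window lengths.
* The DSS bias covariance keeps one DFT bin (plus its conjugate) per
  harmonic $k f < f_s/2$, estimated over consecutive windows of
  `2^round(log2(srate))` samples; whitening discards eigenvalues below
  10⁻⁹ of the largest, so rank-deficient chunks are handled without
  regularization.
* Chunk spectra use a single Welch segment spanning the whole chunk —
  the finest resolution available (≥ 1/30 Hz at the minimum chunk length),
  needed to localize peaks within ±0.05 Hz.
* The covariance stationarity series is detrended by a running median
  (window = 2 × minimum chunk length) before the median + 3 × IQR peak
  rule. A global scale estimate fails when a source switches on partway
  through a recording: the series becomes bimodal and the global IQR
  swallows the onset spike. The local baseline makes the rule sensitive to
  isolated spikes in either regime while rejecting the heavy-tailed
  fluctuation of epoch-level covariance estimates.

## What the synthetic generator emulates — and what it does not

`pink_background()` produces independent unit-variance 1/f Gaussian
channels via exact frequency-domain shaping; `add_noise_sources()` adds
sinusoids with optional linear frequency drift, amplitude ramps, activity
windows, and abrupt topography switches, projected through channel-weight
vectors. `standard_fixtures()` calibrates source amplitudes by a one-shot
linear solve so the raw noise/surroundings ratio hits a stated target:
ratio ≈ 6 for the stationary and drifting scenarios (the EEG-like regime),
ratio ≈ 500 for the 64-channel MEG-like scenario, and ratio ≈ 30 for the
nonstationary scenarios (switching topography, a source active only in the
second half). The larger value for the nonstationary cases is deliberate:
a sinusoid at ratio $R$ carries only about $R/60$ of the power in the
±3 Hz segmentation band, so at ratio 6 a topography switch is invisible to
1 s covariance estimates — the nonstationarity machinery is exercised in
the strong-noise regime it was designed for, while detection and cleaning
are exercised at EEG-like contamination.

Real recordings differ in ways the generator does not model: correlated
background across channels, non-sinusoidal noise waveforms (harmonics-rich
line noise), slow amplitude modulation of the mains, gradual (rather than
abrupt) topography changes, and transient broadband artifacts. Passing
tests on the fixtures therefore demonstrate the mechanics of detection,
segmentation, decomposition and adaptation under controlled ground truth —
not cleaning quality on any particular real dataset, which should always
be verified from the diagnostic figures.

## Problem sizes and degenerate inputs

The shipped tests and the acceptance script work at 24–64 channels,
300 s, 250 Hz — enough that every spectral quantity reaches the
resolution the thresholds assume (0.05 Hz-scale bands need ≳ 30 s
windows) while a full run stays in the seconds range. Recordings shorter
than one minimum chunk, single-channel data, non-finite values, and
configurations with inverted ranges are rejected up front with classed
errors; a recording in which no outlier frequency is found is returned
unchanged with an empty report.

## Known limitations

* Harmonics are handled inside the smoother and the bias covariance, not
  scheduled as separate cleaning frequencies; strong harmonics above
  `maxfreq` are only removed insofar as the smoother nulls them.
* At high sampling rates many harmonics fall below Nyquist and the
  decomposition problem hardens; resampling to ~250–350 Hz first (the CLI
  `--resample` flag) is recommended.
* The EDF writer quantizes to 16 bits over each channel's amplitude range.
* Rank preservation is algebraic, not informational: removed components
  are genuinely gone from the noise band.
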