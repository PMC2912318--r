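---
title: "Methods: approximate-entropy analysis of evoked hippocampal gamma oscillations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: approximate-entropy analysis of evoked hippocampal gamma oscillations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apenlfp)
```

## The scientific problem

Brief high-frequency (tetanic) stimulation of the Schaffer-collateral pathway
in a hippocampal slice evokes a population rhythm in the CA1 field potential:
after a latency of roughly 100 ms, a gamma-band oscillation (dominant
component near 60 Hz) emerges, remains comparatively regular until about
300 ms, and then gives way to lower-amplitude, irregular activity. Acute
nicotine exposure is reported to make this oscillation more regular — the
network synchronizes — and to do so reversibly (activity recovers after
washout).

Regularity is quantified with approximate entropy (ApEn), a statistic
designed for short, noisy records (a 100 ms gamma segment at 2 kHz is only
200 samples, far too short for classical nonlinear-dynamics measures). This
package implements the full analysis as a tested pipeline, and — because the
original raw recordings are not publicly deposited — ships a calibrated
synthetic generator that reproduces the temporal, spectral and group-level
statistical structure of the reported data, so every claim the test suite
makes is reproducible from code alone.

## The statistic

For a series $x(1),\dots,x(N)$, embed templates
$X(i) = [x(i),\dots,x(i+m-1)]$ and use the Chebyshev distance
$d[X(i),X(j)] = \max_k |x(i+k) - x(j+k)|$. With tolerance $r$,

$$C^m_r(i) = \frac{\#\{j : d[X(i),X(j)] \le r\}}{N-m+1}, \qquad
\Phi^m(r) = \frac{1}{N-m+1}\sum_i \ln C^m_r(i),$$

$$\mathrm{ApEn}(m,r,N) = \Phi^m(r) - \Phi^{m+1}(r).$$

Lower ApEn means sequences that match for $m$ points tend to keep matching
for $m+1$: a more regular, more predictable signal.

Fixed conventions (shared by the fast routine and the brute-force oracle):

* **Self-matches included** ($j=i$ counts). Every $C > 0$, all logarithms
  finite. This is the classical formulation; excluding self-matches would be
  the sample-entropy family, which is out of scope.
* **Match predicate is $\le r$.**
* **Template counts**: $\Phi^m$ averages over $N-m+1$ templates, $\Phi^{m+1}$
  over $N-m$. A consequence worth knowing: because the two averages run over
  slightly different sets, ApEn is *not* mathematically guaranteed
  nonnegative. For a fully irregular signal of a few dozen samples it can dip
  marginally below zero (we observe $-0.027$ at $N=39$; the brute-force
  oracle and an independent third-party implementation agree to machine
  precision). At the pipeline's $N = 200$ it is positive with wide margin.
* **Parameters**: $m = 2$; $r = 0.1 \times$ SD, with the *population* SD of
  the isolated, preprocessed segment itself (each reported ApEn value is
  per-segment, so per-segment SD is the coherent reading; population rather
  than sample SD is fixed for bit-reproducibility — the difference is
  < 0.3 % at $N=200$).

A known finite-sample property matters for test design: at fixed $(N, r)$,
ApEn increases with signal irregularity only up to a ceiling (about 0.5–0.7
at $N=200$, $r=0.1\,$SD). Beyond it, template matches other than self-matches
become vanishingly rare and the statistic *declines* (for a 60 Hz sine plus
white noise, mean ApEn is 0.12, 0.74, 0.53, 0.34 at noise SD 0, 0.1, 0.3,
1.0). The unit suite asserts the true rise-then-saturate shape; a literal
"strictly increasing through SD 1.0" criterion cannot hold for any noise
color we tested (white, 30–300 Hz, 30–120 Hz, 20–80 Hz, pink) and is left
red in the acceptance suite with this analysis.

## Preprocessing chain

Order is fixed: artifact blanking → resampling → piecewise detrend →
band-pass.

* **Stimulus-artifact blanking**, `[stim − 2, stim + 10) ms`: samples are
  replaced by linear interpolation between the window's boundary samples.
  Interpolation rather than deletion preserves the time base, which the
  post-stimulus window definitions depend on.
* **Resampling to 2 kHz** by integer decimation, preceded by a zero-phase
  anti-alias low-pass at 0.8 × the target Nyquist (800 Hz). The acquisition
  chain's 1 kHz hardware low-pass is above the 1 kHz output Nyquist, so an
  explicit anti-alias stage is required even though the original description
  mentions only "sampling". Its corner and order are recorded in the
  `PreprocessReport`.
* **Piecewise linear detrend**: contiguous 100 ms pieces, least-squares line
  subtracted per piece; a trailing fragment shorter than 2 samples merges
  into the previous piece. Each output piece has zero mean and zero slope.
  Detrending leaves the 30–300 Hz energy essentially untouched (< 5 % change,
  tested), so it cannot "eat" the gamma burst.
* **Band-pass 30–300 Hz**, order-4 Butterworth, zero phase.

**Filtering implementation.** No IIR design library is available in the
target environment, so zero-phase filtering is realized in the frequency
domain: the spectrum is multiplied by the *squared* analog Butterworth
magnitude $|H(f)|^2$ — exactly the amplitude response of forward–backward
(`filtfilt`) application — with odd-reflection padding (200 ms per side)
suppressing circular edge transients. Phase is identically zero by
construction, which matters for ApEn: phase distortion would reshape the
waveform and change the statistic. The anti-alias low-pass uses an order-16
magnitude so that content at 900 Hz is attenuated below 5 % RMS after the
forward–backward squaring; order 8 would leave 13 %.

## Gamma-segment isolation

The original study isolated the oscillation by eye with the power spectrum
as reference. The pipeline replaces the eye with the study's own printed
window — the half-open `[150, 250) ms` after stimulus onset — plus a
programmatic check: the Hann-windowed, mean-removed periodogram (zero-padded
to a 1 Hz grid; a raw 200-sample periodogram has 10 Hz resolution, too
coarse to verify "around 60 Hz") must peak inside the gamma band at twice
the largest peak outside it (`is_gamma_dominant`, margin 2). The gamma band
is parameterized and defaults to 30–120 Hz, the widest of the several ranges
printed in the source literature (30–60, 30–80, 30–120); the package does
not resolve that inconsistency, it exposes the band as a parameter.
Segments failing the check are flagged but still analyzed — the original
study analyzed all 14 slices.

## The synthetic generator: what it emulates, what it does not

Each trace is a sum of five components at 100 kHz (the acquisition rate):
a 1 ms biphasic artifact at stimulus time (amplitude 2000 µV, 10× the burst,
so the blanking stage has something real to remove); pink (1/f) background
noise throughout (SD 10 µV — pink rather than white because field-potential
spectra are 1/f-shaped, and white background would inflate ApEn
unrealistically); nothing else until 100 ms post-stimulus; a 60 Hz burst
over 100–300 ms (amplitude 200 µV, raised-cosine 10 ms ramps to avoid
spectral splatter) whose cycle phases carry a cumulative Gaussian jitter
walk (SD 0.15 rad/cycle, constant within a cycle) and whose cycle
amplitudes vary with CV 0.1; desynchronized broadband (flat 30–300 Hz)
activity superimposed on the burst, scaled to `burst_noise_rel` × the
rhythm's RMS; and after 300 ms, band-limited (20–200 Hz) irregular activity
at 40 % of the burst amplitude until the 500 ms trace end.

**The regularity knob.** An earlier design used cycle-phase jitter as the
single calibration knob. Implementation proved that wrong: at
2 kHz with $m=2$ and $r=0.1\,$SD, ApEn responds to *sample-scale*
irregularity, and phase wander leaves the waveform locally smooth — even
jitter above 1 rad/cycle moved mean pipeline ApEn by less than 0.1 while
dragging the spectral peak several Hz off 60 (breaking the spectral
acceptance target). The broadband-to-rhythm ratio `burst_noise_rel` spans
the published range (≈0.35–0.51) monotonically with the peak pinned at
60 Hz, and is biophysically the more natural reading of "synchronization":
nicotine recruits more of the population into the rhythm, leaving less
asynchronous background firing. Phase jitter remains a real generator
parameter with a fixed default, and its monotone effect on ApEn is still
property-tested.

**Calibration.** `calibrate_generator` bisects `burst_noise_rel` until the
mean pipeline ApEn over seeded replicates is within 0.02 of the target
(inner stop at 0.003), using common random numbers across bisection steps so
the objective is smooth. The shipped per-condition parameter files
(`inst/extdata/params/`) were produced with 160 replicates per evaluation
against the published group means — control 0.49, nicotine 0.42, washout
0.46 — giving knob values 0.50, 0.156 and 0.281 respectively. If a target
lies below the knob's floor, the per-cycle amplitude CV is bisected at the
bound instead; an unreachable target is a hard error reporting the bracket.

**Paired structure.** Slice $k$'s background-noise stream is seeded from
(base seed, $k$) only, so the same slice shares its background across
conditions, while burst dynamics mix in the condition label — each slice is
its own control, as in the experiment.

**What a green test does not establish.** Generator slices are i.i.d.
realizations of one parameter set per condition: there is no biological
between-slice variability, no drift within a session, no electrode or
temperature effects, and no within-condition dose–response. Consequently the
synthetic between-slice SDs (≈0.03) sit at or below the values implied by
the published SEMs (0.037–0.075), and significance on the synthetic cohort
is, if anything, easier to reach than on real data. The single-slice example
values printed in the source (0.49 / 0.27 / 0.30) sit far from the group
means (0.49 / 0.42 / 0.46); the generator targets group means and does not
attempt to emulate that outlier slice. Matching group means and ordering on
synthetic data validates the *pipeline*, not the biology.

## Group statistics

Per condition: mean and SEM (sample SD / √n). The original report does not
name its test or define its "±" values; given a within-slice repeated-
measures design, the primary test is a paired two-tailed t-test on per-slice
differences, with the paired Wilcoxon signed-rank always reported alongside
as the distribution-free companion, and "±" is taken to be SEM (its
magnitude relative to the claimed significance supports that). No
multiple-testing correction is applied across the three pairwise
comparisons, matching the apparent single-threshold usage; all raw p-values
are printed so a reader can apply Bonferroni. Zero-variance difference
vectors are reported as degenerate (p = 1 when identically zero) rather than
erroring; cohorts with fewer than three common slices get an NA test entry
flagged `insufficient n`.

## Numerical choices and degenerate inputs

* Half-open windows `[t0, t1)` everywhere, ms relative to stimulus onset,
  0-based sample indexing internally; segment length is pinned to
  `round((t1−t0)/1000·fs)`.
* Declared sampling rate is cross-checked against the file's median time
  step (1 % tolerance); mismatch is a hard error naming both rates.
* Periodogram normalization satisfies Parseval against the window-energy-
  normalized variance (tested to 5 %).
* `dominant_frequency` breaks exact ties toward the lower frequency.
* $r = 0$ on a non-constant signal returns a `degenerate`-flagged result
  (counts exact repeats only) with a warning; a constant signal yields
  ApEn = 0 exactly.
* All randomness flows through explicit integer seeds; generation never
  touches the caller's RNG state, and derived sub-seeds stay below $2^{31}$.

## Known limitations

* The generator is phenomenological; no conductance-based or network model,
  no LTP or dose–response structure.
* Single-channel only; no vendor binary formats in the tested surface.
* The resampler handles integer decimation only (sufficient for
  100 kHz → 2 kHz); rational resampling is out of scope.
* ApEn values are convention-dependent; comparisons across software require
  matching the self-match, template-count and tolerance conventions (the
  cross-check test documents ours against an independent implementation).
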