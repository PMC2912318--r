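# apenlfp

Approximate-entropy analysis of stimulus-evoked hippocampal gamma
oscillations.

Tetanic (100 Hz) stimulation of the Schaffer-collateral pathway in a
hippocampal slice evokes a gamma-band (~60 Hz) field-potential oscillation
between roughly 100 and 300 ms post-stimulus. Acute nicotine exposure makes
that oscillation more regular — the CA1 network synchronizes — and the
effect reverses on washout. `apenlfp` implements the complete analysis that
quantifies this with approximate entropy (ApEn), for electrophysiologists
and methods researchers who want the pipeline reproducible end to end:

* **`synthetic_lfp`** — a seeded, calibrated generator of evoked LFP traces
  with the reported temporal structure (≥100 ms latency, regular 100–300 ms
  gamma burst, irregular tail) and condition-dependent regularity
  (control / nicotine / washout, paired by slice);
* **`preprocess`** — stimulus-artifact blanking, anti-aliased decimation to
  2 kHz, piecewise linear detrending, zero-phase 30–300 Hz Butterworth
  band-pass;
* **`gamma_segment`** — isolation of the 150–250 ms post-stimulus window
  with spectral verification (Hann periodogram on a 1 Hz grid, dominant
  frequency, gamma-dominance check);
* **`apen_core`** — ApEn from scratch with the classical conventions
  (self-matches, ≤ r, m = 2, r = 0.1 × SD) plus a brute-force O(N²) oracle;
* **`group_stats`** — per-condition means ± SEM and paired two-tailed t /
  Wilcoxon signed-rank comparisons.

## The statistic

For a series *x*(1)…*x*(N), templates *X*(i) = [*x*(i), …, *x*(i+m−1)] match
when their Chebyshev distance is ≤ r. With
C<sup>m</sup><sub>r</sub>(i) the matching fraction (self-match included) and
Φ<sup>m</sup>(r) the mean of ln C<sup>m</sup><sub>r</sub>(i),

ApEn(m, r, N) = Φ<sup>m</sup>(r) − Φ<sup>m+1</sup>(r),

the average log conditional probability that close length-m sequences stay
close at length m+1. Lower ApEn = more regular signal. Parameters here:
m = 2, r = 0.1 × SD of the analyzed segment.

## Worked example

```r
library(apenlfp)

# a 14-slice simulated cohort with the shipped calibrated parameters
report <- run_pipeline(pipeline_config(), cohort_spec(n_slices = 14, base_seed = 1))
report
```

```
<lfp_comparison_report> 14 slices x 3 conditions
  control   ApEn = 0.487 +/- 0.008 (SEM, n = 14)
  nicotine  ApEn = 0.415 +/- 0.010 (SEM, n = 14)
  washout   ApEn = 0.467 +/- 0.007 (SEM, n = 14)
  nicotine_vs_control    mean diff -0.0727, t = -5.003, p_t = 0.000242, p_wilcoxon = 0.00137
  nicotine_vs_washout    mean diff -0.0527, t = -3.909, p_t = 0.0018, p_wilcoxon = 0.00695
  control_vs_washout     mean diff +0.0201, t = 2.096, p_t = 0.0562, p_wilcoxon = 0.0516
```

Read: complexity drops under nicotine (0.487 → 0.415, paired p ≈ 2×10⁻⁴, the
network synchronizes) and largely recovers on washout (0.467, not
significantly different from control at the 0.05 level). Per-slice values,
tolerances, spectral QC flags and the config snapshot are in
`report$per_slice` and `report$pairwise`; `write_report()` serializes it all
to JSON + CSV.

One trace at a time:

```r
rec <- generate_recording(synth_params(), "control", "slice01", seed = 1)
pp  <- preprocess(rec, pipeline_config())
seg <- isolate_gamma_segment(pp$recording)          # [150, 250) ms, 200 samples
dominant_frequency(power_spectrum(seg))             # 61  (Hz, ~60 Hz gamma)
approximate_entropy(seg, apen_params(m = 2, r_coeff = 0.1))
#> ApEn(m = 2, r = 16.0737, N = 200) = 0.5061
#>   Phi^m = -4.207404, Phi^(m+1) = -4.713463
```

## Command line

```sh
Rscript inst/scripts/apenlfp-cli.R simulate --out-dir traces --n 14 --seed 1
Rscript inst/scripts/apenlfp-cli.R pipeline --in traces --out report.json
# or in one step:
Rscript inst/scripts/apenlfp-cli.R pipeline --simulate --n 14 --seed 1 --out report.json
```

On-disk format: `<name>.csv` (`time_ms,voltage_uV`) plus a flat JSON sidecar
(`fs`, `stim_time_ms`, `condition`, `slice_id`).

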