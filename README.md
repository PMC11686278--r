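# estrocal

Quantitative pipeline for studying how ovarian estrogen state shapes binge
alcohol drinking and BNST CRF neuron physiology in female mice. The package
implements, as tested and reusable R functions, the five analysis stages
such a study runs, plus a synthetic-data module that generates every input
with known ground truth so the whole pipeline is testable without any
external downloads:

1. **Fiber-photometry preprocessing** — two-channel (465 nm GCaMP / 405 nm
   isosbestic) traces sampled at 1017.25 Hz are median-filtered, zero-phase
   lowpass filtered, trimmed (150/400/1000 s for EPM/OF/DID assays),
   block-mean downsampled (×100), motion-corrected by subtracting the best
   linear fit of the isosbestic channel, and z-scored over the whole trace.
2. **Lickometer bout analysis** — drinking bouts are ≥ 2 TTL pulses with
   inter-lick intervals ≤ 1 s spanning ≥ 0.5 s; "motivated" bouts exceed
   1 s. Peri-bout alignment extracts the 10 s of z-scored GCaMP signal
   following each bout onset. Intake is leak-adjusted and
   bodyweight-normalized (g/kg).
3. **Calcium-transient statistics** — DID sessions are segmented into the
   last 30 min of W1, first/last 30 min of EtOH, and first 30 min of W2;
   transients are detected as MAD-thresholded, prominence-screened local
   maxima; per-epoch amplitude distributions are normalized to the W1
   epoch's total event count and summarized by trapezoidal AUC and peak
   location.
4. **Slice-ephys pharmacology** — spontaneous PSC streams yield frequency,
   amplitude, and synaptic drive (frequency × amplitude); per-minute
   percent-of-baseline time courses; responder classification (≥ 15% mean
   wash-on delta OR ≥ 50% single-minute delta); 20% access-resistance QC.
5. **LC-MS/MS calibration** — 1/C-weighted linear calibration of
   analyte/internal-standard peak-area ratios, back-calculation, and LLOQ
   determination (lowest level with mean accuracy 80–120% and CV < 20%)
   over a two-fold serial dilution design (14 standards including a blank).
6. **Receptor expression fractions** — fraction of cells (or of a
   gene-defined subpopulation such as Crh+ neurons) expressing Esr1, Esr2,
   or Gper1 in a sparse genes × cells count matrix (MatrixMarket trio),
   with positivity at count > 0.
7. **Statistics** — paired/Welch t-tests, Pearson correlation, and
   Holm–Sidak step-down adjustment
   (p̃₍ᵢ₎ = max cummax 1 − (1 − p₍ᵢ₎)^(m−i+1)).

## Worked example

Simulate a lickometer session with three scheduled bouts, detect and
summarize them, and normalize a day's intake:

```r
library(estrocal)

sched <- data.frame(onset = c(10, 30, 55), n_licks = c(6, 3, 9))
licks <- simulate_licks(sched, seed = 42)
(bouts <- detect_bouts(licks))
#>   onset   offset n_licks duration
#> 1    10 13.63817       6 3.638171
#> 2    30 31.37898       3 1.378979
#> 3    55 59.66078       9 4.660777
summarize_bouts(bouts)
#>   n_bouts n_motivated time_in_bout mean_bout_duration
#> 1       3           3     9.677928           3.225976
normalize_intake(1.2, 0.2, 0.025, "EtOH")
#> [1] 6.312
```

All three scheduled bouts are recovered exactly; each lasts over 1 s, so
all three count as motivated drinking. The intake call converts a 1.2 g
bottle loss, corrected for a 0.2 g dummy-bottle leak, into 6.312 g ethanol
per kg bodyweight for a 25 g mouse drinking 20% (v/v) ethanol.

A photometry session runs the same way: `simulate_photometry()` returns a
two-channel session plus its ground truth, `preprocess()` produces the
motion-corrected z-trace, `detect_transients()` finds events, and
`amplitude_distribution()` / `summarize_distribution()` compute the
W1-normalized AUC and peak statistics.

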