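---
title: "Models and methods behind estrocal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind estrocal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(estrocal)
```

`estrocal` packages the quantitative stages of an estrous-cycle /
binge-drinking study: fiber-photometry preprocessing, lickometer bout
analysis, calcium-transient distribution statistics, slice-ephys
pharmacology metrics, weighted calibration-curve quantification, and
single-nucleus receptor expression fractions. This vignette records the
models each stage assumes, the parameters that matter, the numerical
choices made where the design was genuinely open, and what the synthetic
data can and cannot establish about real recordings.

## Photometry preprocessing

The raw session is two channels sampled at 1017.25 Hz: 465 nm excitation
(GCaMP, calcium-sensitive) and 405 nm excitation (isosbestic,
calcium-insensitive). Both carry photobleaching, motion artifacts, and
sensor noise; only the 465 channel carries calcium transients. The
pipeline runs, in order:

1. **Denoise** at the acquisition rate: a running median (default window 5
   samples) removes single-sample electrical artifacts, then a
   second-order Butterworth lowpass (default 3 Hz) removes high-frequency
   noise. The lowpass is applied forward–backward (zero phase) so
   transient onsets are not delayed; the trace is demeaned and
   odd-reflection padded first so the filter's zero initial conditions
   cannot leak edge transients into the data. Neither the window nor the
   cutoff is dictated by the recording hardware; 5 samples (~5 ms) and
   3 Hz were chosen for GCaMP6s bandwidth (decay τ ≈ 1.5 s, so signal
   power lives well below 1 Hz) and both are configurable and recorded in
   the provenance.
2. **Trim** the start: 150 s (EPM), 400 s (OF), or 1000 s (DID), the
   segments contaminated by transfer to the apparatus and bottle changes.
3. **Downsample** by block means (default factor 100, effective rate
   ≈ 10.17 Hz). Block averaging rather than decimation buys an extra
   ~10× noise-variance reduction.
4. **Motion-correct**: ordinary least squares of the 465 channel on the
   405 channel; the fitted component (slope · 405 + intercept) is
   subtracted. Because both channels share the same motion trace and
   bleach similarly, the fit removes what they share; the residual keeps
   the transients. The fit is computed on the downsampled channels —
   statistically equivalent at these bandwidths and 100× cheaper than
   fitting at the acquisition rate.
5. **z-score** over the whole analyzed trace, with the sample standard
   deviation (denominator *n* − 1). At these trace lengths the ddof
   convention is numerically irrelevant, but it is fixed and documented
   because it changes values at small *n*.

The residual of step 4 is exactly uncorrelated with the regressor by
construction, and the whole-trace z-score satisfies mean 0 / sd 1 to
1 × 10⁻⁹ — both are asserted for every processed trace in the test suite.
On simulated sessions with motion sd twice the noise sd, the variance
explained by the ground-truth motion trace drops by ~98% after
correction (100-session average, `scripts/acceptance.R`).

**Timing caveat.** Zero-phase smoothing of an asymmetric
(instant-rise, exponential-decay) transient plus block-mean time stamps
shifts the apparent peak ~1–2 effective samples (~0.1–0.2 s) after the
true onset. This is a deterministic property of the filter chain, common
to every epoch and condition, so within-session comparisons are
unaffected. The tests therefore check that the detector lands on the
processed trace's own local maximum to within one effective sample, and
separately bound the total onset-to-peak latency at 0.3 s.

## Bout detection

Licks are clustered greedily: consecutive licks with inter-lick interval
≤ 1.0 s (inclusive) belong to one cluster; clusters with ≥ 2 licks
spanning ≥ 0.5 s are bouts. "Motivated" bouts are those strictly longer
than 1 s — the detection minimum and the motivated filter are deliberately
two separate parameters, since both definitions are used in different
analyses. A bout belongs to an epoch if its *onset* falls inside it; this
makes epoch totals additive over a partition of the session even when a
bout straddles a boundary. The greedy clustering is proven equivalent to
exhaustive enumeration of all maximal qualifying lick runs on 1,000 random
trains in the test suite.

Fluid intake normalization treats fluid density as 1 g/ml when converting
bottle weight loss to volume (the solutions are 20% v/v ethanol or 1% w/v
sucrose in water; the approximation is < 1% off for these), uses
0.789 g/ml for ethanol, clamps the dummy-bottle leak correction at zero,
and divides by bodyweight.

## Transient detection and distribution statistics

Detection operates on the z-trace. The noise scale is the MAD (scaled by
1.4826), robust against the transients themselves inflating the estimate.
A sample is an event peak if it is a local maximum exceeding
`median(z) + k_mad × noise` **and** its topographic prominence — height
above the higher of the two minima separating it from taller terrain —
also exceeds `k_mad × noise`. The prominence screen is what rejects noise
bumps riding the decay shoulder of a larger transient; without it, any
height threshold low enough to be sensitive admits shoulder-riders at an
unacceptable false-discovery rate. Peaks closer than 1 s keep only the
larger (GCaMP6s decay makes faster separations unresolvable at ~10 Hz
effective sampling). Event amplitude is the peak value minus the 10th
percentile of the preceding 5 s, a local baseline that tolerates slow
residual drift. Detection is invariant to adding a constant to the trace.
The default `k_mad = 2.5` is a permissive screening threshold; the
simulation studies in the tests and acceptance script run at
`k_mad = 3.5`, the operating point at which events ≥ 5× the sensor noise
sd are recovered with sensitivity ≥ 0.95 and FDR ≤ 0.05.

The DID session is segmented into four 30-min epochs: the last 30 min of
W1, the first and last 30 min of EtOH, and the first 30 min of W2.
Amplitude distributions use half-open bins of width 0.5 z over [0, 10] z
(unstated in the original workflow; configurable). Each epoch's per-bin
counts are divided by the *total* event count of the same day's W1 epoch,
so the reference distribution sums to 1, a pure rate increase raises an
epoch's total (and AUC) above 1 without moving the distribution's peak,
and a pure amplitude increase shifts the peak without inflating the
total. This is the reading of "normalized to the W1 distribution" that
makes the AUC and peak statistics dissociate rate from amplitude effects;
the alternative per-bin-ratio normalization is available behind
`per_bin_ratio = TRUE`. AUC is the trapezoidal integral over bin centers;
the peak is the argmax bin's center with ties broken toward the lower
amplitude (arbitrary, documented).

## PSC pharmacology

Event streams are (time, amplitude) lists with baseline / wash / washout
window annotations. Frequency is count/duration; synaptic drive is
frequency × mean amplitude; an empty window reports frequency 0 with
amplitude flagged undefined rather than zero. Time courses express each
1-min bin as percent of the baseline-window mean. A cell is a responder
if the mean wash-on deviation from 100% is ≥ 15 points OR any single
wash-on minute deviates ≥ 50 points — both thresholds inclusive, applied
to the frequency metric. When the two rules disagree in sign (possible
with an extreme single minute opposing the mean), the direction follows
the criterion with the larger absolute deviation; the rule never
addresses this case explicitly, so the choice is documented here.
Recordings whose access resistance changes by more than 20% relative to
the first measurement are excluded; the first measurement is the
reference because no other reference is specified.

## Calibration and LLOQ

Calibration fits are weighted least squares of the analyte /
internal-standard peak-area ratio on nominal concentration with weight
1/C per replicate point (per-level-mean fitting is available behind a
flag). The blank is excluded from the fit — its weight is undefined — but
participates in the serial-dilution design: the default is a 4 ng/ml high
standard diluted two-fold into 14 standards including the blank, whose
lowest nonzero level is 4/2¹² ng/ml ≈ 0.98 pg/ml. Back-calculation
inverts the line; values below the fitted blank response are returned
as-is with a flag. The LLOQ is the smallest level whose back-calculated
replicates have mean accuracy within [80%, 120%] (inclusive) and CV
strictly below 20%; levels with one replicate are skipped with a warning
because CV is undefined there. Accuracy is evaluated against the full
fit, not a leave-one-level-out refit. On proportional-noise simulations,
1/C weighting cuts low-concentration back-calculation RMSE by an order of
magnitude relative to the unweighted fit (the acceptance script measures
the ratio).

## Expression fractions

Positivity is raw count > 0. The upstream normalization a single-cell
pipeline applies is column-wise (per cell), and any column scaling leaves
count > 0 unchanged — a property asserted in the tests — so presence /
absence fractions are identical before and after normalization, which is
why this is the defensible reading absent a stated threshold. Duplicate
gene symbols resolve to the first occurrence with a warning. Conditional
fractions (e.g. Esr1 within Crh+ cells) satisfy
P(A | B) · P(B) = P(A ∧ B) exactly.

## Statistics

Holm–Sidak: sort raw p ascending, apply 1 − (1 − p₍ᵢ₎)^(m−i+1), enforce
monotonicity with a running maximum, restore input order, and clamp at
the raw p to protect the adjusted ≥ raw contract against 1-ulp rounding
when the exponent is 1. Unpaired comparisons default to Welch's
unequal-variance form — the safe choice when variance equality is checked
case-by-case upstream — and its type-I error is verified at 0.05 ± 0.01
under an unequal-variance null. Paired comparisons with zero-variance
differences are flagged degenerate instead of returning an infinite
statistic. ANOVA and mixed-effects families are out of scope; the
`adjust_family()` helper applies Holm–Sidak to externally computed
p-value families.

## The synthetic-data module

The generators define the study conditions the pipeline is tested under:

* **Photometry**: Poisson transient times (piecewise-constant rate per
  access period, default 6 events/min), lognormal amplitudes
  (mean 5, sd 1.5 in raw fluorescence units by default), instant-rise /
  exponential-decay kernel (τ = 1.5 s, GCaMP6s-like), shared motion =
  0.5 Hz-lowpassed Gaussian noise with channel-specific gain,
  single-exponential bleach toward an asymptote, and white sensor noise.
  Determinism is per-call: one seeded generator, no global state.
* **Licks**: within-bout intervals uniform on
  [max(0.15, 0.5/(n−1)), 0.95] s, so every scheduled bout is detectable
  by construction; schedules whose realized bouts would close a 1 s gap
  raise an error rather than silently merging.
* **PSC streams**: homogeneous Poisson with a multiplicative rate step
  during the wash window (the E2-like condition multiplies by 3.55; the
  ERα-antagonist-like condition by 0.515), lognormal amplitudes.
* **Calibration**: ratios Normal(slope · C + intercept, cv · mean) —
  proportional noise, the error structure 1/C weighting addresses.
* **Counts**: per-gene Bernoulli detection at the target prevalence
  (0.293 / 0.067 / 0.003 for Esr1 / Esr2 / Gper1 at single-nucleus
  scale), 1 + Poisson positive counts, independent across genes.

What the simulations do **not** emulate: hemodynamic or spectral
structure in the motion and noise (the real artifact spectra are not
characterized, so defaults are stand-ins exposed as parameters);
correlated gene expression (the count generator is independent across
genes, so within-population fractions equal marginals by construction);
bursty or rate-modulated PSC streams beyond the step; indicator
saturation and dye kinetics. Passing tests therefore establish that the
*algorithms* meet their contracts under the stated generative
assumptions, not that the defaults are optimal for any particular rig.

## Problem sizes and determinism

The test suite and acceptance script size their simulations to run on a
single CPU in a couple of minutes while keeping Monte-Carlo error well
inside the asserted bounds: 100 × 120 s sessions for the
motion-correction study (sampled at 101.725 Hz with downsample factor 10,
which preserves the ~10.17 Hz effective rate of the full-scale 1017.25 Hz
/ ×100 configuration), 3 × 600 s sessions for detector operating
characteristics, one 12,600 s DID session per distribution study, 1,000
lick trains and 10,000 responder time courses against brute-force
oracles, and 10,000 null replicates for test calibration. Every
stochastic quantity flows through an explicit integer seed.
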