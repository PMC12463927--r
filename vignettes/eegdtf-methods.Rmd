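---
title: "Methods: band power, directed transfer function connectivity and group statistics for resting-state EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: band power, DTF connectivity and group statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegdtf)
```

## Scope

`eegdtf` implements a complete two-cohort resting-state EEG analysis:
preprocessing, Welch band power in the delta (1–4 Hz), theta (4–7 Hz) and
alpha (8–13 Hz) bands, directed functional connectivity by the directed
transfer function (DTF) over per-epoch multivariate autoregressive (MVAR)
models with phase-randomization surrogate thresholding, a normality-routed
two-group statistics layer with false-discovery-rate control, and a
synthetic EEG generator with known ground truth against which every stage
is validated. The intended study design is a comparison of a mild cognitive
impairment (MCI) cohort against age-matched normal controls (NC), with
MoCA cognitive scores available per subject, but nothing in the code is
specific to that contrast beyond the two group labels.

## Preprocessing

The chain is: common average reference → zero-phase Butterworth band-pass
(1–30 Hz) → segmentation into non-overlapping 5-s epochs → per-epoch
baseline correction, in that order.

* **Average reference** subtracts the instantaneous mean across channels.
  It is idempotent and annihilates any signal component common to all
  electrodes. A consequence that matters downstream: the referenced
  channels sum to exactly zero at every sample, so the data matrix has
  rank *k* − 1.
* **Band-pass**: a Butterworth filter of order 4 per pass applied forward
  and backward (`signal::filtfilt`), giving zero phase and an effective
  8th-order magnitude response. Channels are demeaned before filtering so
  DC offsets cannot excite edge transients. The order is a package choice;
  4th order is standard EEG practice — steep enough at the 30 Hz edge
  without ringing.
* **Epoching** uses the floor rule (trailing remainder discarded); a 5-min
  recording at 250 Hz yields exactly 60 epochs of 1250 samples.
* **Baseline** is the per-epoch, per-channel mean: in continuous resting
  data, the epoch itself is the only baseline available. Whether baseline
  correction should instead span the continuous record is undecidable from
  typical methods descriptions; per-epoch correction was chosen because it
  also removes slow drift that survives the 1 Hz edge.
* **Artifact removal** (ICA or otherwise) requires manual component
  labeling and is deliberately *not* implemented; `preprocessRecording()`
  accepts a `cleaner` hook (a function `EEGRecording -> EEGRecording`)
  through which an external cleaner can be inserted after filtering.

## Welch band power

`welchPsd()` estimates a one-sided spectral density per channel by
averaging modified periodograms over 2-s Hamming-windowed segments with
50% overlap, pooled over all epochs (0.5 Hz resolution, at least three
segments per 5-s epoch). Scaling is the standard density convention: the
integral of the PSD over frequency recovers the signal variance (checked
to 5% for broadband inputs, and to 2% for a pure tone whose integrated
power must be A²/2).

`bandPower()` averages the in-band bins under a half-open convention
`lo ≤ f < hi`, so the 4 Hz bin belongs to theta and not to delta. The
*mean* (not the integral) over bins is used: it is invariant to frequency
resolution, and group contrasts are unaffected by the choice. Absolute
(not relative) power is analysed.

## MVAR models and the directed transfer function

Each 5-s epoch is modelled as an order-*p* vector autoregression

  X(t) = Σₙ Aₙ X(t−n) + e(t)

fitted by ordinary least squares on stacked lagged regressors. The default
order is *p* = 2; `selectOrderBIC()` implements the selection criterion
BIC(p) = log det Σ̂ₚ + k²p·log(N)/N and recovers the generating order on
simulated processes. The residual covariance uses the maximum-likelihood
scaling.

**Rank deficiency.** Because average-referenced channels sum to zero, the
lagged regressor matrix is singular *by construction* on preprocessed
data. The connectivity stage therefore uses the SVD minimum-norm
least-squares solution, the conventional resolution for MVAR on
common-average-referenced EEG; `fitMVAR()` exposes the same behaviour via
`onDeficient = "minnorm"` while its default contract treats rank
deficiency as an error. For the same reason `selectOrderBIC()` uses the
pseudo-determinant (the product of positive eigenvalues) of the residual
covariance.

The spectral transfer matrix is H(f) = Ā(f)⁻¹ with
Ā(f) = I − Σₙ Aₙ e^(−i2πfn/fs) — the identity term is part of the
definition; without it the expression is not invertible-meaningful. The
normalized DTF is

  γ²ᵢⱼ(f) = |Hᵢⱼ(f)|² / Σₘ |Hᵢₘ(f)|²,

the share of total inflow into target *i* attributable to source *j*; each
target row sums to one at every frequency (asserted to 1e−10 in the test
suite). Entry `[i, j]` is flow *from j to i*. The scalar edge weight
DTF_Mean averages γ² over the in-band grid frequencies (0.5 Hz steps over
1–30 Hz by default, half-open band edges) and then over epochs —
per-epoch fitting is what makes the networks "dynamic". Because the band
average depends only on in-band frequencies, the implementation evaluates
H(f) only there; this is an algebraic identity, not an approximation.

An analytic route is kept alongside the estimation route:
`mvarModel()` wraps known coefficients so the DTF of a known process can
be computed exactly, and the test suite checks that the estimated DTF of a
simulated triangular system converges to the analytic DTF (max absolute
error below 0.05 at 5000 samples) with the structurally-zero reverse edge
below 0.02.

## Surrogate significance thresholding

Raw DTF values are positive by construction, so apparent edges need a
null. The null transformation is independent per-channel phase
randomization: FFT each channel, replace all non-DC/non-Nyquist phases
with uniform draws (conjugate symmetry preserved, DC and Nyquist kept
real), inverse FFT. Amplitude spectra are preserved exactly; all
cross-channel phase relations are destroyed. For each of `nSurrogates`
draws (default 1000), every epoch is randomized, the MVAR refit, and the
epoch-averaged DTF_Mean recomputed — the surrogate statistic mirrors the
observed statistic exactly, which is what makes the test exchangeable
under channel independence. The per-edge, per-band threshold is the sorted
surrogate value at rank ⌈(1−α)·n⌉ (rank 950 of 1000 at α = 0.05); observed
values strictly above the threshold are kept, ties and everything below
are set to zero, as is the diagonal.

Two caveats are documented deliberately. First, the null is built on the
epoch-averaged statistic (one null per subject–edge–band), not per epoch;
this matches the observed statistic and is the cheaper of the two
readings. Second, while each edge's exceedance probability is exactly
10/201 at 200 surrogates, edges that share one fit are positively
dependent, so the *pooled* false-positive fraction has roughly 1.5× the
binomial standard deviation; calibration checks should read the interval
accordingly.

The surrogate loop dominates the cost of the whole pipeline
(n_surrogates × n_epochs MVAR fits and complex k×k inversions per
subject), so it is implemented in C++ (RcppArmadillo, FFTW-backed
surrogate synthesis with cached plans, R's RNG for seeded
reproducibility). The exported R functions (`fitMVAR`,
`transferFunction`, `dtf`, `phaseRandomize`) are the reference
implementation; C++/R agreement is a unit test.

## Group statistics

For every unit (electrode × band, or directed edge × band):

1. **Routing**: Shapiro–Wilk on both groups and Levene's test
   (mean-centered, as in SPSS) on the pooled sample, all at α = 0.05.
   Student's *t* (pooled variance) with Cohen's *d* only when all three
   gates pass; otherwise Mann–Whitney *U* with Cliff's delta. Note the
   gates jointly pass with probability ≈ 0.95³ ≈ 0.86 even for ideal
   Gaussian samples — the parametric route dominates but cannot reach 90%.
2. **Effect sizes** use the MCI − NC sign convention (positive = MCI
   higher). The pooled-variance *t* is used rather than Welch's *t*: the
   Levene gate justifies pooling, and it reproduces printed
   summary-statistics *t* values exactly.
3. **FDR**: Benjamini–Hochberg within each family, where a family is all
   units of one band and one metric type (32 electrodes for band power;
   992 directed edges for DTF_Mean) — matching the per-band reporting
   granularity. Significance is q < 0.05.
4. **Chi-square** for 2×2 categorical tables is Pearson's without
   continuity correction.
5. **Correlations** between edge strength and MoCA are Pearson's *r* over
   all subjects pooled, reported with raw two-sided p (no multiplicity
   correction is applied to the correlation family; the family definition
   is left to the caller).

The group comparison runs on the **raw** DTF_Mean values; the thresholded
networks are computed and reported per subject but are not what enters the
test. Zeroing sub-threshold values first would make the group samples
0-inflated and tie-heavy, which the Mann–Whitney route handles poorly; the
raw-value reading is also the one consistent with graded effect sizes on
edges. `compareGroups(value = "thresholded")` restores the other reading
if wanted.

## The synthetic generator

`generateCohorts()` emulates the study design end to end: 32 electrodes
(the ten-twenty labels used throughout; the montage is configurable), 250
Hz, 5-minute recordings by default, n subjects per group, per-subject MoCA
scores drawn from NC 26.70 (1.38) and MCI 19.91 (2.98) truncated to
[0, 30].

Each channel is a sum of three unit-variance band oscillators plus white
noise (SD 0.5). An oscillator is a damped AR(2) resonator at the band
midpoint — chosen so the synthetic signals live inside the model family
the connectivity stage fits.

* **Band amplitudes** default to delta 1.3, theta 0.9, alpha 0.7,
  following the 1/f shape of resting spectra.
* **Pole radii** default to delta 0.95, theta 0.966, alpha 0.969: the slow
  delta rhythm is broad, alpha is the sharpest rhythm. For a free-standing
  oscillator, `makeOscillator()` scales the radius with the band width
  (`r = 1 − π·Δf/(2fs)`), which keeps at least 70% of the generated
  1–30 Hz power inside the requested band.
* **Band effects** multiply the oscillator amplitude of chosen electrodes
  in one group (e.g. delta × 1.5 at Fz in MCI).
* **Couplings are dynamic.** The target's band oscillator is regenerated
  with the lagged, unit-variance source oscillator added (weight =
  `strength` ∈ [0, 1)) to its innovations inside the AR(2) recursion. This
  makes the oscillator pair a genuine vector autoregression in oscillator
  space, with a direction an autoregressive estimator can actually
  recover. The obvious alternative — adding a lagged copy of the source
  oscillator to the target *channel* — fails for a subtle reason worth
  recording: a narrowband signal is nearly deterministic given its own
  past, so a lagged additive copy carries almost no *incremental*
  (Granger) information once the target's own past is conditioned on, and
  its almost-symmetric narrowband cross-correlation can even push the
  estimated direction the wrong way. Measured on two-channel mixtures, the
  additive design produced reverse-edge DTF above the forward edge, while
  the dynamic design separates them cleanly (≈ 0.067 vs 0.028).
* **Per-subject variability**: coupling strengths vary across subjects
  with coefficient of variation 0.25; an optional `mocaLink` adds a linear
  term to MoCA per coupling-strength z-score so the correlation stage can
  be tested for sign recovery.
* Everything is deterministic under the spec's master seed; a manifest
  records subject ids, groups, MoCA and the active ground-truth effects.

What the generator does *not* emulate — and hence what passing tests do
not certify about real data: volume conduction and a common reference
forward model, eye-blink/EMG artifacts, 1/f aperiodic background beyond
the three rhythms, non-stationarity across the recording, and electrode
noise heteroscedasticity. Recovery results on synthetic cohorts establish
the correctness of the estimators, not field sensitivity.

## Numerical and design choices

* Frequency grid 1–30 Hz in 0.5 Hz steps for DTF; Welch resolution 0.5 Hz.
* Strict ">" at the surrogate threshold; ties are non-significant
  (conservative).
* Surrogate fits that fail (singular or non-finite) are redrawn, with an
  error beyond a retry budget of 20.
* `welchPsd` demeans each Welch segment; the all-zero signal maps to an
  all-zero PSD.
* MoCA scores are rounded to integers after truncation to [0, 30].
* Temporal electrodes (T7/T8) sit lateral to the anterior–posterior axis
  used for bottom-up/top-down edge orientation; they are ranked between
  central and frontal, and any edge touching them carries a `lateral`
  flag. A single "frontal" region covers the prefrontal and frontal rows.

## Problem sizes used in the test suite

The validation suite scales the study down so the full set of checks runs
on one CPU: ground-truth recovery uses 20 subjects per group, 15-s
recordings (3 epochs), 100 surrogates and a 1-Hz DTF grid over 20 seeded
replicate cohorts; surrogate calibration pools six 8-channel noise
subjects at 200 surrogates; the oracle comparison uses 5000 samples. The
defaults of the exported functions are the full-scale ones (5-min
recordings, 1000 surrogates, 0.5 Hz grid).

## A worked run

```{r, eval = FALSE}
spec <- cohortSpec(
  nSubjectsPerGroup = 20, durationS = 60,
  bandEffects = data.frame(group = "MCI", band = "delta",
                           electrode = c("Fz", "CP1"), multiplier = 1.5),
  couplings = data.frame(group = "MCI", source = "PO3", target = "CP5",
                         band = "delta", strength = 0.4, lag = 2),
  mocaLink = -2, seed = 1)
cohort <- generateCohorts(spec)

bandTbl <- cohortBandTable(cohort$recordings)
elec <- compareGroups(bandTbl, value = "power")

connTbl <- cohortConnectivityTable(cohort$recordings, nSurrogates = 200)
edges <- compareGroups(connTbl, value = "value")
summarizeFindings(edges[edges$significant, ])
correlateWithMoca(connTbl,
                  edges = edges[edges$significant,
                                c("band", "source", "target")])
```

Or, as one orchestrated run with all tables written to disk:

```{r, eval = FALSE}
cfg <- system.file("extdata", "demo-config.yaml", package = "eegdtf")
res <- runPipeline(cfg, "demo-results")
```

## Known limitations

* DTF is sensitive to volume conduction and reference choice; the
  minimum-norm fit on average-referenced data is the conventional, not a
  principled, resolution of the reference-induced rank deficiency.
* The surrogate null preserves amplitude spectra only; it tests the null
  of no cross-channel phase structure, not of no linear coupling given a
  common drive.
* Per-epoch MVAR with p = 2 assumes 5-s local stationarity and short
  memory; slow couplings spanning more than p samples are attenuated.
* The statistics layer treats subjects as exchangeable within group; no
  covariate adjustment (age, education) is implemented.
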