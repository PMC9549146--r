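---
title: "Comparing uni- and multivariate contrast detection in sparse intracranial EEG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing uni- and multivariate contrast detection in sparse intracranial EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ieegcontrasts)
```

## The problem

Stereo-EEG (SEEG) records field potentials from depth-electrode contacts
implanted in epilepsy patients undergoing presurgical evaluation. Electrode
placement follows the clinical hypothesis, so any cognitive experiment sees a
sparse, idiosyncratic sample of the brain: a handful of linear electrodes with
contacts every 3.5 mm, covering different structures in every subject. Given
two task conditions — here, angry versus happy face trials in a facial emotion
recognition task — the question is *which brain structures respond
differently*, and the answer depends heavily on the statistical lens used.

This package implements and compares three such lenses on a common input, the
single-trial **gamma power trace** (GPT): the time course of mean 55–115 Hz
spectral power, baseline-corrected, on a $[-0.3, 1]$ s peri-stimulus axis at
256 Hz.

1. **Cluster-level permutation test** (exploratory, per contact or per pooled
   structure): pointwise two-sample $t$ statistics are thresholded at the
   two-sided $p < 0.05$ quantile ($df = n_A + n_B - 2$); contiguous
   supra-threshold runs form clusters scored by their mass (sum of $t$);
   cluster mass is referred to the permutation null of the maximum absolute
   cluster mass over 1,000 random relabelings, with the finite-sample
   estimator $p = (1 + \#\{\text{null} \ge \text{obs}\}) / (1 + N)$.
2. **Per-contact ML classification** (predictive, univariate in space):
   single-trial GPTs are augmented by condition-mean subtraction, reduced to
   15 interval statistics, and classified by a bagged-tree ensemble under
   stratified 10-fold cross-validation; performance is the normalized
   Matthews correlation coefficient, $\mathrm{NMCC} = (\mathrm{MCC}+1)/2$,
   tested against the 0.5 chance level with a one-sample $t$-test over fold
   scores.
3. **Searchlight MVPA** (predictive, multivariate in space): for every contact,
   all same-subject contacts within a closed 25 mm ball contribute their full
   scaled GPT time courses as concatenated features to an L2-regularized
   logistic decoder, scored and tested exactly as in (2). A significant
   searchlight is attributed to the structure of its *center* contact.

Method agreement is quantified at the structure level: for each method, the
set of (structure, hemisphere) pairs containing at least one significant
contact (or a significant pooled test), compared pairwise with the Jaccard
index per hemisphere.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| notch frequencies | 50, 100, 150 | Hz | mains line and harmonics |
| notch stop-band width | 2 | Hz | narrow enough to leave the 55 Hz gamma edge intact |
| wavelet frequency grid | 1–125, step 1 | Hz | covers delta through high gamma below the 128 Hz Nyquist of the 256 Hz analysis rate |
| wavelet cycles | $\max(3, f/2)$ | — | constant $\sigma_t \approx 80$ ms above 6 Hz; temporal resolution matched across the gamma band |
| gamma band | 55–115 | Hz | inclusive bounds; 61 frequency rows averaged |
| epoch window / buffer | $[-0.3, 1]$ / 1 | s | buffer absorbs filter and wavelet edge artifacts, cropped before analysis |
| baseline window | $[-0.3, 0]$ | s | pre-stimulus; dB mode ($10\log_{10}$ of power over baseline mean) |
| permutations | 1000 | — | Monte-Carlo resolution ~0.001 |
| cluster-forming / cluster $\alpha$ | 0.05 / 0.05 | — | two-sided pointwise threshold; structure significant iff any cluster $p < 0.05$ |
| feature intervals | $[0.2,0.4), [0.4,0.6), [0.6,1]$ | s | early/mid/late response; 3 × 5 statistics = 15 features |
| hyperparameter grid | trees {250,500,1000} × depth 2–10 × feature fraction {0.15,0.5,0.75} | — | 81 points, searched exhaustively |
| searchlight radius | 25 | mm | several-fold the 3.5 mm contact spacing; larger radii enlarge, not move, detected clusters |
| CV folds | 10 | — | stratified by condition |
| ridge strength | $\lambda = 1/n$ | — | unit-strength L2 in the common $C=1$ parameterization |

## Design choices where the design was open

- **Exhaustive grid instead of model-based search.** The discrete space has 81
  points, fewer than the 100 iterations a sequential optimizer would spend, so
  plain grid search is deterministic and covers at least as much of the space.
- **CV structure.** Hyperparameters are selected on one stratified 10-fold CV;
  the reported fold NMCCs come from a second, freshly seeded 10-fold CV at the
  selected point. Augmentation and feature extraction are refit inside every
  training fold; augmented copies inherit their source trial's fold, and test
  folds are scored on original trials only — both choices exist to make
  information leakage structurally impossible rather than merely unlikely.
- **MCC conventions.** The standard MCC formula is used, with the usual
  convention that a zero denominator factor (single-class predictions) yields
  MCC 0, i.e. NMCC 0.5. A classifier that always answers "angry" is exactly at
  chance by construction.
- **Degenerate fold scores.** When all fold NMCCs are identical the $t$-test
  is undefined; the limit conventions are $p = 1$ at exactly 0.5 (constant
  features must not be significant) and $p = 0$ otherwise.
- **Tie-break in anatomical labeling.** In the 3×3×3 majority vote the
  smallest label code wins ties and "unknown" (code 0) never outvotes a named
  structure; the labeling grid is taken as 1 mm isotropic. Both make the
  assignment deterministic.
- **Closed searchlight ball, per-subject neighborhoods.** Boundary contacts at
  exactly the radius are included; neighborhoods never cross subjects because
  trials are only aligned within a subject. Pooling across subjects happens at
  the structure level.
- **Structure pooling is plain concatenation.** Trials from all contacts of a
  (structure, hemisphere) are stacked into one angry and one happy set,
  weighting every trial equally regardless of its subject's trial count.
- **Sidedness.** Significance requires both a two-sided $p < 0.05$ against
  0.5 *and* mean NMCC > 0.5, covering the "better than chance" and
  "above or below chance" readings conservatively: below-chance decoding never
  counts as a detected contrast.
- **Jaccard of two empty sets is 1** (vacuous agreement); this never occurs on
  the packaged reference table.
- **Reporting rounds half-up to 2 decimals** while raw values are kept in all
  machine outputs.

## The reference summary table

`structure_counts_reference()` ships the per-structure summary of a
13-subject SEEG facial-emotion-recognition cohort (1,004 artifact-free
contacts: 531 LH, 473 RH): implanted contact counts and the number of
significant contacts per method, per (structure, hemisphere), with empty cells
stored as 0. `compare_from_counts()` reproduces from it the published
aggregate statistics: 12/13 (LH/RH) structures for the permutation test
pooling 209/232 contacts, 19/19 structures with 55/47 significant contacts
for ML, 24/23 structures with 157/122 significant centers for the searchlight,
and Jaccard agreements ML–MVPA 0.65 (LH) / 0.62 (RH) and permutation–ML 0.52
(RH).

Recomputing *all* pairwise agreements from the count table also yields
permutation–ML 0.35 (LH) and permutation–MVPA 0.38 (LH) / 0.44 (RH), where the
source report prints 0.33 and 0.44 / 0.37 for those cells (the latter pair
plausibly swapped). The package reports what the count table implies and does
not adjust toward the discrepant printed values.

```{r}
res <- compare_from_counts()
res$agreement
res$summary
```

## What the simulator emulates — and what it does not

`cohort_spec()` / `generate_geometry()` / `generate_gpts()` /
`generate_raw()` produce cohorts matching the study conditions: 13 subjects,
8–14 linear electrodes each with 8–18 contacts at 3.5 mm spacing (≈7/13
subjects left-only, 2/13 right-only, 4/13 bilateral), 45–65 correct
artifact-free trials per condition, GPTs on the $[-0.3,1]$ s axis, and
reaction times of 0.97 s (angry) vs 0.85 s (happy) with SD 0.12 s.

GPT-level noise is temporally smoothed Gaussian (moving average ≈50 ms,
rescaled to unit SD) — a declared stand-in for the autocorrelation of real
gamma power, since no noise model is prescribed by the study conditions.
Condition effects are additive amplitude offsets (in units of noise SD)
confined to chosen structures and latency windows; a latency-shift variant
exists for multivariate-vs-univariate sensitivity demonstrations but defaults
off. Raw-voltage simulation adds pink-noise background, a 50 Hz line
component, and 55–115 Hz band-limited bursts at 4096 Hz.

The simulator does **not** model volume conduction, epileptic spikes, eye or
muscle artifacts, biophysically realistic field spread, inter-contact
correlation within an electrode, or non-stationary baselines. Passing tests
on synthetic cohorts therefore demonstrate calibration and recovery under the
declared statistical model, not performance on clinical recordings; the
contact-level results of any real cohort remain irreproducible without its
(non-public) recordings, which is why validation rests on aggregate
statistics plus synthetic-data properties.

Structure centroids used by the geometry generator
(`dk_centroids()`) are approximate, package-authored template-space
coordinates — plausible geometry, not atlas measurements.

## Numerical choices

- **Notch filtering**: Hamming-window FIR band-stop kernels (order $2 f_s$,
  ≈1.65 Hz transition) cascaded by kernel convolution and applied by FFT
  convolution with exact group-delay compensation (symmetric FIR ⇒ zero net
  phase). Attenuation at 50 Hz exceeds 50 dB while 55 Hz sits in the passband.
- **Resampling** is Fourier-domain (spectrum truncation), anti-aliasing by
  construction; epochs are cut with 1 s buffers on both edges, and the
  buffered $[-1.3, 2]$ s axis at 256 Hz (845 samples) is cropped to 333
  samples after the wavelet transform.
- **Morlet transform**: complex wavelets truncated at ±5$\sigma_t$, unit
  energy, FFT convolution sized so no circular wrap-around reaches the
  retained window.
- **Time axes** are sample grids $k/f_s$ containing $t = 0$ exactly, so epochs
  align to stimulus onset without interpolation.
- **Permutation nulls** draw random relabelings with a fixed seed; cluster
  geometry and masses are exactly invariant to trial order, Monte-Carlo
  p-values up to binomial error. Skewness/kurtosis use the standardized
  biased-moment estimators with the zero-variance convention skew = kurt = 0.
- **Per-structure and per-contact seeds** are derived from a deterministic
  string hash of the unit's identity, so results do not depend on iteration
  order and cohorts can be evaluated in parallel without changing numbers.

## Problem sizes used by the test-suite calibrations

The packaged checks run the statistical calibrations at reduced but
statistically meaningful scales, chosen once: type-I error of the permutation
test over 500 null simulations (15 trials/condition, 100 timepoints, 1,000
permutations; accepted band [0.03, 0.08]); exhaustive-enumeration agreement on
4+4-trial instances (all 70 relabelings); ML chance calibration over 200 null
contacts of 60 trials/condition (±0.03); searchlight chance calibration over
120 centers from 20 independent null cohorts (±0.03); monotone detection
across effect sizes 0–3 SD; searchlight recovery of a planted 3 SD effect
structure in ≥90% of 10 seeds; and end-to-end recovery of a 70 Hz burst
through the full spectral chain. Calibration runs use a single hyperparameter
point from the search grid, which cannot change chance-level expectations.

## Known limitations

- No multiple-comparison correction across structures is applied, matching
  the comparison design (each method's p-values arise differently); counts of
  significant structures are therefore liberal for all three methods alike.
- The permutation test's sensitivity depends on the cluster-forming
  threshold; very brief or very diffuse effects can be missed at the default.
- The searchlight attributes a neighborhood's evidence entirely to its center
  contact's structure; information carried by peripheral members is credited
  to the center's structure, an intentional bias of the method.
- Ridge logistic regression at fixed unit strength is not tuned per
  neighborhood; heavily duplicated channels change effective regularization
  only marginally (a property the tests assert).
- The ML ensemble's NMCC distribution under the null has fold-level variance
  that the $t$-test treats as Gaussian; with 10 folds this is an
  approximation, mitigated by the additional mean > 0.5 requirement.
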