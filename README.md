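# ieegcontrasts

Detecting task-condition contrasts in sparse intracranial EEG, three ways.

Stereo-EEG (SEEG) cognitive experiments record single-trial brain activity
from depth-electrode contacts whose placement follows clinical, not
scientific, criteria. Given two task conditions (here: angry vs happy face
trials in a facial emotion recognition task), different statistical lenses
give different answers to *which brain structures respond differently*. This
package implements three standard lenses on a common input — the single-trial
**gamma power trace** (GPT): mean 55–115 Hz spectral power, baseline
corrected, on a [−0.3, 1] s axis at 256 Hz — and quantifies how much they
agree:

1. **Cluster-level permutation test** (per contact, or per structure by
   pooling trials across contacts): pointwise two-sample *t*, two-sided
   *p* < 0.05 cluster-forming threshold, cluster mass = Σ*t*, max-statistic
   null over 1,000 relabelings, p = (1 + #{null ≥ obs}) / (1 + N).
2. **Per-contact ML classification**: condition-mean-subtraction augmentation
   (leakage-safe, refit per CV fold), 15 interval statistics
   ([0.2,0.4) / [0.4,0.6) / [0.6,1] s × mean, SD, median, skewness, kurtosis),
   bagged trees with grid-searched hyperparameters, stratified 10-fold CV
   scored by the normalized Matthews correlation coefficient
   NMCC = (MCC + 1)/2, *t*-tested against the 0.5 chance level.
3. **Searchlight MVPA** for sparse electrodes: every contact centers a closed
   25 mm ball of same-subject contacts; their scaled GPT time courses are
   concatenated and decoded by ridge logistic regression under the same CV
   and test.

Structure-level agreement between methods is the per-hemisphere **Jaccard
index** of the sets of (structure, hemisphere) pairs each method flags.
It also ships the full preprocessing chain from raw voltage (FIR notch at
50/100/150 Hz, common average reference, buffered epoching, resampling to
256 Hz, Morlet time–frequency transform on 1–125 Hz, dB baseline correction,
gamma-band averaging) and a seeded synthetic-cohort simulator (geometry,
GPTs, raw voltage, reaction times) for calibration and power studies.

## Worked example

Simulate a 2-subject cohort with a 2.5 SD gamma-amplitude effect planted in
the left precentral gyrus between 0.3 and 0.6 s, then run all three methods
and compare them:

```r
library(ieegcontrasts)

spec <- cohort_spec(n_subjects = 2, electrodes_per_subject = c(3, 3),
                    contacts_per_electrode = c(8, 8),
                    trials_per_condition = c(50, 60), seed = 42)
geom <- generate_geometry(spec)
eff  <- effect_spec(tibble::tibble(structure = "PRECENTRAL", hemisphere = "LH"),
                    effect_size = 2.5, effect_window_s = c(0.3, 0.6))
sim  <- generate_gpts(geom, spec, eff)

res <- run_pipeline(sim$gpts,
                    perm = perm_config(n_permutations = 500),
                    space = search_space(250, 6, 0.5),
                    seed = 7)

dplyr::filter(res$permtest, significant)
#> # A tibble: 1 × 7
#>   structure  hemisphere n_contacts n_clusters   min_p significant test
#> 1 PRECENTRAL LH                  8          4 0.00200 TRUE        <clstr_ts>

dplyr::filter(res$ml, significant) |>
  dplyr::select(subject, contact, structure, mean_nmcc, p)
#> # A tibble: 12 × 5
#>    subject contact structure           mean_nmcc        p
#>  4 SYN02   E1-1    PRECENTRAL              0.954 3.38e- 9
#>  5 SYN02   E1-2    PRECENTRAL              0.977 3.54e-10
#>  ...                                   (all 8 planted contacts, plus 4
#>  ...                                    near-threshold false positives)

res$agreement
#> # A tibble: 6 × 4
#>   pair             hemisphere jaccard jaccard_2dp
#> 1 permutation-ml   LH           0.2          0.2
#> 3 permutation-mvpa LH           0.333        0.33
#> 5 ml-mvpa          LH           0.333        0.33
#> ...
```

The pooled permutation test flags exactly the planted structure; the ML
classifier decodes every planted contact at NMCC ≈ 0.93–0.98 (chance is 0.5)
plus a few false positives at the nominal 5% rate; the searchlight finds the
planted structure and its spatial neighbors within the 25 mm radius. The
Jaccard values quantify exactly this kind of partial overlap.

A reference summary of a real 13-subject SEEG cohort (1,004 contacts) is
packaged; its published aggregate statistics are reproduced by:

```r
res <- compare_from_counts(structure_counts_reference())
res$agreement   # ml-mvpa 0.65 (LH) / 0.62 (RH), permutation-ml 0.52 (RH), ...
res$summary     # structures and significant contacts per method and hemisphere
```

A thin CLI over the same functions lives at `inst/cli/ieeg-contrasts`
(subcommands `simulate`, `pipeline`, `compare`, `report`).

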