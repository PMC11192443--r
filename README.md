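# natisc

Leave-one-out intersubject correlation (ISC) analysis for naturalistic
fMRI, built for the question of whether a brain network tracks rich,
time-extended stimuli — films, audio stories, music — and how strongly
that tracking depends on stimulus class. The package is aimed at
researchers analysing region-level BOLD time courses from passive
viewing/listening paradigms, and at anyone who wants a tested, synthetic
reference implementation of the ISC machinery.

## What it computes

For participant *i*, condition *c*, and functional region of interest
(fROI) *f*, the leave-one-out ISC is

> r_i = cor( x_i , mean over j ≠ i of x_j )

on temporally z-scored series starting 6 s after stimulus onset, Fisher
transformed (z = atanh r) before statistics. Around that core the package
provides:

* **fROI definition** — group-constrained, subject-specific selection of
  the top 10% of gray-matter voxels per parcel by localizer t value, with
  a suprathreshold-voxel quality check (`define_froi()`, `qc_localizer()`,
  `extract_froi_timecourse()`).
* **Peak/trough-removal analysis** — recompute ISCs after deleting the
  time points where the group-average series exceeds |z| > 1, compare
  against an m-matched random-removal permutation null and against each
  other (`detect_extremes()`, `removed_isc()`, `random_removal_null()`,
  `peak_trough_analysis()`).
* **Mixed-model suite** — condition-type contrasts with crossed random
  intercepts (fROI, participant, stimulus), per-stimulus and per-fROI
  variants, an fROI × condition-type interaction model, BH-FDR
  correction, and LRT/AIC model comparison (`fit_condition_model()` and
  friends, via lme4).
* **Content-Unit scoring** — a lexical semantic-richness metric for
  free-text stimulus descriptions: filler-phrase cleaning, stop-word
  removal, proper-noun merging, rule-based lemmatization, a
  ≥ 3-participant inclusion filter, token counts and pairwise shared-type
  counts, and the CU–ISC association (`count_cus()`,
  `shared_cu_pairwise()`, `cu_isc_association()`).
* **A synthetic study generator** — an additive shared-signal model
  x = √a·s + √(1−a)·ε whose expected leave-one-out ISC is
  a/√(a + (1−a)/(n−1)) in closed form, a ten-condition design template
  with published durations and Ns, rest scans, localizer t-maps with a
  planted block, and description corpora with controllable concept
  overlap (`make_design()`, `simulate_timecourses()`, `simulate_corpus()`,
  `simulate_tmap()`).

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate.R` … `06_cu.R`) writing tables to `results/`. Its core, by
hand:

```r
library(natisc)

design <- make_design("paper", seed = 1)      # 10 conditions, 47 participants
tcs <- preprocess_timecourses(simulate_timecourses(design))
isc <- compute_isc_table(tcs)

round(tapply(isc$r, isc$condition_type, mean), 4)
#>  -M/-L  +M/-L  +M/+L
#> 0.0382 0.1752 0.2889

fit_condition_model(isc)
#> LME fit 'condition' (REML, singular), logLik 808.52, AIC -1603.03
#> reference level: +M/-L
#>                 name    beta      se         p
#>          (Intercept)  0.1804 0.01043 5.493e-67
#>  condition_type-M/-L -0.1414 0.01974 7.906e-13
#>  condition_type+M/+L  0.1216 0.01463 9.600e-17
```

Read: meaningful nonverbal stimuli are tracked well above the zero
baseline (intercept 0.18 on the Fisher-z scale), more weakly than
meaningful verbal stimuli (+0.12) and more strongly than non-meaningful
ones (−0.14) — the ordering the generator's default tracking strengths
(a = 0.11 / 0.047 / 0.003) plant by calibration against the closed form.
The `singular` flag is expected: the generator plants no condition-level
heterogeneity, so that variance component sits at zero.

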