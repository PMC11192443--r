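---
title: "Methods: leave-one-out ISC analysis for naturalistic fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: leave-one-out ISC analysis for naturalistic fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The measure

Intersubject correlation (ISC) indexes how reliably a brain region tracks a
time-extended stimulus. For participant $i$ in a given functional region of
interest (fROI) and condition, the leave-one-out ISC is

$$ r_i = \mathrm{cor}\!\left(x_i,\ \tfrac{1}{n-1}\sum_{j \neq i} x_j\right), $$

where the $x$ are temporally z-scored regional BOLD series beginning 6 s
after stimulus onset (3 samples at TR = 2 s, excluding the initial
hemodynamic rise). The leave-one-out average is computed on the z-scored
series and is not re-standardized; Pearson correlation is invariant to its
scale, so this choice only fixes the order of operations. ISCs are Fisher
transformed ($z = \operatorname{atanh} r$) before any parametric test. A
correlation of exactly $\pm 1$ is treated as an error rather than mapped to
$\pm\infty$ — downstream mixed models cannot absorb infinities — with
opt-in clipping at $1 - 10^{-7}$ for callers that want it.

`natisc` implements this pipeline end to end: subject-specific fROI
definition from localizer contrast maps, preprocessing and the ISC table,
peak/trough-removal analyses with a permutation null, a mixed-model suite,
and Content-Unit (CU) scoring of free-text stimulus descriptions. A
synthetic-data generator with an analytically tractable shared-signal model
stands in for scanner and survey data throughout.

# The synthetic study

## Additive shared-signal model

Each simulated series is

$$ x = \sqrt{a}\, s + \sqrt{1-a}\, \varepsilon, $$

with one shared per-condition signal $s$ and participant-specific noise
$\varepsilon$, both Gaussian, smoothed with the same temporal kernel and
standardized. The parameter $a \in [0, 1)$ is the proportion of variance
locked to the stimulus. Under this model the expected leave-one-out ISC has
the closed form

$$ \mathbb{E}[r] \;\to\; \frac{a}{\sqrt{a + (1-a)/(n-1)}}, $$

which the package exposes as `expected_loo_isc()` and the tests use as a
free oracle: at $T = 1000$ samples, $n = 30$, $a = 0.25$ the simulated mean
leave-one-out $r$ must land within $\pm 0.02$ of $0.476$ (it does, with
observed error about $0.002$).

Hemodynamic realism is approximated by Gaussian temporal smoothing (FWHM 3
TRs by default) rather than HRF convolution: what matters for the
peak-removal machinery is autocorrelation, and first-level modelling is out
of scope. Because signal and noise pass through the same kernel, smoothing
shapes the spectrum without touching $a$; the tests verify that the
expected ISC is smoothing-invariant within Monte-Carlo tolerance.

## Calibration of the default tracking strengths

The `"paper"` design template carries ten naturalistic conditions in three
types — meaningful verbal (`+M/+L`), meaningful nonverbal (`+M/-L`), and
non-meaningful (`-M/-L`) — with their published durations (including the
16 s fixation at each end) and per-condition Ns (33, 32, 32, 31, 34, 31,
29, 29, 14, 15 over a 47-participant pool). Default tracking strengths

| condition type | $a$ | expected ISC at $n = 30$ |
|---|---|---|
| `+M/+L` | 0.110 | 0.293 |
| `+M/-L` | 0.047 | 0.166 |
| `-M/-L` | 0.003 | 0.016 |

were solved once from the closed form so the simulated condition-type mean
ISCs approximate the 0.295 / 0.164 / 0.0163 ordering the analysis is
designed to detect. Per-fROI multiplicative modifiers on $a$ (all 1 by
default) let simulations plant regional tracking differences. The
participation matrix samples each condition's N from the pool with a
per-condition seeded stream; the joint per-participant pattern of the real
study is not reproduced (it is not printed anywhere), only the margins.

One global seed expands into independent per-stream seeds (signal, noise,
participation, rest, text) through a counter-based hash (`stream_seed()`),
so any module rerun in isolation reproduces its output bit for bit.

## What the generator does not emulate

No head motion, scanner drift, physiological noise, spatial voxel
correlation (beyond the planted localizer block), condition-level response
heterogeneity, or non-Gaussian BOLD features. Passing tests therefore show
that the *statistical machinery* behaves as specified under a controlled
generative model — not that the scientific conclusions would replicate on
real scanner data.

# fROI definition

Within each group parcel, after gray-matter masking, the subject-specific
fROI is the top $\lceil 0.10\, m \rceil$ voxels by localizer t value
($m$ = eligible voxel count). Choices worth stating:

* **Ceiling, not floor or round** — guarantees a nonempty fROI for tiny
  parcels and makes counts reproducible (a 1000-voxel parcel yields exactly
  100 voxels).
* **GM masking precedes ranking**, and the 10% is taken of the GM-masked
  count (the denominator question the procedure leaves open; decided here).
* **Ties break by lower linear voxel index**, so the selection is a pure
  function of the map across platforms and sort implementations.
* Voxels are addressed by 1-based storage-order linear index; any NIfTI
  affine is honoured only in I/O, never in selection logic.

The localizer QC counts voxels across the parcels with one-tailed
$p < 0.001$ (uncorrected, via the t quantile at the contrast's df) and
excludes a participant when *fewer than* 100 survive — exactly 100 passes.

# Peak and trough removal

Peaks (troughs) of a condition are samples of the participant- and
fROI-averaged, z-normalized series strictly above $+1$ (below $-1$).
Removal deletes those samples from every participant's series — deletion,
not interpolation, since interpolation would re-introduce the excursion —
and ISCs are recomputed on the concatenated remainder. The reference
distribution removes $m$ uniformly chosen samples ($m$ = peak count),
10,000 draws by default, and the empirical p is one-tailed lower with
add-one smoothing, $p = (1 + \#\{\text{null} \le \text{obs}\})/(1 + N)$.
Detection pools fROIs by default (per-fROI detection is available behind a
flag); the null recomputes per-fROI ISCs and averages afterwards. Random
draws are unrestricted (they may overlap the peak set). The head-to-head
peak-vs-trough test trims the trough set to the $m$ lowest-valued points
and applies a pooled-variance two-sample t test on the per-(participant ×
fROI) Fisher z values.

## A calibration caveat discovered by the tests

The removal-null machinery is *not* calibrated under the global null, and
the package's tests document this rather than hide it. On pure-noise data
($a = 0$) the peak-removal empirical p rejects at $\alpha = 0.05$ nearly
always, not 5% of the time. The reason is structural: peaks are selected
from the observed group-average series, and under joint normality
$\mathbb{E}[x_i \mid g] = \mathbb{E}[\bar{x}_{-i} \mid g] = g$ — the group
mean's extremes are exactly the samples where participants happen to agree,
in noise as in signal. Deleting them removes positive-covariance samples
and pushes the ISC below a null built from random deletions. The effect
does not vanish with more participants, fROIs, or time points (measured
rejection 0.97–1.0 for $n$ = 10–30, 1–5 fROIs, $T$ = 150–600). It is
consistent with the empirical observation that trough removal also lands
significantly below the random-removal null on real data. Peak-removal
p values should therefore be read as *descriptive contrasts against random
removal*, not as calibrated tests of "no concentrated signal"; the
head-to-head peak-vs-trough comparison is the better-behaved statistic.

Two related numerical notes. First, the null's mean is monotone in the
amount removed only on the correlation scale: shortening a stationary
series shrinks $\mathbb{E}[r]$ toward zero, but on the Fisher scale
atanh's convexity (larger $\mathrm{var}(r)$ at shorter $T$) can outweigh
that shrinkage, so mean z can *rise* slightly with $m$. Second,
leave-one-out ISCs are positively correlated across participants (each
series enters the others' averages; measured mean pairwise correlation
$\approx 0.10$ at $n = 10$ under noise), which inflates the variance of
their mean by roughly $1 + (n-1)\bar{\rho} \approx 1.9$. A one-sample t
test across participants — as in the resting-state control — consequently
rejects at ~11% rather than 5% under the null. The rest check is kept
because a *positive* rest result still flags pipeline artifacts, but its
nominal level should not be taken literally.

# The mixed-model suite

All models take Fisher z as response with condition type dummy coded,
reference `+M/-L` unless stated:

* `fit_condition_model()`: condition type + crossed random intercepts for
  fROI, participant, and condition (stimulus).
* `fit_per_condition_model()`: each `+M/-L` stimulus recoded as its own
  type (six levels for the full design); random intercepts fROI +
  participant; reference either the zero baseline (no-intercept fit),
  `+M/+L`, or `-M/-L`, with p values FDR-corrected across the three
  baselines per stimulus (`per_condition_tests()`).
* `fit_per_froi_model()`: the condition-type model within each fROI
  (participant + condition intercepts), FDR across the five fROIs.
* `fit_interaction_model()`: `z ~ 0 + froi + froi:condition_type +
  (1 | condition) + (1 | participant)`.

Fits use `lme4`; p values are two-tailed Wald tests on the normal
approximation (a Satterthwaite correction would change digits, not
conclusions, and every acceptance check here is simulation-based rather
than digit-matching). Coefficients are reported from REML fits;
likelihood-ratio tests and AIC comparisons always refit under ML, and
passing REML fits to the LRT is an error. Random intercepts whose grouping
factor has a single level are dropped with a warning; variance components
estimated at zero are retained and flagged `singular` — with only two
non-meaningful stimuli this happens by design, and it makes the Wald SE of
the `-M/-L` contrast slightly anticonservative (measured 2-SE coverage
~91% rather than 95% in the recovery simulations). FDR correction is
Benjamini–Hochberg via `stats::p.adjust` behind the `fdr_bh()` surface.

# Content-Unit scoring

A CU is operationalized lexically: a lemma remaining after (1) removal of
self-referential, meta-descriptive, and confidence/belief phrases
(case-insensitive, longest-first, word-boundary matches; default lexicons
ship as editable plain text — the original survey's exact lists are not
recoverable), (2) stop-word removal, (3) multiword proper-noun merging
("Mr. Bean" becomes one token), and (4) lemmatization. No installed R
package provides a lemmatizer, so the package uses a purpose-built rule
lemmatizer (irregular-form table plus plural/-ing/-ed suffix rules with
e-restoration); the tests verify it over the generator's entire
vocabulary of inflected forms and over hand-written fixtures.

Counting applies two rules jointly: the inclusion lexicon keeps lemmas
used by at least three distinct participants anywhere in a stimulus's
responses, and a response's `cu_count` is the number of *tokens* of
included lemmas (repeats count — the same entity can take part in several
events of a subclip). Pairwise shared CUs are counted as *types* per
subclip per participant pair ("shared" is a set notion), then averaged
over pairs, then over subclips. Clip-level CU values average over subclips
rather than summing, normalizing for different subclip counts.

The CU–ISC association reports (a) the Pearson correlation between
per-stimulus CU values and per-stimulus mean Fisher z over an *explicit*
stimulus scope — the procedure is described once over all ten stimuli and
once over the eight meaningful ones, so the scope is a required argument
with no default — refused below three stimuli or for a constant metric;
and (b) model comparisons against the condition-type model: adding
centered CU as a fixed effect (nested, LRT) and replacing condition type
with centered CU (non-nested, AIC).

The description generator plants `core_concepts_per_subclip` concepts per
~30 s subclip (12 for meaningful, 3 for non-meaningful stimuli by default,
mentioned independently with probability 0.5 by each of 20 describers),
drawing inflected surface forms so the lemmatizer is exercised, and
optionally interleaves filler from the removal lexicons on an independent
random stream — so toggling filler must not change a single CU count,
which is tested.

# Defaults and problem sizes

| parameter | default | where |
|---|---|---|
| TR | 2 s | design |
| onset exclusion | 6 s (3 samples) | `preprocess_timecourses()` |
| temporal smoothing | 3 TRs FWHM | generator |
| fROI fraction | 0.10 | `define_froi()` |
| QC threshold | p < 0.001, 100 voxels | `qc_localizer()` |
| peak threshold | |z| > 1 | `detect_extremes()` |
| null draws | 10,000 | `random_removal_null()` |
| CU inclusion | ≥ 3 participants | `count_cus()` |
| describers per stimulus | 20 | `simulate_corpus()` |

The test suite runs the calibration checks at deliberately modest sizes —
20 seeds at $T = 1000$ for the closed form, 100 seeds of the full
ten-condition design for coefficient recovery, 150 pure-noise replicates
with 400-draw nulls for the (documented) calibration property, 500 rest
replicates, 50 burst-signal seeds for peak-sensitivity power — chosen so
the whole suite completes in a few minutes while keeping Monte-Carlo error
well inside each criterion's tolerance. The `analysis/` drivers use 1,000
null draws; the full 10,000 is a parameter change.

# Known limitations

* The generator's participation pattern matches condition Ns, not the
  joint per-participant stimulus counts of the real study.
* The additive model has no condition-level effect heterogeneity, so the
  condition random intercept is frequently singular in simulations.
* The rule lemmatizer covers common English inflection and the shipped
  vocabulary; it is not a general-purpose lemmatizer.
* Peak-removal empirical p values are anticonservative by construction
  (see above) — a property of the procedure, not of this implementation.
* Voxel-level ISC maps, intra-subject (test–retest) correlation, and
  sliding-window ISC are out of scope.
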