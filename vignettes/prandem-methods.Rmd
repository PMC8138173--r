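---
title: "Methods: dmCpG calling in paired prandial-state methylation cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dmCpG calling in paired prandial-state methylation cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

Each probe's methylation fraction β is analysed on the M-value scale,
M = log₂(β/(1−β)). M-values are roughly homoscedastic across the (0, 1)
range, which matters at the extremes where β compresses variance; β is kept
for effect sizes because a difference of methylation fractions is the
interpretable unit. Conversion is exact and is clipped only at import
(β of exactly 0 or 1, where the logit diverges; the clipping constant,
default 1e-6, is configurable because scanner pipelines differ in how they
emit degenerate values).

Two inferential units exist:

* **Association within a prandial state.** Per probe, the M-values of the 12
  subjects are tested against a covariate x (BMI, one fatty acid's percent,
  or a saturation-group sum). Test selection is normality-adaptive: both
  vectors are screened by Shapiro–Wilk at α = 0.05, Pearson's r is used when
  both pass, Spearman's ρ otherwise. The gate requiring *both* vectors is the
  strictest of the defensible readings and is configurable
  (`gate = "both" | "either" | "y_only"`). Spearman uses average ranks for
  ties and the t approximation for its p-value (an exact option exists for
  tie-free vectors); at n = 12 the approximation is adequate and is what
  mainstream tools report.

* **Paired prandial contrast within a BMI class.** Per probe, per-subject
  differences d = M(PS) − M(FS) are screened by Shapiro–Wilk: paired t when
  normal-looking, Wilcoxon signed-rank otherwise, with the exact null for up
  to 25 non-zero differences (zero differences dropped, the standard
  signed-rank convention; fewer than 3 non-zero gives p = 1). With 4
  subjects per class the exact Wilcoxon two-sided p can never go below
  0.125, so calls at that class size arise only from the t branch — the
  package warns about this rather than silently switching to an
  anticonservative approximation.

A probe is a **dmCpG** under the dual rule p < α (default 0.05, nominal —
deliberately no genome-wide correction, mirroring the discovery-oriented
design this package targets) *and* |Δβ| > 0.10. Δβ is the difference of
group-mean β between extremes: obese minus normoweight for BMI; top minus
bottom covariate tertile (size ⌊n/3⌋) for fatty acids, which in the balanced
12-subject design is the exact analogue of the BMI contrast; PS minus FS for
paired calls. Direction is *hyper* when the association (or PS − FS shift)
is positive.

Glucose is never a permitted covariate (glycemia was uninformative in the
target design), nor is C18:3 (incompletely determined); the measured panel
is 3 SFA, 4 MUFA and 8 PUFA, percent-normalized per sample so the measured
fatty acids sum to 100.

## Cell-composition adjustment

Whole-blood methylation reflects leukocyte composition. Proportions of six
cell types are taken as input (reference-based deconvolution itself is out
of scope). For associations, the adjusted p-value comes from OLS of M on the
covariate plus the cell proportions (one column dropped under the sum-to-one
constraint, constant columns dropped), a two-sided t-test on the covariate
coefficient; both adjusted and unadjusted p-values are reported side by
side, since which one a given study treats as primary is a reporting choice.
For paired contrasts the adjustment happens in difference space: d is
regressed on the per-subject differences of the cell proportions and the
prandial effect is the intercept's t-test. Under normal errors this is
exactly calibrated; with only 4 subjects just one cell-difference column
fits (n − 3 cap, columns chosen by variance), so the class-level adjustment
is partial at that size — an honest degrees-of-freedom limit, not a bug.

## Probe filtering

Five stages, attribution in fixed order (a probe failing several counts
once, under the first): user-supplied SNP-affected list → chrX/chrY →
detection failure (p > 0.01 in *any* sample by default; quantifier
configurable) → any missing value (probe-wise removal, not imputation) → age
association at p < 0.05 under the same adaptive correlation test. The
retained set is order-independent; only the attribution changes with order.
Both prandial states are filtered independently and the union of removals is
applied to both, so all downstream analyses share one probe universe.

## Set-level summaries

Overlap percentages use an explicit denominator policy: the FA set's size in
BMI-vs-FA comparisons, the smaller set in FA-vs-FA comparisons. CpG-island
geography is computed in 0-based half-open coordinates: a position inside
[start, end) is island; the 2,000 gap bases on either side are shore; the
next 2,000 shelf; everything else open sea. Measuring distance in gap bases
from the half-open boundary makes the 2 kb/4 kb edges exact and testable
against a per-base brute-force scan. Genomic-context distributions are
tested by chi-square goodness of fit against the probe-universe proportions
(the universe is orders of magnitude larger than any dmCpG set, so treating
its proportions as fixed is appropriate; a 2×k contingency mode exists).
Categories with expected count below 1 are merged into a neighbour.
Baseline-β quartile profiles bin each probe's mean β over the normoweight
samples into [0, .25), [.25, .5), [.5, .75), [.75, 1]. Gene-set
over-representation is a one-sided hypergeometric tail within an explicit,
caller-supplied universe (no bundled annotation database), with
Benjamini–Hochberg q-values and significance at q < 0.05.

## The synthetic cohort generator

`generate_cohort()` emulates the study conditions: 12 male subjects, 4 per
BMI class (BMI uniform within 18.5–24.9 / 25–29.9 / 30–40), each measured in
FS and PS. Design choices, in the order the RNG consumes them:

* **Subjects**: BMI, age (uniform 25–45), fatty-acid profiles as a subject
  trait (correlation 0.9 between states, within-saturation-group correlation
  0.5, means/SDs set to typical adult whole-blood percentages), leukocyte
  fractions Dirichlet (concentration 200) around blood-typical means.
* **Annotation**: synthetic chromosomes with regularly spaced islands
  (500–2,000 bp, 25 kb spacing) and probes placed at construction-known
  island/shore/shelf/open-sea offsets (~30/25/15/30%), ~2% on sex
  chromosomes; gene compartments with realistic proportions.
* **Baselines**: a 3-component β mixture — Beta(2,20), Beta(5,5), Beta(20,2)
  with weights 0.4/0.2/0.4 — reproducing array bimodality.
* **Noise**: per-probe, per-subject random effect (SD 0.25 M) *shared
  between states*, plus within-subject residuals (SD 0.12 M, the order of
  technical-replicate variation) drawn per state. This variance
  decomposition is what makes paired contrasts both powerful and specific;
  a purely i.i.d. model would give the dual rule a paired false-positive
  rate near 1% at n = 4, which no replicated array experiment shows.
* **Planted associations** (defaults: 200 BMI probes, 100 on palmitate) are
  subject traits present in both states: M = m₀ + b·x + ε, with b solved by
  1-D root finding so the noise-free extreme-group Δβ hits its target
  (default 0.2) and the noise SD set so the population M-scale correlation
  equals the target r (default 0.9; direction split 50/50). Hosts are drawn
  from mid-baseline probes, where a 0.2 Δβ is reachable; an unreachable
  target is an error naming the probe. Planting in one state only was
  rejected: it leaks the covariate effect into the paired contrast.
* **Prandial shifts** (default 150 probes, β + 0.2 in PS, overweight class
  only) preferentially occupy island/promoter probes with baseline β < 0.3 —
  low-methylated regulatory regions are where postprandial hypermethylation
  concentrates in the target design.
* **Confounding** (the `confounded` preset): probes load on the centered
  granulocyte fraction (loadings N(0, 3) M per unit fraction), while the
  granulocyte mean tracks BMI (+0.01/BMI unit) and rises by 0.10
  postprandially — the magnitude of postprandial granulocytosis. Both
  effects are injected on the normalized sum-to-one scale so the configured
  values arrive undiluted.

Everything is a single seeded RNG stream; identical seeds give byte-identical
cohorts. What the generator does **not** emulate: Infinium I/II chemistry
bias, batch effects, genuine LD/SNP structure, prandial-state-specific
association effects, and realistic correlation between neighbouring probes.
Passing tests therefore demonstrate the statistical machinery — calibration,
recovery, confounding control, bookkeeping — not robustness to array
artefacts.

## Numerical and degenerate-input choices

* β = 0/1 at import: clipped to [1e-6, 1 − 1e-6] with a warning.
* Constant probes: excluded from association testing with a logged count
  (the Shapiro and correlation tests are undefined); constant probes cannot
  be removed by the age filter.
* All-zero paired differences: p = 1 by convention, logged.
* Wilcoxon with tied absolute differences: normal approximation with
  continuity correction (the exact null assumes no ties).
* Identical groups in the Mann–Whitney comparison: p = 1.
* Zero PS counts in FS/PS ratio terms: dropped with a message; fewer than 3
  usable pairs is an error.
* Interval sets are merged on construction (abutting half-open intervals
  merge), so nested or overlapping island annotations cannot produce
  ambiguous shore/shelf distances.

## Problem sizes

The validation suite uses 20,000-probe cohorts for calibration and
confounding checks (3 binomial SEs at that size is ±0.46 percentage points
on a 5% rate), 10,000 probes for recovery scoring, and 1,000 random island
layouts for the geography oracle. The recovery threshold (sensitivity ≥
0.95) is the oracle value 0.999 — obtained by direct simulation of the
calling rule on the planted-effect model before implementation — minus a
5-point tolerance.

## Known limitations

* With 4 subjects per class, the Wilcoxon branch cannot call and the
  cell-adjusted paired model is partial; class-level prandial inference at
  that size rests on the t branch and normality of differences.
* The Spearman p-value is a t approximation; at n = 12 with heavy ties it
  can deviate from the exact permutation null by more than rounding.
* Saturation-group covariates are sums of member percentages; compositional
  constraints (percentages summing to 100) induce negative correlation
  between groups that the generator reproduces only partially.
* The enrichment engine is generic over caller-supplied gene sets; it does
  not reproduce any curated annotation content.
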