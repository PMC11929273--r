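---
title: "Quantifying DCIS intratumor divergence and its association with outcome"
author: "DCISevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying DCIS intratumor divergence and its association with outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DCISevo)
```

## The scientific problem

Ductal carcinoma in situ (DCIS) is a pre-invasive breast neoplasm. After
treatment, some tumors recur as DCIS, some progress to invasive ductal
carcinoma (IDC), and most do neither. Because every neoplasm accumulates its
own idiosyncratic set of alterations, marker panels generalize poorly;
*evolutionary* summaries — how many alterations a tumor has accumulated and
how genetically and phenotypically divergent two distant regions of it are —
are candidate prognostic measurements that do not depend on the identity of
any particular gene.

DCISevo implements this measurement framework for studies that profile **two
geographically distinct samples per tumor**: somatic SNV call sets (whole
exome), bin-level copy-number profiles (low-pass WGS), ordinal
immunohistochemistry intensity profiles, and clinical covariates with
follow-up, plus the downstream statistics: cohort comparisons, cross-sectional
discrimination, and endpoint-specific survival models with stability-selected
covariates and risk stratification. A synthetic cohort generator with the same
data structure makes every stage testable without controlled-access patient
data.

## Genetic divergence metrics

For two samples with variant identity sets $A$ and $B$ (a variant is the
exact tuple chromosome, position, ref, alt):

* **SNV burden** $= |A \cup B|$.
* **SNV divergence** $= 100\,(|A \cup B| - |A \cap B|)/|A \cup B|$, the
  percentage of mutations private to one sample. Unions smaller than
  `min_union_snvs` (default 5) give a *missing* divergence — a ratio on a
  handful of calls is noise, and missing is never coerced to 0. This is why
  divergence analyses run on fewer tumors than burden analyses.

Copy-number profiles are uniform bins (50 kb by default) with a
purity/ploidy-corrected log2 ratio. A bin is **altered** iff its ratio is
present and $|\log_2| > 0.3$ — the inequality is strict, so a bin at exactly
0.3 is normal. With $A$, $B$ now the altered-bin sets:

* **CNA burden** $=$ altered bp / considered bp per sample (bins with a
  missing ratio leave both numerator and denominator).
* **CNA divergence** $= 100\,\mathrm{bp}(A \triangle B)/\mathrm{bp}(A \cup B)$,
  missing when the union is empty. Bins are bp-weighted, which equals bin
  counting on a uniform grid but stays correct for truncated
  chromosome-end bins.

Direction (gain vs loss) is ignored by default when deciding whether an
alteration is shared, because the sets are defined over *altered regions*; a
`directionAware` flag instead treats a bin gained in one sample and lost in
the other as discordant (it stays in the union, leaves the intersection). For
tumors with a synchronous invasive component, `dcisIdcDivergence()` reports
the mean of the two DCIS-vs-IDC comparisons; if exactly one comparison is
computable the other is used alone (recorded via `nComparisons`), keeping the
patient in the analysis rather than discarding an informative comparison.

## Ordinal IHC statistics

Stain intensity is scored visually as the proportion of the slide at each
level of an ordered scale — 4 levels (absence/low/medium/high) for most
markers, 2 (absent/present) for some. Three scales of comparison:

* **Intensity score** (per sample): weighted sum of the profile normalized by
  the maximum staining, with default weights $(0,1,2,3)/3$ encoding medium
  $\approx 2\times$ and high $\approx 3\times$ the intensity of low; for
  binary markers the score is the presence fraction. The weight vector is an
  argument, since relative stain intensities are an empirical choice. The
  patient-level **MIS** is the mean over the (1–2) available samples.
* **Earth Mover's Distance** (between samples): minimum total transport of
  proportion mass between adjacent categories turning one profile into the
  other. On an ordered 1-D histogram this equals the sum of absolute CDF
  differences at the $K-1$ interior cut points; the test suite checks that
  identity against a general minimum-cost transport linear program. EMD is
  normalized by $K-1$ by default so 2- and 4-level markers share a $[0,1]$
  scale.
* **Cumulative Density Index** (within sample): uniformity of the profile,
  operationalized as $1 - \mathrm{EMD}(p, u)/\mathrm{EMD}(e_1, u)$ with
  unnormalized EMD, $u$ the uniform profile and $e_1$ a point mass at an
  extreme category. This is the simplest construction matching both stated
  endpoints — 0 for all mass at an extreme, 1 for uniform — and is symmetric
  in which extreme is used; other constructions with the same endpoints
  exist, so CDI values should be compared only within this package. The
  patient-level value is the mean of the two samples' CDIs.

## Cohort comparisons

Per-patient metrics are compared across cohorts with rank tests
(Mann–Whitney U for two groups, Kruskal–Wallis followed by Dunn's pooled-rank
z tests under the Holm–Šidák step-down adjustment for three). Where a metric
is close enough to normal (CNA divergence), one-way ANOVA with Tukey HSD is
used; CNA burden, measured once per *sample*, uses a mixed-effects ANOVA with
a per-patient random intercept on the square-root-transformed fraction
(variance-stabilizing for proportions), with the omnibus Satterthwaite F and
Tukey-adjusted contrasts of estimated marginal means. Dunn's z uses the
standard tie-corrected pooled-rank variance; the Mann–Whitney switches from
exact to the continuity-corrected normal approximation at a combined n of 30
(configurable). One numerical caveat: with *exactly* duplicated per-patient
values the mixed model sits on the zero-residual-variance boundary and its F
statistic is unreliable; the equivalence with the collapsed one-value-per-
patient ANOVA holds in the near-duplicate limit and is tested there.

For the cross-sectional question (pure DCIS vs DCIS adjacent to invasive
cancer), `rfGiniRanking()` ranks candidate features by random-forest mean
decrease in Gini impurity, the top features feed `logisticDiscriminator()`,
and `aicCompare()` refits all candidate models on the intersection of
complete-case patients so AICs are comparable on one dataset.

## Endpoint construction and survival modeling

Two primary endpoints: **non-invasive recurrence** (recurrents are events;
progressors are *discarded*, not censored — their biology is the competing
process under study) and **progression** (progressors are events; recurrents
discarded). Two supplementary modes: `any_recurrence` (either event) and
`progression_censor_recurrents` (recurrents censored at their recurrence
time). Nonrecurrents are always censored at last follow-up. Median follow-up
is summarized by the reverse Kaplan–Meier method (KM on the flipped event
indicator, i.e. of the censoring distribution).

The modeling pipeline per endpoint:

1. **Imputation**: clinical covariates are mean-imputed (categoricals are
   dummy-coded first, so their dummies impute to observed level proportions).
   Measurement columns (burden, divergences, IHC) are never imputed — a
   missing divergence is informative missingness, and imputing it would leak
   the burden signal into the divergence column.
2. **Coding and standardization**: categoricals are coded one dummy per
   non-reference level, the reference being the alphabetically first observed
   level (`treatment` against `lumpectomy_only`, `er_status` against `neg`).
   Full one-dummy-per-level coding was rejected: for a binary covariate it
   creates a perfectly anticollinear pair whose LASSO selection splits
   arbitrarily between the two dummies, making the selection frequency of
   either dummy uninterpretable. All columns are z-scored (sample SD), so
   hazard ratios are per 1 SD; `hrRescale()` converts to natural units.
3. **Stability selection** (`coxLassoStability()`): 100 repetitions; each
   draws a fold assignment (seed `base_seed + r`), fits the Cox-LASSO path
   (log-spaced, 100 points over 4 decades by default) and keeps the
   covariates with nonzero coefficients at the lambda minimizing the
   ten-fold cross-validated partial-likelihood deviance. Covariates selected
   in at least 90% of repetitions form the final set. Fold draws are the only
   randomness, so results are bit-reproducible from `base_seed`. A known
   property of the deviance-minimizing lambda is over-selection: a noise
   covariate whose sample correlation with the outcome is large *in the
   dataset at hand* is retained in nearly every repetition, and no amount of
   fold re-randomization removes it. The frequency threshold therefore
   suppresses unstable covariates, not dataset-level coincidences.
4. **Final fit**: Cox partial likelihood (Efron ties) on the selected
   variables, using all endpoint patients with available (imputed) data for
   them; per-covariate Wald tests and Schoenfeld-residual proportional-
   hazards p-values are reported alongside (flagged, not enforced). A
   complete-case refit of the same model (no imputation) is reported as the
   sensitivity variant.
5. **Stratification**: per-patient relative risk
   $r_i = \exp(\beta^\top x_i)$ against the all-covariates-at-mean reference
   ($r = 1$ by construction on standardized covariates); the high/low split
   maximizes Youden's J over midpoints of consecutive unique risks, plus one
   boundary candidate outside each end of the range so anti-informative
   scores resolve to the degenerate classification with $J = 0$; ties break
   toward the smallest threshold. J is computed against the *binary* outcome
   indicator regardless of censoring time (the literal construction); with
   heavy censoring this threshold is optimistic, and because it is chosen on
   the same data it stratifies, the subsequent log-rank p-value is
   descriptive, not confirmatory. Groups are compared by log-rank, with KM
   curves, per-group medians and at-risk tables exported.

## The synthetic cohort generator

`simulationConfig()` defines a generative model with the same structure the
analysis assumes; `paperLikeConfig()` anchors its marginals to study-scale
summary statistics by moment matching:

* per-cohort SNV burden — negative binomial (overdispersed counts; SD larger
  than the mean), means/SDs 13.4/18.2, 19.2/26.4, 39.7/46.2 for
  nonrecurrents/recurrents/progressors;
* per-cohort SNV divergence, CNA altered fraction and CNA divergence — beta
  distributions matched to 17.0/28.2/18.4% (SD 13.8/25.5/19.3), 15.9/17.3/
  24.6% (15.0/14.8/17.1) and 77.4/67.7/63.7% (16.4/23.4/21.7) respectively;
* cohort sizes 99/69/56; administrative censoring uniform on 60–174 months,
  whose median (117) matches the reverse-KM median follow-up and whose lower
  end encodes the minimum five-year follow-up of nonrecurrents.

Per patient, the generator draws a union burden $U$ and divergence $d$,
splits $\mathrm{round}(Ud)$ variants as private (evenly between samples,
remainder to sample 1) and the rest shared; draws an altered fraction $f$ and
CNA divergence $D$, computes the shared altered-bin count
$s = 2fn(1-D)/(2-D)$ (the unique count making the realized symmetric-
difference ratio equal $D$ when both samples carry $fn$ altered bins), and
places shared and private bins disjointly on a 500-bin grid. The two samples
deliberately share one altered-fraction draw — the anchor is a per-sample
marginal, and tying the pair keeps the divergence identity exact. Log2 ratios
are emitted from Normal(±0.5, 0.15) *truncated outside the 0.3 calling
threshold* for altered bins and Normal(0, 0.05) clipped inside it for normal
bins, so the calling rule recovers the drawn quantities exactly; the ground-
truth table records realized (post-rounding) values, which is what the
constructive-consistency tests compare against. IHC profiles are Dirichlet
draws per marker (ER, GLUT1) with mild cohort gradients; 18 clinical
covariates are generated (treatment multinomial, ER status Bernoulli,
surgical margin Gamma in mm, plus realistic nuisance covariates) with
configurable missingness that never touches outcomes.

Outcomes follow a Weibull proportional-hazards model (shape 1.2; scales 180
and 240 months for recurrence and progression) with log-hazard shifts from a
named beta map on standardized latent features. Two coupling modes:

* **conditional** (default for `paperLikeConfig()`): cohort sizes are fixed,
  features are drawn from the labelled cohort's distributions, and event
  times are drawn from the PH model *conditioned* on the label (events before
  the censoring time; nonrecurrents observed at it). Observed per-cohort
  feature marginals equal the configured anchors exactly, which is the
  property the fidelity checks need.
* **latent**: a latent group determines the feature distributions, both event
  times are drawn unconditionally, and the label is assigned post hoc from
  the earliest of recurrence, progression and censoring — the observational-
  study data-generating story. Under nonzero effects the observed cohorts'
  feature distributions are then hazard-distorted away from the configured
  ones, which is why this mode is not used for anchor-fidelity checks.

The default beta map encodes the qualitative association pattern the package
is designed to detect — divergence drives recurrence (1.3 per SD, plus
treatment and ER-status effects), burden drives progression (1.2 per SD,
margin protective) — with within-cohort effect sizes chosen, together with
the mild IHC gradients, so that the pattern is recoverable by the stability-
selection pipeline at study scale. What the generator does *not* emulate:
correlation between burden and divergence (independent by default), FFPE
artifacts and caller error (upstream of this package), per-sample burden
variation within a patient, and genomic position structure (bins and variant
positions are abstract labels). Passing tests therefore demonstrate the
pipeline's statistical behavior under the assumed data structure, not the
properties of any variant caller.

## Problem sizes and numerical choices in the test suite

Oracle checks run 1,000 random instances per metric (divergence against
brute-force element classification; EMD against a transport LP within 1e-9)
and 200 Youden instances against an exhaustive scan. Calibration checks use
2,000 null replicates per test (levels asserted at 0.05 ± 0.015) and 200 Cox
replicates at n = 250 for CI coverage. Stability-selection recovery uses 50
meta-replicates of the n = 300 scenario with 30 repetitions each on a
30-point, 1.5-decade lambda grid; the end-to-end check runs 20 seeded
study-scale cohorts with 40 repetitions per model on a 40-point grid; the
generator-fidelity check uses 2,000 patients per cohort. Degenerate inputs
are errors, not guesses: all-missing CNA profiles, all-tied sign-test pairs,
single-class labels, constant risk vectors and fewer events than CV folds
all raise informative errors, and zero-variance covariates are dropped with
a warning before standardization.

## Known limitations

* The CDI construction matches the stated endpoints but is one of several
  possible; compare CDI values only within this package.
* The Youden threshold ignores censoring times (binary outcome reading); a
  time-dependent ROC would be the principled alternative.
* No competing-risks (Fine–Gray) modeling: the discard/censor endpoint rules
  are implemented as stated instead, and the two primary endpoints should
  not be interpreted jointly as cause-specific hazards.
* Stability selection inherits the over-selection of the deviance-minimizing
  lambda (see above); selected sets are best read as "stable under fold
  re-randomization", not as exact support recovery.
* The generator's conditional mode couples censoring and event times through
  the label conditioning, so cohort-wide reverse-KM follow-up is upward
  biased there; the follow-up summary is anchored on the nonrecurrent
  cohort, where it is exact.
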