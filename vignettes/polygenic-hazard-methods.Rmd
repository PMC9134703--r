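---
title: "Polygenic hazard scores and amyloid onset: models, assumptions and design choices"
author: "PolygenicHazard package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic hazard scores and amyloid onset: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PolygenicHazard)
```

This vignette is the package's own account of the statistical methods it
implements: what each model assumes, which parameters matter and why their
defaults are what they are, the numerical choices underneath, and what the
synthetic-cohort validation does and does not establish about real data.

## 1. The polygenic hazard score

The score is a weighted allele-dosage sum, $\mathrm{PHS}_i = \sum_j w_j
d_{ij}$, interpreted as a log relative hazard under proportional hazards:
$h(t \mid \mathrm{PHS}) = h_0(t)\,e^{\mathrm{PHS}}$. Derivation proceeds in
three steps.

**Candidate screen.** Variants with GWAS association $p < 10^{-5}$
(`filterCandidateSnps()`; the inequality is strict, a variant exactly at
the threshold is excluded).

**Forward stepwise Cox selection.** Starting from a model containing only
the two forced APOE variants, the candidate giving the largest
partial-likelihood improvement enters at each step if its one-degree
likelihood-ratio $p$ is below `alphaEntry`; selection stops when no
candidate qualifies or `maxSnps` SNPs have entered. Published descriptions
of this construction state the outcome (a few dozen SNPs) rather than the
entry rule, so both knobs are exposed, with defaults `alphaEntry = 0.05`
and `maxSnps = 31`. Ties in improvement (rare with continuous survival
times) break by the smaller GWAS $p$-value, then lexicographic id, making
selection reproducible. Weights come from the **final joint Cox refit**,
not the single-variant fits: the score must reproduce the joint model's
linear predictor, and single-variant coefficients would double-count
correlated effects.

**Scoring and stratification.** `computePhs()` refuses missing dosages
rather than imputing, and `alignDosages()` flips a dosage ($2-d$) only when
the file's counted allele is the panel's other allele; strand is never
inferred, so a mismatch at a palindromic (A/T or C/G) variant is an error.
Whether the summed score should be re-centred or scaled is not fixed by
convention, so post-scaling is an option and off by default; cohort values
in the literature span roughly $-1.6$ to $3.1$, which raw weighted sums
reproduce. Strata default to the cohort mean $\pm 1$ SD — for Gaussian
scores the high group is the top $\approx 15.9\%$ (the $\sim$84th
percentile) — and explicit cutpoints (such as the published 1.04 and
$-0.67$) override the cohort-derived ones.

## 2. Amyloid progression curve and age-of-onset imputation

Amyloid PET is expressed on the Centiloid (CL) scale (0 = typical young
control, 100 = typical mild AD); values $\ge 20$ CL are abnormal, with the
boundary inclusive (`classifyAbnormal(20)` is `TRUE`).

Individual scan series are short (a handful of scans over a few years), so
the long natural history must be assembled from many short segments.
`fitProgressionCurve()` uses the slope-versus-level construction of the
trajectory-modelling literature:

1. each individual contributes an accumulation **rate** (least-squares
   slope of CL against age) at their mean **level**;
2. the rate is modelled as a quadratic in level, $f(\mathrm{CL})$ — the
   natural shape if the truth is logistic, since a logistic trajectory
   satisfies $d\mathrm{CL}/d\tau = k\,(\mathrm{CL}-F)(C-\mathrm{CL})/(C-F)$
   exactly;
3. integrating $d\mathrm{CL}/d\tau = f(\mathrm{CL})$ from the threshold in
   both directions gives disease time $\tau(\mathrm{CL})$, anchored so
   $\tau(20) = 0$.

Numerical choices: the integral is a cumulative trapezoid over a 2001-point
CL grid spanning the central 99% of the floor-to-ceiling range; a fitted
rate that dips non-positive is clipped at 2% of the peak rate (with a
warning), which bounds the traversal time of the near-boundary tails
instead of letting it diverge; interpolation beyond the grid continues the
terminal slope linearly. A cohort whose individual rates are all
$\approx 0$ has no progression signal and is an error. The fit is intended
for 20 or more individuals with at least two scans each; below that a
warning is issued, below five it is an error.

`estimateOnsetAge()` follows the trajectory-level definition: the elapsed
disease time between crossing the threshold and reaching the participant's
**mean longitudinal CL** (unweighted over scans, as no weighting is
specified by the definition) is subtracted from the mean scan age. Mean
level below threshold ⇒ censored (`never_abnormal`). Because the curve is
flat near its ceiling, disease time diverges there, so saturated mean
levels are clamped to 2.5% below the ceiling with a warning — scans at
saturation carry no timing information beyond "long ago", and the clamp
bounds the imputation instead of producing onset ages before birth. Whether
elapsed time should be anchored at the scan level rather than the
trajectory mean is not settled; the trajectory-mean rule is the literal
reading and the one implemented. Onset is computed from the whole-neocortex
region by default (the region used for the onset analyses), configurable.

On noiseless logistic trajectories the imputed onset falls within half a
year of the true 20-CL crossing for over 95% of converters, and the curve
itself recovers $\tau(\mathrm{CL})$ within 0.25 years across 10–80 CL
(see `test-acceptance.R`, which runs these checks at 200–300 individuals).

## 3. Cognitive composites

Composites are means of z-standardised constituent tests, standardised
against the **baseline, cognitively normal** sample only; a reference test
with zero SD is an error naming the test. A visit missing some
constituents averages the available ones by default (configurable to
strict-complete), and a visit missing all constituents propagates `NA` —
never zero. CDR sum-of-boxes is a clinical sum and passes through raw.
Per-test direction conventions are not universal (timed tasks score
"worse" upward), so `compositeSpec()` takes a $\pm 1$ direction per test.

## 4. Association models

**Cross-sectional.** OLS of baseline regional CL on PHS, controlling for
age, sex, education and binary APOE ε4 status (0 = no ε4, 1 = one or two
ε4 alleles). In ε4-carrier or non-carrier subgroups the APOE covariate is
dropped automatically — it has no variation there. FDR (Benjamini-
Hochberg, the step-up procedure, via `stats::p.adjust`) is applied across
the three-region family on the predictor's $p$-values. Rank-deficient
designs are refused with the collinear columns named.

**Longitudinal.** The change model is interaction-only:

$$\Delta_c = \beta_0 + \beta_1\,\mathrm{PHS}{\times}T + \beta_2\,
\mathrm{CL}(fc){\times}T + \beta_3\,\mathrm{entorhinal}{\times}T +
\beta_4\,\mathrm{age}{\times}T + \beta_5\,\mathrm{sex}{\times}T +
\beta_6\,\mathrm{edu}{\times}T + \beta_7\,\mathrm{APOE}{\times}T +
(1 \mid \mathrm{patient})$$

with $T$ the years since baseline. The equation contains **no Time main
effect**; the default implements it literally, and `timeMainEffect = TRUE`
adds one (common practice, and necessary whenever the population has a
nonzero average slope — the parameter-recovery tests use it because the
synthetic generator has a base atrophy slope). Continuous covariates are
centred and scaled inside the fit; Time stays in years so slopes are
per-year. Fitting is **maximum likelihood** by default (not REML) so
likelihood-ratio tests on fixed effects are valid; a REML flag exists.
$p$-values use Satterthwaite degrees of freedom (`lmerTest`); a singular
random-intercept fit degenerates to OLS with a warning and an
`olsFallback` flag rather than reporting a boundary fit silently.
Cognitive models are restricted to participants who are non-AD at
**baseline** (the restriction-by-diagnosis convention is ambiguous;
baseline diagnosis is the default).

Backward AIC selection repeatedly drops the interaction term whose removal
lowers AIC most, never touching the intercept or random intercept.
Simple-effect slopes at PHS $= \pm 1$ SD are linear contrasts,
$\beta_T + \ell \beta_1$, with delta-method standard errors; their
difference is $2\beta_1$ by construction. The atrophy panel fits the same
model per ROI controlling only for sex, education and APOE (regional
volumes are assumed pre-adjusted for age and intracranial volume upstream;
an optional residualisation against a healthy reference subset covers
inputs that are not), then applies FDR across the 33-ROI family.

## 5. Onset survival analysis

Survival time is years from **birth** to (a) the imputed amyloid onset
(event), (b) withdrawal (censored), or (c) the last completed follow-up
without an event (censored); only the high and low PHS strata enter. Cox
models adjust for baseline age, sex and education and use the Efron tie
approximation; monotone likelihood (complete separation) is an error
suggesting penalisation rather than a silently divergent estimate.
Kaplan-Meier medians are the first age at which survival reaches 0.5
(absent when the curve never does), with complementary log-log confidence
intervals — a CI method choice, made because it respects the [0,1] scale.

Using age as the time scale normally calls for left truncation at study
entry to avoid immortal-time bias, and `truncate = TRUE` provides it. It
is **off by default**, for a structural reason: participants already
abnormal at their first scan have imputed onsets *before* study entry, and
delayed-entry risk sets cannot contain an event that precedes entry — under
truncation such records must be dropped (the implementation does, with a
warning), discarding most prevalent cases. The literal from-birth analysis
keeps them and matches the published definition; the truncated variant is
the conservative incidence-only analysis. With all entry ages set to zero
the two estimators coincide exactly, which is tested.

## 6. The synthetic cohort generator

The generator exists so that every downstream stage can be validated
against known ground truth. Its defaults describe one fixed set of study
conditions mirroring a large longitudinal ageing cohort:

| parameter | default | rationale |
|---|---|---|
| participants | 780 | cohort with both genotype and imaging data |
| panel | 31 SNPs + 2 APOE pseudo-variants | score panel size |
| SNP effects | fixed pattern, \|β\| 0.05–0.18 | GWAS-scale log-hazards |
| APOE weights | ε4 $+1.0$, ε2 $-0.45$ per allele | ε4 dominates the score |
| allele frequencies | uniform 0.05–0.5 | common variants |
| baseline hazard | Gompertz, rate $3\times10^{-6}$/y, shape 0.14/y | incidence doubling ≈ every 5 y; median onset ≈ 75 y at score 0 |
| Centiloid trajectory | logistic, floor 0, ceiling 100, rate 0.15/y | ≈ 2.8 CL/y at threshold, ≈ 19 y from 20 to 80 CL |
| CL noise | 5 CL per scan | test–retest variability |
| visits | every 1.5 y, ≤ 8, dropout 0.18/visit | mean follow-up ≈ 4.8 y |
| entry age | N(73, 6.5), truncated 55–95 | ageing-cohort age structure |

Onset ages are drawn by inverse-transform sampling from
$h(t) = h_0(t) e^{s}$, so the generative hazard ratio between any two
score values is exactly $e^{s_1 - s_2}$ — the property the Cox recovery
tests exploit. Trajectories cross the threshold exactly at the drawn onset
(the anchor invariant); onsets beyond a 110-year horizon are
never-converters. Longitudinal outcomes follow random-intercept linear
growth with score-dependent slopes (atrophy $-0.002$ volume-fraction/y and
cognition $-0.03$ SD/y per score unit — large enough to be recoverable at
cohort scale, small enough to be plausible). APOE enters as two
independent pseudo-variants, which reproduces the qualitative structure
that all ε4/ε4 individuals land in the high stratum and the low stratum
has no carriers; it ignores the real negative association between ε2 and
ε4 carriage.

**Diagnosis is a stand-in.** No generative link from score to clinical
diagnosis is established in this setting, so the generator ranks a noisy
latent severity (entry age minus onset age) and labels the top fractions
AD (10.6%) and MCI (15.9%) to mirror the reference cohort's composition.
Analyses conditioning on diagnosis should read it as a label with the
right marginal frequencies and the right direction of association, nothing
more. CDR-SB is clamped at zero, so its generative model is only
piecewise-linear.

**What passing tests do not show.** The generator has no linkage
disequilibrium, no population stratification, no imputation-error
structure, no tracer- or site-specific Centiloid calibration error, no
informative dropout, and measurement noise is Gaussian and homoscedastic.
Parameter recovery on these cohorts demonstrates that the estimators are
correctly implemented and calibrated under their assumed models — not that
those models are adequate for any particular real cohort.

## 7. Validation problem sizes

The acceptance suite runs oracle equivalences (dot-product scoring, normal
equations, hand-computed Benjamini-Hochberg, grid-searched Cox partial
likelihood on 8 subjects, empirical survival) exactly; parameter recovery
at 800 participants over 100 replicates for the stratum log hazard ratio
$\ln 3.9$, the mixed-model interaction and the cross-sectional slope; null
calibration of the likelihood-ratio and interaction tests over 2000
replicates each (type-I error required inside 0.03–0.07 at nominal 0.05)
and of the 33-ROI FDR family over 25 replicates; and the onset and
stratification accuracy checks of sections 2 and 1. These sizes were
chosen as the smallest at which the binomial noise of a coverage count is
comfortably below the margins being asserted.

## 8. Known limitations

- The progression curve assumes a common trajectory shape shifted in time
  across individuals; pathological heterogeneity in accumulation rate
  appears as curve mis-estimation, not as a flagged condition.
- Onset imputation for saturated scans is bounded by the ceiling clamp and
  therefore compresses genuinely very early onsets toward the clamp level.
- The interaction-only longitudinal model is faithful to its printed form
  but biased whenever a Time main effect truly exists and is omitted; use
  `timeMainEffect = TRUE` unless replicating the literal model.
- Stepwise selection inherits the usual post-selection inference caveats:
  the reported panel weights are conditional on selection and their naive
  standard errors are optimistic.
- No competing-risks handling (death before amyloid abnormality censors
  non-informatively by assumption) and no parametric survival models.
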