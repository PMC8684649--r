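---
title: "Adiposity indices and the MUNO phenotype: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adiposity indices and the MUNO phenotype: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

A substantial fraction of normal-weight maintenance-hemodialysis patients
are metabolically unhealthy: despite a BMI below 25 kg/m², they carry two
or more metabolic-syndrome components and a correspondingly elevated
cardiometabolic risk. This *metabolically unhealthy non-obese* (MUNO)
phenotype is driven largely by visceral fat, which BMI does not see.
Several inexpensive anthropometric/lipid surrogates of visceral adiposity
exist; the practical question is which of them best discriminates MUNO in
a dialysis population, where fluid status, inflammation and the
near-universal prevalence of hypertension distort the usual anthropometric
relationships.

`munodx` implements the full comparison workflow for seven indices —
three traditional (BMI, waist circumference WC, waist-to-height ratio
WHtR) and four visceral-obesity scores (VAI, LAP, CVAI, ABSI) — against a
rule-based MUNO classification, on patient-level records or on a built-in
synthetic cohort.

## The indices

With WC in cm, height in m, TG and HDL-C in mmol/L, age in years:

* BMI = weight / height²; WHtR = WC / height (same length unit).
* LAP (lipid accumulation product):
  men (WC − 65) × TG; women (WC − 58) × TG. Below the sex anchor the
  value is negative; it is retained unmodified, because the downstream
  quartile and ROC analyses are rank-based and a per-cohort count of
  non-positive values is logged instead.
* VAI (visceral adiposity index):
  men WC/(39.68 + 1.88 BMI) × TG/1.03 × 1.31/HDL;
  women WC/(36.58 + 1.89 BMI) × TG/0.81 × 1.52/HDL.
* CVAI (Chinese visceral adiposity index):
  men −267.93 + 0.68 age + 0.03 BMI + 4.00 WC + 22.00 log₁₀TG − 16.32 HDL;
  women −187.32 + 1.71 age + 4.23 BMI + 1.12 WC + 39.76 log₁₀TG − 11.66 HDL.
  The men's BMI coefficient (0.03) is strikingly small next to the
  women's (4.23). We transcribe the constants as printed in the source we
  implement and flag the asymmetry here rather than silently "correcting"
  it; for men the score is in practice dominated by the 4.00 × WC term.
* ABSI (a body shape index): WC(m) / (BMI^{2/3} × height^{1/2}).
  WC is stored in cm everywhere in the package; only this formula
  converts to metres, internally, so a silent 100× unit error cannot
  propagate.

All index computation is in double precision; rounding (2 decimals)
happens only in the presentation copies of the output tables.

## The phenotype rule

A record with BMI < 25 kg/m² is MUNO if at least two of the four
components hold, MHNO otherwise; BMI ≥ 25 is out of scope
(`not_applicable`, and excluded by the eligibility filter):

1. SBP ≥ 130 mmHg or DBP ≥ 85 mmHg, or antihypertensive use;
2. TG ≥ 1.7 mmol/L;
3. HDL-C < 1.0 (men) / < 1.3 (women) mmol/L, or lipid-lowering drug use;
4. FPG ≥ 5.6 mmol/L, or antidiabetic treatment.

Thresholds are inclusive exactly as written. Medication use is sufficient
for its component regardless of the measured value, and lipid-lowering
use feeds only the HDL component, not the TG component — the rule text
attaches it there and we do not extend it. Blood pressure is the single
pre-dialysis SBP/DBP pair stored in the record (understood to be the
average of repeated readings, which is the data provider's job).

Eligibility mirrors the study design: dialysis vintage strictly greater
than 3 months, complete analysis fields (complete-case analysis with a
logged exclusion count — how missing covariates were handled upstream is
not stated, so complete-case is assumed and flagged in the manifest), and
BMI < 25. A record failing several rules is counted once, in the fixed
order vintage → incomplete → BMI, so exclusion reports are reproducible.

## Statistical workflow

**Descriptives.** Continuous variables are summarised as median (IQR) and
compared by Mann–Whitney U; categorical by counts and Pearson chi-square
*without* Yates correction (the choice is not specified in the source
design, so we document ours). Quantiles everywhere use linear
interpolation between order statistics (`stats::quantile` type 7), and
the quartile cutpoints reuse the same estimator so the descriptive and
regression surfaces cannot drift apart. The Mann–Whitney U is computed
from midranks; the two-sided p-value is an exact enumeration of group
assignments when both groups have n < 8 (and the enumeration is below
2×10⁵ assignments), otherwise the normal approximation with continuity
correction. Whether the original analysis used exact or asymptotic
p-values is unstated; asymptotic is the default at the study's sample
sizes.

**Quartile logistic regression.** Each index is binned into quartiles
with the closed-right convention Q1 = (−∞, q25], Q2 = (q25, q50],
Q3 = (q50, q75], Q4 = (q75, ∞); a value exactly at a cutpoint falls in
the lower quartile. MUNO is regressed on three quartile dummies (Q1
reference) adjusted for age (years, continuous), sex (male = 1),
education (≥ junior high = 1) and smoking history (ever = 1), pooling
the sexes — the regression table is not sex-stratified, unlike the ROC
analysis. The fit is maximum likelihood via IRLS (`stats::glm`,
binomial, convergence tolerance 1e−8 on the deviance scale, up to 100
iterations). ORs are exp(coef) with 95% Wald intervals
exp(coef ± 1.96 SE); Wald is documented as our choice since the source
CI style is unstated. A rank-deficient design (constant or collinear
covariate) is an error, and separation (non-convergence or SE > 10) is a
flagged row, never a silent number.

**ROC, Youden, DeLong.** The classification direction is fixed: higher
index predicts MUNO, for all seven indices (all increase with
adiposity/metabolic burden). Empirical ROC curves place one vertex per
distinct score with ties grouped; the trapezoid AUC then equals the
Mann–Whitney pair statistic (#concordant + ½ #tied)/(n₁n₀) exactly,
which the test suite asserts against exhaustive pair counting. Youden's
J = sensitivity + specificity − 1 is maximised over the observed distinct
values (rule: positive if score ≥ cutoff); midpoints between observed
values are not used, and a tie in J resolves to the smallest cutoff —
unambiguous and reproducible. AUC variance, its 95% CI, and the paired
AUC comparison use DeLong's placement-value covariance with normal
theory; the CI is clamped to [0, 1]. Degenerate variance returns the
null result (Z = 0, p = 1) when the two AUCs are equal — e.g. identical
score vectors — and p = 0 with an infinite Z when a real AUC difference
has no sampling variability (perfect separation); both carry a
`degenerate` flag. All p-values are two-sided. The default comparison
list contains the nine pairs whose intervals overlap in the motivating
analysis (BMI–WC, BMI–WHtR, BMI–ABSI, WC–WHtR, WC–ABSI, WC–CVAI,
WHtR–CVAI, WHtR–ABSI, LAP–VAI).

## The synthetic cohort generator

No patient-level hemodialysis data ship with the package; the generator
exists so that every pipeline stage is exercised end-to-end under known
conditions.

**Structure.** A Gaussian copula with four latent factors — metabolic
severity, anthropometry, blood pressure, lipids — produces correlated
standard-normal latents per variable (defaults: WC–BMI ≈ 0.77,
TG–HDL ≈ −0.39, severity coupling TG, FPG, SBP and HDL). Each latent maps
through a monotone inverse-CDF transform to a lognormal marginal
parameterised by a target (median, q1, q3): the lognormal is the simplest
positive, right-skewed family that reproduces a median/IQR summary, which
is how dialysis labs are reported. Age is a truncated normal on 18–90
years (median 54, IQR ≈ 22), rounded to whole years; height is
sex-specific normal (1.66 ± 0.06 m men, 1.55 ± 0.055 m women, typical of
the study region); weight is derived from the drawn BMI and height so
anthropometry is internally consistent. Medication flags follow logistic
links to the latent lab scales (base rates ≈ 0.50 antihypertensive, 0.24
antidiabetic, 0.08 lipid-lowering). Monotone transforms preserve rank
correlations, so the latent correlation matrix is also the Spearman
structure of the output, which the tests verify.

**Marginal targets.** The default per-variable targets are pooled
quantiles of a two-component mixture (34.4% MHNO / 65.6% MUNO) of
lognormal fits to the per-group published medians and IQRs; they are
frozen as numbers in `default_marginals()`. The factor loadings and
medication links are *chosen plausible values*, not estimates from any
cohort — the true inter-variable correlations of the study are unknown —
and are exposed in the configuration precisely so users can vary them.

**The prevalence knob.** The rule-based MUNO prevalence is an emergent
property of the marginals, the dependence and the medication links. The
defaults were calibrated once, at design time, so that the untilted
cohort lands near the 65.6% target; at generation time a scalar tilt
along the severity factor is then solved by bisection so the realised
prevalence among eligible records matches the configured knob exactly
(up to one subject). Because the baseline is already close, the solved
tilt is small (|δ| ≈ 0.04 latent SD at the defaults) and the marginal
medians move by well under 1%. Everything is deterministic given the
seed: all random draws happen up front in a fixed order, and the
bisection is a deterministic function of them.

**Separability scenarios.** `make_separability_scenario()` draws a
MUNO-destined flag per subject and shifts the latents of destined
subjects: a shared mild shift on all metabolic/anthropometric latents
plus a boost on the latents feeding the chosen index. Dominance — the
chosen index attaining the top AUC — is guaranteed *against the destined
flag*; with a zero shift scale the variables are independent of the flag
and all AUCs sit at 0.5. When the scenario cohort is analysed through
the rule-based phenotype instead, indices built from TG and HDL gain an
intrinsic extra advantage because the rule shares their inputs — the
same mathematical coupling the source analysis itself acknowledges as a
limitation — so only TG/HDL-heavy dominant choices (VAI, LAP) are
guaranteed to stay on top through the full pipeline. The boost sizes are
set so that low-variance ratio indices cannot hijack a rival's scenario
(a WC shift alone would hand ABSI, whose variance is tiny, the top AUC;
the WC and WHtR boosts therefore move BMI alongside WC, and the WHtR
boost additionally lowers height). One geometric caveat: a boost sitting
in a rival ratio index's denominator can push that rival *below* chance
(ABSI under a BMI boost).

**What the generator does not emulate.** Real dialysis cohorts have
missingness patterns, device rounding, centre effects, and a joint
distribution in which the phenotype labels and the labs are mutually
consistent by construction — our mixture-plus-rule pipeline only
approximates that. Passing the structural tests therefore shows the
*machinery* is correct under known conditions; it is not evidence about
the discriminative ordering of the indices in any real population.

## Numerical and design choices, collected

* Quantiles: type 7 everywhere (descriptives and quartile cutpoints).
* Quartile intervals closed on the right; boundary value → lower bin.
* Logistic CIs: Wald; convergence 1e−8 (deviance), 100 iterations.
* Youden candidates: observed distinct values; tie → smallest cutoff
  (with a 1e−12 guard so floating-point-equal J values tie correctly).
* DeLong degenerate variance: p = 1 if ΔAUC = 0, p = 0 otherwise.
* Mann–Whitney: exact enumeration below n = 8 per group, tie-aware;
  U reported in the min(U, U′) convention.
* LAP not truncated at 0; non-positive count logged.
* Chi-square without continuity correction.
* Exclusion priority: vintage → incomplete fields → BMI.
* YAML run configs: a bare `n:` key is read back from YAML 1.1's boolean
  interpretation.

## Problem sizes used by the test suite

The suite exercises the oracles on 500 random small ROC instances
(n ≤ 12) against exhaustive enumeration, the DeLong variance against a
10,000-replicate stratified bootstrap at n = 30, null coverage of the
logistic Wald interval over 200 replicates of n = 2000, generator
calibration at n = 5000, and the VAI-dominant scenario at n = 4000;
these sizes give comfortable Monte-Carlo margins for the assertions while
keeping the default test run fast on a single core.

## Known limitations

* The CVAI men's coefficients are transcribed as printed; if the 0.03 BMI
  coefficient is a typographical artefact of the source, men's CVAI
  values here inherit it (ranks, and hence ROC results, are barely
  affected since WC dominates the men's score).
* Complete-case analysis only; no imputation.
* One row per patient; no longitudinal records.
* No trend tests across quartiles, no interaction terms, no partial or
  smoothed ROC, no multiplicity adjustment across descriptive rows —
  faithful to the workflow being implemented, which has none of these.
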