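---
title: "PhysiAge: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PhysiAge: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(PhysiAge)
```

## The model

PhysiAge is a physiological aging score built in two stages.

First, an ordinary least-squares model predicts *phenotypic age* — a
biological-age estimate computed from nine blood-biochemistry markers plus
calendar age through the Levine mapping — from four accessible inputs:

$$\widehat{raw} = \beta_0 + \beta_1\,\mathrm{Sex} + \beta_2\,\mathrm{Gluc}
  + \beta_3\,\mathrm{Steps} + \beta_4\,\mathrm{SysBP}$$

with sex coded 1 = male / 0 = female, fasting glucose in mmol/L, average
daily step count in steps/day and systolic blood pressure in mmHg. The
published constant instance is $(-18.5,\,1.972,\,3.348,\,-0.0004715,\,
0.3988)$, shipped as `publishedPhysiAgeModel()`.

Second, because the raw predictions compress the age axis (predictions
cluster in a narrow band), each prediction is re-anchored by a
*normalization factor*: $NF_a$ is the median raw prediction among training
participants of integer calendar age $a$, and

$$\mathrm{PhysiAge} = \frac{\widehat{raw}}{NF_{\mathrm{age}}}\times
\mathrm{age}, \qquad \Delta\mathrm{Age} = \mathrm{PhysiAge} -
\mathrm{age}.$$

An exact algebraic consequence — and a tested invariant — is that the
median $\Delta$Age within every populated training age is zero: the median
is equivariant under the positive scaling $x \mapsto x\,a/NF_a$, so the
scaled median equals $a$ exactly. $NF$ is the raw per-age median with no
smoothing; ages unpopulated in training are filled by linear interpolation
between the nearest populated ages (nearest value at the endpoints) and
flagged, so downstream users can tell observed from interpolated entries.

The phenotypic-age target is computed as a fully parameterized mapping
(`PhenoAgeConfig`): a linear predictor $xb$ over the nine biomarkers plus
age, a Gompertz-style ten-year mortality risk
$M = 1 - \exp(-e^{xb}(e^{h\gamma}-1)/\gamma)$, and the outer transform
$a + \log(b\log(1-M))/c$. The two transforms compose to an affine function
of $xb$, which the implementation exploits twice: `computePhenoAge()`
evaluates the composition on the log scale (no $1-M$ underflow for extreme
panels, though $M$ is still validated to lie in $(0,1)$), and
`invertBiomarkerForPhenoAge()` solves one biomarker analytically so a panel
hits any target phenotypic age, with round-trip error at machine precision
(contract: $<10^{-6}$ years). CRP is carried on its natural-log scale
(`crp_ln`) so no hidden transform happens inside the mapping. The numeric
Levine constants are not re-derived here; they ship as an externally
sourced, clearly labeled data file, and every self-contained test uses
synthetic configurations or the inversion round-trip instead.

## Pipeline parameters

| parameter | default | units | rationale |
|---|---|---|---|
| QC age range | 20–84 | years | ages at 85 are a code for 85+, held out and scored separately at age 85 with $NF$ clamped to the highest tabulated age |
| zero-entry rule | drop | — | a zero in any physiological column marks a missing measurement; sex (0 = female) and age are exempt |
| step-outlier fence `k` | 1.5 | IQR multiples | box-and-whisker rule over the whole population; accelerometer artifacts reach millions of steps/day |
| `trainFraction` | 0.8 | — | 80/20 split, stratified by sex, per-stratum counts rounded half-up (documented so partitions reproduce across implementations) |
| t test | Welch | — | the contrast is reported only as a two-tailed t test in the source material; Welch is the safer default and the pooled-variance form is one flag away |
| significance stars | 0.05 / 0.01 / 0.001 | — | no multiple-testing correction anywhere in the matching analyses; a BH-FDR column is emitted for reference only |
| signature cutoffs | p < 0.05 (deltaAge), p < 0.01 (groups) | — | strict inequality at the boundary |

The glucose unit is mmol/L throughout; `readCohort()` converts a declared
mg/dL column by dividing by 18.016 and logs the conversion.

## What the synthetic generator emulates

`simulateNhanesCohort()` stands in for a 2005–2006-style survey cohort of
n = 3342 adults aged 20–84 (uniform integer ages). Each physiological
variable is Gaussian around a linear-in-age mean,
$v = v_{20} + s\,(\mathrm{age}-20) + \mathcal N(0,\sigma_v)$, with the
value at age 20 and the residual SD set to clinically plausible adult
values (glucose 5.0 ± 0.8 mmol/L, systolic BP 112 ± 12 mmHg, diastolic BP
74 ± 10, resting heart rate 75 ± 11, BMI 27.5 ± 6, steps 9,500 ± 4,000).

**Slope calibration.** The slope of each variable is solved so that the
*population Spearman* correlation with age equals its target (glucose
0.400, systolic BP 0.474, resting heart rate −0.224, diastolic BP −0.151,
BMI 0.075, steps 0.029). The closed-form Pearson identity
$\rho = s\,\sigma_{age}/\sqrt{s^2\sigma_{age}^2+\sigma_v^2}$ is biased
once ranks are taken (≈ 0.017 too low at $\rho = 0.474$ — a full
2-standard-error half-width at n = 3342), so the implementation instead
root-finds the signal-to-noise ratio on a large fixed internal reference
sample (100,000 draws under a constant internal seed, memoised). The
calibration contract — realized rho within $2/\sqrt{n-3}$ of target — is
tested over 50 seeds. Setting a slope explicitly bypasses calibration.

**Latent phenotypic age.** In the default `age_anchored` mode,
`phenoage_true` = age + a residual with total SD 7.4 years, matching the
observed phenoage–age spread (rho ≈ 0.94 given the uniform-age SD of
≈ 18.8 years). Half of the residual variance
(`phenoage_covariate_share = 0.5`) is carried by the participant's
physiological deviations from their age trend, combined along the
published-coefficient direction; the other half is independent noise. The
share matters: with a purely independent residual the median-per-age
normalization erases *all* mortality-relevant signal from ΔAge by
construction, which would contradict the observed alive/deceased contrast;
conversely, physiology genuinely drives phenotypic age (glucose is itself
one of its nine inputs), so a nonzero share is the realistic choice.
`share = 0` remains available as the fully null generator. A
`planted_truth` mode instead draws `phenoage_true` directly from the
published coefficients over the simulated covariates plus
$\mathcal N(0, \sigma = 12)$, for parameter-recovery studies.

Each participant also receives a nine-biomarker panel constructed by the
analytic inversion so the Levine mapping reproduces `phenoage_true`
exactly (glucose and age are shared with the participant; log-CRP is the
free biomarker). The pipeline therefore computes its own response from the
panel, exercising the same code path real biomarker data would.

**Mortality.** Ten-year vital status follows a Gompertz-type hazard
$h = h_0\,e^{b\,(\mathrm{phenoage}-50)}$ with $h_0 = 0.0025$/yr and
$b = 0.09$/yr — $b$ matches the Gompertz rate of the phenotypic-age
mortality model (0.0077/month) and $h_0$ yields roughly one death per ten
participants over follow-up, like the reference survey's 72/669. An
optional glucose term (`glucoseLogHR`, default 0; 0.3/mmol/L in the
tradeoff study, a diabetes-scale hazard) plants mortality signal that the
phenotypic-age target does not carry, reproducing the direction of the
ablation tradeoff: omitting glucose *improves* the test RMSE against
calendar age while *weakening* the alive/deceased separation.

**Four-group cohort and metabolome.** `simulateMitoHealthCohort()` draws
young (20–30) and trained/normal/impaired older adults (65–80) at sizes
17/19/17/6 with group means ordered so that scored ΔAge ends up
trained < normal < impaired (steps 13,000/8,000/4,000; glucose
5.2/5.6/6.5 mmol/L; systolic BP 125/135/145 mmHg for the older groups).
The metabolomics subset is 12/17/16/3 per group (48 samples; the 36
non-young ones form the older-adult screen subset).
`simulateMetabolome()` plants rank correlation by a Gaussian copula:
normal scores of the ΔAge ranks (and of the ordinal group codes
young = 0 < trained = 1 < normal = 2 < impaired = 3), latent correlation
$r = 2\sin(\pi\rho/6)$, mixed and exponentiated into log-normal
abundances. Planting both a ΔAge and a group target is supported because a
ΔAge-only plant cannot reliably clear the group screen's p < 0.01 — in
this cohort the group ordinal is only weakly rank-correlated with ΔAge
(the young sit between the trained and the normal older adults).  A
caveat: for jointly planted metabolites the *marginal* ΔAge correlation
inside the 36-sample older-adult subset overshoots its nominal target
(the group component adds ΔAge correlation there), so planted-rho
recovery is asserted on a metabolite planted in the ΔAge screen only.

**What the generator does not emulate.** Survey sampling weights, the real
age pyramid, the plateaus of blood pressure and glucose at high ages
(means are linear in age throughout), accelerometer epoch processing, the
true joint distribution of the nine biomarkers, and raw mass-spectrometry
processing. Passing tests show the pipeline's statistics behave correctly
under a controlled data-generating process; they do not certify the
published coefficient values against real survey data.

## Numerical and design choices

- **Seeding.** Every stochastic function takes its own seed and runs in an
  isolated RNG scope, restoring the caller's state; the pipeline expands
  one top-level seed into named per-stage streams, so stage-level reruns
  match the full run. The 85+ block of the cohort generator is drawn from
  a derived substream, making the base cohort realization invariant to
  `n_85plus`. Slope calibration uses its own constant internal seed and is
  independent of cohort seeds.
- **Spearman p-values** use the documented t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ df, mid-ranks for ties,
  pairwise deletion of missing values, and are never NaN: zero rank
  variance is flagged degenerate, $|\rho| = 1$ reports p = 0.
- **Kruskal–Wallis** contrasts delegate to `stats::kruskal.test`
  (tie-corrected, asymptotic chi-square p); a fully constant input is
  defined as H = 0, p = 1, flagged degenerate. Pairwise follow-ups are
  unadjusted Wilcoxon rank-sum tests, emitted as a documented stand-in
  since the pairwise test behind the group figures is not named.
- **85+ convention.** Whether the normalization table should include age
  85 is not decidable from the source material; this implementation clamps
  to the highest tabulated age and logs the clamping.
- **Sex-stratified screen** defaults to Pearson (as its figure caption
  states, in contrast to the Spearman used elsewhere) and is configurable.
- **Worked-example anchoring.** The printed NF table is not available in
  text form, so the worked examples are verified by solving the single NF
  entry each example implies and re-scoring; the 60-year-old steps example
  is the one fully self-contained check (two printed scores share one
  NF_60 ≈ 49.96). The two age-20 examples imply slightly different NF_20
  values (40.33 vs 40.00), an internal inconsistency of the printed
  examples worth knowing about.

## Problem sizes used by the test suite

The suite builds one canonical cohort (n = 3342 plus 81 participants at
the 85+ code), a 59-person four-group cohort with a 48-sample metabolite
matrix, 50-seed replicates for the calibration contract and coefficient
coverage (n = 2673 per replicate), and 200-seed replicates for the
type-I-error checks at 113 metabolites × 36 samples. These sizes keep
every stochastic check at its intended operating point while the whole
suite runs in well under a minute.

## Known limitations

- The clock is linear; pathologically low glucose or blood pressure maps
  to a spuriously young score, and no interaction or plateau terms are
  offered.
- The generator's linear age trends make the normalization factor nearly
  linear in age, unlike the plateau seen in real data at high ages; NF
  behavior above ~75 should not be over-interpreted.
- Mortality is a binary ten-year status with independent draws — no
  censoring times, no survival modeling.
- The shipped phenotypic-age constants are transcribed, not re-derived;
  analyses that depend on their absolute scale inherit that provenance.
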