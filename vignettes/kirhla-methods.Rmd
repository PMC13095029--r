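---
title: "Maternal KIR x fetal HLA-C interaction analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Maternal KIR x fetal HLA-C interaction analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific question

During pregnancy, uterine natural killer cells carrying maternal killer
immunoglobulin-like receptors (KIR) interact with HLA-C molecules on fetal
trophoblast. HLA-C alleles split into two ligand groups by the amino acid at
position 80 — C1 (asparagine) and C2 (lysine) — and KIR gene content forms
two broad haplotypes, A (mostly inhibitory receptors) and B (mostly
activating, including KIR2DS1, the one activating receptor that binds C2).
Because half of the fetal genome is paternal, a fetal C2 allele can be
immunologically "foreign" to a C2-negative mother, and particular maternal
KIR / fetal HLA-C combinations have been proposed to shift offspring birth
weight by amounts on the order of 250 g — an order of magnitude larger than
common-variant effects on birth weight.

`kirhla` implements the full statistical pipeline needed to test such
maternal-fetal genotype (MFG) interactions with *imputed* KIR and HLA types:
pre-imputation SNP panel harmonization, conversion of imputation output into
analysis regressors, phenotype quality control, six interaction linear mixed
models, fixed-effect meta-analysis across cohorts, and a power study under
imputation error. A synthetic cohort generator with the same genetic
structure drives every stage, so the whole pipeline runs and is tested
without access-controlled cohort data.

## The six models

For pair $i$, with birth weight $BW_i$ in grams,

$$BW_i = \beta_0 + \beta_1 F_i + \beta_2 M_i + \beta_3 F_i M_i +
  \boldsymbol\beta_4^\top \mathrm{Cov}_i + u_{m(i)} + \varepsilon_i,$$

where $u_{m(i)} \sim N(0, \sigma^2_m)$ is a random intercept for the mother
(mothers may contribute several children) and
$\varepsilon_i \sim N(0, \sigma^2_e)$. The fetal term $F_i$ is one of

* **C2 presence** — 0/1 for at least one fetal C2-group allele (models 1-2);
* **relative C2 count** — 0/1/2 for fewer/equal/more fetal C2 alleles than
  the mother (models 3-4);
* **paternal-origin C2** — 1 when the fetus carries a C2 that must be
  paternal while the mother is C1/C1 (models 5-6);

and the maternal term $M_i$ is the dosage of either the KIR B haplotype
(AA = 0, AB/BA = 1, BB = 2) or KIR2DS1 copy number (0/1/2), taken as the
expectation under the imputation posterior. $\beta_3$, the MFG interaction,
is the coefficient of interest throughout.

### Parental-origin inference

Only mother-offspring genotypes are observed, so paternal origin is
inferred by transmission logic over the $\le 4$ possible
(maternal-transmitted, paternal) allele assignments:

* mother C1/C1, fetus C1/C2: the C2 must be paternal, and the mother
  carries no C2 — coded 1;
* mother C1/C2, fetus C1/C2: the fetal C2 may be either parent's — the
  pair is excluded from models 5-6 as unresolvable;
* every other consistent combination codes 0. Note that a fetus of a
  C2-carrying mother can hold an unambiguously paternal C2 (e.g. mC1C2 /
  fC2C2), but the indicator targets the allorecognition hypothesis — a
  paternal C2 presented to a C2-*negative* maternal immune system — so such
  pairs are controls, not cases. The test suite checks this coding against
  a brute-force enumerator of all nine genotype combinations; exactly two
  are Mendelian-inconsistent (opposite homozygotes) and exactly one is
  ambiguous.

### Estimation choices

The mixed models are fitted by REML (`lme4::lmer`) with Wald
normal-reference 95% intervals and p-values on the fixed effects; this is
the conventional default for this design and produces exactly the
(estimate, SE) pairs that fixed-effect meta-analysis consumes. The
mother-level variance may legitimately sit on the boundary
($\hat\sigma^2_m = 0$) when sibships are rare; we allow this rather than
erroring, and when every mother has one child the fixed-effect estimates
provably coincide with OLS (tested to 1e-6 relative tolerance). Sex is
coded male = 1; covariates default to offspring sex, gestational age (where
recorded), genotyping batch (when it varies), and five maternal plus five
child ancestry principal components. The interaction estimate is invariant
to recentering covariates, which the suite checks at 1e-8.

## Deriving regressors from imputation output

* **Hard calls.** Dosages or posterior quality scores map to copy number by
  fixed thresholds with an inclusive missing zone: 0 for $d \le 0.3$, 1 for
  $0.7 \le d \le 1.3$, 2 for $d \ge 1.7$, otherwise missing. One rule
  serves both dosage-style and Q-value-style input, since both live on the
  same [0, 2] scale.
* **Ligand groups.** Classification uses the first-field allele family
  alone: C1 = \*01, \*03, \*07, \*08, \*12, \*14, \*16; C2 = \*02, \*04,
  \*05, \*06, \*15, \*17, \*18. Unlisted families are excluded with a
  logged reason rather than silently grouped.
* **KIR dosages** are posterior expectations per locus; a configuration
  switch (`hardcall_kir`) hard-calls them first for sensitivity analyses.
  Whether published analyses used continuous or hard-called KIR dosages is
  not documented; both paths are supported.
* **Mendelian-inconsistent pairs** (opposite homozygotes, expected under
  imputation error) are excluded with a logged reason, not an error.

## Panel harmonization

Before KIR imputation, the SNP panel is restricted to the chromosome 19
KIR region (53-58 Mb, build 37, 1-based inclusive), palindromic (A/T, C/G)
variants whose cohort frequency matches the *complement* of the reference
frequency within 0.05 are strand-flipped, and variants are dropped when
(a) no reference match exists, (b) the cohort-reference frequency
difference exceeds 10 percentage points, or (c) the frequency lies in the
45-55% band where flips are undetectable. The commonly stated fourth
clause for this step ("the same allele ≤55% in one dataset and ≥45% in the
other") is inconsistent taken literally — it would remove nearly every
variant — so it is implemented by its evident intent, a cross-dataset
straddle of 50% within the ambiguity band, and is separately switchable. Since the
within-cohort band rule already covers every straddling variant, the
straddle reason can only appear when the band rule is disabled. Filters are
idempotent and every dropped variant carries exactly one primary reason.

## Phenotype quality control

In order: (1) keep pregnancies carried to term, $37 \le \mathrm{GA} < 43$
weeks, where gestational age exists; (2) for self-reported birth weights,
average repeated reports, excluding individuals whose reports differ by
$\ge 1$ kg or whose mean lies outside (2.5, 4.5) kg; (3) exclude birth
weights beyond $k$ SDs of the cohort mean, computed in a single pass. The
default $k$ is the standard-normal quantile at $1 - 1/(2n)$ rounded to an
integer — the level at which about one observation is expected beyond each
tail — giving $k = 3$ at $n = 625$ and $k = 4$ at $n = 4550$. Cohorts
whose published multiple differs from this rule (the rule's input sample
size is not documented) set `k` explicitly.

## The synthetic cohort generator

The generator is the package's study-conditions definition, not a tuning
dial. Maternal C-group genotypes are Hardy-Weinberg draws at C2 allele
frequency 0.35; KIR haplotypes are drawn at B frequency 0.45 with KIR2DS1
binomial over B copies at 0.9 — plausible European-range values, set once
and configurable, since no population frequencies are published alongside
the models. Fetal genotypes are one uniformly chosen maternal allele plus
a population-drawn paternal allele (random mating; paternal genotypes are
never observed, only inferred). Birth weight follows the model-2 structure
with defaults $\beta_0 = 3500$ g, residual SD 360 g and mother-level SD
300 g (total SD $\approx 470$ g, matching published cohort descriptives of
roughly 3,500 (470) g), sex effect 130 g, gestational-age effect 150
g/week centred at 40 weeks, zero PC effects, and a 10% chance that a
mother contributes a second child sharing her genotypes and random
intercept. Gestational age is drawn from $N(39.9, 1.2^2)$ weeks.

### The imputation-error channel

Imputation error is modelled as a per-locus categorical mis-call: with
probability equal to the accuracy the called state is the truth, otherwise
one of the other two states uniformly. The posterior sharpness is
configurable; the default places the whole posterior mass on the called
state. A deliberately sub-unit default would shrink every dosage toward 1
by a fixed affine map and hence bias interaction estimates away from the
generative value even at accuracy 1.0, so the point-mass default keeps
"accuracy 1 ⇒ exact truth" true end to end. The published sensitivity
analysis describes accuracy only as a scalar (down to 70%), so this
categorical channel is our documented stand-in for its unspecified error
mechanism; it is harsher than real imputation error, which concentrates on
adjacent copy numbers.

What the generator does *not* emulate: SNP-level haplotypes and linkage
disequilibrium (beyond the KIR2DS1-B linkage parameter), population
stratification (PCs are noise with zero effect), assortative mating,
non-European frequency regimes, and correlated HLA/KIR errors. Passing
tests therefore demonstrate the statistical machinery under the assumed
generative model, not robustness to those real-data features.

## Power study

For each (accuracy, effect, n) cell the generator sets **both** the
maternal KIR2DS1 main effect and the interaction to the cell's effect
size, so a single model-2 fit per replicate yields Wald tests for both
endpoints; an effect of 0 estimates the test size. Replicates default to
200 (binomial SE $\le 0.016$ at the null), with the fitted covariates
limited to sex and gestational age. Replicate counts, alpha and the error
model of such sensitivity analyses are rarely standardized; ours are
explicit, configurable choices recorded in the output metadata.

## Numerical and design notes

* Wald (normal) inference everywhere, including the pooled meta-analysis
  estimate — standard fixed-effect IVW practice at these sample sizes.
  Cochran's Q and I² are computed as diagnostics only.
* Degenerate designs (a constant genetic regressor, e.g. no KIR B carriers)
  raise an error naming the column; in multi-model runs the failure is
  recorded and the remaining models proceed.
* Posterior tables must sum to 1 within 1e-6 per sample and locus.
* All randomness flows from named integer seeds; every simulation,
  error-injection and power run is byte-reproducible, and file outputs
  carry `# key: value` metadata headers including the seed.
* Problem sizes used by the test suite: the null-calibration check runs
  1,000 cohorts of 2,000 pairs; effect-recovery runs 200 cohorts of 10,602
  pairs; the power check runs 200 replicates per accuracy at 10,602 pairs.
  These sizes give Monte-Carlo standard errors small enough for the stated
  acceptance bands while keeping a full test run desk-scale.

## Known limitations

* The paternal-origin indicator conditions on C2-negative mothers by
  design; it does not generalize to paternal-origin inference for
  C2-positive mothers (which would require phased or parental data).
* The mixed model assumes Gaussian residuals and a shared mother-level
  variance; no robust/sandwich options are provided.
* No random-effects meta-analysis or meta-regression; heterogeneity is
  reported, not modelled.
* Real genotype imputation (reference panels, phasing, the KIR/HLA
  imputation tools themselves) is upstream of this package and out of
  scope; the pipeline starts from their outputs.
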