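# kirhla

Maternal KIR × fetal HLA-C genotype interaction analysis of offspring
birth weight.

## What this package is for

Maternal killer immunoglobulin-like receptors (KIR) on uterine natural
killer cells engage HLA-C molecules on fetal trophoblast. HLA-C alleles
fall into two ligand groups (C1/C2, by the residue at position 80) and KIR
gene content forms two broad haplotypes, A (inhibitory) and B (activating,
carrying KIR2DS1 which binds C2). Combinations such as *maternal KIR2DS1
with a paternally inherited fetal C2* have been proposed to change birth
weight by ~250 g. Testing this at biobank scale requires *imputed* KIR and
HLA types, and a pipeline that handles everything around the regression:
panel harmonization before KIR imputation, hard-calling and ligand-group
classification, parental-origin inference from mother–offspring genotypes
alone, phenotype QC, per-cohort mixed models and cross-cohort
meta-analysis.

`kirhla` implements that pipeline for statistical geneticists and
perinatal epidemiologists, plus a synthetic mother–offspring cohort
generator (with a configurable imputation-error channel) so every stage
runs, and is tested, without access-controlled cohort data.

## The model

For pair *i* the package fits six variants of

```
BW_i = β0 + β1·F_i + β2·M_i + β3·F_i·M_i + β4·Cov_i + u_mother(i) + ε_i
```

with a mother-level random intercept `u` (REML via lme4) and Wald
inference. `F` is fetal C2 presence (0/1), relative C2 count vs the mother
(0/1/2), or paternal-origin C2 (0/1; mother C1/C1 with fetus C1/C2 —
het/het pairs are excluded as unresolvable). `M` is the maternal KIR
B-haplotype dosage (AA=0, AB/BA=1, BB=2) or KIR2DS1 copy number. Per-cohort
interaction estimates `β3` are pooled by fixed-effect inverse-variance
weighting. See `vignettes/kirhla-methods.Rmd` for the complete account.

## A worked example

```r
library(kirhla)

cfg <- simulation_config(n_pairs = 5000, beta3 = 250, seed = 42)
sim <- simulate_cohort(cfg)                                # truth + phenotypes
obs <- inject_imputation_error(sim$truth, kir_accuracy = 0.95,
                               hla_accuracy = 0.97, seed = 43)
der <- derive_mfg(obs$hla, obs$kir, sim$pairs)             # regressors + audit
des <- build_design(der$derived, sim$pairs, model_spec(2))
fit_mixed_model(des)
```

```
Model 2: presence x kir2ds1_dosage, n = 4909
  interaction: 223.2 g (95% CI 184.9, 261.6), p = 3.4e-30
  variance: mother 98621, residual 132070
```

Of the 5,000 simulated pairs, 4,909 survive derivation (imputation error
produces some hard-call failures and Mendelian-inconsistent pairs, all
logged in the audit table). The simulated 250 g interaction between fetal
C2 presence and maternal KIR2DS1 copy number is recovered at 223 g —
slightly attenuated by the injected genotype error, with a CI covering
the truth; the variance components are the mother-level and residual
variances in g². Pooling across cohorts:

```r
ivw_pool(c(-12, 31, 4), c(28, 45, 19), c("cohortA", "cohortB", "cohortC"))
```

```
IVW fixed-effect meta-analysis of 3 cohort(s)
  pooled: 2.4 g (95% CI -26.6, 31.5), p = 0.869
  heterogeneity: Q = 0.68, I2 = 0.0%
```

A thin command-line wrapper over the same functions lives at
`inst/scripts/kirhla-cli.R` (subcommands `simulate`, `harmonize`,
`derive`, `qc`, `fit`, `meta`, `power`, `all`; YAML configuration).

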