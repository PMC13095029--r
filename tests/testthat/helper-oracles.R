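# Independent brute-force oracles used across tests.

# All 9 mother x fetus ligand-group genotype combinations, as C2-allele
# counts 0/1/2.
mfg_combinations <- expand.grid(mother = 0:2, fetus = 0:2)

genotype_pair <- function(k) {
  switch(as.character(k),
         "0" = c("C1", "C1"),
         "1" = c("C1", "C2"),
         "2" = c("C2", "C2"))
}

# Enumerate every (maternal-transmitted, paternal) allele assignment
# consistent with the fetal genotype multiset and classify the combination:
# Mendelian consistency, the relative-C2 coding, and the paternal-origin C2
# indicator (1 only when every consistent assignment hands the fetus a
# paternal C2 while the mother carries none - the allorecognition condition -
# and NA when the assignments disagree about the paternal allele group).
enumerate_mfg <- function(mother, fetus) {
  assignments <- unique(list(c(fetus[1], fetus[2]), c(fetus[2], fetus[1])))
  consistent <- Filter(function(a) a[1] %in% mother, assignments)
  if (length(consistent) == 0L) {
    return(list(consistent = FALSE, relative = NA, paternal = NA))
  }
  fc <- sum(fetus == "C2")
  mc <- sum(mother == "C2")
  paternal_is_c2 <- unique(vapply(consistent, function(a) a[2] == "C2",
                                  logical(1)))
  pat <- if (length(paternal_is_c2) > 1L) {
    NA_integer_
  } else if (paternal_is_c2 && mc == 0L) {
    1L
  } else {
    0L
  }
  list(consistent = TRUE,
       relative = as.integer(sign(fc - mc) + 1L),
       paternal = pat)
}

# One full simulate -> inject -> derive -> design -> fit pass for model 2.
fit_model2 <- function(cfg, accuracy = 1, covariates = c("sex",
                                                         "gestational_age")) {
  sim <- simulate_cohort(cfg)
  obs <- inject_imputation_error(sim$truth, accuracy, accuracy,
                                 seed = cfg$seed + 1L)
  der <- derive_mfg(obs$hla, obs$kir, sim$pairs)
  des <- build_design(der$derived, sim$pairs, model_spec(2),
                      covariates = covariates)
  fit_mixed_model(des)
}

# Closed-form OLS via the normal equations on a design table.
ols_oracle <- function(design) {
  d <- design$data
  covs <- setdiff(names(d), c("pair_id", "mother_id", "birth_weight",
                              "fetal", "maternal", "interaction"))
  X <- cbind(1, d$fetal, d$maternal,
             if (length(covs)) as.matrix(d[covs]),
             d$fetal * d$maternal)
  beta <- solve(crossprod(X), crossprod(X, d$birth_weight))
  beta[nrow(beta), 1]
}
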