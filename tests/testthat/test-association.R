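sim_derived <- function(n = 800, seed = 1, sibship_rate = 0.1, ...) {
  cfg <- simulation_config(n_pairs = n, seed = seed,
                           sibship_rate = sibship_rate, ...)
  sim <- simulate_cohort(cfg)
  obs <- inject_imputation_error(sim$truth, 1, 1, seed = seed + 1000L)
  der <- derive_mfg(obs$hla, obs$kir, sim$pairs)
  list(derived = der$derived, pairs = sim$pairs)
}

test_that("the six model specifications cross fetal codings with maternal
          terms", {
  fetal <- vapply(1:6, function(m) model_spec(m)$fetal_term, character(1))
  maternal <- vapply(1:6, function(m) model_spec(m)$maternal_term,
                     character(1))
  expect_equal(fetal, rep(c("presence", "relative_count", "paternal_origin"),
                          each = 2))
  expect_equal(maternal, rep(c("kir_b_dosage", "kir2ds1_dosage"), 3))
  expect_error(model_spec(7), "1..6")
})

test_that("ambiguous paternal-origin pairs are dropped from the design of
          models 5-6 only", {
  d <- sim_derived(n = 600, seed = 3)
  n_amb <- sum(is.na(d$derived$pat_c2f))
  expect_gt(n_amb, 0)
  des2 <- build_design(d$derived, d$pairs, model_spec(2))
  des5 <- build_design(d$derived, d$pairs, model_spec(5))
  expect_equal(des2$n_used, nrow(d$derived))
  expect_equal(des5$n_used, nrow(d$derived) - n_amb)
  expect_true(all(des5$audit$reason == "PATERNAL_AMBIGUOUS"))
  expect_setequal(des5$audit$pair_id,
                  d$derived$pair_id[is.na(d$derived$pat_c2f)])
})

test_that("a constant genetic regressor raises a degenerate-design error
          naming the column", {
  d <- sim_derived(n = 300, seed = 4)
  d$derived$kir_b_dosage <- 0       # every mother KIR AA
  expect_error(build_design(d$derived, d$pairs, model_spec(1)),
               "`maternal` is constant")
})

test_that("mixed-model fit returns coherent Wald inference and variance
          components", {
  d <- sim_derived(n = 1000, seed = 5, beta3 = 150)
  des <- build_design(d$derived, d$pairs, model_spec(2))
  fit <- fit_mixed_model(des)
  cf <- fit$coefficients
  expect_true(all(cf$se > 0))
  expect_true(all(cf$ci_low < cf$estimate & cf$estimate < cf$ci_high))
  expect_true(all(c("mother_var", "resid_var") %in%
                    names(fit$var_components)))
  expect_equal(fit$n_used, des$n_used)
  expect_identical(fit$interaction$term, "fetal:maternal")
})

test_that("with one child per mother the LMM reproduces the OLS normal
          equations", {
  for (s in 1:5) {
    d <- sim_derived(n = 400, seed = 100 + s, sibship_rate = 0,
                     beta2 = 80, beta3 = 150)
    des <- build_design(d$derived, d$pairs, model_spec(2),
                        covariates = c("sex", "gestational_age"))
    fit <- fit_mixed_model(des)
    oracle <- ols_oracle(des)
    expect_lt(abs(fit$interaction$estimate - oracle) / abs(oracle), 1e-6)
  }
})

test_that("the interaction estimate is invariant under covariate
          recentering", {
  d <- sim_derived(n = 800, seed = 6, beta3 = 120)
  des_raw <- build_design(d$derived, d$pairs, model_spec(2))
  pairs_centred <- d$pairs
  for (cn in c(paste0("mother_pc", 1:5), paste0("child_pc", 1:5))) {
    pairs_centred[[cn]] <- pairs_centred[[cn]] - mean(pairs_centred[[cn]])
  }
  des_c <- build_design(d$derived, pairs_centred, model_spec(2))
  f1 <- fit_mixed_model(des_raw)
  f2 <- fit_mixed_model(des_c)
  expect_lt(abs(f1$interaction$estimate - f2$interaction$estimate), 1e-8)
})

test_that("run_all_models fits every model, honours missing gestational
          age, and is deterministic", {
  d <- sim_derived(n = 700, seed = 7, beta3 = 100)
  res <- run_all_models(d$derived, d$pairs, cohort_id = "COH1")
  expect_length(res$fits, 6)
  expect_setequal(unique(res$results$model_id), 1:6)
  expect_true(all(res$results$se > 0))
  expect_true("gestational_age" %in% res$fits[["1"]]$covariates)

  no_ga <- d$pairs
  no_ga$gestational_age <- NA_real_
  res_noga <- run_all_models(d$derived, no_ga, cohort_id = "COH1")
  expect_false("gestational_age" %in% res_noga$fits[["1"]]$covariates)

  res2 <- run_all_models(d$derived, d$pairs, cohort_id = "COH1")
  expect_identical(res$results, res2$results)
})

test_that("a failing model is reported without aborting the others", {
  d <- sim_derived(n = 300, seed = 8)
  d$derived$kir_b_dosage <- 0
  res <- run_all_models(d$derived, d$pairs, cohort_id = "X")
  expect_setequal(names(res$errors), c("1", "3", "5"))
  expect_setequal(unique(res$results$model_id), c(2, 4, 6))
})
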