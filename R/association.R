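#' Specification of one of the six interaction models
#'
#' The six models cross three fetal HLA-C2 codings with two maternal KIR
#' terms:
#' \tabular{lll}{
#'   model \tab fetal term \tab maternal term \cr
#'   1 \tab C2 presence (0/1) \tab KIR B-haplotype dosage \cr
#'   2 \tab C2 presence (0/1) \tab KIR2DS1 dosage \cr
#'   3 \tab relative C2 count (0/1/2) \tab KIR B-haplotype dosage \cr
#'   4 \tab relative C2 count (0/1/2) \tab KIR2DS1 dosage \cr
#'   5 \tab paternal-origin C2 (0/1) \tab KIR B-haplotype dosage \cr
#'   6 \tab paternal-origin C2 (0/1) \tab KIR2DS1 dosage \cr
#' }
#' Every model regresses birth weight on the fetal term, the maternal term,
#' their product (the interaction of interest), the configured covariates,
#' and a mother-level random intercept.
#'
#' @param model_id Integer 1-6.
#' @return An object of class `kirhla_model_spec` with elements `model_id`,
#'   `fetal_term` (`"presence"`, `"relative_count"` or `"paternal_origin"`),
#'   `maternal_term` (`"kir_b_dosage"` or `"kir2ds1_dosage"`), and the
#'   derived-table column names `fetal_col`/`maternal_col`.
#' @export
model_spec <- function(model_id) {
  if (!model_id %in% 1:6) stop("`model_id` must be in 1..6", call. = FALSE)
  fetal <- c("presence", "presence", "relative_count", "relative_count",
             "paternal_origin", "paternal_origin")[model_id]
  maternal <- if (model_id %% 2L == 1L) "kir_b_dosage" else "kir2ds1_dosage"
  structure(
    list(
      model_id = as.integer(model_id),
      fetal_term = fetal,
      maternal_term = maternal,
      fetal_col = switch(fetal, presence = "c2f",
                         relative_count = "po_f",
                         paternal_origin = "pat_c2f"),
      maternal_col = maternal
    ),
    class = "kirhla_model_spec"
  )
}

#' Assemble the model-ready design table for one model
#'
#' Merges the derived regressors with the phenotype table on `pair_id`,
#' selects the model's fetal and maternal terms, forms the interaction
#' product, and drops rows with missing regressors or covariates - including
#' the ambiguous-paternal-origin pairs, whose indicator is `NA`, for the
#' paternal-origin models. Covariates default to every one of offspring sex,
#' gestational age, genotyping batch and the five maternal and five child
#' PCs that is present and non-constant in the data; `year_of_birth` is
#' included only when requested.
#'
#' @param derived The `derived` table from [derive_mfg()].
#' @param pheno Phenotype table sharing `pair_id`.
#' @param spec A [model_spec()].
#' @param covariates Optional character vector overriding the automatic
#'   covariate choice (column names in `pheno`; `"sex"` is recoded male = 1).
#' @param year_of_birth Include year of birth as a covariate (default
#'   `FALSE`).
#' @return List of class `kirhla_design`: `data` (columns `birth_weight`,
#'   `mother_id`, `fetal`, `maternal`, covariates), `covariates`, `spec`,
#'   `audit` (dropped pairs and reasons) and `n_used`.
#' @export
build_design <- function(derived, pheno, spec, covariates = NULL,
                         year_of_birth = FALSE) {
  stopifnot(inherits(spec, "kirhla_model_spec"))
  dat <- merge(derived, pheno, by = "pair_id",
               suffixes = c("", ".pheno"), sort = TRUE)

  if (is.null(covariates)) {
    candidates <- c("sex", "gestational_age", "batch",
                    paste0("mother_pc", 1:5), paste0("child_pc", 1:5),
                    if (year_of_birth) "year_of_birth")
    covariates <- intersect(candidates, names(dat))
    covariates <- covariates[vapply(covariates, function(cn) {
      v <- dat[[cn]]
      sum(!is.na(v)) == nrow(dat) && length(unique(v)) > 1L
    }, logical(1))]
  }

  fetal <- dat[[spec$fetal_col]]
  maternal <- dat[[spec$maternal_col]]
  used <- data.frame(
    pair_id = dat$pair_id,
    mother_id = dat$mother_id,
    birth_weight = dat$birth_weight,
    fetal = fetal,
    maternal = maternal,
    stringsAsFactors = FALSE
  )
  for (cn in covariates) {
    used[[cn]] <- if (cn == "sex") as.integer(dat$sex == "male") else dat[[cn]]
  }

  miss <- !stats::complete.cases(used)
  reason <- rep(NA_character_, nrow(used))
  reason[is.na(used$fetal)] <- if (spec$fetal_term == "paternal_origin") {
    "PATERNAL_AMBIGUOUS"
  } else {
    "MISSING_FETAL_TERM"
  }
  reason[is.na(reason) & miss] <- "MISSING_REGRESSOR"
  audit <- data.frame(pair_id = used$pair_id[miss],
                      reason = reason[miss], stringsAsFactors = FALSE)
  used <- used[!miss, , drop = FALSE]
  used$interaction <- used$fetal * used$maternal

  for (cn in c("fetal", "maternal", "interaction")) {
    if (nrow(used) == 0L || stats::var(used[[cn]]) == 0) {
      stop("degenerate design for model ", spec$model_id,
           ": column `", cn, "` is constant", call. = FALSE)
    }
  }
  rownames(used) <- NULL
  structure(list(data = used, covariates = covariates, spec = spec,
                 audit = audit, n_used = nrow(used)),
            class = "kirhla_design")
}

#' Fit one interaction model as a linear mixed model
#'
#' Fits `birth_weight ~ fetal + maternal + fetal:maternal + covariates +
#' (1 | mother_id)` by REML via [lme4::lmer()], with Wald (normal-reference)
#' 95\% confidence intervals and p-values on the fixed effects. The
#' mother-level variance may sit on the boundary (zero) when sibships are
#' rare; in that case - in particular when every mother has exactly one
#' child - the fixed-effect estimates coincide with ordinary least squares.
#'
#' @param design A [build_design()] result.
#' @return Object of class `kirhla_fit`: `coefficients` (term, estimate, se,
#'   ci_low, ci_high, p), `interaction` (the interaction row as a list),
#'   `var_components` (`mother_var`, `resid_var`), `n_used`, `spec`,
#'   `covariates`.
#' @export
fit_mixed_model <- function(design) {
  stopifnot(inherits(design, "kirhla_design"))
  dat <- design$data
  if (length(unique(dat$mother_id)) < 2L) {
    stop("need >= 2 distinct mothers", call. = FALSE)
  }
  covs <- design$covariates
  cov_terms <- if (length(covs)) {
    ifelse(covs == "batch", "factor(batch)", covs)
  } else {
    character(0)
  }
  fml <- stats::as.formula(paste(
    "birth_weight ~ fetal * maternal",
    if (length(cov_terms)) paste("+", paste(cov_terms, collapse = " + "))
    else "",
    "+ (1 | mother_id)"
  ))
  fit <- suppressMessages(lme4::lmer(
    fml, data = dat, REML = TRUE,
    control = lme4::lmerControl(
      calc.derivs = FALSE,
      check.nobs.vs.nlev = "ignore",
      check.nobs.vs.rankZ = "ignore",
      check.nobs.vs.nRE = "ignore"
    )
  ))
  est <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("singular fixed-effect covariance in model ", design$spec$model_id,
         call. = FALSE)
  }
  z <- stats::qnorm(0.975)
  coefs <- data.frame(
    term = names(est),
    estimate = unname(est),
    se = unname(se),
    ci_low = unname(est - z * se),
    ci_high = unname(est + z * se),
    p = unname(2 * stats::pnorm(-abs(est / se))),
    stringsAsFactors = FALSE
  )
  vc <- as.data.frame(lme4::VarCorr(fit))
  mother_var <- vc$vcov[vc$grp == "mother_id"][1]
  resid_var <- vc$vcov[vc$grp == "Residual"][1]
  irow <- coefs[coefs$term == "fetal:maternal", ]
  structure(
    list(
      coefficients = coefs,
      interaction = as.list(irow),
      var_components = c(mother_var = mother_var, resid_var = resid_var),
      n_used = nrow(dat),
      spec = design$spec,
      covariates = covs
    ),
    class = "kirhla_fit"
  )
}

#' @export
print.kirhla_fit <- function(x, ...) {
  s <- x$spec
  cat(sprintf("Model %d: %s x %s, n = %d\n", s$model_id, s$fetal_term,
              s$maternal_term, x$n_used))
  cat(sprintf("  interaction: %.1f g (95%% CI %.1f, %.1f), p = %.3g\n",
              x$interaction$estimate, x$interaction$ci_low,
              x$interaction$ci_high, x$interaction$p))
  cat(sprintf("  variance: mother %.0f, residual %.0f\n",
              x$var_components["mother_var"], x$var_components["resid_var"]))
  invisible(x)
}

#' Fit all six interaction models for one cohort
#'
#' Runs [build_design()] and [fit_mixed_model()] for each requested model and
#' collects every fixed-effect row into one long result table - the input
#' format of the meta-analysis stage. A failing model (e.g. a degenerate
#' design) is recorded with the error message and the run continues.
#'
#' @inheritParams build_design
#' @param cohort_id Label written into the result rows.
#' @param models Integer vector of model ids (default `1:6`).
#' @return List with `results` (columns `cohort`, `model_id`, `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p`, `n_used`), `fits` (the
#'   `kirhla_fit` objects, named by model id) and `errors` (named character
#'   vector of failure messages, if any).
#' @export
run_all_models <- function(derived, pheno, cohort_id = "cohort",
                           models = 1:6, covariates = NULL,
                           year_of_birth = FALSE) {
  rows <- list()
  fits <- list()
  errors <- character(0)
  for (m in models) {
    res <- tryCatch({
      des <- build_design(derived, pheno, model_spec(m),
                          covariates = covariates,
                          year_of_birth = year_of_birth)
      fit_mixed_model(des)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[as.character(m)] <- conditionMessage(res)
      next
    }
    fits[[as.character(m)]] <- res
    cf <- res$coefficients
    rows[[length(rows) + 1L]] <- data.frame(
      cohort = cohort_id, model_id = m, term = cf$term,
      estimate = cf$estimate, se = cf$se,
      ci_low = cf$ci_low, ci_high = cf$ci_high, p = cf$p,
      n_used = res$n_used, stringsAsFactors = FALSE
    )
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cohort = character(0), model_id = integer(0),
               term = character(0), estimate = numeric(0), se = numeric(0),
               ci_low = numeric(0), ci_high = numeric(0), p = numeric(0),
               n_used = integer(0), stringsAsFactors = FALSE)
  rownames(results) <- NULL
  list(results = results, fits = fits, errors = errors)
}
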