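#' Grid for the power-vs-imputation-accuracy study
#'
#' @param accuracy_values Imputation accuracies in (0, 1] applied to both the
#'   KIR and HLA error channels.
#' @param effect_sizes Effect sizes in grams (applied to both the maternal
#'   KIR2DS1 main effect and the interaction in the generative model, so one
#'   fit per replicate yields both endpoints; an effect of 0 estimates the
#'   test size).
#' @param sample_sizes Cohort sizes (mother-offspring pairs).
#' @param alpha Nominal two-sided level of the Wald test.
#' @param replicates Simulated cohorts per grid cell.
#' @param seed Base seed; every cell and replicate derives its own stream
#'   deterministically from it.
#' @return Object of class `kirhla_power_grid`.
#' @export
power_grid <- function(accuracy_values, effect_sizes, sample_sizes,
                       alpha = 0.05, replicates = 200L, seed = 1L) {
  if (any(accuracy_values <= 0 | accuracy_values > 1)) {
    stop("accuracies must lie in (0, 1]", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)",
                                     call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  structure(
    list(accuracy_values = accuracy_values, effect_sizes = effect_sizes,
         sample_sizes = as.integer(sample_sizes), alpha = alpha,
         replicates = as.integer(replicates), seed = as.integer(seed)),
    class = "kirhla_power_grid"
  )
}

#' Estimate power to detect maternal-KIR2DS1 main and interaction effects
#'
#' For every grid cell, repeatedly simulates a cohort with the cell's effect
#' size (on both the maternal KIR2DS1 main effect and the fetal-C2 x
#' KIR2DS1 interaction), passes the true genotypes through the
#' imputation-error channel at the cell's accuracy, derives the analysis
#' regressors, fits the C2-presence x KIR2DS1 mixed model (model 2), and
#' records rejection of each Wald test at `alpha`. Rejection rates are
#' reported with binomial Monte-Carlo standard errors. Cells whose design is
#' degenerate in a replicate (e.g. no genotype variation) count the
#' replicate as failed rather than aborting the run. Fully deterministic
#' given the grid seed.
#'
#' @param grid A [power_grid()].
#' @param config A [simulation_config()] providing the generative model;
#'   its `n_pairs`, `beta2`, `beta3`, accuracies and `seed` are overridden
#'   cell by cell.
#' @param covariates Covariates used in the fitted model (default offspring
#'   sex and gestational age).
#' @return Data frame with one row per cell and endpoint: `accuracy`,
#'   `effect`, `n`, `endpoint` (`"main"`/`"interaction"`), `power`,
#'   `mc_se`, `replicates`, `failed`.
#' @export
estimate_power <- function(grid, config,
                           covariates = c("sex", "gestational_age")) {
  stopifnot(inherits(grid, "kirhla_power_grid"),
            inherits(config, "kirhla_config"))
  cells <- expand.grid(accuracy = grid$accuracy_values,
                       effect = grid$effect_sizes,
                       n = grid$sample_sizes,
                       KEEP.OUT.ATTRS = FALSE)
  out <- list()
  for (ci in seq_len(nrow(cells))) {
    acc <- cells$accuracy[ci]
    eff <- cells$effect[ci]
    n <- cells$n[ci]
    rej_main <- logical(0)
    rej_int <- logical(0)
    failed <- 0L
    for (r in seq_len(grid$replicates)) {
      seed_r <- (grid$seed + 104729L * ci + 2L * r) %% 2147483647L
      cfg <- simulation_config(
        n_pairs = n,
        c2_allele_freq = config$c2_allele_freq,
        kir_b_hap_freq = config$kir_b_hap_freq,
        p_2ds1_given_b = config$p_2ds1_given_b,
        beta0 = config$beta0, beta1 = config$beta1,
        beta2 = eff, beta3 = eff,
        covariate_effects = config$covariate_effects,
        resid_sd = config$resid_sd, mother_sd = config$mother_sd,
        sibship_rate = config$sibship_rate,
        kir_accuracy = acc, hla_accuracy = acc,
        seed = seed_r
      )
      res <- tryCatch({
        sim <- simulate_cohort(cfg)
        obs <- inject_imputation_error(sim$truth, acc, acc,
                                       seed = seed_r + 1L)
        der <- derive_mfg(obs$hla, obs$kir, sim$pairs)
        des <- build_design(der$derived, sim$pairs, model_spec(2),
                            covariates = covariates)
        fit <- fit_mixed_model(des)
        cf <- fit$coefficients
        c(main = cf$p[cf$term == "maternal"],
          interaction = cf$p[cf$term == "fetal:maternal"])
      }, error = function(e) NULL)
      if (is.null(res)) {
        failed <- failed + 1L
      } else {
        rej_main <- c(rej_main, res["main"] < grid$alpha)
        rej_int <- c(rej_int, res["interaction"] < grid$alpha)
      }
    }
    for (ep in c("main", "interaction")) {
      rej <- if (ep == "main") rej_main else rej_int
      p_hat <- if (length(rej)) mean(rej) else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        accuracy = acc, effect = eff, n = n, endpoint = ep,
        power = p_hat,
        mc_se = if (length(rej)) sqrt(p_hat * (1 - p_hat) / length(rej))
        else NA_real_,
        replicates = length(rej), failed = failed,
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "alpha") <- grid$alpha
  attr(res, "seed") <- grid$seed
  res
}

#' Format a power table as per-accuracy power curves
#'
#' Produces a deterministic human-readable summary (one line per grid cell
#' and endpoint, failed cells flagged) alongside the machine-readable table.
#'
#' @param table Output of [estimate_power()].
#' @return Character vector of report lines (invisibly also attached as
#'   `attr(, "table")`).
#' @export
power_report <- function(table) {
  if (nrow(table) == 0L) stop("empty power table", call. = FALSE)
  header <- sprintf(
    "Power curves (alpha = %s, base seed = %s)",
    format(attr(table, "alpha")), format(attr(table, "seed"))
  )
  tab <- table[order(table$endpoint, table$n, table$effect,
                     -table$accuracy), , drop = FALSE]
  lines <- sprintf(
    "  %-12s n=%-6d effect=%6.1f g  accuracy=%.2f  power=%s (MC SE %s)%s",
    tab$endpoint, tab$n, tab$effect, tab$accuracy,
    ifelse(is.na(tab$power), "FAILED", sprintf("%.3f", tab$power)),
    ifelse(is.na(tab$mc_se), "-", sprintf("%.3f", tab$mc_se)),
    ifelse(tab$failed > 0L, sprintf("  [%d failed replicate(s)]", tab$failed),
           "")
  )
  structure(c(header, lines), table = tab)
}
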