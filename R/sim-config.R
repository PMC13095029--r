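#' Configuration for the synthetic mother-offspring cohort generator
#'
#' Bundles every parameter of the generative model: population frequencies of
#' the HLA-C C2 ligand group and the KIR B haplotype, the linkage of KIR2DS1
#' to B-haplotype copies, the birth-weight linear predictor (intercept, fetal,
#' maternal and interaction effects in grams), covariate effects, variance
#' components, the sibship rate, and the per-locus imputation accuracies used
#' by the error channel.
#'
#' The birth-weight model mirrors the interaction regression the package fits:
#' `BW = beta0 + beta1*C2f + beta2*KIR2DS1m + beta3*C2f*KIR2DS1m +
#' covariates + mother intercept + residual`, where `C2f` is fetal C2-group
#' presence (0/1) and `KIR2DS1m` the true maternal KIR2DS1 copy number.
#' Gestational age enters centred at 40 weeks so `beta0` remains the mean
#' birth weight of a C2-negative, KIR2DS1-free pregnancy at term.
#'
#' @param n_pairs Number of mother-offspring pairs to generate.
#' @param c2_allele_freq Population frequency of C2-group HLA-C alleles.
#' @param kir_b_hap_freq Population frequency of the KIR B haplotype.
#' @param p_2ds1_given_b Probability that a B haplotype copy carries KIR2DS1.
#' @param beta0 Intercept, grams.
#' @param beta1 Fetal C2-presence main effect, grams.
#' @param beta2 Maternal KIR2DS1 per-copy main effect, grams.
#' @param beta3 Interaction effect (fetal C2 x maternal KIR2DS1 copy), grams.
#' @param covariate_effects Named list with elements `sex` (grams, male vs
#'   female), `gestational_age` (grams per week, centred at 40 weeks),
#'   `mother_pcs` and `child_pcs` (length-5 numeric, grams per PC unit).
#' @param resid_sd Residual SD, grams. Must be positive.
#' @param mother_sd SD of the mother-level random intercept, grams.
#' @param sibship_rate Probability that a mother contributes a second child
#'   (sharing her random intercept and genotypes).
#' @param kir_accuracy,hla_accuracy Per-locus imputation accuracies in (0, 1]
#'   used by [inject_imputation_error()] when not overridden there.
#' @param seed Integer seed; identical configurations generate identical
#'   cohorts.
#'
#' @return An object of class `kirhla_config` (a validated list).
#' @seealso [simulate_cohort()], [inject_imputation_error()]
#' @export
#' @examples
#' cfg <- simulation_config(n_pairs = 100, beta3 = 250, seed = 1)
#' cohort <- simulate_cohort(cfg)
#' head(cohort$pairs)
simulation_config <- function(n_pairs,
                              c2_allele_freq = 0.35,
                              kir_b_hap_freq = 0.45,
                              p_2ds1_given_b = 0.9,
                              beta0 = 3500,
                              beta1 = 0,
                              beta2 = 0,
                              beta3 = 0,
                              covariate_effects = list(
                                sex = 130,
                                gestational_age = 150,
                                mother_pcs = rep(0, 5),
                                child_pcs = rep(0, 5)
                              ),
                              resid_sd = 360,
                              mother_sd = 300,
                              sibship_rate = 0.1,
                              kir_accuracy = 1,
                              hla_accuracy = 1,
                              seed = 1L) {
  chk_prob <- function(x, name, open_zero = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < 0 || x > 1 || (open_zero && x == 0)) {
      stop("`", name, "` must be a probability in ",
           if (open_zero) "(0, 1]" else "[0, 1]", call. = FALSE)
    }
  }
  if (!is.numeric(n_pairs) || length(n_pairs) != 1L || is.na(n_pairs) ||
      n_pairs < 1 || n_pairs != floor(n_pairs)) {
    stop("`n_pairs` must be a positive integer", call. = FALSE)
  }
  chk_prob(c2_allele_freq, "c2_allele_freq")
  chk_prob(kir_b_hap_freq, "kir_b_hap_freq")
  chk_prob(p_2ds1_given_b, "p_2ds1_given_b")
  chk_prob(sibship_rate, "sibship_rate")
  chk_prob(kir_accuracy, "kir_accuracy", open_zero = TRUE)
  chk_prob(hla_accuracy, "hla_accuracy", open_zero = TRUE)
  if (!is.numeric(resid_sd) || resid_sd <= 0) {
    stop("`resid_sd` must be > 0", call. = FALSE)
  }
  if (!is.numeric(mother_sd) || mother_sd < 0) {
    stop("`mother_sd` must be >= 0", call. = FALSE)
  }
  ce <- covariate_effects
  for (nm in c("sex", "gestational_age", "mother_pcs", "child_pcs")) {
    if (is.null(ce[[nm]])) stop("`covariate_effects$", nm, "` is required",
                                call. = FALSE)
  }
  if (length(ce$mother_pcs) != 5L || length(ce$child_pcs) != 5L) {
    stop("PC effect vectors must have length 5", call. = FALSE)
  }
  structure(
    list(
      n_pairs = as.integer(n_pairs),
      c2_allele_freq = c2_allele_freq,
      kir_b_hap_freq = kir_b_hap_freq,
      p_2ds1_given_b = p_2ds1_given_b,
      beta0 = beta0, beta1 = beta1, beta2 = beta2, beta3 = beta3,
      covariate_effects = ce,
      resid_sd = resid_sd,
      mother_sd = mother_sd,
      sibship_rate = sibship_rate,
      kir_accuracy = kir_accuracy,
      hla_accuracy = hla_accuracy,
      seed = as.integer(seed)
    ),
    class = "kirhla_config"
  )
}

#' @export
print.kirhla_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  pairs: %d  seed: %d  sibship rate: %.2f\n",
              x$n_pairs, x$seed, x$sibship_rate))
  cat(sprintf("  C2 allele freq: %.3f  KIR B hap freq: %.3f  P(2DS1 | B): %.2f\n",
              x$c2_allele_freq, x$kir_b_hap_freq, x$p_2ds1_given_b))
  cat(sprintf("  effects (g): beta0=%.0f beta1=%.0f beta2=%.0f beta3=%.0f\n",
              x$beta0, x$beta1, x$beta2, x$beta3))
  cat(sprintf("  SDs (g): resid=%.0f mother=%.0f\n", x$resid_sd, x$mother_sd))
  cat(sprintf("  imputation accuracy: KIR=%.2f HLA=%.2f\n",
              x$kir_accuracy, x$hla_accuracy))
  invisible(x)
}
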