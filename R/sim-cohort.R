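#' Simulate a mother-offspring cohort with KIR/HLA-C structure
#'
#' Draws maternal HLA-C ligand-group genotypes under Hardy-Weinberg
#' equilibrium at the configured C2 allele frequency, maternal KIR haplotypes
#' (A/B) at the configured B frequency with KIR2DS1 copies binomial over B
#' copies, and fetal genotypes by Mendelian transmission of one uniformly
#' chosen maternal allele plus one paternal allele drawn from the population
#' (random mating). Birth weight follows the configured linear predictor with
#' a mother-level random intercept shared across sibships and a Gaussian
#' residual.
#'
#' Each mother contributes a second child with probability `sibship_rate`;
#' siblings share the mother's genotypes and random intercept but draw their
#' own transmitted/paternal alleles, covariates and residuals. The final
#' mother's sibship is truncated so exactly `n_pairs` pairs are returned.
#'
#' @param config A [simulation_config()] object.
#' @return A list of class `kirhla_cohort` with elements:
#'   \describe{
#'     \item{pairs}{Phenotype/covariate table, one row per pair: `pair_id`,
#'       `mother_id`, `cohort_id`, `birth_weight` (g), `sex`
#'       (`"male"`/`"female"`), `gestational_age` (weeks), `batch`,
#'       `mother_pc1..5`, `child_pc1..5`, `year_of_birth`.}
#'     \item{truth}{Ground-truth genotypes, one row per pair: maternal allele
#'       groups, transmitted and paternal fetal allele groups, maternal KIR
#'       haplotypes, B copies and KIR2DS1 copies.}
#'     \item{config}{The configuration used.}
#'   }
#' @export
#' @examples
#' cohort <- simulate_cohort(simulation_config(n_pairs = 200, seed = 7))
#' table(cohort$truth$fetal_paternal_allele)
simulate_cohort <- function(config) {
  if (!inherits(config, "kirhla_config")) {
    stop("`config` must be created by simulation_config()", call. = FALSE)
  }
  set.seed(config$seed)
  n <- config$n_pairs

  ## allocate pairs to mothers: 1 child each, +1 with prob sibship_rate,
  ## truncated so the pair count is exactly n
  extra <- stats::rbinom(n, 1L, config$sibship_rate)
  kids <- 1L + extra
  cum <- cumsum(kids)
  n_m <- which(cum >= n)[1L]
  kids <- kids[seq_len(n_m)]
  kids[n_m] <- kids[n_m] - (cum[n_m] - n)
  midx <- rep(seq_len(n_m), kids)

  f <- config$c2_allele_freq
  q <- config$kir_b_hap_freq

  ## mother-level draws (1 = C2 / B)
  m_a1 <- stats::rbinom(n_m, 1L, f)
  m_a2 <- stats::rbinom(n_m, 1L, f)
  m_h1 <- stats::rbinom(n_m, 1L, q)
  m_h2 <- stats::rbinom(n_m, 1L, q)
  n_b <- m_h1 + m_h2
  m_2ds1 <- stats::rbinom(n_m, n_b, config$p_2ds1_given_b)
  u_mother <- stats::rnorm(n_m, 0, config$mother_sd)
  m_pcs <- matrix(stats::rnorm(n_m * 5L), n_m, 5L)

  ## pair-level draws
  pick2 <- stats::rbinom(n, 1L, 0.5)
  transmitted <- ifelse(pick2 == 1L, m_a2[midx], m_a1[midx])
  paternal <- stats::rbinom(n, 1L, f)
  sex_male <- stats::rbinom(n, 1L, 0.5)
  ga <- stats::rnorm(n, 39.9, 1.2)
  c_pcs <- matrix(stats::rnorm(n * 5L), n, 5L)
  yob <- sample(1990:2000, n, replace = TRUE)

  c2f <- as.integer(transmitted + paternal > 0L)
  ds1 <- m_2ds1[midx]
  ce <- config$covariate_effects
  lp <- config$beta0 +
    config$beta1 * c2f +
    config$beta2 * ds1 +
    config$beta3 * c2f * ds1 +
    ce$sex * sex_male +
    ce$gestational_age * (ga - 40) +
    drop(m_pcs[midx, , drop = FALSE] %*% ce$mother_pcs) +
    drop(c_pcs %*% ce$child_pcs)
  bw <- lp + u_mother[midx] + stats::rnorm(n, 0, config$resid_sd)

  grp <- function(x) ifelse(x == 1L, "C2", "C1")
  hap <- function(x) ifelse(x == 1L, "B", "A")
  mother_id <- sprintf("M%06d", midx)
  pair_id <- sprintf("P%06d", seq_len(n))

  pairs <- data.frame(
    pair_id = pair_id,
    mother_id = mother_id,
    cohort_id = "SIM",
    birth_weight = bw,
    sex = ifelse(sex_male == 1L, "male", "female"),
    gestational_age = ga,
    batch = "B1",
    stringsAsFactors = FALSE
  )
  colnames(m_pcs) <- paste0("mother_pc", 1:5)
  colnames(c_pcs) <- paste0("child_pc", 1:5)
  pairs <- cbind(pairs,
                 as.data.frame(m_pcs[midx, , drop = FALSE]),
                 as.data.frame(c_pcs))
  pairs$year_of_birth <- yob
  rownames(pairs) <- NULL

  truth <- data.frame(
    pair_id = pair_id,
    mother_id = mother_id,
    mother_allele1 = grp(m_a1[midx]),
    mother_allele2 = grp(m_a2[midx]),
    fetal_maternal_allele = grp(transmitted),
    fetal_paternal_allele = grp(paternal),
    mother_hap1 = hap(m_h1[midx]),
    mother_hap2 = hap(m_h2[midx]),
    mother_b_copies = n_b[midx],
    mother_2ds1_copies = ds1,
    stringsAsFactors = FALSE
  )

  structure(list(pairs = pairs, truth = truth, config = config),
            class = "kirhla_cohort")
}

#' @export
print.kirhla_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d pairs, %d mothers (seed %d)\n",
              nrow(x$pairs), length(unique(x$pairs$mother_id)),
              x$config$seed))
  invisible(x)
}

# HLA-C first-field families used when emitting named alleles; classification
# back to ligand groups must be the identity on these.
.c1_families <- c("01", "03", "07", "08", "12", "14", "16")
.c2_families <- c("02", "04", "05", "06", "15", "17", "18")

#' Pass true genotypes through a per-locus imputation-error channel
#'
#' Emulates imperfect KIR/HLA imputation: at each locus of each individual the
#' called state equals the truth with probability `accuracy`, otherwise one of
#' the other states is chosen uniformly at random. The called state receives
#' posterior mass `posterior_confidence` and the remainder is spread uniformly
#' over the alternative states, so every posterior row sums to 1. With the
#' default point-mass sharpness, `accuracy = 1` reproduces the truth exactly
#' and dosages are exact copy numbers.
#'
#' HLA-C genotypes are treated as a three-state locus (C2-allele count 0/1/2)
#' per individual; mothers appear once even when they contribute two children.
#' Maternal KIR is reported at two loci, the B-haplotype copy number and the
#' KIR2DS1 copy number, in a long KIR*IMP-style posterior table.
#'
#' @param truth The `truth` table of a [simulate_cohort()] result.
#' @param kir_accuracy,hla_accuracy Per-locus accuracies in (0, 1].
#' @param seed Integer seed for the error channel.
#' @param posterior_confidence Posterior mass on the called state, in
#'   (1/3, 1]. Default 1 (point mass).
#' @param hla_format `"dosage"` emits a C2-group dosage (expectation of the
#'   C2-allele count under the posterior) per sample; `"alleles"` emits
#'   two-field allele names with families drawn from the classifiable C1/C2
#'   lists.
#' @return List with `hla` (columns `sample_id`, `allele1`, `allele2`,
#'   `c2_dosage`, `quality`) and `kir` (columns `sample_id`, `locus`,
#'   `state`, `posterior`; loci `"KIR_B_HAPLOTYPE"` and `"KIR2DS1"`).
#' @export
inject_imputation_error <- function(truth, kir_accuracy, hla_accuracy, seed,
                                    posterior_confidence = 1,
                                    hla_format = c("dosage", "alleles")) {
  hla_format <- match.arg(hla_format)
  for (acc in c(kir_accuracy, hla_accuracy)) {
    if (!is.numeric(acc) || length(acc) != 1L || is.na(acc) ||
        acc <= 0 || acc > 1) {
      stop("accuracies must lie in (0, 1]", call. = FALSE)
    }
  }
  if (posterior_confidence <= 1 / 3 || posterior_confidence > 1) {
    stop("`posterior_confidence` must lie in (1/3, 1]", call. = FALSE)
  }
  set.seed(seed)
  conf <- posterior_confidence

  # mis-call a vector of 3-state (0/1/2) truths at the given accuracy
  miscall <- function(true_state, accuracy) {
    n <- length(true_state)
    wrong <- stats::runif(n) >= accuracy
    shift <- sample.int(2L, n, replace = TRUE)
    ifelse(wrong, (true_state + shift) %% 3L, true_state)
  }

  ## ---- HLA: one genotype state per unique individual -----------------------
  first <- !duplicated(truth$mother_id)
  mothers <- data.frame(
    sample_id = truth$mother_id[first],
    state = (truth$mother_allele1[first] == "C2") +
      (truth$mother_allele2[first] == "C2"),
    stringsAsFactors = FALSE
  )
  fetuses <- data.frame(
    sample_id = truth$pair_id,
    state = (truth$fetal_maternal_allele == "C2") +
      (truth$fetal_paternal_allele == "C2"),
    stringsAsFactors = FALSE
  )
  hla_true <- rbind(mothers, fetuses)
  called <- miscall(hla_true$state, hla_accuracy)

  if (hla_format == "dosage") {
    # expectation of the C2 count: conf on the called state, remainder split
    # over the other two states (whose counts sum to 3 - called)
    dosage <- conf * called + (1 - conf) / 2 * (3 - called)
    hla <- data.frame(
      sample_id = hla_true$sample_id,
      allele1 = NA_character_,
      allele2 = NA_character_,
      c2_dosage = dosage,
      quality = conf,
      stringsAsFactors = FALSE
    )
  } else {
    n_i <- length(called)
    fam1 <- ifelse(called >= 1L,
                   sample(.c2_families, n_i, replace = TRUE),
                   sample(.c1_families, n_i, replace = TRUE))
    fam2 <- ifelse(called == 2L,
                   sample(.c2_families, n_i, replace = TRUE),
                   sample(.c1_families, n_i, replace = TRUE))
    hla <- data.frame(
      sample_id = hla_true$sample_id,
      allele1 = sprintf("C*%s:01", fam1),
      allele2 = sprintf("C*%s:01", fam2),
      c2_dosage = NA_real_,
      quality = conf,
      stringsAsFactors = FALSE
    )
  }

  ## ---- KIR: two loci per mother -------------------------------------------
  kir_samples <- truth$mother_id[first]
  b_called <- miscall(truth$mother_b_copies[first], kir_accuracy)
  d_called <- miscall(truth$mother_2ds1_copies[first], kir_accuracy)

  posterior_rows <- function(sample_id, called, locus) {
    n <- length(called)
    state <- rep(0:2, times = n)
    called_rep <- rep(called, each = 3L)
    post <- ifelse(state == called_rep, conf, (1 - conf) / 2)
    data.frame(
      sample_id = rep(sample_id, each = 3L),
      locus = locus,
      state = state,
      posterior = post,
      stringsAsFactors = FALSE
    )
  }
  kir <- rbind(
    posterior_rows(kir_samples, b_called, "KIR_B_HAPLOTYPE"),
    posterior_rows(kir_samples, d_called, "KIR2DS1")
  )

  list(hla = hla, kir = kir)
}
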