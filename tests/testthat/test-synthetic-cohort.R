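test_that("configuration validation rejects invalid probabilities and sizes", {
  expect_error(simulation_config(n_pairs = 0), "positive integer")
  expect_error(simulation_config(n_pairs = 10, c2_allele_freq = 1.2),
               "probability")
  expect_error(simulation_config(n_pairs = 10, resid_sd = 0), "resid_sd")
  expect_error(simulation_config(n_pairs = 10, kir_accuracy = 0), "\\(0, 1\\]")
})

test_that("same config and seed give byte-identical cohorts", {
  cfg <- simulation_config(n_pairs = 500, beta3 = 100, seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$pairs, b$pairs)
  expect_identical(a$truth, b$truth)
  obs1 <- inject_imputation_error(a$truth, 0.8, 0.8, seed = 3)
  obs2 <- inject_imputation_error(b$truth, 0.8, 0.8, seed = 3)
  expect_identical(obs1, obs2)
})

test_that("degenerate C2 frequency of zero makes every genotype C1/C1", {
  cfg <- simulation_config(n_pairs = 300, c2_allele_freq = 0, seed = 2)
  sim <- simulate_cohort(cfg)
  expect_true(all(sim$truth$mother_allele1 == "C1"))
  expect_true(all(sim$truth$fetal_paternal_allele == "C1"))
  obs <- inject_imputation_error(sim$truth, 1, 1, seed = 3)
  der <- derive_mfg(obs$hla, obs$kir, sim$pairs)
  expect_true(all(der$derived$c2f == 0))
})

test_that("allele frequencies and maternal HWE proportions are recovered", {
  f <- 0.35
  n <- 50000
  cfg <- simulation_config(n_pairs = n, c2_allele_freq = f, seed = 101)
  sim <- simulate_cohort(cfg)
  fetal_c2 <- (sim$truth$fetal_maternal_allele == "C2") +
    (sim$truth$fetal_paternal_allele == "C2")
  se_mean <- sqrt(2 * f * (1 - f) / n)
  expect_lt(abs(mean(fetal_c2) - 2 * f), 3 * se_mean)

  first <- !duplicated(sim$truth$mother_id)
  mg <- (sim$truth$mother_allele1[first] == "C2") +
    (sim$truth$mother_allele2[first] == "C2")
  n_m <- sum(first)
  hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  for (g in 0:2) {
    p <- hwe[g + 1]
    expect_lt(abs(mean(mg == g) - p), 3 * sqrt(p * (1 - p) / n_m))
  }
})

test_that("every fetus is Mendelian-consistent with its mother and the
          maternal-labelled allele is carried by the mother", {
  sim <- simulate_cohort(simulation_config(n_pairs = 5000, seed = 5))
  tr <- sim$truth
  carried <- tr$fetal_maternal_allele == tr$mother_allele1 |
    tr$fetal_maternal_allele == tr$mother_allele2
  expect_true(all(carried))
  expect_true(all(tr$mother_2ds1_copies <= tr$mother_b_copies))
})

test_that("birth weight has the configured null moments", {
  cfg <- simulation_config(
    n_pairs = 60000, beta1 = 0, beta2 = 0, beta3 = 0,
    covariate_effects = list(sex = 0, gestational_age = 0,
                             mother_pcs = rep(0, 5), child_pcs = rep(0, 5)),
    resid_sd = 360, mother_sd = 300, seed = 77
  )
  sim <- simulate_cohort(cfg)
  bw <- sim$pairs$birth_weight
  total_sd <- sqrt(360^2 + 300^2)
  expect_lt(abs(mean(bw) - 3500), 4 * total_sd / sqrt(length(bw)))
  expect_lt(abs(sd(bw) - total_sd) / total_sd, 0.02)
})

test_that("sibships share maternal genotypes and raise the pair count
          bookkeeping correctly", {
  cfg <- simulation_config(n_pairs = 2000, sibship_rate = 0.5, seed = 9)
  sim <- simulate_cohort(cfg)
  expect_equal(nrow(sim$pairs), 2000)
  dup <- sim$truth[sim$truth$mother_id %in%
                     sim$truth$mother_id[duplicated(sim$truth$mother_id)], ]
  expect_gt(nrow(dup), 0)
  by_mother <- split(dup, dup$mother_id)
  same_geno <- vapply(by_mother, function(d) {
    length(unique(d$mother_allele1)) == 1L &&
      length(unique(d$mother_2ds1_copies)) == 1L
  }, logical(1))
  expect_true(all(same_geno))
})

test_that("error channel: accuracy 1 reproduces truth through hard calls", {
  sim <- simulate_cohort(simulation_config(n_pairs = 1000, seed = 21))
  obs <- inject_imputation_error(sim$truth, 1, 1, seed = 22)
  der <- derive_mfg(obs$hla, obs$kir, sim$pairs)
  expect_equal(der$n_kept, 1000)
  tr <- sim$truth
  true_fc <- (tr$fetal_maternal_allele == "C2") +
    (tr$fetal_paternal_allele == "C2")
  expect_equal(der$derived$fetal_c2_count, as.integer(true_fc))
  expect_equal(der$derived$kir2ds1_dosage,
               as.numeric(tr$mother_2ds1_copies[match(der$derived$mother_id,
                                                      tr$mother_id)]))
})

test_that("error channel: miscall fraction matches 1 - accuracy", {
  n <- 10000 # mothers, 2 KIR loci each -> 20000 locus calls
  cfg <- simulation_config(n_pairs = n, sibship_rate = 0, seed = 31)
  sim <- simulate_cohort(cfg)
  obs <- inject_imputation_error(sim$truth, 0.7, 1, seed = 32)
  kir <- obs$kir
  called <- kir[kir$posterior == max(kir$posterior), ]
  truth_long <- rbind(
    data.frame(sample_id = sim$truth$mother_id,
               locus = "KIR_B_HAPLOTYPE", true = sim$truth$mother_b_copies),
    data.frame(sample_id = sim$truth$mother_id,
               locus = "KIR2DS1", true = sim$truth$mother_2ds1_copies)
  )
  m <- merge(called, truth_long, by = c("sample_id", "locus"))
  frac <- mean(m$state == m$true)
  expect_lt(abs(frac - 0.7), 3 * sqrt(0.7 * 0.3 / nrow(m)))
})

test_that("error channel posteriors are normalised and sharpness is
          configurable", {
  sim <- simulate_cohort(simulation_config(n_pairs = 200, seed = 41))
  obs <- inject_imputation_error(sim$truth, 0.9, 0.9, seed = 42,
                                 posterior_confidence = 0.9)
  sums <- tapply(obs$kir$posterior, paste(obs$kir$sample_id, obs$kir$locus),
                 sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  expect_equal(sort(unique(obs$kir$posterior)), c(0.05, 0.9))
  expect_error(inject_imputation_error(sim$truth, 0, 1, seed = 1),
               "\\(0, 1\\]")
})

test_that("allele-name output round-trips to the true ligand groups at
          accuracy 1", {
  sim <- simulate_cohort(simulation_config(n_pairs = 500, seed = 51))
  obs <- inject_imputation_error(sim$truth, 1, 1, seed = 52,
                                 hla_format = "alleles")
  expect_true(all(grepl("^C\\*\\d{2}:01$", obs$hla$allele1)))
  der <- derive_mfg(obs$hla, obs$kir, sim$pairs)
  tr <- sim$truth
  true_fc <- (tr$fetal_maternal_allele == "C2") +
    (tr$fetal_paternal_allele == "C2")
  expect_equal(der$derived$fetal_c2_count, as.integer(true_fc))
})
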