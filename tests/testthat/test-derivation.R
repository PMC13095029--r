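test_that("hard-call thresholds map dosages with inclusive boundaries", {
  d <- c(0, 0.3, 0.31, 0.5, 0.69, 0.7, 1, 1.3, 1.31, 1.5, 1.69, 1.7, 1.85, 2)
  expect_equal(
    hardcall_from_dosage(d),
    c(0L, 0L, NA, NA, NA, 1L, 1L, 1L, NA, NA, NA, 2L, 2L, 2L)
  )
  expect_error(hardcall_from_dosage(2.1), "outside")
  expect_error(hardcall_from_dosage(-0.1), "outside")
})

test_that("hard-calling is monotone non-decreasing on its called range", {
  d <- sort(runif(500, 0, 2))
  calls <- hardcall_from_dosage(d)
  called <- calls[!is.na(calls)]
  expect_true(all(diff(called) >= 0))
})

test_that("ligand-group classification covers all 14 families and rejects
          others", {
  c1 <- sprintf("C*%s:01", c("01", "03", "07", "08", "12", "14", "16"))
  c2 <- sprintf("C*%s:01", c("02", "04", "05", "06", "15", "17", "18"))
  expect_equal(classify_c_group(c1), rep("C1", 7))
  expect_equal(classify_c_group(c2), rep("C2", 7))
  expect_equal(classify_c_group("C*04:01"), "C2")
  expect_equal(classify_c_group("C*07:02"), "C1")
  expect_error(classify_c_group("C*99:01"), "unclassifiable")
  expect_warning(res <- classify_c_group("C*99:01", strict = FALSE),
                 "unclassifiable")
  expect_true(is.na(res))
})

test_that("fetal C2 presence saturates at one C2 allele", {
  expect_equal(fetal_c2_presence(c("C1", "C2")), 1L)
  expect_equal(fetal_c2_presence(c("C1", "C1")), 0L)
  expect_equal(fetal_c2_presence(c("C2", "C2")), 1L)
})

test_that("relative and paternal-origin codings match the stated
          configurations", {
  expect_equal(relative_c2_coding(c("C1", "C2"), c("C1", "C1")), 0L)
  expect_equal(relative_c2_coding(c("C1", "C1"), c("C1", "C2")), 2L)
  expect_equal(relative_c2_coding(c("C1", "C2"), c("C2", "C2")), 2L)
  expect_equal(relative_c2_coding(c("C2", "C2"), c("C2", "C2")), 1L)

  expect_equal(paternal_c2_indicator(c("C1", "C1"), c("C1", "C2")), 1L)
  expect_true(is.na(paternal_c2_indicator(c("C1", "C2"), c("C1", "C2"))))
  expect_equal(paternal_c2_indicator(c("C2", "C2"), c("C1", "C2")), 0L)
  expect_error(relative_c2_coding(c("C1", "C1"), c("C2", "C2")),
               "inconsistent")
})

test_that("Mendelian consistency only fails for opposite homozygotes", {
  expect_false(mendelian_consistent(c("C1", "C1"), c("C2", "C2")))
  expect_false(mendelian_consistent(c("C2", "C2"), c("C1", "C1")))
  for (f in 0:2) {
    expect_true(mendelian_consistent(c("C1", "C2"), genotype_pair(f)))
  }
})

test_that("dosage from posteriors is the posterior expectation", {
  expect_equal(dosage_from_posteriors(c("0" = 1, "1" = 0, "2" = 0)), 0)
  expect_equal(dosage_from_posteriors(c("0" = 0, "1" = 1, "2" = 0)), 1)
  expect_equal(dosage_from_posteriors(c("0" = 0.2, "1" = 0.5, "2" = 0.3)),
               1.1)
  expect_error(dosage_from_posteriors(c("0" = 0.5, "1" = 0.4)), "sum to")
})

test_that("derive_mfg excludes and logs bad records with one primary
          reason each", {
  pairs <- data.frame(
    pair_id = c("F1", "F2", "F3", "F4"),
    mother_id = c("M1", "M2", "M3", "M4"),
    stringsAsFactors = FALSE
  )
  hla <- data.frame(
    sample_id = c("M1", "F1", "M2", "F2", "M3", "F3", "M4", "F4"),
    allele1 = c(NA, NA, NA, NA, "C*99:01", "C*01:01", "C*02:01", "C*02:01"),
    allele2 = c(NA, NA, NA, NA, "C*01:01", "C*01:01", "C*01:01", "C*02:01"),
    c2_dosage = c(1, 1, 0.5, 1, NA, NA, NA, NA),
    quality = 1,
    stringsAsFactors = FALSE
  )
  kir <- do.call(rbind, lapply(c("M1", "M2", "M3", "M4"), function(m) {
    data.frame(sample_id = m,
               locus = rep(c("KIR_B_HAPLOTYPE", "KIR2DS1"), each = 3),
               state = rep(0:2, 2),
               posterior = rep(c(0, 1, 0), 2),
               stringsAsFactors = FALSE)
  }))
  res <- derive_mfg(hla, kir, pairs)
  # M2 dosage 0.5 is in the missing zone, M3 allele unclassifiable;
  # F1 (het/het) and F4 (mC1C2/fC2C2) survive
  expect_setequal(res$derived$pair_id, c("F1", "F4"))
  dropped <- res$audit[res$audit$dropped, ]
  expect_equal(dropped$reason[dropped$pair_id == "F2"], "HARDCALL_MISSING")
  expect_equal(dropped$reason[dropped$pair_id == "F3"],
               "UNCLASSIFIED_ALLELE")
  expect_equal(res$n_input, res$n_kept + nrow(dropped))
  # ambiguous pair annotated but kept
  expect_true(is.na(res$derived$pat_c2f[res$derived$pair_id == "F1"]))
  amb <- res$audit[!res$audit$dropped, ]
  expect_equal(amb$pair_id, "F1")
  expect_equal(amb$reason, "PATERNAL_AMBIGUOUS")
})

test_that("derive_mfg detects Mendelian inconsistency and missing KIR", {
  pairs <- data.frame(pair_id = c("F1", "F2"), mother_id = c("M1", "M2"),
                      stringsAsFactors = FALSE)
  hla <- data.frame(
    sample_id = c("M1", "F1", "M2", "F2"),
    allele1 = c("C*01:01", "C*02:01", "C*01:01", "C*01:01"),
    allele2 = c("C*01:01", "C*02:01", "C*01:01", "C*01:01"),
    c2_dosage = NA_real_, quality = 1, stringsAsFactors = FALSE
  )
  kir <- data.frame(sample_id = "M1",
                    locus = rep(c("KIR_B_HAPLOTYPE", "KIR2DS1"), each = 3),
                    state = rep(0:2, 2), posterior = rep(c(1, 0, 0), 2),
                    stringsAsFactors = FALSE)
  res <- derive_mfg(hla, kir, pairs)
  expect_equal(nrow(res$derived), 0)
  expect_setequal(res$audit$reason,
                  c("MENDELIAN_INCONSISTENT", "KIR_MISSING"))
  bad <- data.frame(sample_id = "M1", locus = "KIR2DS1", state = 0:2,
                    posterior = c(0.5, 0.4, 0.08))
  expect_error(derive_mfg(hla, bad, pairs), "sum to 1")
})
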