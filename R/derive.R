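#' Hard-call an imputed dosage
#'
#' Maps a dosage (or HLA*IMP:02-style Q value) in \[0, 2\] to an integer copy
#' number using fixed thresholds with a missing zone between them:
#' 0 for d <= 0.3, 1 for 0.7 <= d <= 1.3, 2 for d >= 1.7, otherwise `NA`.
#' All boundaries are inclusive.
#'
#' @param d Numeric vector of dosages in \[0, 2\].
#' @return Integer vector of calls in `{0, 1, 2, NA}`.
#' @export
#' @examples
#' hardcall_from_dosage(c(0, 0.3, 0.5, 1, 1.5, 1.85, 2))
hardcall_from_dosage <- function(d) {
  if (!is.numeric(d)) stop("`d` must be numeric", call. = FALSE)
  bad <- !is.na(d) & (d < 0 | d > 2)
  if (any(bad)) {
    stop("dosage outside [0, 2]: ", paste(d[bad], collapse = ", "),
         call. = FALSE)
  }
  out <- rep(NA_integer_, length(d))
  out[!is.na(d) & d <= 0.3] <- 0L
  out[!is.na(d) & d >= 0.7 & d <= 1.3] <- 1L
  out[!is.na(d) & d >= 1.7] <- 2L
  out
}

#' Classify an HLA-C allele into the C1 or C2 ligand group
#'
#' Ligand group is determined by the first-field allele family alone (the
#' amino acid at position 80 of the mature protein segregates with the
#' family): C1 families are `*01, *03, *07, *08, *12, *14, *16` and C2
#' families `*02, *04, *05, *06, *15, *17, *18`. The second field is ignored.
#'
#' @param allele Character vector of two-field HLA-C allele names, e.g.
#'   `"C*04:01"`.
#' @param strict If `TRUE` (default) an allele family outside both lists is
#'   an error; if `FALSE` such alleles classify as `NA` with a warning, so
#'   table-level callers can exclude and log them.
#' @return Character vector of `"C1"`/`"C2"` (possibly `NA`).
#' @export
#' @examples
#' classify_c_group(c("C*04:01", "C*07:02"))
classify_c_group <- function(allele, strict = TRUE) {
  fam <- sub("^C\\*([0-9]+).*$", "\\1", allele)
  ok <- grepl("^C\\*[0-9]+(:[0-9]+.*)?$", allele)
  fam <- sprintf("%02d", suppressWarnings(as.integer(fam)))
  out <- rep(NA_character_, length(allele))
  out[ok & fam %in% .c1_families] <- "C1"
  out[ok & fam %in% .c2_families] <- "C2"
  unknown <- is.na(out) & !is.na(allele)
  if (any(unknown)) {
    msg <- paste0("unclassifiable HLA-C allele(s): ",
                  paste(unique(allele[unknown]), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  out
}

.count_c2 <- function(pair) {
  if (length(pair) != 2L || !all(pair %in% c("C1", "C2"))) {
    stop("a genotype must be two values in {\"C1\", \"C2\"}", call. = FALSE)
  }
  sum(pair == "C2")
}

#' Fetal C2-group presence indicator
#'
#' Codes the fetal genotype 1 if at least one C2-group allele is present and
#' 0 otherwise (the fetal term of models 1 and 2).
#'
#' @param fetus Character vector of two ligand groups, e.g. `c("C1", "C2")`.
#' @return 0 or 1.
#' @export
fetal_c2_presence <- function(fetus) {
  as.integer(.count_c2(fetus) > 0L)
}

#' Mendelian consistency of a mother-fetus ligand-group pair
#'
#' A pair is consistent when the fetus carries at least one group the mother
#' could have transmitted, i.e. at least one fetal allele group is present in
#' the maternal genotype.
#'
#' @param mother,fetus Character vectors of two ligand groups each.
#' @return Logical scalar.
#' @export
mendelian_consistent <- function(mother, fetus) {
  mc <- .count_c2(mother)
  fc <- .count_c2(fetus)
  !((mc == 0L && fc == 2L) || (mc == 2L && fc == 0L))
}

#' Relative fetal C2 coding (fewer / equal / more than the mother)
#'
#' Codes the sign of (fetal C2 count - maternal C2 count) as 0 (fewer),
#' 1 (equal) or 2 (more) - the fetal term of models 3 and 4. The "more C2"
#' configurations are mC1C1/fC1C2 and mC1C2/fC2C2.
#'
#' @inheritParams mendelian_consistent
#' @return 0, 1 or 2.
#' @export
relative_c2_coding <- function(mother, fetus) {
  if (!mendelian_consistent(mother, fetus)) {
    stop("Mendelian-inconsistent mother-fetus pair", call. = FALSE)
  }
  as.integer(sign(.count_c2(fetus) - .count_c2(mother)) + 1L)
}

#' Paternal-origin fetal C2 indicator
#'
#' Codes 1 when the fetus carries a C2 allele that must have come from the
#' father while the mother carries no C2 at all (mother C1/C1, fetus C1/C2) -
#' the configuration in which a paternal C2 is presented to a C2-negative
#' maternal immune system. When both mother and fetus are C1/C2 the origin of
#' the fetal C2 cannot be resolved from mother-offspring genotypes alone and
#' the indicator is `NA` (such pairs are excluded from the paternal-origin
#' models). All other consistent configurations code 0: either no fetal C2
#' exists, transmission forces the fetal C2 to be maternal, or the mother
#' herself carries C2.
#'
#' @inheritParams mendelian_consistent
#' @return 1, 0, or `NA` when the origin is ambiguous.
#' @export
#' @examples
#' paternal_c2_indicator(c("C1", "C1"), c("C1", "C2")) # 1
#' paternal_c2_indicator(c("C1", "C2"), c("C1", "C2")) # NA (ambiguous)
#' paternal_c2_indicator(c("C2", "C2"), c("C1", "C2")) # 0 (maternal C2)
paternal_c2_indicator <- function(mother, fetus) {
  if (!mendelian_consistent(mother, fetus)) {
    stop("Mendelian-inconsistent mother-fetus pair", call. = FALSE)
  }
  mc <- .count_c2(mother)
  fc <- .count_c2(fetus)
  if (mc == 0L && fc == 1L) return(1L)
  if (mc == 1L && fc == 1L) return(NA_integer_)
  0L
}

#' Expected copy number under an imputation posterior
#'
#' Converts a per-locus posterior distribution over copy-number states into a
#' continuous dosage (the posterior expectation). Point-mass posteriors give
#' exactly 0, 1 or 2.
#'
#' @param posteriors Numeric vector of probabilities named by copy-number
#'   state (`"0"`, `"1"`, `"2"`), or unnamed in state order 0, 1, 2.
#' @param tol Tolerance for the sum-to-one check.
#' @return Dosage in \[0, 2\].
#' @export
#' @examples
#' dosage_from_posteriors(c("0" = 0.2, "1" = 0.5, "2" = 0.3)) # 1.1
dosage_from_posteriors <- function(posteriors, tol = 1e-6) {
  states <- if (is.null(names(posteriors))) {
    seq_along(posteriors) - 1
  } else {
    as.numeric(names(posteriors))
  }
  if (any(is.na(states)) || any(posteriors < 0)) {
    stop("posteriors must be non-negative and named by integer state",
         call. = FALSE)
  }
  if (abs(sum(posteriors) - 1) > tol) {
    stop("posterior probabilities sum to ", format(sum(posteriors)),
         ", not 1 (tolerance ", tol, ")", call. = FALSE)
  }
  sum(states * posteriors)
}

# vectorised genotype (C2-count) per sample from an HLA call table
.hla_states <- function(hla) {
  has_alleles <- !is.na(hla$allele1) & !is.na(hla$allele2)
  state <- rep(NA_integer_, nrow(hla))
  reason <- rep(NA_character_, nrow(hla))
  if (any(has_alleles)) {
    g1 <- suppressWarnings(classify_c_group(hla$allele1[has_alleles],
                                            strict = FALSE))
    g2 <- suppressWarnings(classify_c_group(hla$allele2[has_alleles],
                                            strict = FALSE))
    s <- (g1 == "C2") + (g2 == "C2")
    state[has_alleles] <- as.integer(s)
    reason[has_alleles][is.na(s)] <- "UNCLASSIFIED_ALLELE"
  }
  from_dosage <- !has_alleles & !is.na(hla$c2_dosage)
  if (any(from_dosage)) {
    hc <- hardcall_from_dosage(hla$c2_dosage[from_dosage])
    state[from_dosage] <- hc
    reason[from_dosage][is.na(hc)] <- "HARDCALL_MISSING"
  }
  reason[is.na(state) & is.na(reason)] <- "NO_HLA_CALL"
  list(state = state, reason = reason)
}

#' Derive maternal-fetal genotype regressors from imputed calls
#'
#' Joins the HLA call table (mothers and offspring) and the maternal KIR
#' posterior table to the pair manifest and computes the Table-style analysis
#' regressors: fetal C2 presence (`c2f`), the relative fetal C2 coding
#' (`po_f`), the paternal-origin C2 indicator (`pat_c2f`, `NA` when
#' ambiguous) and the maternal KIR B-haplotype and KIR2DS1 dosages.
#'
#' Pairs with an unclassifiable allele, a dosage in the hard-call missing
#' zone, a missing HLA/KIR record, or a Mendelian-inconsistent genotype pair
#' are excluded and logged in the audit table with a single primary reason;
#' pairs whose paternal origin is merely ambiguous are kept (with
#' `pat_c2f = NA`) and annotated, since they are dropped only from the
#' paternal-origin models.
#'
#' @param hla HLA call table: `sample_id`, `allele1`, `allele2`, `c2_dosage`,
#'   `quality` (offspring samples keyed by `pair_id`, mothers by
#'   `mother_id`).
#' @param kir KIR posterior table: `sample_id`, `locus`, `state`,
#'   `posterior`, with loci `"KIR_B_HAPLOTYPE"` and `"KIR2DS1"`.
#' @param pairs Pair manifest with at least `pair_id` and `mother_id`.
#' @param hardcall_kir If `TRUE`, KIR dosages are hard-called via
#'   [hardcall_from_dosage()] before use (default keeps the continuous
#'   posterior expectation).
#' @param tol Tolerance for per-locus posterior sums.
#' @return List with `derived` (one row per retained pair: `pair_id`,
#'   `mother_id`, `mother_c2_count`, `fetal_c2_count`, `c2f`, `po_f`,
#'   `pat_c2f`, `kir_b_dosage`, `kir2ds1_dosage`, `mendelian_ok`) and
#'   `audit` (`pair_id`, `reason`, `dropped`).
#' @export
derive_mfg <- function(hla, kir, pairs, hardcall_kir = FALSE, tol = 1e-6) {
  stopifnot(all(c("sample_id", "allele1", "allele2", "c2_dosage") %in%
                  names(hla)),
            all(c("sample_id", "locus", "state", "posterior") %in%
                  names(kir)),
            all(c("pair_id", "mother_id") %in% names(pairs)))

  ## per-locus posterior sums must be 1
  key <- paste(kir$sample_id, kir$locus, sep = "\r")
  sums <- tapply(kir$posterior, key, sum)
  if (any(abs(sums - 1) > tol)) {
    stop("KIR posterior rows do not sum to 1 (tolerance ", tol, ") for: ",
         paste(utils::head(sub("\r", " / ", names(sums)[abs(sums - 1) > tol]),
                           5L), collapse = ", "),
         call. = FALSE)
  }
  dosages <- tapply(kir$state * kir$posterior, key, sum)

  st <- .hla_states(hla)
  m_row <- match(pairs$mother_id, hla$sample_id)
  f_row <- match(pairs$pair_id, hla$sample_id)
  mc <- ifelse(is.na(m_row), NA_integer_, st$state[m_row])
  fc <- ifelse(is.na(f_row), NA_integer_, st$state[f_row])

  b_dos <- dosages[paste(pairs$mother_id, "KIR_B_HAPLOTYPE", sep = "\r")]
  d_dos <- dosages[paste(pairs$mother_id, "KIR2DS1", sep = "\r")]
  if (hardcall_kir) {
    b_dos <- as.numeric(hardcall_from_dosage(pmin(pmax(b_dos, 0), 2)))
    d_dos <- as.numeric(hardcall_from_dosage(pmin(pmax(d_dos, 0), 2)))
  }

  reason <- rep(NA_character_, nrow(pairs))
  reason[is.na(mc)] <- ifelse(is.na(m_row[is.na(mc)]), "NO_HLA_RECORD",
                              st$reason[m_row[is.na(mc)]])
  sel <- is.na(reason) & is.na(fc)
  reason[sel] <- ifelse(is.na(f_row[sel]), "NO_HLA_RECORD",
                        st$reason[f_row[sel]])
  mend_ok <- !is.na(mc) & !is.na(fc) &
    !((mc == 0L & fc == 2L) | (mc == 2L & fc == 0L))
  reason[is.na(reason) & !mend_ok] <- "MENDELIAN_INCONSISTENT"
  reason[is.na(reason) & (is.na(b_dos) | is.na(d_dos))] <- "KIR_MISSING"

  keep <- is.na(reason)
  ambiguous <- keep & mc == 1L & fc == 1L

  derived <- data.frame(
    pair_id = pairs$pair_id[keep],
    mother_id = pairs$mother_id[keep],
    mother_c2_count = mc[keep],
    fetal_c2_count = fc[keep],
    c2f = as.integer(fc[keep] > 0L),
    po_f = as.integer(sign(fc[keep] - mc[keep]) + 1L),
    pat_c2f = ifelse(ambiguous[keep], NA_integer_,
                     as.integer(mc[keep] == 0L & fc[keep] == 1L)),
    kir_b_dosage = as.numeric(b_dos[keep]),
    kir2ds1_dosage = as.numeric(d_dos[keep]),
    mendelian_ok = rep(TRUE, sum(keep)),
    stringsAsFactors = FALSE
  )
  rownames(derived) <- NULL

  audit <- rbind(
    data.frame(pair_id = pairs$pair_id[!keep], reason = reason[!keep],
               dropped = rep(TRUE, sum(!keep)), stringsAsFactors = FALSE),
    data.frame(pair_id = pairs$pair_id[ambiguous],
               reason = rep("PATERNAL_AMBIGUOUS", sum(ambiguous)),
               dropped = rep(FALSE, sum(ambiguous)),
               stringsAsFactors = FALSE)
  )
  rownames(audit) <- NULL

  list(derived = derived, audit = audit,
       n_input = nrow(pairs), n_kept = nrow(derived))
}
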