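#' Term-pregnancy gestational-age filter
#'
#' Keeps pairs carried to term: gestational age >= 37 and < 43 completed
#' weeks. Records without gestational age (cohorts that do not collect it)
#' pass through unfiltered.
#'
#' @param ga Numeric vector of gestational ages in weeks (may contain `NA`).
#' @return Logical vector: `TRUE` = keep.
#' @export
gestation_filter <- function(ga) {
  is.na(ga) | (ga >= 37 & ga < 43)
}

#' Sample-size-derived SD multiple for birth-weight outlier exclusion
#'
#' Returns the number of standard deviations within which essentially all of
#' a cohort's birth weights are expected to fall: the standard-normal
#' quantile at `1 - 1/(2n)` (the level at which one observation is expected
#' beyond each tail), rounded to the nearest integer. Cohorts may override
#' the rule with an explicit k.
#'
#' @param n Cohort sample size (>= 2).
#' @return Integer SD multiple, e.g. 3 at n = 625 and 4 at n = 4550.
#' @export
sd_k_from_n <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 2) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  as.integer(round(stats::qnorm(1 - 1 / (2 * n))))
}

#' Single-pass k-SD birth-weight outlier exclusion
#'
#' Computes the mean and SD once on the supplied weights and drops
#' observations more than `k` SDs from the mean (no re-iteration). With zero
#' variance nothing is dropped and a warning is issued.
#'
#' @param bw Numeric vector of birth weights in grams.
#' @param k Integer SD multiple (see [sd_k_from_n()]).
#' @return Logical vector: `TRUE` = keep.
#' @export
sd_outlier_filter <- function(bw, k) {
  ok <- !is.na(bw)
  if (sum(ok) < 2L) stop("need >= 2 birth weights", call. = FALSE)
  m <- mean(bw[ok])
  s <- stats::sd(bw[ok])
  if (s == 0) {
    warning("zero birth-weight variance; no outliers excluded",
            call. = FALSE)
    return(rep(TRUE, length(bw)))
  }
  is.na(bw) | abs(bw - m) <= k * s
}

#' Clean self-reported birth weights (biobank-style questionnaire data)
#'
#' For an individual with one or more self-reported birth weights in kg:
#' if the spread between reports is >= 1 kg the individual is excluded
#' (reason `SELF_REPORT_DISCREPANCY`); otherwise the reports are averaged.
#' Averages below 2.5 kg or above 4.5 kg are excluded (reason
#' `SELF_REPORT_BOUNDS`) to limit reporting error and residual preterm
#' births in cohorts lacking gestational age. The result is returned in
#' grams.
#'
#' @param reported_weights Numeric vector of reported weights in kg for one
#'   individual.
#' @return Birth weight in grams, or `NA` with a `"reason"` attribute when
#'   excluded (`NA` without a reason for an empty input).
#' @export
#' @examples
#' ukb_selfreport_clean(c(3.2, 3.4)) # 3300
ukb_selfreport_clean <- function(reported_weights) {
  w <- reported_weights[!is.na(reported_weights)]
  if (length(w) == 0L) return(NA_real_)
  if (max(w) - min(w) >= 1) {
    return(structure(NA_real_, reason = "SELF_REPORT_DISCREPANCY"))
  }
  m <- mean(w)
  if (m < 2.5 || m > 4.5) {
    return(structure(NA_real_, reason = "SELF_REPORT_BOUNDS"))
  }
  m * 1000
}

#' Apply the full phenotype QC sequence to one cohort
#'
#' Runs, in order: the gestational-age window (where gestational age is
#' recorded), self-report cleaning (when a `reported_weights` column of
#' semicolon-separated kg values is present, it replaces `birth_weight`),
#' and the single-pass k-SD outlier exclusion with k derived from the
#' post-filter sample size unless overridden. The audit reconciles exactly:
#' input rows = output rows + dropped rows, each with one reason code.
#'
#' @param pheno Phenotype table (see [simulate_cohort()] for the schema).
#' @param k Optional integer override of the SD multiple.
#' @return List with `pheno` (retained rows), `audit` (`pair_id`, `reason`),
#'   `k` (the multiple used) and `n_input`/`n_kept`.
#' @export
qc_cohort <- function(pheno, k = NULL) {
  stopifnot("pair_id" %in% names(pheno), "birth_weight" %in% names(pheno))
  audit <- data.frame(pair_id = character(0), reason = character(0),
                      stringsAsFactors = FALSE)
  cur <- pheno

  if ("gestational_age" %in% names(cur)) {
    keep <- gestation_filter(cur$gestational_age)
    audit <- rbind(audit, data.frame(pair_id = cur$pair_id[!keep],
                                     reason = rep("GA_WINDOW", sum(!keep)),
                                     stringsAsFactors = FALSE))
    cur <- cur[keep, , drop = FALSE]
  }

  if ("reported_weights" %in% names(cur)) {
    parsed <- lapply(strsplit(as.character(cur$reported_weights), ";",
                              fixed = TRUE),
                     function(x) suppressWarnings(as.numeric(x)))
    cleaned <- lapply(parsed, ukb_selfreport_clean)
    bw <- vapply(cleaned, as.numeric, numeric(1))
    reasons <- vapply(cleaned, function(x) {
      r <- attr(x, "reason")
      if (is.null(r)) NA_character_ else r
    }, character(1))
    drop <- !is.na(reasons)
    audit <- rbind(audit, data.frame(pair_id = cur$pair_id[drop],
                                     reason = reasons[drop],
                                     stringsAsFactors = FALSE))
    cur$birth_weight[!drop] <- bw[!drop]
    cur <- cur[!drop, , drop = FALSE]
  }

  if (is.null(k)) k <- sd_k_from_n(nrow(cur))
  keep <- sd_outlier_filter(cur$birth_weight, k)
  audit <- rbind(audit, data.frame(pair_id = cur$pair_id[!keep],
                                   reason = rep("SD_OUTLIER", sum(!keep)),
                                   stringsAsFactors = FALSE))
  cur <- cur[keep, , drop = FALSE]
  rownames(cur) <- NULL
  rownames(audit) <- NULL

  list(pheno = cur, audit = audit, k = k,
       n_input = nrow(pheno), n_kept = nrow(cur))
}
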