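#' Restrict a SNP panel to a genomic window
#'
#' Keeps variants whose 1-based position lies inside `[start, end]`
#' inclusive. The default window is the chromosome 19 segment containing the
#' KIR gene cluster on genome build 37 (53-58 Mb).
#'
#' @param panel Data frame with at least `snp_id` and `position`.
#' @param start,end Window bounds in bp, 1-based inclusive.
#' @return The subset of `panel` inside the window.
#' @export
region_extract <- function(panel, start = 53e6, end = 58e6) {
  if (start >= end) stop("`start` must be < `end`", call. = FALSE)
  panel[!is.na(panel$position) & panel$position >= start &
          panel$position <= end, , drop = FALSE]
}

.is_palindromic <- function(a, b) {
  key <- paste(pmin(toupper(a), toupper(b)), pmax(toupper(a), toupper(b)))
  key %in% c("A T", "C G")
}

#' Flip palindromic SNPs with strand-misaligned frequencies
#'
#' For A/T and C/G SNPs the strand is not identifiable from the alleles, so
#' misalignment shows up as a cohort frequency matching the *complement* of
#' the reference frequency. Rows where `|(1 - cohort_freq) - ref_freq| <=
#' tolerance` while `|cohort_freq - ref_freq| > tolerance` get their allele
#' labels swapped and their cohort frequency complemented; all other rows are
#' returned unchanged. Non-palindromic rows are never flipped (a warning is
#' emitted if only such rows were supplied).
#'
#' @param panel Data frame with `allele_a`, `allele_b`, `cohort_freq`,
#'   `ref_freq` and optionally `palindromic` (computed from the alleles when
#'   absent).
#' @param tolerance Frequency agreement tolerance (default 0.05).
#' @return `panel` with flips applied and a logical `flipped` column.
#' @export
flip_palindromic <- function(panel, tolerance = 0.05) {
  pal <- if ("palindromic" %in% names(panel)) {
    panel$palindromic
  } else {
    .is_palindromic(panel$allele_a, panel$allele_b)
  }
  if (nrow(panel) > 0L && !any(pal)) {
    warning("no palindromic SNPs in input; nothing to flip", call. = FALSE)
  }
  flip <- pal & !is.na(panel$ref_freq) &
    abs((1 - panel$cohort_freq) - panel$ref_freq) <= tolerance &
    abs(panel$cohort_freq - panel$ref_freq) > tolerance
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    tmp <- panel$allele_a[flip]
    panel$allele_a[flip] <- panel$allele_b[flip]
    panel$allele_b[flip] <- tmp
    panel$cohort_freq[flip] <- 1 - panel$cohort_freq[flip]
  }
  panel$flipped <- flip
  panel
}

#' Frequency-consistency filters against the KIR reference panel
#'
#' Applies, in order, the drop rules used before KIR imputation:
#' \enumerate{
#'   \item `UNMATCHED` - no reference frequency available;
#'   \item `FREQ_DIFF` - cohort vs reference allele frequency differs by more
#'     than `max_diff` (default 10 percentage points);
#'   \item `AMBIGUOUS_NEAR_50` - both cohort alleles lie in the ambiguity
#'     band (default \[0.45, 0.55\]), where a strand flip cannot be detected;
#'   \item `AMBIGUOUS_STRADDLE` - the cohort and reference frequencies sit on
#'     opposite sides of 0.50 while both lie in the band (only reachable when
#'     the band rule is disabled, kept as a separate reason).
#' }
#' Each dropped SNP carries exactly one primary reason (the first rule that
#' fires).
#'
#' @param panel Data frame with `snp_id`, `cohort_freq`, `ref_freq`.
#' @param max_diff Maximum tolerated |cohort - reference| frequency
#'   difference.
#' @param band Ambiguity band around 0.5, a length-2 numeric.
#' @param near50_rule,straddle_rule Logical switches for the two ambiguity
#'   rules.
#' @return List with `keep` (retained rows) and `audit`
#'   (`snp_id`, `reason` for dropped rows).
#' @export
frequency_filter <- function(panel, max_diff = 0.10, band = c(0.45, 0.55),
                             near50_rule = TRUE, straddle_rule = TRUE) {
  reason <- rep(NA_character_, nrow(panel))
  cf <- panel$cohort_freq
  rf <- panel$ref_freq
  reason[is.na(rf)] <- "UNMATCHED"
  sel <- is.na(reason) & abs(cf - rf) > max_diff
  reason[sel] <- "FREQ_DIFF"
  in_band <- function(x) x >= band[1] & x <= band[2]
  if (near50_rule) {
    # both cohort alleles in the band <=> the b-allele frequency is in it
    sel <- is.na(reason) & in_band(cf)
    reason[sel] <- "AMBIGUOUS_NEAR_50"
  }
  if (straddle_rule) {
    sel <- is.na(reason) & in_band(cf) & in_band(rf) &
      (cf - 0.5) * (rf - 0.5) < 0
    reason[sel] <- "AMBIGUOUS_STRADDLE"
  }
  keep <- is.na(reason)
  list(
    keep = panel[keep, , drop = FALSE],
    audit = data.frame(snp_id = panel$snp_id[!keep],
                       reason = reason[!keep],
                       stringsAsFactors = FALSE)
  )
}

#' Harmonize a SNP panel against the KIR reference before imputation
#'
#' Runs the full pre-imputation pipeline in the documented order: region
#' extraction, palindromic strand flipping, then the frequency-consistency
#' filters. Re-running on its own output is the identity.
#'
#' @inheritParams region_extract
#' @inheritParams flip_palindromic
#' @inheritParams frequency_filter
#' @param flip_tolerance Tolerance passed to [flip_palindromic()].
#' @return List with `panel` (retained, possibly flipped rows), `audit`
#'   (one `snp_id`/`reason` row per dropped SNP, including
#'   `OUT_OF_REGION`), and `n_input`/`n_kept`.
#' @export
harmonize_panel <- function(panel, start = 53e6, end = 58e6,
                            flip_tolerance = 0.05, max_diff = 0.10,
                            band = c(0.45, 0.55), near50_rule = TRUE,
                            straddle_rule = TRUE) {
  in_region <- region_extract(panel, start, end)
  audit <- data.frame(
    snp_id = setdiff(panel$snp_id, in_region$snp_id),
    reason = if (nrow(in_region) < nrow(panel)) "OUT_OF_REGION" else
      character(0),
    stringsAsFactors = FALSE
  )
  flipped <- suppressWarnings(flip_palindromic(in_region, flip_tolerance))
  filt <- frequency_filter(flipped, max_diff = max_diff, band = band,
                           near50_rule = near50_rule,
                           straddle_rule = straddle_rule)
  audit <- rbind(audit, filt$audit)
  rownames(audit) <- NULL
  list(panel = filt$keep, audit = audit,
       n_input = nrow(panel), n_kept = nrow(filt$keep))
}

#' Harmonize Oxford HAPS/SAMPLE haplotypes against reference frequencies
#'
#' Computes cohort allele-b frequencies directly from the phased haplotype
#' columns, matches each variant to the reference frequency table by
#' `snp_id`, applies [harmonize_panel()], and returns the HAPS object
#' restricted to the retained variants (with flipped rows' allele labels,
#' haplotype codes and frequencies complemented).
#'
#' @param haps A haplotype panel from [read_haps()] (list with `snps` and
#'   0/1 `haplotypes` matrix).
#' @param ref_freq Data frame with `snp_id` and `freq` (reference frequency
#'   of allele b).
#' @param ... Passed to [harmonize_panel()].
#' @return List with `haps` (filtered panel), `audit` and the harmonized
#'   `panel` table.
#' @export
harmonize_haps <- function(haps, ref_freq, ...) {
  snps <- haps$snps
  panel <- data.frame(
    snp_id = snps$snp_id,
    position = snps$position,
    allele_a = snps$allele_a,
    allele_b = snps$allele_b,
    cohort_freq = rowMeans(haps$haplotypes),
    ref_freq = ref_freq$freq[match(snps$snp_id, ref_freq$snp_id)],
    stringsAsFactors = FALSE
  )
  res <- harmonize_panel(panel, ...)
  keep_idx <- match(res$panel$snp_id, snps$snp_id)
  out_snps <- snps[keep_idx, , drop = FALSE]
  out_hap <- haps$haplotypes[keep_idx, , drop = FALSE]
  was_flipped <- res$panel$flipped
  if (any(was_flipped)) {
    tmp <- out_snps$allele_a[was_flipped]
    out_snps$allele_a[was_flipped] <- out_snps$allele_b[was_flipped]
    out_snps$allele_b[was_flipped] <- tmp
    out_hap[was_flipped, ] <- 1L - out_hap[was_flipped, ]
  }
  rownames(out_snps) <- NULL
  list(haps = list(snps = out_snps, haplotypes = out_hap,
                   samples = haps$samples),
       panel = res$panel, audit = res$audit,
       n_input = res$n_input, n_kept = res$n_kept)
}
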