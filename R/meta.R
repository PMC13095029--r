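#' Fixed-effect inverse-variance weighted pooling
#'
#' Pools per-cohort estimates with weights proportional to the inverse
#' squared standard errors: the pooled estimate is the weighted mean, the
#' pooled standard error `(sum 1/se^2)^(-1/2)`, with a normal-reference 95\%
#' confidence interval and two-sided p-value. Cochran's Q and I^2 are
#' reported as heterogeneity diagnostics only.
#'
#' @param estimate Numeric vector of per-cohort effect estimates (grams).
#' @param se Positive per-cohort standard errors.
#' @param cohort Optional cohort labels (defaults to `study1`, ...).
#' @return Object of class `kirhla_meta`: `estimate`, `se`, `ci_low`,
#'   `ci_high`, `p`, `weights` (normalised, named by cohort), `q`, `i2`,
#'   `k` (number of studies).
#' @export
#' @examples
#' ivw_pool(c(10, -4, 0), c(2, 5, 1))
ivw_pool <- function(estimate, se, cohort = NULL) {
  if (length(estimate) == 0L) stop("no effects to pool", call. = FALSE)
  if (length(se) != length(estimate)) {
    stop("`estimate` and `se` lengths differ", call. = FALSE)
  }
  if (any(!is.finite(se)) || any(se <= 0)) {
    stop("standard errors must be positive and finite", call. = FALSE)
  }
  if (is.null(cohort)) cohort <- paste0("study", seq_along(estimate))
  w <- 1 / se^2
  pooled <- sum(w * estimate) / sum(w)
  pooled_se <- 1 / sqrt(sum(w))
  z <- stats::qnorm(0.975)
  q <- sum(w * (estimate - pooled)^2)
  df <- length(estimate) - 1L
  i2 <- if (df > 0L && q > 0) max(0, (q - df) / q) * 100 else 0
  structure(
    list(
      estimate = pooled,
      se = pooled_se,
      ci_low = pooled - z * pooled_se,
      ci_high = pooled + z * pooled_se,
      p = 2 * stats::pnorm(-abs(pooled / pooled_se)),
      weights = stats::setNames(w / sum(w), cohort),
      q = q, i2 = i2, k = length(estimate)
    ),
    class = "kirhla_meta"
  )
}

#' @export
print.kirhla_meta <- function(x, ...) {
  cat(sprintf("IVW fixed-effect meta-analysis of %d cohort(s)\n", x$k))
  cat(sprintf("  pooled: %.1f g (95%% CI %.1f, %.1f), p = %.3g\n",
              x$estimate, x$ci_low, x$ci_high, x$p))
  cat(sprintf("  heterogeneity: Q = %.2f, I2 = %.1f%%\n", x$q, x$i2))
  invisible(x)
}

#' Meta-analyse the interaction term of every model across cohorts
#'
#' Takes the long result table produced by [run_all_models()] (possibly
#' row-bound over cohorts), extracts the interaction rows, and pools them per
#' model with [ivw_pool()].
#'
#' @param results Result table with columns `cohort`, `model_id`, `term`,
#'   `estimate`, `se`, `n_used`.
#' @param term Which term to pool (default the interaction).
#' @return Named list of `kirhla_meta` objects, one per model id present.
#' @export
meta_analyse <- function(results, term = "fetal:maternal") {
  rows <- results[results$term == term, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows with term `", term, "`", call. = FALSE)
  out <- list()
  for (m in sort(unique(rows$model_id))) {
    r <- rows[rows$model_id == m, , drop = FALSE]
    r <- r[order(r$cohort), , drop = FALSE]
    out[[as.character(m)]] <- ivw_pool(r$estimate, r$se, r$cohort)
  }
  out
}

#' Forest-style table of cohort and pooled interaction effects
#'
#' Builds, for each model, a block of cohort rows (ordered by cohort id)
#' followed by a pooled row - the tabular form of a forest plot. Panels
#' group the models by fetal HLA-C2 condition: A = C2 presence (models 1-2),
#' B = relative C2 count (models 3-4), C = paternal-origin C2 (models 5-6).
#'
#' @inheritParams meta_analyse
#' @return Data frame with columns `model_id`, `panel`, `maternal_term`,
#'   `row_type` (`"cohort"`/`"pooled"`), `cohort`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `p`, `weight`, `n_used`.
#' @export
forest_table <- function(results, term = "fetal:maternal") {
  rows <- results[results$term == term, , drop = FALSE]
  if (nrow(rows) == 0L) stop("no rows with term `", term, "`", call. = FALSE)
  panel_of <- c("A", "A", "B", "B", "C", "C")
  blocks <- list()
  for (m in sort(unique(rows$model_id))) {
    r <- rows[rows$model_id == m, , drop = FALSE]
    r <- r[order(r$cohort), , drop = FALSE]
    pooled <- ivw_pool(r$estimate, r$se, r$cohort)
    spec <- model_spec(m)
    blocks[[length(blocks) + 1L]] <- data.frame(
      model_id = m,
      panel = panel_of[m],
      maternal_term = spec$maternal_term,
      row_type = c(rep("cohort", nrow(r)), "pooled"),
      cohort = c(r$cohort, "pooled"),
      estimate = c(r$estimate, pooled$estimate),
      se = c(r$se, pooled$se),
      ci_low = c(r$ci_low, pooled$ci_low),
      ci_high = c(r$ci_high, pooled$ci_high),
      p = c(r$p, pooled$p),
      weight = c(unname(pooled$weights), 1),
      n_used = c(r$n_used, sum(r$n_used)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out
}
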