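#' Inverse-variance-weighted fixed-effects pooling for one CpG
#'
#' Weights `w_i = 1/se_i^2`; pooled estimate `sum(w*b)/sum(w)`; pooled SE
#' `1/sqrt(sum(w))`; two-sided normal p-value; Cochran's
#' `Q = sum(w*(b - pooled)^2)` and `I2 = max(0, (Q - (k-1))/Q) * 100`
#' computed from the same fixed-effects weights as heterogeneity
#' diagnostics.  Non-converged rows are dropped before pooling.
#'
#' @param rows data frame of per-cohort results for one CpG, with columns
#'   `beta, se, converged` (and optionally `cpg_id`, `cohort_id`).
#' @param min_cohorts minimum number of contributing cohorts (default 3).
#' @param cohort_order fixed cohort ordering for the direction string; by
#'   default the order of appearance.
#' @return one-row data frame: `cpg_id, beta_pooled, se_pooled, pval, k, Q,
#'   I2, direction_string`, or `NULL` (with attribute `"reason"`) when fewer
#'   than `min_cohorts` converged rows are available.
#' @export
ivw_fixed_effects <- function(rows, min_cohorts = 3L,
                              cohort_order = NULL) {
  ok <- if ("converged" %in% names(rows)) rows$converged &
          is.finite(rows$beta) & is.finite(rows$se) & rows$se > 0
        else is.finite(rows$beta) & is.finite(rows$se) & rows$se > 0
  use <- rows[ok, , drop = FALSE]
  k <- nrow(use)
  cid <- if ("cpg_id" %in% names(rows) && nrow(rows) > 0) rows$cpg_id[1]
         else NA_character_
  if (k < min_cohorts) return(NULL)
  w <- 1 / use$se^2
  bp <- sum(w * use$beta) / sum(w)
  sp <- 1 / sqrt(sum(w))
  Q <- sum(w * (use$beta - bp)^2)
  if (k == 1 || Q < 1e-12) Q <- 0
  I2 <- if (Q > 0) max(0, (Q - (k - 1)) / Q) * 100 else 0
  dirs <- if (!is.null(cohort_order) && "cohort_id" %in% names(rows)) {
    v <- rep("?", length(cohort_order))
    idx <- match(use$cohort_id, cohort_order)
    v[idx[!is.na(idx)]] <- ifelse(use$beta[!is.na(idx)] >= 0, "+", "-")
    paste(v, collapse = "")
  } else paste(ifelse(use$beta >= 0, "+", "-"), collapse = "")
  data.frame(cpg_id = cid, beta_pooled = bp, se_pooled = sp,
             pval = 2 * stats::pnorm(-abs(bp) / sp), k = k, Q = Q, I2 = I2,
             direction_string = dirs, stringsAsFactors = FALSE)
}

#' Meta-analyze per-cohort EWAS results across all CpGs
#'
#' Pools every CpG with [ivw_fixed_effects()], then attaches Bonferroni and
#' Benjamini-Hochberg FDR significance flags (family = CpGs actually
#' pooled) and reports the genomic inflation factor of the pooled p-values.
#'
#' @param results row-bound per-cohort [fit_cox_per_cpg()] outputs.
#' @param min_cohorts minimum contributing cohorts per CpG.
#' @param alpha significance level for both multiplicity procedures.
#' @return list with `meta` (data frame of `MetaRow`s incl. `bonferroni_sig`
#'   and `fdr_sig`), `lambda` (genomic inflation of pooled p-values),
#'   `omitted` (character vector of omission reasons).
#' @export
meta_analyze <- function(results, min_cohorts = 3L, alpha = 0.05) {
  cohort_order <- unique(results$cohort_id)
  split_rows <- split(results, results$cpg_id)
  pooled <- lapply(split_rows, ivw_fixed_effects, min_cohorts = min_cohorts,
                   cohort_order = cohort_order)
  omitted <- sprintf("%s: fewer than %d converged cohorts",
                     names(pooled)[vapply(pooled, is.null, logical(1))],
                     min_cohorts)
  meta <- do.call(rbind, pooled[!vapply(pooled, is.null, logical(1))])
  if (is.null(meta) || nrow(meta) == 0)
    return(list(meta = NULL, lambda = NA_real_, omitted = omitted))
  rownames(meta) <- NULL
  flags <- multiplicity(meta$pval, alpha = alpha)
  meta$bonferroni_sig <- flags$bonferroni
  meta$fdr_sig <- flags$fdr
  list(meta = meta, lambda = genomic_inflation(meta$pval), omitted = omitted)
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(1 - p, 1)) / qchisq(0.5, 1)`: the ratio of the
#' observed median association chi-square to its null expectation (0.4549).
#' Values near 1 indicate calibrated tests.
#'
#' @param pvals p-values in (0, 1].
#' @return scalar lambda.
#' @export
genomic_inflation <- function(pvals) {
  if (length(pvals) == 0) stop("empty p-value list")
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::median(stats::qchisq(1 - pvals, df = 1)) / stats::qchisq(0.5, 1)
}

#' Bonferroni and Benjamini-Hochberg significance flags
#'
#' @param pvals p-values in (0, 1].
#' @param alpha family-wise / FDR level (default 0.05).
#' @return list of logical vectors `bonferroni` (p <= alpha/m) and `fdr`
#'   (BH step-up at level alpha).
#' @export
multiplicity <- function(pvals, alpha = 0.05) {
  m <- length(pvals)
  list(bonferroni = pvals <= alpha / m,
       fdr = stats::p.adjust(pvals, method = "BH") <= alpha)
}

#' Leave-one-out cohort sensitivity for one CpG
#'
#' Re-pools the CpG `k` times, omitting one cohort each time.
#'
#' @param rows per-cohort results for one CpG (as in [ivw_fixed_effects()]).
#' @param min_cohorts minimum cohorts for each reduced pooling.
#' @return data frame with a `left_out` column and one `MetaRow` per
#'   omitted cohort; empty (with a warning) when fewer than
#'   `min_cohorts + 1` cohorts contribute.
#' @export
leave_one_out <- function(rows, min_cohorts = 3L) {
  ok <- rows$converged & is.finite(rows$se) & rows$se > 0
  use <- rows[ok, , drop = FALSE]
  if (nrow(use) < min_cohorts + 1) {
    warning("too few cohorts for leave-one-out validation")
    return(data.frame())
  }
  out <- lapply(seq_len(nrow(use)), function(i) {
    m <- ivw_fixed_effects(use[-i, , drop = FALSE], min_cohorts = min_cohorts)
    cbind(left_out = use$cohort_id[i], m, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Cohort-exclusion sensitivity re-analysis
#'
#' Drops cohorts with a high proportion of deaths (>= 30%) or high genomic
#' inflation (lambda strictly > 1.5) and re-pools all CpGs.
#'
#' @param cohort_stats data frame `cohort_id, death_prop, lambda`.
#' @param results row-bound per-cohort EWAS results.
#' @param min_cohorts minimum contributing cohorts per CpG.
#' @param death_prop_max exclusion bound on the death proportion
#'   (inclusive, default 0.30).
#' @param lambda_max exclusion bound on cohort lambda (strict, default 1.5).
#' @return list as in [meta_analyze()], plus `excluded_cohorts`.
#' @export
sensitivity_exclusion <- function(cohort_stats, results, min_cohorts = 3L,
                                  death_prop_max = 0.30, lambda_max = 1.5) {
  stopifnot(all(unique(results$cohort_id) %in% cohort_stats$cohort_id))
  drop <- cohort_stats$cohort_id[cohort_stats$death_prop >= death_prop_max |
                                   cohort_stats$lambda > lambda_max]
  keep_rows <- results[!results$cohort_id %in% drop, , drop = FALSE]
  if (nrow(keep_rows) == 0 ||
      length(unique(keep_rows$cohort_id)) == 0)
    stop("all cohorts excluded by the sensitivity rules")
  out <- meta_analyze(keep_rows, min_cohorts = min_cohorts)
  out$excluded_cohorts <- drop
  out
}
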