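#' One-sided Fisher enrichment of significant CpGs over genomic features
#'
#' For each category (by default every level of the annotation's island
#' relation and gene region), builds the 2x2 table of significant vs
#' background CpGs in vs out of the category and computes the one-sided
#' (enrichment-direction) hypergeometric tail probability
#' `P(X >= a)`, with Benjamini-Hochberg FDR across categories.
#'
#' @param sig_cpgs significant CpG ids (must be a subset of the
#'   background).
#' @param background_cpgs background CpG ids (all post-QC CpGs).
#' @param annot probe annotation data frame.
#' @param categories named list mapping category labels to CpG id sets;
#'   by default derived from `island_relation` and `gene_region`.
#' @return data frame `category, a, b, c, d, odds_ratio, pval, fdr_q`
#'   where (a, b, c, d) = (sig in category, sig out, non-sig in, non-sig
#'   out).  An empty significant set gives p = 1 everywhere.
#' @export
fisher_enrichment <- function(sig_cpgs, background_cpgs, annot = NULL,
                              categories = NULL) {
  if (!all(sig_cpgs %in% background_cpgs))
    stop("significant set must be a subset of the background")
  if (is.null(categories)) {
    ann <- annot[annot$cpg_id %in% background_cpgs, ]
    categories <- c(
      split(ann$cpg_id, paste0("island:", ann$island_relation)),
      split(ann$cpg_id, paste0("region:", ann$gene_region)))
  }
  n_sig <- length(sig_cpgs)
  n_bg <- length(background_cpgs)
  rows <- lapply(names(categories), function(cat) {
    incat <- intersect(categories[[cat]], background_cpgs)
    a <- sum(sig_cpgs %in% incat)
    b <- n_sig - a
    c_ <- length(incat) - a
    d <- (n_bg - n_sig) - c_
    p <- if (n_sig == 0) 1 else
      stats::phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
    or <- (a * d) / (b * c_)
    data.frame(category = cat, a = a, b = b, c = c_, d = d,
               odds_ratio = or, pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_q <- stats::p.adjust(out$pval, method = "BH")
  out
}

#' Read a clock coefficient table
#'
#' TSV with columns `cpg_id, weight`; the intercept is carried on a special
#' row with `cpg_id == "INTERCEPT"`.
#'
#' @param path TSV path.
#' @param name clock name.
#' @return object of class `clock_definition`: list `name, weights
#'   (named), intercept`.
#' @export
read_clock <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  int <- tab$weight[tab$cpg_id == "INTERCEPT"]
  w <- tab[tab$cpg_id != "INTERCEPT", ]
  clock_definition(name, stats::setNames(w$weight, w$cpg_id),
                   if (length(int)) int else 0)
}

#' Construct a clock definition
#' @param name clock name.
#' @param weights named numeric vector of CpG weights (>= 1, finite).
#' @param intercept intercept on the output scale (years or score units).
#' @return `clock_definition` object.
#' @export
clock_definition <- function(name, weights, intercept = 0) {
  stopifnot(length(weights) >= 1, all(is.finite(weights)),
            is.finite(intercept), !is.null(names(weights)))
  structure(list(name = name, weights = weights, intercept = intercept),
            class = "clock_definition")
}

#' Synthetic demonstration clock
#'
#' A random linear combination over a subset of CpGs, for exercising the
#' scoring/acceleration machinery without published coefficient sets (which
#' are not bundled).
#'
#' @param cpg_pool CpG ids to draw from.
#' @param n_cpgs number of clock CpGs.
#' @param seed RNG seed.
#' @param intercept intercept (default 40, "years").
#' @return `clock_definition`.
#' @export
synthetic_clock <- function(cpg_pool, n_cpgs = 30L, seed = 1L,
                            intercept = 40) {
  set.seed(as.integer(seed))
  picks <- sample(cpg_pool, min(n_cpgs, length(cpg_pool)))
  clock_definition("synthetic_demo",
                   stats::setNames(stats::rnorm(length(picks), 0, 10), picks),
                   intercept)
}

#' Apply an epigenetic clock to a beta matrix
#'
#' `score = intercept + sum(weight * beta)` per sample.  Missing clock CpG
#' values are imputed by the cohort (row) mean; samples observing fewer than
#' `min_observed` of the clock CpGs are flagged missing (NA).  Clock CpGs
#' entirely absent from the matrix count as unobserved.
#'
#' @param beta CpG x sample matrix.
#' @param clock a `clock_definition`.
#' @param min_observed minimum observed fraction of clock CpGs per sample.
#' @return named numeric score vector (one per sample).
#' @export
apply_clock <- function(beta, clock, min_observed = 0.5) {
  w <- clock$weights
  present <- intersect(names(w), rownames(beta))
  sub <- matrix(NA_real_, nrow = length(w), ncol = ncol(beta),
                dimnames = list(names(w), colnames(beta)))
  if (length(present))
    sub[present, ] <- beta[present, , drop = FALSE]
  obs_frac <- colMeans(!is.na(sub))
  row_mean <- rowMeans(sub, na.rm = TRUE)
  row_mean[is.nan(row_mean)] <- 0
  for (j in seq_len(ncol(sub))) {
    miss <- is.na(sub[, j])
    sub[miss, j] <- row_mean[miss]
  }
  score <- clock$intercept + drop(crossprod(sub, w))
  score[obs_frac < min_observed] <- NA_real_
  stats::setNames(score, colnames(beta))
}

#' Epigenetic age acceleration
#'
#' `difference` mode: clock value minus chronological age (the default,
#' matching the discrepancy definition); `residual` mode: residuals of the
#' clock value regressed on age.
#'
#' @param clock_values numeric clock outputs.
#' @param chron_age chronological ages, aligned.
#' @param mode `"difference"` or `"residual"`.
#' @return numeric acceleration vector.
#' @export
age_acceleration <- function(clock_values, chron_age,
                             mode = c("difference", "residual")) {
  mode <- match.arg(mode)
  stopifnot(length(clock_values) == length(chron_age))
  if (mode == "difference") return(clock_values - chron_age)
  if (stats::sd(chron_age, na.rm = TRUE) == 0)
    stop("residual mode undefined for constant age")
  stats::resid(stats::lm(clock_values ~ chron_age))
}

#' Mortality model adjusted for aging scores
#'
#' Fully-adjusted per-CpG Cox fit with acceleration scores and/or a
#' mortality risk score appended as covariates, to test whether the CpG's
#' mortality association is independent of epigenetic aging measures.
#'
#' @param cohort a `cohort_dataset`.
#' @param cpg_id CpG to fit.
#' @param scores data frame or matrix of per-sample score covariates.
#' @param model covariate set.
#' @param cell_fractions sample x cell-type matrix.
#' @return one-row data frame as in [fit_cox_per_cpg()].
#' @export
adjusted_mortality_model <- function(cohort, cpg_id, scores,
                                     model = c("full", "basic"),
                                     cell_fractions = cohort$cell_fractions_true) {
  model <- match.arg(model)
  Z <- cbind(ewas_design(cohort, model, cell_fractions), as.matrix(scores))
  meth <- cohort$beta[cpg_id, ]
  obs <- !is.na(meth) & stats::complete.cases(Z)
  y <- survival::Surv(cohort$time, cohort$event)
  r <- if (sum(cohort$event[obs]) >= 2 && stats::sd(meth[obs]) > 0) {
    x <- cbind(meth = meth[obs], Z[obs, , drop = FALSE])
    keep <- c(TRUE, apply(x[, -1, drop = FALSE], 2,
                          function(v) stats::sd(v) > 0))
    cox_fit_one(x[, keep, drop = FALSE], y[obs, , drop = FALSE], "efron")
  } else list(beta = NA_real_, se = NA_real_, pval = NA_real_,
              converged = FALSE)
  data.frame(cpg_id = cpg_id, cohort_id = cohort$cohort_id, model = model,
             beta = r$beta, se = r$se, pval = r$pval, n = sum(obs),
             events = sum(cohort$event[obs]), converged = r$converged,
             stringsAsFactors = FALSE)
}

#' Cross-cohort CpG-CpG correlations (inverse-variance pooled Fisher z)
#'
#' Pairwise Pearson correlations between score CpGs and target CpGs,
#' computed within each cohort on pairwise-complete observations, then
#' pooled across cohorts on the Fisher-z scale with weights `n - 3`.
#' Constant CpGs give NA entries.
#'
#' @param cohorts list of `cohort_dataset`s.
#' @param score_cpgs,target_cpgs CpG id vectors.
#' @return correlation matrix (score x target).
#' @export
score_cpg_correlations <- function(cohorts, score_cpgs, target_cpgs) {
  zsum <- matrix(0, length(score_cpgs), length(target_cpgs),
                 dimnames = list(score_cpgs, target_cpgs))
  wsum <- zsum
  for (co in cohorts) {
    have_s <- score_cpgs[score_cpgs %in% rownames(co$beta)]
    have_t <- target_cpgs[target_cpgs %in% rownames(co$beta)]
    if (!length(have_s) || !length(have_t)) next
    r <- suppressWarnings(
      stats::cor(t(co$beta[have_s, , drop = FALSE]),
                 t(co$beta[have_t, , drop = FALSE]),
                 use = "pairwise.complete.obs"))
    n_eff <- ncol(co$beta)
    z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
    w <- matrix(n_eff - 3, nrow(z), ncol(z))
    valid <- is.finite(z)
    z[!valid] <- 0; w[!valid] <- 0
    zsum[have_s, have_t] <- zsum[have_s, have_t] + w * z
    wsum[have_s, have_t] <- wsum[have_s, have_t] + w
  }
  out <- tanh(zsum / wsum)
  out[wsum == 0] <- NA_real_
  out
}
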