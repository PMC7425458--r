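#' Reference-based cell-fraction estimation (constrained projection)
#'
#' Houseman-style deconvolution: finds nonnegative cell-type weights whose
#' reference-profile mixture best fits the sample's beta values in least
#' squares, subject to the weights summing to at most 1; the solution is
#' renormalized to sum to 1 for reporting.  The fit uses the reference's
#' discriminating CpGs intersected with the observed CpGs of the sample.
#'
#' @param beta_sample named beta vector for one sample (names = CpG ids), or
#'   a CpG x sample matrix (one estimate per column).
#' @param ref a `reference_matrix`.
#' @param use_discriminating restrict to the reference's marker CpGs
#'   (default TRUE; falls back to all shared CpGs if too few markers).
#' @return named fraction vector (or sample x cell-type matrix for matrix
#'   input), each row nonnegative and summing to 1.
#' @export
estimate_cell_fractions <- function(beta_sample, ref,
                                    use_discriminating = TRUE) {
  if (is.matrix(beta_sample)) {
    out <- t(apply(beta_sample, 2, estimate_cell_fractions, ref = ref,
                   use_discriminating = use_discriminating))
    colnames(out) <- ref$cell_types
    return(out)
  }
  k <- length(ref$cell_types)
  shared <- intersect(colnames(ref$profiles),
                      names(beta_sample)[!is.na(beta_sample)])
  if (use_discriminating) {
    disc <- intersect(ref$discriminating, shared)
    if (length(disc) >= k) shared <- disc
  }
  if (length(shared) < k)
    stop("fewer observed reference CpGs than cell types")
  A <- t(ref$profiles[, shared, drop = FALSE])   # CpG x cell type
  if (qr(A)$rank < k)
    stop("rank-deficient reference on the shared CpGs")
  b <- beta_sample[shared]
  x <- pracma::lsqnonneg(A, b)$x
  if (sum(x) > 1 + 1e-8) {
    # activate the sum-to-one face of the constraint set
    M <- 1e6
    x <- pracma::lsqnonneg(rbind(A, sqrt(M)), c(b, sqrt(M)))$x
  }
  s <- sum(x)
  if (s > 0) x <- x / s
  stats::setNames(as.numeric(x), ref$cell_types)
}

LYMPHOID_TYPES <- c("CD4T", "CD8T_naive", "CD8T_mem", "NK", "Bcell")

#' Neutrophil-lymphocyte ratio from estimated cell fractions
#'
#' `NLR = granulocyte fraction / sum(lymphoid fractions)`, with the
#' granulocyte compartment standing in for neutrophils (the 450K blood
#' reference resolves granulocytes, not neutrophils specifically) and the
#' lymphoid denominator summing CD4T, naive and memory/effector CD8T, NK
#' and B cells.  A zero lymphoid sum yields `NA` flagged undefined, never
#' infinity.
#'
#' @param fractions named fraction vector or sample x cell-type matrix.
#' @param granulocyte,lymphoid column names of the compartments.
#' @return numeric NLR (vector for matrix input) with attribute
#'   `"undefined"` marking zero-lymphoid samples.
#' @export
compute_nlr <- function(fractions, granulocyte = "Gran",
                        lymphoid = LYMPHOID_TYPES) {
  if (!is.matrix(fractions)) fractions <- t(as.matrix(fractions))
  if (!granulocyte %in% colnames(fractions))
    stop("granulocyte fraction '", granulocyte, "' not present")
  lym <- intersect(lymphoid, colnames(fractions))
  if (length(lym) == 0) stop("no lymphoid fraction present")
  gran <- fractions[, granulocyte]
  denom <- rowSums(fractions[, lym, drop = FALSE])
  undef <- denom == 0
  nlr <- ifelse(undef, NA_real_, gran / denom)
  attr(nlr, "undefined") <- unname(undef)
  nlr
}

#' Mortality models for the neutrophil-lymphocyte ratio
#'
#' Cox proportional-hazards fits of all-cause mortality on NLR under three
#' adjustment modes: `without` cell-fraction covariates, `with_houseman`
#' (cell fractions added), and `with_cpg` (cell fractions plus one CpG's
#' methylation).
#'
#' @param cohort a `cohort_dataset`.
#' @param nlr per-sample NLR vector.
#' @param cpg_id CpG whose methylation enters the `with_cpg` mode.
#' @param model covariate set, `"full"` or `"basic"`.
#' @param cell_fractions sample x cell-type matrix for the adjusted modes.
#' @param method tie handling.
#' @return data frame `mode, coef, se, pval, converged` (coefficients are
#'   log-HR per unit NLR).
#' @export
nlr_mortality_models <- function(cohort, nlr, cpg_id,
                                 model = c("full", "basic"),
                                 cell_fractions = cohort$cell_fractions_true,
                                 method = "efron") {
  model <- match.arg(model)
  y <- survival::Surv(cohort$time, cohort$event)
  Z0 <- ewas_design(cohort, model, cell_fractions, use_cells = FALSE)
  Zc <- ewas_design(cohort, model, cell_fractions, use_cells = TRUE)
  meth <- cohort$beta[cpg_id, ]
  fit_mode <- function(mode, Z, extra = NULL) {
    x <- cbind(nlr = nlr, Z, extra)
    obs <- stats::complete.cases(x)
    r <- if (sum(cohort$event[obs]) >= 2 && stats::sd(nlr[obs]) > 0)
      cox_fit_one(x[obs, , drop = FALSE], y[obs, , drop = FALSE], method)
    else list(beta = NA_real_, se = NA_real_, pval = NA_real_,
              converged = FALSE)
    data.frame(mode = mode, coef = r$beta, se = r$se, pval = r$pval,
               converged = r$converged, stringsAsFactors = FALSE)
  }
  rbind(fit_mode("without", Z0),
        fit_mode("with_houseman", Zc),
        fit_mode("with_cpg", Zc, extra = cbind(meth = meth)))
}
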