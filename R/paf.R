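#' Dichotomize methylation at the cohort mean
#'
#' Exposure indicator: 1 where the beta value is strictly greater than the
#' within-cohort mean of that CpG, 0 otherwise; missing values stay missing.
#'
#' @param beta_vector per-sample beta values for one CpG.
#' @return integer 0/1 vector (NA preserved).
#' @export
dichotomize_exposure <- function(beta_vector) {
  if (all(is.na(beta_vector))) stop("all values missing")
  as.integer(beta_vector > mean(beta_vector, na.rm = TRUE))
}

#' Miettinen's population attributable fraction
#'
#' Case-based form `PAF = pc * (rr - 1) / rr`, with `pc` the exposure
#' prevalence among cases (deaths) and `rr` the adjusted rate (hazard)
#' ratio for exposed vs unexposed.  Negative when the exposure is
#' protective (`rr < 1`).
#'
#' @param pc proportion exposed among cases, in [0, 1].
#' @param rr rate/hazard ratio, > 0.
#' @return attributable fraction (<= pc, and <= 1).
#' @export
miettinen_paf <- function(pc, rr) {
  stopifnot(pc >= 0, pc <= 1)
  if (any(rr <= 0)) stop("rr must be > 0")
  pc * (rr - 1) / rr
}

#' Cohort-level attributable fraction for above-mean methylation
#'
#' Dichotomizes the CpG at the cohort mean, fits an adjusted Cox
#' proportional-hazards model of mortality on the binary exposure (covariate
#' set plus cell fractions), and plugs the exposure prevalence among deaths
#' and the adjusted hazard ratio into Miettinen's formula.
#'
#' @param cohort a `cohort_dataset`.
#' @param cpg_id CpG to evaluate.
#' @param model covariate set.
#' @param cell_fractions sample x cell-type matrix.
#' @param use_covariates set `FALSE` for an unadjusted exposure fit.
#' @return list `pc, rr, paf, converged`.
#' @export
paf_from_cohort <- function(cohort, cpg_id, model = c("full", "basic"),
                            cell_fractions = cohort$cell_fractions_true,
                            use_covariates = TRUE) {
  model <- match.arg(model)
  if (sum(cohort$event) == 0) stop("no deaths in cohort")
  expo <- dichotomize_exposure(cohort$beta[cpg_id, ])
  obs <- !is.na(expo)
  Z <- if (use_covariates) {
    ewas_design(cohort, model, cell_fractions, use_cells = TRUE)
  } else NULL
  x <- cbind(exposed = expo, Z)[obs, , drop = FALSE]
  y <- survival::Surv(cohort$time, cohort$event)[obs, , drop = FALSE]
  r <- cox_fit_one(x, y, method = "efron")
  if (!r$converged) return(list(pc = NA_real_, rr = NA_real_,
                                paf = NA_real_, converged = FALSE))
  cases <- cohort$event[obs] == 1
  pc <- mean(expo[obs][cases])
  rr <- exp(r$beta)
  list(pc = pc, rr = rr, paf = miettinen_paf(pc, rr), converged = TRUE)
}
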