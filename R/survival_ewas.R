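BASIC_COVARS <- c("age_decade", "sex", "plate", "chip", "row", "column")
FULL_COVARS <- c(BASIC_COVARS, "education", "phys_act", "smoking_status",
                 "pack_years", "bmi", "alcohol", "hypertension", "diabetes",
                 "cancer_history", "chd_history")

#' Build the adjustment design matrix for a cohort
#'
#' Expands the basic (age decades as indicator contrasts with the youngest
#' observed decade as reference, sex, technical plate/chip/row/column
#' factors) or fully-adjusted covariate set into a numeric model matrix and
#' appends estimated cell-type proportions, dropping the largest-mean cell
#' fraction to break the sum-to-one collinearity.  Constant and aliased
#' columns are removed so downstream partial-likelihood fits are full rank.
#'
#' @param cohort a `cohort_dataset`.
#' @param model `"basic"` or `"full"`.
#' @param cell_fractions sample x cell-type matrix; defaults to the cohort's
#'   true simulated fractions.  `NULL`-able via `use_cells = FALSE`.
#' @param use_cells include cell-fraction covariates.
#' @return numeric matrix (no intercept), rows aligned to cohort samples.
#' @export
ewas_design <- function(cohort, model = c("full", "basic"),
                        cell_fractions = cohort$cell_fractions_true,
                        use_cells = TRUE) {
  model <- match.arg(model)
  vars <- if (model == "basic") BASIC_COVARS else FULL_COVARS
  cov <- cohort$covariates[, intersect(vars, names(cohort$covariates)),
                           drop = FALSE]
  cov <- droplevels(cov)
  # single-level factors and constants carry no information
  cov <- cov[, vapply(cov, function(x) length(unique(x)) > 1, logical(1)),
             drop = FALSE]
  Z <- if (ncol(cov) == 0) matrix(numeric(0), nrow = nrow(cohort$covariates),
                                  ncol = 0)
       else stats::model.matrix(~ ., data = cov)[, -1, drop = FALSE]
  if (use_cells && !is.null(cell_fractions)) {
    cf <- as.matrix(cell_fractions)
    drop_col <- which.max(colMeans(cf))
    Z <- cbind(Z, cf[, -drop_col, drop = FALSE])
  }
  keep <- apply(Z, 2, function(x) stats::sd(x) > 0)
  Z <- Z[, keep, drop = FALSE]
  if (ncol(Z) > 1) {
    q <- qr(Z)
    Z <- Z[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  Z
}

cox_fit_one <- function(x, y, method, divergence_bound = 50) {
  out <- list(beta = NA_real_, se = NA_real_, pval = NA_real_,
              converged = FALSE)
  storage.mode(x) <- "double"
  # nuisance dummies for sparse factor levels may diverge; convergence is
  # judged on the methylation coefficient alone, so warnings are muffled
  fit <- tryCatch(
    withCallingHandlers(
      survival::coxph.fit(x, y, strata = NULL, offset = NULL,
                          init = rep(0, ncol(x)),
                          control = survival::coxph.control(),
                          weights = NULL, method = method,
                          rownames = NULL),
      warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) NULL)
  if (is.null(fit) || is.null(fit$coefficients)) return(out)
  # exact collinearity leaves NA coefficients: treat as non-converged
  if (any(!is.finite(fit$coefficients))) return(out)
  b <- fit$coefficients[1]
  v <- fit$var[1, 1]
  if (!is.finite(b) || !is.finite(v) || v <= 0 ||
      abs(b) > divergence_bound) return(out)
  out$beta <- unname(b)
  out$se <- sqrt(v)
  out$pval <- 2 * stats::pnorm(-abs(b) / out$se)
  out$converged <- TRUE
  out
}

#' Per-CpG Cox proportional-hazards screening within one cohort
#'
#' For each CpG, maximizes the Cox partial likelihood of all-cause mortality
#' on methylation plus the chosen covariate set and cell-fraction covariates.
#' The coefficient is the log hazard ratio per +1.0 beta value; the hazard
#' ratio per 10% methylation increase is `exp(0.1 * beta)`.  Failures
#' (no events, constant methylation, Newton divergence, `|beta|` beyond the
#' divergence bound) are reported as `converged = FALSE`, never as errors.
#'
#' @inheritParams ewas_design
#' @param cpg_ids subset of CpGs to fit (default: all rows of `beta`).
#' @param method tie handling, `"efron"` (default) or `"breslow"`.
#' @param divergence_bound absolute log-HR beyond which a fit is declared
#'   non-converged.
#' @return data frame (one row per CpG): `cpg_id, cohort_id, model, beta,
#'   se, pval, n, events, converged`.
#' @export
fit_cox_per_cpg <- function(cohort, model = c("full", "basic"),
                            cell_fractions = cohort$cell_fractions_true,
                            cpg_ids = rownames(cohort$beta),
                            method = c("efron", "breslow"),
                            divergence_bound = 50, use_cells = TRUE) {
  model <- match.arg(model)
  method <- match.arg(method)
  Z <- ewas_design(cohort, model, cell_fractions, use_cells)
  y <- survival::Surv(cohort$time, cohort$event)
  enough_events <- sum(cohort$event) >= 2
  res <- lapply(cpg_ids, function(cid) {
    meth <- cohort$beta[cid, ]
    obs <- !is.na(meth)
    r <- list(beta = NA_real_, se = NA_real_, pval = NA_real_,
              converged = FALSE)
    if (enough_events && sum(obs) >= 3 && sum(cohort$event[obs]) >= 2 &&
        stats::sd(meth[obs]) > 0) {
      x <- cbind(meth = meth[obs], Z[obs, , drop = FALSE])
      r <- cox_fit_one(x, y[obs, , drop = FALSE], method, divergence_bound)
    }
    data.frame(cpg_id = cid, cohort_id = cohort$cohort_id, model = model,
               beta = r$beta, se = r$se, pval = r$pval,
               n = sum(obs), events = sum(cohort$event[obs]),
               converged = r$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res); rownames(out) <- NULL; out
}

#' Two-step residual Cox screening (low-death cohorts)
#'
#' Step 1 regresses each probe's beta values on the covariate set (plus cell
#' fractions) by ordinary least squares; step 2 fits a single-predictor Cox
#' model of mortality on the residuals.  Used in place of the joint fit when
#' a cohort has too few deaths for stable multivariable partial-likelihood
#' maximization.
#'
#' @inheritParams fit_cox_per_cpg
#' @return data frame as in [fit_cox_per_cpg()].
#' @export
fit_cox_two_step <- function(cohort, model = c("full", "basic"),
                             cell_fractions = cohort$cell_fractions_true,
                             cpg_ids = rownames(cohort$beta),
                             method = c("efron", "breslow"),
                             divergence_bound = 50, use_cells = TRUE) {
  model <- match.arg(model)
  method <- match.arg(method)
  Z <- ewas_design(cohort, model, cell_fractions, use_cells)
  Z1 <- cbind(1, Z)
  y <- survival::Surv(cohort$time, cohort$event)
  enough_events <- sum(cohort$event) >= 2
  res <- lapply(cpg_ids, function(cid) {
    meth <- cohort$beta[cid, ]
    obs <- !is.na(meth)
    r <- list(beta = NA_real_, se = NA_real_, pval = NA_real_,
              converged = FALSE)
    if (enough_events && sum(obs) >= 3 && sum(cohort$event[obs]) >= 2 &&
        stats::sd(meth[obs]) > 0) {
      resid <- stats::lm.fit(Z1[obs, , drop = FALSE], meth[obs])$residuals
      if (stats::sd(resid) > 1e-12) {
        x <- matrix(resid, ncol = 1, dimnames = list(NULL, "meth_resid"))
        r <- cox_fit_one(x, y[obs, , drop = FALSE], method, divergence_bound)
      }
    }
    data.frame(cpg_id = cid, cohort_id = cohort$cohort_id, model = model,
               beta = r$beta, se = r$se, pval = r$pval,
               n = sum(obs), events = sum(cohort$event[obs]),
               converged = r$converged, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res); rownames(out) <- NULL; out
}

#' Run a cohort's EWAS, auto-selecting the two-step variant
#'
#' Cohorts with fewer than `two_step_threshold` deaths (default 50) use the
#' two-step residual analysis; all others use the joint fit.
#'
#' @inheritParams fit_cox_per_cpg
#' @param two_step_threshold event count below which the two-step residual
#'   variant is used.
#' @return data frame as in [fit_cox_per_cpg()], with an attribute
#'   `"two_step"` recording which path was taken.
#' @export
run_cohort_ewas <- function(cohort, model = c("full", "basic"),
                            cell_fractions = cohort$cell_fractions_true,
                            cpg_ids = rownames(cohort$beta),
                            two_step_threshold = 50L, ...) {
  model <- match.arg(model)
  two_step <- sum(cohort$event) < two_step_threshold
  f <- if (two_step) fit_cox_two_step else fit_cox_per_cpg
  out <- f(cohort, model, cell_fractions, cpg_ids, ...)
  attr(out, "two_step") <- two_step
  out
}

#' Proportional-hazards diagnostic per CpG
#'
#' Scaled-Schoenfeld-residual score test of the methylation coefficient
#' against time (identity time transform).  Returns a p-value per CpG and
#' never excludes anything automatically; with fewer than 3 events the test
#' is undefined and flagged.
#'
#' @inheritParams fit_cox_per_cpg
#' @return data frame `cpg_id, ph_pval, defined`.
#' @export
check_proportional_hazards <- function(cohort, cpg_ids,
                                       model = c("full", "basic"),
                                       cell_fractions = cohort$cell_fractions_true,
                                       use_cells = TRUE) {
  model <- match.arg(model)
  Z <- ewas_design(cohort, model, cell_fractions, use_cells)
  res <- lapply(cpg_ids, function(cid) {
    meth <- cohort$beta[cid, ]
    obs <- !is.na(meth)
    if (sum(cohort$event[obs]) < 3)
      return(data.frame(cpg_id = cid, ph_pval = NA_real_, defined = FALSE,
                        stringsAsFactors = FALSE))
    df <- data.frame(time = cohort$time[obs], event = cohort$event[obs],
                     meth = meth[obs], Z[obs, , drop = FALSE],
                     check.names = TRUE)
    p <- tryCatch({
      # sparse nuisance dummies may diverge; only the methylation row of
      # the score test is consumed
      fit <- suppressWarnings(
        survival::coxph(survival::Surv(time, event) ~ ., data = df))
      zp <- survival::cox.zph(fit, transform = "identity", terms = FALSE)
      unname(zp$table["meth", "p"])
    }, error = function(e) NA_real_)
    data.frame(cpg_id = cid, ph_pval = p, defined = is.finite(p),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res); rownames(out) <- NULL; out
}

#' Per-CpG screening for an incident-disease outcome
#'
#' Identical contract to [fit_cox_per_cpg()] with an alternate right-censored
#' outcome (e.g. incident coronary heart disease); subjects with prevalent
#' disease at baseline are excluded from the risk set.
#'
#' @inheritParams fit_cox_per_cpg
#' @param time2,event2 alternate outcome vectors (length = samples).
#' @param prevalent logical vector marking prevalent disease at baseline
#'   (default: the cohort's `chd_history` indicator).
#' @return data frame as in [fit_cox_per_cpg()].
#' @export
fit_incident_disease <- function(cohort, time2, event2,
                                 model = c("full", "basic"),
                                 prevalent = cohort$covariates$chd_history == 1,
                                 cell_fractions = cohort$cell_fractions_true,
                                 cpg_ids = rownames(cohort$beta), ...) {
  model <- match.arg(model)
  keep <- !prevalent
  if (!any(keep)) stop("empty risk set: all subjects prevalent at baseline")
  sub <- cohort
  sub$beta <- cohort$beta[, keep, drop = FALSE]
  sub$covariates <- droplevels(cohort$covariates[keep, , drop = FALSE])
  sub$time <- time2[keep]
  sub$event <- event2[keep]
  sub$cell_fractions_true <- cohort$cell_fractions_true[keep, , drop = FALSE]
  cf <- if (is.null(cell_fractions)) NULL
        else as.matrix(cell_fractions)[keep, , drop = FALSE]
  fit_cox_per_cpg(sub, model, cf, cpg_ids, ...)
}
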