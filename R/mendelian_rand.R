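COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Harmonize exposure and outcome GWAS summary statistics
#'
#' Merges the two tables on shared SNP ids; flips the outcome effect sign
#' (and effect-allele frequency) where the effect/other alleles are swapped
#' relative to the exposure; resolves opposite-strand reports via allele
#' complements; drops palindromic (A/T, C/G) SNPs whose exposure allele
#' frequency falls in the ambiguous window; and finally orients every
#' instrument so the SNP-exposure effect is nonnegative.
#'
#' @param exposure,outcome data frames with columns `snp_id, effect_allele,
#'   other_allele, eaf, beta, se` (as from [generate_mr_summaries()]).
#' @param palindromic_window exposure-eaf interval inside which palindromic
#'   SNPs are ambiguous and dropped (default (0.42, 0.58)).
#' @return object of class `instrument_set`: list with `snp_ids, bx, sx,
#'   by, sy`, `harmonized = TRUE`, and tallies `n_dropped_palindromic`,
#'   `n_dropped_incompatible`.
#' @export
harmonize <- function(exposure, outcome,
                      palindromic_window = c(0.42, 0.58)) {
  m <- merge(exposure, outcome, by = "snp_id",
             suffixes = c("_x", "_y"), sort = TRUE)
  if (nrow(m) == 0) stop("no shared SNPs between exposure and outcome")
  ex_e <- toupper(m$effect_allele_x); ex_o <- toupper(m$other_allele_x)
  ou_e <- toupper(m$effect_allele_y); ou_o <- toupper(m$other_allele_y)

  same <- ou_e == ex_e & ou_o == ex_o
  swap <- ou_e == ex_o & ou_o == ex_e
  flip_e <- unname(COMPLEMENT[ou_e]); flip_o <- unname(COMPLEMENT[ou_o])
  same_strand <- !same & !swap & flip_e == ex_e & flip_o == ex_o
  swap_strand <- !same & !swap & flip_e == ex_o & flip_o == ex_e
  compatible <- same | swap | same_strand | swap_strand
  flip_sign <- swap | swap_strand

  pal <- is_palindromic(ex_e, ex_o) &
    m$eaf_x > palindromic_window[1] & m$eaf_x < palindromic_window[2]
  keep <- compatible & !pal

  by <- ifelse(flip_sign, -m$beta_y, m$beta_y)
  bx <- m$beta_x
  neg <- bx < 0
  set <- list(snp_ids = m$snp_id[keep],
              bx = abs(bx)[keep], sx = m$se_x[keep],
              by = ifelse(neg, -by, by)[keep], sy = m$se_y[keep],
              harmonized = TRUE,
              n_dropped_palindromic = sum(pal & compatible),
              n_dropped_incompatible = sum(!compatible))
  class(set) <- "instrument_set"
  set
}

n_instruments <- function(set) length(set$bx)

#' Wald ratio causal estimate (single instrument)
#'
#' `estimate = by/bx`, first-order delta-method `se = sy/|bx|`; for binary
#' outcomes on the log-odds scale the estimate exponentiates to an odds
#' ratio.
#'
#' @param set an `instrument_set` with exactly one instrument.
#' @return list `estimate, se, pval, or, ci_lower, ci_upper` (CI on the OR
#'   scale, 95%).
#' @export
wald_ratio <- function(set) {
  if (n_instruments(set) != 1) stop("Wald ratio requires exactly 1 instrument")
  if (set$bx == 0) stop("null instrument: bx = 0")
  est <- set$by / set$bx
  se <- set$sy / abs(set$bx)
  z <- est / se
  list(estimate = est, se = se, pval = 2 * stats::pnorm(-abs(z)),
       or = exp(est), ci_lower = exp(est - 1.96 * se),
       ci_upper = exp(est + 1.96 * se))
}

#' MR-Egger regression
#'
#' Weighted least squares of the SNP-outcome effects on the SNP-exposure
#' effects with an unconstrained intercept, weights `1/sy^2`.  The slope is
#' the causal estimate; the intercept tests directional pleiotropy.
#'
#' @param set an `instrument_set` with >= 3 instruments.
#' @return list `slope, slope_se, slope_p, intercept, intercept_se,
#'   intercept_p, n_snps`.
#' @export
mr_egger <- function(set) {
  k <- n_instruments(set)
  if (k < 3) stop("MR-Egger requires >= 3 instruments")
  fit <- stats::lm(set$by ~ set$bx, weights = 1 / set$sy^2)
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], slope_se = cf[2, 2],
       slope_p = cf[2, 4],
       intercept = cf[1, 1], intercept_se = cf[1, 2],
       intercept_p = cf[1, 4], n_snps = k)
}

weighted_median_point <- function(r, w) {
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- (cumsum(w) - w / 2) / sum(w)
  if (s[1] >= 0.5) return(r[1])
  if (s[length(s)] <= 0.5) return(r[length(r)])
  i <- max(which(s < 0.5))
  r[i] + (r[i + 1] - r[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

#' Weighted-median MR estimate
#'
#' Per-instrument ratio estimates `r_j = by_j/bx_j` with weights
#' `w_j = (bx_j/sy_j)^2` (inverse of the first-order ratio variance);
#' the estimate is the 50% point of the weighted empirical distribution by
#' cumulative-weight interpolation, consistent while up to half the weight
#' comes from invalid instruments.  SE by parametric bootstrap (resampling
#' `bx_j`, `by_j` from their sampling normals).
#'
#' @param set an `instrument_set` with >= 3 instruments.
#' @param n_boot bootstrap replicates for the SE (0 skips the bootstrap).
#' @param seed bootstrap RNG seed.
#' @param weights `"approx"` for `(bx/sy)^2`, `"exact"` for the full
#'   first-order ratio variance including exposure-side error.
#' @return list `estimate, se, pval, n_snps`.
#' @export
weighted_median <- function(set, n_boot = 1000L, seed = 1L,
                            weights = c("approx", "exact")) {
  weights <- match.arg(weights)
  if (n_instruments(set) < 3) stop("weighted median requires >= 3 instruments")
  drop <- set$bx == 0
  if (any(drop)) {
    warning(sum(drop), " instrument(s) with bx = 0 dropped")
    set <- with(set, list(bx = bx[!drop], sx = sx[!drop],
                          by = by[!drop], sy = sy[!drop]))
  }
  wfun <- function(bx, sx, by, sy) {
    if (weights == "approx") (bx / sy)^2
    else 1 / (sy^2 / bx^2 + by^2 * sx^2 / bx^4)
  }
  est <- weighted_median_point(set$by / set$bx,
                               wfun(set$bx, set$sx, set$by, set$sy))
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    k <- length(set$bx)
    boots <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, set$bx, set$sx)
      by <- stats::rnorm(k, set$by, set$sy)
      ok <- bx != 0
      weighted_median_point(by[ok] / bx[ok],
                            wfun(bx[ok], set$sx[ok], by[ok], set$sy[ok]))
    }, numeric(1))
    se <- stats::sd(boots)
  }
  p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(est / se))
       else NA_real_
  list(estimate = est, se = se, pval = p, n_snps = length(set$bx))
}

weighted_mode_point <- function(r, w, h) {
  if (h <= 0 || length(unique(r)) == 1) return(r[which.max(w)])
  grid <- seq(min(r), max(r), length.out = 512)
  dens <- function(x) vapply(x, function(xx)
    sum(w * stats::dnorm((xx - r) / h)), numeric(1))
  y <- dens(grid)
  i <- which.max(y)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  if (lo == hi) return(grid[i])
  stats::optimize(dens, c(lo, hi), maximum = TRUE)$maximum
}

#' Weighted-mode MR estimate
#'
#' The causal estimate is the argmax of a weighted Gaussian kernel density
#' over the per-instrument ratio estimates (the largest cluster of
#' consistent instruments), with bandwidth `bandwidth_factor` times the
#' modified Silverman rule `0.9 * min(sd, mad) * k^(-1/5)` on the ratios.
#' SE by parametric bootstrap.
#'
#' @inheritParams weighted_median
#' @param bandwidth_factor multiplier on the Silverman bandwidth.
#' @return list `estimate, se, pval, bandwidth, n_snps`.
#' @export
weighted_mode <- function(set, bandwidth_factor = 1, n_boot = 1000L,
                          seed = 1L) {
  k <- n_instruments(set)
  if (k < 3) stop("weighted mode requires >= 3 instruments")
  r <- set$by / set$bx
  w <- (set$bx / set$sy)^2
  if (all(w == 0)) stop("degenerate instrument set: all weights zero")
  w <- w / sum(w)
  spread <- min(stats::sd(r), stats::mad(r))
  if (!is.finite(spread)) spread <- 0
  h <- bandwidth_factor * 0.9 * spread * k^(-1 / 5)
  est <- weighted_mode_point(r, w, h)
  se <- NA_real_
  if (n_boot > 0) {
    set.seed(as.integer(seed))
    boots <- vapply(seq_len(n_boot), function(i) {
      bx <- stats::rnorm(k, set$bx, set$sx)
      by <- stats::rnorm(k, set$by, set$sy)
      ok <- bx != 0
      rb <- by[ok] / bx[ok]
      wb <- (bx[ok] / set$sy[ok])^2
      wb <- wb / sum(wb)
      sp <- min(stats::sd(rb), stats::mad(rb))
      hb <- bandwidth_factor * 0.9 * sp * sum(ok)^(-1 / 5)
      weighted_mode_point(rb, wb, hb)
    }, numeric(1))
    se <- stats::sd(boots)
  }
  p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(est / se))
       else NA_real_
  list(estimate = est, se = se, pval = p, bandwidth = h, n_snps = k)
}

#' Run all applicable MR estimators for one instrument set
#'
#' Wald ratio when a single instrument is present; MR-Egger, weighted
#' median and weighted mode when three or more are.
#'
#' @inheritParams weighted_median
#' @param exponentiate report odds ratios (binary outcome on log-odds
#'   scale).
#' @return data frame with one row per method: `method, estimate, se,
#'   pval, n_snps, ci_lower, ci_upper`, OR columns when `exponentiate`,
#'   and the harmonization tally `n_dropped_palindromic`.
#' @export
mr_all_methods <- function(set, n_boot = 1000L, seed = 1L,
                           exponentiate = TRUE) {
  rows <- list()
  if (n_instruments(set) == 1) {
    w <- wald_ratio(set)
    rows$wald <- data.frame(method = "wald_ratio", estimate = w$estimate,
                            se = w$se, pval = w$pval, n_snps = 1L)
  }
  if (n_instruments(set) >= 3) {
    e <- mr_egger(set)
    rows$egger <- data.frame(method = "mr_egger", estimate = e$slope,
                             se = e$slope_se, pval = e$slope_p,
                             n_snps = e$n_snps)
    m <- weighted_median(set, n_boot, seed)
    rows$median <- data.frame(method = "weighted_median",
                              estimate = m$estimate, se = m$se,
                              pval = m$pval, n_snps = m$n_snps)
    mo <- weighted_mode(set, n_boot = n_boot, seed = seed)
    rows$mode <- data.frame(method = "weighted_mode",
                            estimate = mo$estimate, se = mo$se,
                            pval = mo$pval, n_snps = mo$n_snps)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out$ci_lower <- out$estimate - 1.96 * out$se
  out$ci_upper <- out$estimate + 1.96 * out$se
  if (exponentiate) {
    out$or <- exp(out$estimate)
    out$or_ci_lower <- exp(out$ci_lower)
    out$or_ci_upper <- exp(out$ci_upper)
  }
  out$n_dropped_palindromic <-
    if (!is.null(set$n_dropped_palindromic)) set$n_dropped_palindromic
    else NA_integer_
  rownames(out) <- NULL
  out
}
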