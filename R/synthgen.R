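# Default leukocyte compartments resolved by 450K whole-blood references.
DEFAULT_CELL_TYPES <- c("CD4T", "CD8T_naive", "CD8T_mem", "NK", "Bcell",
                        "Mono", "Gran")

# Typical whole-blood mean fractions used as the Dirichlet centre.
DEFAULT_CELL_MEANS <- c(CD4T = 0.15, CD8T_naive = 0.05, CD8T_mem = 0.05,
                        NK = 0.05, Bcell = 0.05, Mono = 0.10, Gran = 0.55)

#' Simulation configuration for a multi-cohort methylation-mortality study
#'
#' Bundles and validates all knobs of the synthetic cohort generator.  The
#' defaults describe a scaled-down consortium: 4 cohorts of 250 adults,
#' roughly one fifth of whom die over a 12-year administrative follow-up
#' window, with per-CpG methylation generated as leukocyte-mixture profiles
#' plus logit-scale biological variation.
#'
#' @param n_cohorts number of cohorts.
#' @param n_subjects_per_cohort samples per cohort.
#' @param n_cpgs number of CpG probes.
#' @param causal_cpg_ids character vector of CpG ids that carry a true
#'   mortality effect (must be among the generated ids).
#' @param causal_loghr_per_unit_beta log hazard ratio per +1.0 methylation
#'   beta for each causal CpG (recycled to `length(causal_cpg_ids)`).
#' @param baseline_hazard_scale exponential baseline hazard, 1/years.
#' @param admin_censor_years administrative censoring time, years.
#' @param dropout_max_years upper bound of the uniform dropout time; censoring
#'   is `min(admin_censor_years, U(0, dropout_max_years))`.
#' @param covariate_effect_sizes named numeric map of covariate log-hazard
#'   effects; recognised names: `age` (per year, centred at 65), `sex`
#'   (male vs female), `smoking_current`, `bmi` (per unit, centred at 27).
#' @param cell_noise_sd sd of logit-scale biological noise added on top of
#'   the cell-mixture methylation signal.
#' @param missing_rate per-entry probability of masking a beta value (MCAR).
#' @param seed integer RNG seed; cohort `c` uses stream `seed + c`.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_cohorts = 4L,
                       n_subjects_per_cohort = 250L,
                       n_cpgs = 500L,
                       causal_cpg_ids = character(),
                       causal_loghr_per_unit_beta = numeric(),
                       baseline_hazard_scale = 0.025,
                       admin_censor_years = 12,
                       dropout_max_years = 3 * admin_censor_years,
                       covariate_effect_sizes = c(age = 0.07, sex = 0.4,
                                                  smoking_current = 0.4,
                                                  bmi = 0.02),
                       cell_noise_sd = 1.5,
                       missing_rate = 0.02,
                       seed = 1L) {
  stopifnot(n_cohorts >= 1, n_subjects_per_cohort >= 1, n_cpgs >= 1,
            baseline_hazard_scale >= 0, admin_censor_years >= 0,
            dropout_max_years >= 0, cell_noise_sd >= 0,
            missing_rate >= 0, missing_rate < 1)
  if (length(causal_cpg_ids) > 0 && length(causal_loghr_per_unit_beta) == 0)
    stop("causal_loghr_per_unit_beta required when causal_cpg_ids given")
  if (length(causal_cpg_ids) > 0)
    causal_loghr_per_unit_beta <- rep_len(causal_loghr_per_unit_beta,
                                          length(causal_cpg_ids))
  cfg <- list(n_cohorts = as.integer(n_cohorts),
              n_subjects_per_cohort = as.integer(n_subjects_per_cohort),
              n_cpgs = as.integer(n_cpgs),
              causal_cpg_ids = as.character(causal_cpg_ids),
              causal_loghr_per_unit_beta = as.numeric(causal_loghr_per_unit_beta),
              baseline_hazard_scale = baseline_hazard_scale,
              admin_censor_years = admin_censor_years,
              dropout_max_years = dropout_max_years,
              covariate_effect_sizes = covariate_effect_sizes,
              cell_noise_sd = cell_noise_sd,
              missing_rate = missing_rate,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' CpG probe identifiers used by the generator
#' @param n_cpgs number of probes.
#' @return character vector like `cg00000001`.
#' @export
cpg_ids <- function(n_cpgs) sprintf("cg%08d", seq_len(n_cpgs))

#' Generate a cell-type reference methylation matrix
#'
#' Builds mean methylation profiles (cell type x CpG, beta scale) with a
#' designated block of discriminating marker CpGs: each marker CpG is highly
#' methylated (0.9) in its owner cell type and lowly methylated (0.1) in all
#' others, so any two distinct cell types differ by 0.8 at two marker CpGs
#' and the deconvolution design is full column rank.  Non-marker CpGs share a
#' common Beta(2, 2) level across cell types with small per-type jitter.
#'
#' Requesting duplicated cell-type names yields identical (copied) profiles
#' and sets the `rank_deficient` conditioning flag.
#'
#' @param cell_types character vector of cell-type names (>= 2).
#' @param n_cpgs number of CpGs.
#' @param seed RNG seed.
#' @param markers_per_type number of marker CpGs assigned per cell type.
#' @return object of class `reference_matrix`: list with `profiles`
#'   (cell type x CpG matrix), `cell_types`, `cpg_ids`, `discriminating`
#'   (marker CpG ids) and logical `rank_deficient`.
#' @export
generate_reference_matrix <- function(cell_types = DEFAULT_CELL_TYPES,
                                      n_cpgs = 500L, seed = 1L,
                                      markers_per_type = 10L) {
  if (length(cell_types) < 2) stop("need at least 2 cell types")
  set.seed(as.integer(seed))
  ids <- cpg_ids(n_cpgs)
  k <- length(cell_types)
  uniq <- !duplicated(cell_types)
  n_marker <- min(n_cpgs, markers_per_type * sum(uniq))
  base <- stats::rbeta(n_cpgs, 2, 2)
  profiles <- matrix(rep(base, each = k), nrow = k,
                     dimnames = list(cell_types, ids))
  jitter <- matrix(stats::rnorm(k * n_cpgs, 0, 0.02), nrow = k)
  profiles <- pmin(pmax(profiles + jitter, 0.01), 0.99)
  if (n_marker > 0) {
    owner <- rep(which(uniq), length.out = n_marker)
    for (j in seq_len(n_marker)) {
      profiles[, j] <- 0.1
      profiles[owner[j], j] <- 0.9
    }
  }
  # duplicated names copy their first occurrence exactly
  if (any(!uniq)) {
    for (i in which(!uniq)) {
      profiles[i, ] <- profiles[match(cell_types[i], cell_types), ]
    }
  }
  disc <- ids[seq_len(n_marker)]
  rank_def <- qr(t(profiles[, disc, drop = FALSE]))$rank < k
  structure(list(profiles = profiles, cell_types = cell_types,
                 cpg_ids = ids, discriminating = disc,
                 rank_deficient = rank_def),
            class = "reference_matrix")
}

rdirichlet_mat <- function(n, alpha) {
  x <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  x / rowSums(x)
}

simulate_covariates <- function(n, cohort_id) {
  age <- pmin(pmax(stats::rnorm(n, 66, 9), 40), 99)
  decade <- factor(paste0(floor(age / 10) * 10, "s"))
  smoking <- factor(sample(c("never", "former", "current"), n, TRUE,
                           prob = c(0.45, 0.35, 0.20)),
                    levels = c("never", "former", "current"))
  pack_years <- ifelse(smoking == "never", 0,
                       round(stats::rgamma(n, shape = 2, scale = 12), 1))
  data.frame(
    sample_id = sprintf("%s_S%04d", cohort_id, seq_len(n)),
    age = age,
    age_decade = decade,
    sex = factor(sample(c("F", "M"), n, TRUE)),
    education = factor(sample(c("low", "mid", "high"), n, TRUE)),
    smoking_status = smoking,
    pack_years = pack_years,
    bmi = pmin(pmax(stats::rnorm(n, 27, 4), 16), 50),
    phys_act = factor(sample(c("low", "mid", "high"), n, TRUE)),
    alcohol = factor(sample(c("none", "moderate", "heavy"), n, TRUE,
                            prob = c(0.4, 0.5, 0.1))),
    hypertension = stats::rbinom(n, 1, 0.40),
    diabetes = stats::rbinom(n, 1, 0.12),
    cancer_history = stats::rbinom(n, 1, 0.12),
    chd_history = stats::rbinom(n, 1, 0.12),
    # desk-scale batch structure: enough levels to exercise the technical
    # adjustment without starving the partial likelihood of events per
    # parameter at a few hundred samples
    plate = factor(sample(paste0("P", 1:2), n, TRUE)),
    chip = factor(sample(paste0("chip", 1:4), n, TRUE)),
    row = factor(sample(paste0("R", 1:3), n, TRUE)),
    column = factor(sample(paste0("C", 1:2), n, TRUE)),
    stringsAsFactors = FALSE)
}

covariate_linear_predictor <- function(cov, effects) {
  eta <- numeric(nrow(cov))
  if (!length(effects)) return(eta)
  if ("age" %in% names(effects))
    eta <- eta + effects[["age"]] * (cov$age - 65)
  if ("sex" %in% names(effects))
    eta <- eta + effects[["sex"]] * (cov$sex == "M")
  if ("smoking_current" %in% names(effects))
    eta <- eta + effects[["smoking_current"]] * (cov$smoking_status == "current")
  if ("bmi" %in% names(effects))
    eta <- eta + effects[["bmi"]] * (cov$bmi - 27)
  eta
}

#' Generate synthetic cohorts under a proportional-hazards mortality model
#'
#' For each cohort (independent RNG stream `seed + cohort index`):
#' per-sample leukocyte fractions are drawn from a Dirichlet centred on
#' typical whole-blood composition; beta values are the fraction-weighted
#' mixture of the reference profiles plus logit-scale Gaussian noise, mapped
#' back through the inverse logit (so values stay inside (0, 1) without
#' truncation artifacts); survival times are exponential with hazard
#' `baseline_hazard_scale * exp(eta)` where `eta` sums the causal CpG effects
#' (log-HR per unit beta, applied to the realised beta values) and the
#' covariate effects; censoring is `min(admin_censor_years, U(0,
#' dropout_max_years))`; beta entries are masked missing completely at random
#' at `missing_rate`.
#'
#' @param config a [sim_config()].
#' @param ref optional [generate_reference_matrix()] output; by default one is
#'   generated with the config's CpG count and seed.
#' @return list of `cohort_dataset` objects, each with elements `cohort_id`,
#'   `beta` (CpG x sample), `covariates`, `time`, `event`,
#'   `cell_fractions_true` (sample x cell type) and `truth` (per-CpG true
#'   log-HR).
#' @export
generate_cohorts <- function(config, ref = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(ref))
    ref <- generate_reference_matrix(n_cpgs = config$n_cpgs,
                                     seed = config$seed)
  ids <- ref$cpg_ids
  if (length(ids) != config$n_cpgs)
    stop("reference matrix CpG count does not match config")
  bad <- setdiff(config$causal_cpg_ids, ids)
  if (length(bad))
    stop("causal CpG ids not among generated CpGs: ",
         paste(bad, collapse = ", "))
  loghr <- stats::setNames(numeric(length(ids)), ids)
  loghr[config$causal_cpg_ids] <- config$causal_loghr_per_unit_beta

  alpha_base <- 60 * DEFAULT_CELL_MEANS[ref$cell_types]
  alpha_base[is.na(alpha_base)] <- 60 / length(ref$cell_types)
  # causal effects act on beta centred at its expected mixture value, so
  # baseline_hazard_scale remains the hazard of an average subject
  mean_frac <- alpha_base / sum(alpha_base)
  beta_centre <- drop(mean_frac %*% ref$profiles)

  lapply(seq_len(config$n_cohorts), function(ci) {
    set.seed(config$seed + ci)
    n <- config$n_subjects_per_cohort
    cohort_id <- sprintf("cohort%02d", ci)
    frac <- rdirichlet_mat(n, alpha_base)
    colnames(frac) <- ref$cell_types
    mix <- frac %*% ref$profiles                       # sample x CpG
    mix <- pmin(pmax(mix, 1e-4), 1 - 1e-4)
    noise <- matrix(stats::rnorm(n * length(ids), 0, config$cell_noise_sd),
                    nrow = n)
    beta <- stats::plogis(stats::qlogis(mix) + noise)  # sample x CpG
    cov <- simulate_covariates(n, cohort_id)
    rownames(frac) <- cov$sample_id
    eta <- drop(sweep(beta, 2, beta_centre) %*% loghr) +
      covariate_linear_predictor(cov, config$covariate_effect_sizes)
    rate <- config$baseline_hazard_scale * exp(eta)
    t_death <- ifelse(rate > 0, stats::rexp(n, pmax(rate, 1e-300)), Inf)
    censor <- pmin(config$admin_censor_years,
                   stats::runif(n, 0, config$dropout_max_years))
    time <- pmin(t_death, censor)
    event <- as.integer(t_death <= censor)
    beta <- t(beta)                                    # CpG x sample
    dimnames(beta) <- list(ids, cov$sample_id)
    if (config$missing_rate > 0) {
      mask <- stats::runif(length(beta)) < config$missing_rate
      beta[mask] <- NA_real_
    }
    structure(list(cohort_id = cohort_id, beta = beta, covariates = cov,
                   time = time, event = event,
                   cell_fractions_true = frac, truth = loghr),
              class = "cohort_dataset")
  })
}

#' Generate two-sample MR summary statistics
#'
#' SNP-exposure effects `bx` are uniform on (0.1, 0.4) plus estimation noise;
#' SNP-outcome effects are `true_effect * bx + alpha + noise`, where `alpha`
#' is zero for valid instruments and Normal(`pleiotropy_mean`,
#' `pleiotropy_sd`) for the pleiotropic fraction (drawn independently of
#' `bx`, so the InSIDE assumption holds).  Alleles are non-palindromic and
#' consistent between the two tables.
#'
#' @param n_snps number of instruments (>= 1).
#' @param true_effect causal effect of exposure on outcome.
#' @param pleiotropy_frac fraction of instruments with a direct outcome
#'   effect.
#' @param pleiotropy_mean mean direct effect of pleiotropic instruments.
#' @param seed RNG seed.
#' @param exposure_se,outcome_se standard errors of the two association
#'   estimates.
#' @param pleiotropy_sd sd of the pleiotropic direct effects.
#' @return list with data frames `exposure` and `outcome`, columns
#'   `snp_id, effect_allele, other_allele, eaf, beta, se, pval, n`.
#' @export
generate_mr_summaries <- function(n_snps, true_effect = 0,
                                  pleiotropy_frac = 0, pleiotropy_mean = 0,
                                  seed = 1L,
                                  exposure_se = 0.02, outcome_se = 0.05,
                                  pleiotropy_sd = 0.02) {
  if (n_snps < 1) stop("n_snps must be >= 1")
  stopifnot(pleiotropy_frac >= 0, pleiotropy_frac <= 1)
  set.seed(as.integer(seed))
  snp <- sprintf("rs%06d", sample.int(999999, n_snps))
  pairs <- rbind(c("A", "G"), c("G", "A"), c("C", "T"), c("T", "C"))
  al <- pairs[sample.int(4, n_snps, TRUE), , drop = FALSE]
  eaf <- stats::runif(n_snps, 0.05, 0.95)
  bx_true <- stats::runif(n_snps, 0.1, 0.4)
  bx <- bx_true + stats::rnorm(n_snps, 0, exposure_se)
  n_pleio <- round(pleiotropy_frac * n_snps)
  alpha <- numeric(n_snps)
  if (n_pleio > 0)
    alpha[seq_len(n_pleio)] <- stats::rnorm(n_pleio, pleiotropy_mean,
                                            pleiotropy_sd)
  by <- true_effect * bx_true + alpha + stats::rnorm(n_snps, 0, outcome_se)
  mk <- function(b, se) {
    se <- rep_len(pmax(se, 1e-12), n_snps)
    data.frame(snp_id = snp, effect_allele = al[, 1], other_allele = al[, 2],
               eaf = eaf, beta = b, se = se,
               pval = 2 * stats::pnorm(-abs(b / se)),
               n = 10000L, stringsAsFactors = FALSE)
  }
  list(exposure = mk(bx, exposure_se), outcome = mk(by, outcome_se))
}

#' Simulate SNP dosages with QC metadata
#'
#' Hardy-Weinberg dosages for unlinked biallelic variants, plus the per-SNP
#' metadata (call rate, HWE p, MAF) consumed by [filter_genotypes()].
#'
#' @param n_snps number of variants.
#' @param sample_ids character vector of sample ids.
#' @param seed RNG seed.
#' @return list with `dosage` (SNP x sample matrix, values 0/1/2) and
#'   `metadata` data frame.
#' @export
simulate_genotypes <- function(n_snps, sample_ids, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(sample_ids)
  maf <- stats::runif(n_snps, 0.05, 0.5)
  dos <- t(vapply(maf, function(p) stats::rbinom(n, 2, p), numeric(n)))
  dimnames(dos) <- list(sprintf("snp%05d", seq_len(n_snps)), sample_ids)
  meta <- data.frame(snp_id = rownames(dos),
                     call_rate = stats::runif(n_snps, 0.97, 1.0),
                     hwe_p = stats::runif(n_snps),
                     maf = maf, stringsAsFactors = FALSE)
  list(dosage = dos, metadata = meta)
}
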