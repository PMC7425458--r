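test_that("three-subject worked example hits the closed-form MLE", {
  co <- toy3()
  for (m in c("efron", "breslow")) {
    f <- fit_cox_per_cpg(co, "basic", cell_fractions = NULL,
                         use_cells = FALSE, method = m)
    expect_equal(f$beta, -log(2) / 2, tolerance = 1e-6)
    expect_equal(exp(f$beta), 1 / sqrt(2), tolerance = 1e-6)
    expect_true(f$converged)
  }
  # agreement with a brute-force partial-likelihood grid oracle
  oracle <- cox_grid_oracle(c(1, 0, 1), c(1, 2, 3), c(1, 1, 1))
  expect_equal(oracle, -log(2) / 2, tolerance = 1e-3)
})

test_that("constant methylation and zero events are flagged, not errors", {
  co <- make_toy_cohort(rep(0.5, 5), 1:5, c(1, 1, 1, 0, 0))
  f <- fit_cox_per_cpg(co, "basic", cell_fractions = NULL, use_cells = FALSE)
  expect_false(f$converged)
  co0 <- make_toy_cohort(runif(5), 1:5, rep(0, 5))
  f0 <- fit_cox_per_cpg(co0, "basic", cell_fractions = NULL,
                        use_cells = FALSE)
  expect_false(f0$converged)
})

test_that("duplicating every subject keeps beta and shrinks the SE by ~1/sqrt(2)", {
  set.seed(10)
  x <- runif(40)
  tm <- rexp(40, exp(0.8 * x))
  ev <- rep(1L, 40)
  co1 <- make_toy_cohort(x, tm, ev)
  co2 <- make_toy_cohort(c(x, x), c(tm, tm), c(ev, ev))
  f1 <- fit_cox_per_cpg(co1, "basic", cell_fractions = NULL,
                        use_cells = FALSE)
  f2 <- fit_cox_per_cpg(co2, "basic", cell_fractions = NULL,
                        use_cells = FALSE)
  expect_equal(f2$beta, f1$beta, tolerance = 0.02)
  expect_equal(f2$se / f1$se, 1 / sqrt(2), tolerance = 0.05)
})

test_that("two-step residual analysis matches the direct fit when covariates are inert", {
  set.seed(11)
  n <- 60
  x <- runif(n)
  tm <- rexp(n, 0.2 * exp(x))
  ev <- as.integer(tm < 6); tm <- pmin(tm, 6)
  co <- make_toy_cohort(x, tm, ev)
  # constant covariates: residuals are centred beta values; Cox is
  # invariant to predictor centring
  co$covariates$age_decade <- factor(rep("60s", n))
  direct <- fit_cox_per_cpg(co, "basic", cell_fractions = NULL,
                            use_cells = FALSE)
  two <- fit_cox_two_step(co, "basic", cell_fractions = NULL,
                          use_cells = FALSE)
  expect_equal(two$beta, direct$beta, tolerance = 1e-8)

  # covariate orthogonal to methylation with a symmetric null effect:
  # joint and two-step estimates coincide
  co2 <- make_toy_cohort(c(x, x), c(tm, tm), c(ev, ev))
  co2$covariates$bmi <- c(rep(25, n), rep(29, n))  # +-constant mirrored halves
  joint <- fit_cox_per_cpg(co2, "full", cell_fractions = NULL,
                           use_cells = FALSE)
  two2 <- fit_cox_two_step(co2, "full", cell_fractions = NULL,
                           use_cells = FALSE)
  expect_equal(two2$beta, joint$beta, tolerance = 1e-6)

  # methylation an exact linear function of the covariates: zero residuals
  co3 <- make_toy_cohort(seq(0.1, 0.9, length.out = n), tm, ev)
  co3$covariates$bmi <- seq(20, 30, length.out = n)
  bad <- fit_cox_two_step(co3, "full", cell_fractions = NULL,
                          use_cells = FALSE)
  expect_false(bad$converged)
})

test_that("two-step auto-selection respects the event threshold", {
  set.seed(12)
  n <- 80
  co <- make_toy_cohort(runif(n), rexp(n, 0.05), rbinom(n, 1, 0.3))
  r <- run_cohort_ewas(co, "basic", cell_fractions = NULL,
                       two_step_threshold = 1000, use_cells = FALSE)
  expect_true(attr(r, "two_step"))
  r2 <- run_cohort_ewas(co, "basic", cell_fractions = NULL,
                        two_step_threshold = 2, use_cells = FALSE)
  expect_false(attr(r2, "two_step"))
})

test_that("PH diagnostic is calibrated under PH and powered against crossing hazards", {
  set.seed(13)
  cfg <- sim_config(n_cohorts = 1, n_subjects_per_cohort = 150, n_cpgs = 200,
                    baseline_hazard_scale = 0.06, missing_rate = 0, seed = 21)
  co <- generate_cohorts(cfg)[[1]]
  ph <- check_proportional_hazards(co, rownames(co$beta), model = "basic",
                                   use_cells = FALSE)
  rate <- mean(ph$ph_pval[ph$defined] < 0.05, na.rm = TRUE)
  expect_gt(rate, 0.005)
  expect_lt(rate, 0.12)

  # effect reversing sign partway through follow-up: mostly rejected
  rejected <- vapply(1:20, function(i) {
    set.seed(100 + i)
    n <- 300; b <- 1; h0 <- 0.3; t0 <- 1.5
    x <- rep(c(0, 1), n / 2)
    E <- rexp(n)
    H0 <- h0 * exp(b * x) * t0
    tm <- ifelse(E < H0, E / (h0 * exp(b * x)),
                 t0 + (E - H0) / (h0 * exp(-b * x)))
    coX <- make_toy_cohort(x, tm, rep(1L, n))
    p <- check_proportional_hazards(coX, "cg_toy", model = "basic",
                                    use_cells = FALSE)$ph_pval
    p < 0.05
  }, logical(1))
  expect_gt(mean(rejected), 0.5)

  # fewer than 3 events: undefined, flagged
  co2 <- make_toy_cohort(runif(6), 1:6, c(1, 1, 0, 0, 0, 0))
  p2 <- check_proportional_hazards(co2, "cg_toy", model = "basic",
                                   use_cells = FALSE)
  expect_false(p2$defined)
})

test_that("incident-disease fits exclude prevalent subjects and mirror mortality", {
  set.seed(14)
  n <- 80
  co <- make_toy_cohort(runif(n), rexp(n, 0.3), rbinom(n, 1, 0.6))
  co$covariates$chd_history <- rep(0L, n)
  same <- fit_incident_disease(co, co$time, co$event, model = "basic",
                               cell_fractions = NULL, use_cells = FALSE)
  base <- fit_cox_per_cpg(co, "basic", cell_fractions = NULL,
                          use_cells = FALSE)
  expect_equal(same$beta, base$beta)
  co$covariates$chd_history <- rep(1L, n)
  expect_error(fit_incident_disease(co, co$time, co$event, model = "basic",
                                    cell_fractions = NULL),
               "empty risk set")
})

test_that("estimates are unbiased with nominal CI coverage on simulated data", {
  # moderate-scale check of the estimation contract (acceptance covers the
  # full-replication version)
  hits <- 0; reps <- 40; ests <- numeric(reps)
  for (i in seq_len(reps)) {
    set.seed(200 + i)
    n <- 300
    x <- plogis(rnorm(n, 0, 1.2))
    b <- 1
    tm <- rexp(n, 0.08 * exp(b * x))
    cens <- runif(n, 0, 15)
    co <- make_toy_cohort(x, pmin(tm, cens), as.integer(tm <= cens))
    f <- fit_cox_per_cpg(co, "basic", cell_fractions = NULL,
                         use_cells = FALSE)
    ests[i] <- f$beta
    hits <- hits + (abs(f$beta - b) < 1.96 * f$se)
  }
  expect_lt(abs(mean(ests) - 1), 3 * sd(ests) / sqrt(reps))
  expect_gte(hits / reps, 0.85)
})
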