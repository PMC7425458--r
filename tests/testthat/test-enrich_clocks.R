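test_that("one-sided Fisher enrichment matches hypergeometric tail sums", {
  # table (3,1;1,3): P(X >= 3) with margins 4/4 over 8 = 17/70
  bg <- paste0("cg", 1:8)
  sig <- bg[1:4]
  cats <- list(feat = bg[c(1, 2, 3, 5)])
  res <- fisher_enrichment(sig, bg, categories = cats)
  expect_equal(res$a, 3); expect_equal(res$b, 1)
  expect_equal(res$c, 1); expect_equal(res$d, 3)
  expect_equal(res$pval, 17 / 70, tolerance = 1e-12)
  expect_equal(res$pval, fisher.test(matrix(c(3, 1, 1, 3), 2),
                                     alternative = "greater")$p.value,
               tolerance = 1e-10)

  # depletion direction: p >= 0.5, OR < 1
  cats2 <- list(feat = bg[5:7])
  res2 <- fisher_enrichment(sig, bg, categories = cats2)
  expect_gte(res2$pval, 0.5)
  expect_lt(res2$odds_ratio, 1)

  # significant set == background: p = 1 everywhere
  res3 <- fisher_enrichment(bg, bg, categories = cats)
  expect_equal(res3$pval, 1)
  expect_error(fisher_enrichment(c(sig, "cgX"), bg, categories = cats),
               "subset")
})

test_that("implementation equals exhaustive tail summation for all margins <= 20", {
  tail_sum <- function(a, b, c_, d) {
    # direct summation of the hypergeometric tail from first principles
    m <- a + c_; n2 <- b + d; k <- a + b
    kk <- a:min(m, k)
    sum(choose(m, kk) * choose(n2, k - kk)) / choose(m + n2, k)
  }
  set.seed(61)
  combos <- expand.grid(a = 0:8, b = 0:8, c_ = 0:8, d = 0:8)
  combos <- combos[rowSums(combos) > 0 &
                   combos$a + combos$b <= 20 & combos$c_ + combos$d <= 20 &
                   combos$a + combos$c_ <= 20 & combos$b + combos$d <= 20, ]
  combos <- combos[sample(nrow(combos), 400), ]
  for (i in seq_len(nrow(combos))) {
    a <- combos$a[i]; b <- combos$b[i]; c_ <- combos$c_[i]; d <- combos$d[i]
    impl <- phyper(a - 1, a + c_, b + d, a + b, lower.tail = FALSE)
    expect_equal(impl, tail_sum(a, b, c_, d), tolerance = 1e-10)
  }
})

test_that("clock scoring is linear with mean imputation of missing sites", {
  beta <- matrix(c(0.6, 0.2), nrow = 2,
                 dimnames = list(c("cg1", "cg2"), "s1"))
  clk <- clock_definition("demo", c(cg1 = 1, cg2 = -1), intercept = 50)
  expect_equal(unname(apply_clock(beta, clk)), 50.4)
  clk0 <- clock_definition("zero", c(cg1 = 0, cg2 = 0), intercept = 7)
  expect_equal(unname(apply_clock(beta, clk0)), 7)

  # imputation consistency: a sample sitting at the cohort mean scores
  # identically whether the value is observed or imputed
  set.seed(62)
  B <- matrix(runif(2 * 10), nrow = 2,
              dimnames = list(c("cg1", "cg2"), paste0("s", 1:10)))
  B["cg2", 10] <- mean(B["cg2", 1:9])
  s_obs <- apply_clock(B, clk)
  B_miss <- B; B_miss["cg2", 10] <- NA
  s_imp <- apply_clock(B_miss, clk)
  expect_equal(s_imp[10], s_obs[10], tolerance = 1e-12)

  # below 50% observed: flagged missing
  B3 <- B; B3[, 1] <- NA
  expect_true(is.na(apply_clock(B3, clk)[1]))

  # linearity over in-range mixtures
  x <- B[, 1]; y <- B[, 2]; a <- 0.3; b <- 0.5
  mix <- matrix(a * x + b * y, ncol = 1, dimnames = list(names(x), "m"))
  lhs <- unname(apply_clock(mix, clk))
  rhs <- a * unname(apply_clock(B, clk)[1]) + b * unname(apply_clock(B, clk)[2]) -
    (a + b - 1) * clk$intercept
  expect_equal(lhs, rhs, tolerance = 1e-10)
})

test_that("age acceleration modes behave as defined", {
  expect_equal(age_acceleration(50.4, 48, "difference"), 2.4)
  age <- c(40, 50, 60, 70)
  expect_equal(age_acceleration(age, age, "difference"), rep(0, 4))
  expect_equal(unname(age_acceleration(age, age, "residual")), rep(0, 4),
               tolerance = 1e-12)
  set.seed(63)
  clock <- age + rnorm(4)
  expect_equal(sum(age_acceleration(clock, age, "residual")), 0,
               tolerance = 1e-10)
  expect_error(age_acceleration(clock, rep(50, 4), "residual"), "constant")
})

test_that("score adjustment leaves an independent CpG's association intact", {
  set.seed(64)
  cfg <- sim_config(n_cohorts = 1, n_subjects_per_cohort = 400, n_cpgs = 40,
                    baseline_hazard_scale = 0.04,
                    causal_cpg_ids = "cg00000030",
                    causal_loghr_per_unit_beta = 1.2,
                    missing_rate = 0, seed = 65)
  co <- generate_cohorts(cfg)[[1]]
  unadj <- fit_cox_per_cpg(co, "full", cpg_ids = "cg00000030")
  score <- rnorm(400)                      # independent of CpG and outcome
  adj <- adjusted_mortality_model(co, "cg00000030",
                                  scores = cbind(risk_score = score))
  expect_true(adj$converged)
  expect_lt(abs(adj$beta - unadj$beta), 2 * unadj$se)

  # score equal to the CpG itself: collinear, flagged
  dup <- adjusted_mortality_model(co, "cg00000030",
                                  scores = cbind(copy = co$beta["cg00000030", ]))
  expect_true(!dup$converged || dup$se > 2 * unadj$se)
})

test_that("pooled CpG correlations recover exact and null structure", {
  set.seed(66)
  mk <- function(seed) {
    set.seed(seed)
    b1 <- runif(200)
    m <- rbind(cg_a = b1, cg_b = 1 - b1, cg_c = runif(200))
    structure(list(cohort_id = paste0("c", seed), beta = m,
                   covariates = NULL), class = "cohort_dataset")
  }
  cohorts <- list(mk(1), mk(2))
  r <- score_cpg_correlations(cohorts, c("cg_a", "cg_b", "cg_c"),
                              c("cg_a", "cg_c"))
  expect_equal(r["cg_a", "cg_a"], 1, tolerance = 1e-6)
  expect_equal(r["cg_b", "cg_a"], -1, tolerance = 1e-6)
  expect_lt(abs(r["cg_c", "cg_a"]), 3 / sqrt(400))
  # constant CpG: undefined
  cohorts2 <- lapply(cohorts, function(co) {
    co$beta <- rbind(co$beta, cg_const = rep(0.5, 200)); co })
  r2 <- score_cpg_correlations(cohorts2, "cg_const", "cg_a")
  expect_true(is.na(r2["cg_const", "cg_a"]))
})

test_that("clock TSV round-trips through read_clock", {
  tf <- tempfile(fileext = ".tsv")
  write.table(data.frame(cpg_id = c("cg1", "cg2", "INTERCEPT"),
                         weight = c(1.5, -2, 40)),
              tf, sep = "\t", row.names = FALSE, quote = FALSE)
  clk <- read_clock(tf, "demo")
  expect_equal(clk$intercept, 40)
  expect_equal(clk$weights, c(cg1 = 1.5, cg2 = -2))
})
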