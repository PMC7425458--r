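gwas_row <- function(snp, ea, oa, eaf, beta, se = 0.02) {
  data.frame(snp_id = snp, effect_allele = ea, other_allele = oa,
             eaf = eaf, beta = beta, se = se,
             pval = 2 * pnorm(-abs(beta / se)), n = 1000L,
             stringsAsFactors = FALSE)
}

test_that("harmonization aligns alleles, drops ambiguous palindromes, orients bx >= 0", {
  exp_tab <- rbind(gwas_row("rs1", "A", "G", 0.3, 0.2),
                   gwas_row("rs2", "C", "T", 0.6, -0.15),
                   gwas_row("rs3", "A", "T", 0.5, 0.25),
                   gwas_row("rs4", "A", "T", 0.2, 0.3))
  out_tab <- rbind(gwas_row("rs1", "A", "G", 0.3, 0.10),   # same alleles
                   gwas_row("rs2", "T", "C", 0.4, 0.08),   # swapped
                   gwas_row("rs3", "A", "T", 0.5, 0.05),   # palindromic, ambiguous
                   gwas_row("rs4", "A", "T", 0.2, 0.12))   # palindromic, clear eaf
  set <- harmonize(exp_tab, out_tab)
  expect_equal(set$n_dropped_palindromic, 1)
  expect_setequal(set$snp_ids, c("rs1", "rs2", "rs4"))
  i1 <- match("rs1", set$snp_ids); i2 <- match("rs2", set$snp_ids)
  expect_equal(set$by[i1], 0.10)                  # unchanged
  # rs2: outcome alleles swapped (sign flip) and exposure beta negative
  # (orientation flip): net sign positive
  expect_equal(set$bx[i2], 0.15)
  expect_equal(set$by[i2], 0.08)
  expect_true(all(set$bx >= 0))
  expect_error(harmonize(exp_tab, gwas_row("rs9", "A", "G", 0.5, 0.1)),
               "no shared")
})

test_that("Wald ratio and its delta-method SE are exact", {
  set <- make_set(bx = 0.1, by = 0.05, sy = 0.02)
  w <- wald_ratio(set)
  expect_equal(w$estimate, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$or, exp(0.5))
  expect_equal(wald_ratio(make_set(0.1, 0))$estimate, 0)
  # ratio invariance to joint scaling
  expect_equal(wald_ratio(make_set(0.2, 0.1, sy = 0.04))$estimate, 0.5)
  expect_error(wald_ratio(make_set(0, 0.1)), "null instrument")
})

test_that("MR-Egger recovers exact-line slopes and intercepts", {
  set <- make_set(bx = c(0.1, 0.2, 0.3), by = c(0.15, 0.20, 0.25))
  e <- mr_egger(set)
  expect_equal(e$slope, 0.5, tolerance = 1e-9)
  expect_equal(e$intercept, 0.1, tolerance = 1e-9)

  set2 <- make_set(bx = c(0.1, 0.2, 0.4), by = 0.3 * c(0.1, 0.2, 0.4))
  e2 <- mr_egger(set2)
  expect_equal(e2$slope, 0.3, tolerance = 1e-9)
  expect_equal(e2$intercept, 0, tolerance = 1e-9)
  expect_error(mr_egger(make_set(c(0.1, 0.2), c(0.1, 0.2))), ">= 3")
})

test_that("weighted median interpolates cumulative weights and resists outliers", {
  s <- make_set(bx = rep(1, 3), by = c(0.4, 0.5, 0.6))
  expect_equal(weighted_median(s, n_boot = 0)$estimate, 0.5)

  # one gross outlier among 10: median stays near the valid ratio while the
  # IVW-style weighted mean is dragged away
  bx <- rep(0.2, 10); by <- 0.3 * bx; by[10] <- 5 * bx[10]
  s2 <- make_set(bx, by)
  wm <- weighted_median(s2, n_boot = 200, seed = 1)
  ivw_mean <- sum((bx / 0.01)^2 * (by / bx)) / sum((bx / 0.01)^2)
  expect_lt(abs(wm$estimate - 0.3), 0.02)
  expect_gt(abs(ivw_mean - 0.3), 0.4)

  # identical ratios: estimate exact, bootstrap SE shrinks with sy
  s3 <- make_set(rep(0.3, 4), rep(0.09, 4), sy = rep(1e-6, 4),
                 sx = rep(1e-6, 4))
  wm3 <- weighted_median(s3, n_boot = 100, seed = 2)
  expect_equal(wm3$estimate, 0.3, tolerance = 1e-6)
  expect_lt(wm3$se, 1e-4)
})

test_that("weighted mode finds the majority cluster and limits to the mean", {
  s <- make_set(bx = rep(1, 4), by = c(0.3, 0.3, 0.3, 0.9))
  m <- weighted_mode(s, n_boot = 0)
  expect_lt(abs(m$estimate - 0.3), 0.05)

  # single tight cluster: mode ~ weighted mean within bandwidth tolerance
  set.seed(3)
  r <- 0.4 + rnorm(20, 0, 0.01)
  s2 <- make_set(rep(1, 20), r)
  m2 <- weighted_mode(s2, n_boot = 0)
  expect_lt(abs(m2$estimate - mean(r)), 0.02)

  # infinite-bandwidth limit: argmax at the weighted mean of the ratios
  s3 <- make_set(rep(1, 5), c(0.1, 0.2, 0.3, 0.6, 0.8))
  m3 <- weighted_mode(s3, bandwidth_factor = 1e6, n_boot = 0)
  expect_equal(m3$estimate, mean(c(0.1, 0.2, 0.3, 0.6, 0.8)),
               tolerance = 0.01)
})

test_that("all estimators coincide when every instrument has the same ratio", {
  s <- make_set(bx = c(0.1, 0.2, 0.3, 0.4), by = 0.25 * c(0.1, 0.2, 0.3, 0.4))
  e <- mr_egger(s)$slope
  wm <- weighted_median(s, n_boot = 0)$estimate
  mo <- weighted_mode(s, n_boot = 0)$estimate
  s1 <- make_set(0.2, 0.05)
  w <- wald_ratio(s1)$estimate
  expect_equal(e, 0.25, tolerance = 1e-6)
  expect_equal(wm, 0.25, tolerance = 1e-6)
  expect_equal(mo, 0.25, tolerance = 1e-6)
  expect_equal(w, 0.25, tolerance = 1e-6)
})

test_that("Egger slope attenuates by the exposure reliability ratio (NOME violation)", {
  # exposure-side measurement error dilutes the Egger slope like any
  # errors-in-variables regression: attenuation ~ var(bx_true)/var(bx)
  reps <- 150
  slopes <- vapply(seq_len(reps), function(r) {
    s <- generate_mr_summaries(50, true_effect = 0.3, pleiotropy_frac = 0,
                               seed = 9000 + r, exposure_se = 0.06)
    mr_egger(harmonize(s$exposure, s$outcome))$slope
  }, numeric(1))
  var_true <- 0.3^2 / 12                  # bx_true ~ U(0.1, 0.4)
  expected <- 0.3 * var_true / (var_true + 0.06^2)
  mc_se <- sd(slopes) / sqrt(reps)
  expect_lt(abs(mean(slopes) - expected), 3 * mc_se + 0.005)
  expect_lt(mean(slopes), 0.3)            # attenuation is toward the null
})

test_that("with pleiotropy under InSIDE the Egger intercept tracks the mean direct effect", {
  s <- generate_mr_summaries(100, true_effect = 0, pleiotropy_frac = 1,
                             pleiotropy_mean = 0.1, seed = 44)
  set <- harmonize(s$exposure, s$outcome)
  e <- mr_egger(set)
  expect_lt(abs(e$intercept - 0.1), 3 * e$intercept_se + 0.01)
})
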