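# Shared in-code fixtures for the test suite.

# Minimal cohort with fully controlled survival data and no covariates.
make_toy_cohort <- function(beta_row, time, event, id = "toy",
                            cpg = "cg_toy") {
  n <- length(time)
  structure(list(
    cohort_id = id,
    beta = matrix(beta_row, nrow = 1, byrow = TRUE,
                  dimnames = list(cpg, paste0("s", seq_len(n)))),
    covariates = data.frame(sample_id = paste0("s", seq_len(n))),
    time = time, event = event,
    cell_fractions_true = NULL, truth = NULL), class = "cohort_dataset")
}

# The three-subject dataset whose Cox MLE has the closed form -log(2)/2.
toy3 <- function() make_toy_cohort(c(1, 0, 1), c(1, 2, 3), c(1, 1, 1))

# Instrument set constructor for MR tests.
make_set <- function(bx, by, sx = rep(0.01, length(bx)),
                     sy = rep(0.01, length(bx))) {
  structure(list(snp_ids = paste0("rs", seq_along(bx)), bx = bx, sx = sx,
                 by = by, sy = sy, harmonized = TRUE,
                 n_dropped_palindromic = 0L, n_dropped_incompatible = 0L),
            class = "instrument_set")
}

# Brute-force partial-likelihood maximizer over a coefficient grid
# (independent oracle for single-predictor Cox fits, Breslow ties).
cox_grid_oracle <- function(x, time, event, grid = seq(-3, 3, 1e-4)) {
  logpl <- vapply(grid, function(b) {
    eta <- b * x
    sum(vapply(which(event == 1), function(i)
      eta[i] - log(sum(exp(eta[time >= time[i]]))), numeric(1)))
  }, numeric(1))
  grid[which.max(logpl)]
}
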