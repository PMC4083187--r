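test_that("tau filter handles degenerate inputs per contract", {
  expect_identical(thompson_tau_filter(c(10, 10, 10, 10))$retained,
                   c(10, 10, 10, 10))
  expect_length(thompson_tau_filter(c(10, 10, 10, 10))$removed_idx, 0)
  expect_warning(r <- thompson_tau_filter(c(5, 50)), "fewer than 3")
  expect_identical(r$retained, c(5, 50))
  expect_error(thompson_tau_filter(1:10, alpha = 0), "alpha")
})

test_that("tau filter removes a gross outlier and keeps the rest in order", {
  r <- thompson_tau_filter(c(9.8, 10.0, 10.2, 10.5, 35.0), alpha = 0.05)
  expect_equal(r$removed, 35.0)
  expect_equal(r$retained, c(9.8, 10.0, 10.2, 10.5))
  ref <- tau_filter_oracle(c(9.8, 10.0, 10.2, 10.5, 35.0))
  expect_equal(r$retained, ref$retained)
})

test_that("tau filter matches the brute-force oracle on random data", {
  set.seed(2024)
  for (i in 1:500) {
    n <- sample(3:50, 1)
    x <- rnorm(n, mean = runif(1, 0, 50), sd = runif(1, 0.1, 10))
    if (i %% 3 == 0)  # salt some gross outliers in
      x[sample(n, 1)] <- x[1] + sample(c(-1, 1), 1) * runif(1, 20, 60)
    got <- thompson_tau_filter(x, alpha = 0.05)
    ref <- tau_filter_oracle(x, alpha = 0.05)
    expect_identical(got$retained, ref$retained)
    expect_identical(got$removed_idx, ref$removed_idx)
  }
})

test_that("methylation statistic identities hold", {
  expect_equal(pct_cpg_methylation(50, 50, 0), 0)
  expect_equal(pct_cpg_methylation(40, 80, 5), 45)
  expect_equal(pct_cpg_methylation(25, 60, 3), 100 - 100 * 25 / 60 - 3)
  for (a in c(1, 17, 60)) expect_equal(pct_cpg_methylation(a, a, 0), 0)
  for (b in c(5, 42, 95)) expect_equal(pct_cpg_methylation(0, b, 0), 100)
  # strictly decreasing in the HpaII mean, increasing in the MspI mean
  h <- seq(5, 60, by = 5)
  expect_true(all(diff(sapply(h, pct_cpg_methylation,
                              mspi_mean = 70, control_mean = 2)) < 0))
  m <- seq(30, 90, by = 5)
  expect_true(all(diff(sapply(m, function(mm)
    pct_cpg_methylation(25, mm, 2))) > 0))
  expect_error(pct_cpg_methylation(10, 0, 0), "MspI")
  expect_error(pct_cpg_methylation(-1, 50, 0), "non-negative")
})

test_that("negative estimates are legal and unclipped", {
  expect_lt(pct_cpg_methylation(50, 55, 20), 0)
})

test_that("singleton and zero-variance groups give width-zero intervals", {
  e1 <- suppressWarnings(
    estimate_methylation(comet_groups(0, 30, 60), n_boot = 50, seed = 1))
  expect_equal(e1$pct_methylation, 50)
  expect_equal(e1$ci_low, 50)
  expect_equal(e1$ci_high, 50)
  e2 <- estimate_methylation(
    comet_groups(rep(2, 6), rep(40, 6), rep(80, 6)), n_boot = 50, seed = 1)
  expect_equal(e2$pct_methylation, 48)
  expect_equal(e2$ci_high - e2$ci_low, 0)
})

test_that("estimates are reproducible byte-for-byte given a seed", {
  g <- toy_groups()
  e1 <- estimate_methylation(g, n_boot = 200, seed = 11)
  e2 <- estimate_methylation(g, n_boot = 200, seed = 11)
  expect_identical(serialize(e1, NULL), serialize(e2, NULL))
  e3 <- estimate_methylation(g, n_boot = 200, seed = 12)
  expect_false(identical(e1$ci_low, e3$ci_low))
})

test_that("bootstrap interval brackets the replicate median", {
  g <- toy_groups()
  e <- estimate_methylation(g, n_boot = 500, seed = 3)
  expect_lte(e$ci_low, median(e$boot))
  expect_lte(median(e$boot), e$ci_high)
  expect_equal(length(e$boot) + e$n_boot_discarded, e$n_boot)
})

test_that("estimator recovers truth on simulated linear-regime data", {
  p <- linear_params(0.5, seed = 314)
  g <- groups_from_table(simulate_cell_population(p, "s"))[[1]]
  e <- estimate_methylation(g, n_boot = 500, seed = 1)
  expect_equal(e$pct_methylation, 50, tolerance = 2 / 50)
  expect_lt(e$ci_high - e$ci_low, 5)
})

test_that("interval estimates have near-nominal coverage of the analytic expectation", {
  p0 <- linear_params(0.5)
  A <- expected_methylation_statistic(p0)$statistic
  hits <- sapply(1:60, function(i) {
    g <- groups_from_table(
      simulate_cell_population(linear_params(0.5, seed = 6000 + i), "s"))[[1]]
    e <- estimate_methylation(g, n_boot = 400, seed = i)
    e$ci_low <= A && A <= e$ci_high
  })
  expect_gte(mean(hits), 0.80)
})

test_that("condition contrasts difference the point estimates and straddle zero when equal", {
  u <- suppressWarnings(
    estimate_methylation(comet_groups(0, 100 - 60.2, 100), n_boot = 100,
                         seed = 1))
  t <- suppressWarnings(
    estimate_methylation(comet_groups(0, 100 - 34.0, 100), n_boot = 100,
                         seed = 2))
  d <- compare_conditions(u, t)
  expect_equal(d$difference, 26.2)
  g <- toy_groups()
  e1 <- estimate_methylation(g, n_boot = 300, seed = 5)
  e2 <- estimate_methylation(g, n_boot = 300, seed = 6)
  d0 <- compare_conditions(e1, e2)
  expect_equal(d0$difference, 0)
  expect_lte(d0$ci_low, 0)
  expect_gte(d0$ci_high, 0)
  e3 <- estimate_methylation(g, n_boot = 300, ci_level = 0.9, seed = 7)
  expect_error(compare_conditions(e1, e3), "confidence levels")
})

test_that("model-object methods expose the fit consistently", {
  e <- estimate_methylation(toy_groups(), n_boot = 200, seed = 8)
  expect_equal(unname(coef(e)), e$pct_methylation)
  ci <- confint(e)
  expect_equal(unname(ci[1, ]), c(e$ci_low, e$ci_high))
  expect_error(confint(e, level = 0.8), "level")
  expect_output(print(e), "methylation")
  expect_output(summary(e), "outliers removed")
  f <- tempfile(fileext = ".pdf")
  pdf(f); plot(e); dev.off()
  expect_true(file.size(f) > 0)
  unlink(f)
})
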