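test_that("parameter invariants are enforced with the offending field named", {
  expect_error(sim_params(m = 1.2), "'m'")
  expect_error(sim_params(m = 0.5, h = 0.4, e = 0.2), "must not exceed 1")
  expect_error(sim_params(m = 0.5, kappa = 0), "'kappa'")
  expect_error(sim_params(m = 0.5, sigma = -1), "'sigma'")
  expect_error(sim_params(m = 0.5, S = 0), "'S'")
})

test_that("expected tail intensity follows the saturating response", {
  expect_equal(expected_tail_intensity(0, 500), 0)
  expect_equal(expected_tail_intensity(1000, 1000), 100 * (1 - exp(-1)))
  b <- seq(0, 5000, by = 250)
  ti <- expected_tail_intensity(b, 1200)
  expect_true(all(diff(ti) > 0))
  expect_true(all(ti >= 0 & ti < 100))
  expect_error(expected_tail_intensity(10, -1), "kappa")
})

test_that("simulated populations have the design's group structure", {
  p <- sim_params(m = 0.6, seed = 5)
  x <- simulate_cell_population(p, "s1")
  expect_equal(nrow(x), 3L * p$n_wells * p$n_cells)
  counts <- table(x$treatment)
  expect_equal(unname(c(counts["control"], counts["HpaII"], counts["MspI"])),
               rep(p$n_wells * p$n_cells, 3L))
  # default design: >= 9 wells, 50-100 comets/well, >= 400 comets/sample
  expect_gte(p$n_wells, 9L)
  expect_gte(p$n_cells, 50L)
  expect_lte(p$n_cells, 100L)
  expect_gte(p$n_wells * p$n_cells, 400L)
  expect_true(all(x$tail_intensity >= 0 & x$tail_intensity <= 100))
  expect_true(all(x$well %in% seq_len(p$n_wells)))
})

test_that("unmethylated DNA makes the isoschizomer groups exchangeable", {
  p <- sim_params(m = 0, lambda0 = 0, sigma = 0, S = 500, d = 0.8,
                  kappa = 4000, n_cells = 200, n_wells = 9, seed = 42)
  x <- simulate_cell_population(p, "s")
  mh <- mean(x$tail_intensity[x$treatment == "HpaII"])
  mm <- mean(x$tail_intensity[x$treatment == "MspI"])
  # identical break distributions: means agree within Monte-Carlo error
  expect_lt(abs(mh - mm) / mm, 0.02)
  expect_true(all(x$tail_intensity[x$treatment == "control"] == 0))
})

test_that("full methylation blocks HpaII entirely", {
  p <- sim_params(m = 1, lambda0 = 0, sigma = 0, seed = 7)
  x <- simulate_cell_population(p, "s")
  expect_true(all(x$tail_intensity[x$treatment == "HpaII"] == 0))
  expect_true(all(x$tail_intensity[x$treatment == "control"] == 0))
  expect_true(all(x$tail_intensity[x$treatment == "MspI"] > 0))
})

test_that("identical seeds reproduce byte-identical CSV output", {
  p <- sim_params(m = 0.4, seed = 99, n_cells = 50, n_wells = 9)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_comet_csv(simulate_cell_population(p, "s"), f1)
  write_comet_csv(simulate_cell_population(p, "s"), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  unlink(c(f1, f2))
})

test_that("the simulator does not disturb the caller's RNG stream", {
  set.seed(123)
  a <- runif(1)
  set.seed(123)
  invisible(simulate_cell_population(sim_params(m = 0.5, seed = 1), "s"))
  b <- runif(1)
  expect_identical(a, b)
})

test_that("median estimate is non-decreasing in the true methylation level", {
  med <- sapply(c(0, 0.25, 0.5, 0.75, 1), function(m) {
    stats <- sapply(1:20, function(s) {
      p <- sim_params(m = m, S = 300, d = 0.8, lambda0 = 10, sigma = 2,
                      kappa = 4000, n_cells = 20, n_wells = 5,
                      seed = 100 * m + s)
      g <- groups_from_table(simulate_cell_population(p, "s"))[[1]]
      pct_cpg_methylation(mean(g$hpaii), mean(g$mspi), mean(g$control))
    })
    median(stats)
  })
  expect_true(all(diff(med) >= 0))
})

test_that("simulated CEA counts follow the enzyme-susceptibility model", {
  p <- sim_params(m = 0, lambda0 = 0, sigma = 0)
  s0 <- simulate_cea_counts(p, scale_dpm = 5000, seed = 1)
  # unmethylated: equal Poisson means, so counts agree within noise
  expect_lt(abs(s0$dpm_hpaii - s0$dpm_mspi) /
              max(s0$dpm_mspi, 1), 0.01)
  s1 <- simulate_cea_counts(sim_params(m = 1), scale_dpm = 100,
                            background_dpm = 0, seed = 2)
  expect_equal(s1$dpm_hpaii, 0)
  # ratio of means: E(hpaii)/E(mspi) = 1 - m
  p4 <- sim_params(m = 0.4, S = 1000, d = 1, lambda0 = 0, sigma = 0)
  reps <- sapply(1:50, function(i) {
    s <- simulate_cea_counts(p4, scale_dpm = 10, seed = i)
    c(s$dpm_hpaii, s$dpm_mspi)
  })
  expect_equal(mean(reps[1, ]) / mean(reps[2, ]), 0.6, tolerance = 0.02)
  expect_error(simulate_cea_counts(p, scale_dpm = -1), "scale_dpm")
})

test_that("analytic statistic expectation matches large-sample simulation", {
  p <- linear_params(0.5, n_cells = 200, n_wells = 10, seed = 77)
  g <- groups_from_table(simulate_cell_population(p, "s"))[[1]]
  raw <- pct_cpg_methylation(mean(g$hpaii), mean(g$mspi), mean(g$control))
  expect_equal(raw, expected_methylation_statistic(p)$statistic,
               tolerance = 0.01)
})
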