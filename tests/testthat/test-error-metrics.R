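test_that("the error ratio is symmetric, >= 1, and matches the worked example", {
  expect_equal(error_ratio(10000, 5000), 2)
  expect_equal(error_ratio(10000, 20000), 2)
  expect_equal(error_ratio(12345, 12345), 1)
  set.seed(1)
  a <- exp(stats::rnorm(200, 10, 2)); b <- exp(stats::rnorm(200, 10, 2))
  expect_equal(error_ratio(a, b), error_ratio(b, a))
  expect_true(all(error_ratio(a, b) >= 1))
  expect_true(all(error_ratio(a, b)[a != b] > 1))
  expect_error(error_ratio(-1, 5), "positive")
  expect_error(error_ratio(5, 0), "positive")
})

test_that("percentage differences are signed and observed-anchored", {
  expect_equal(pct_difference(14000, 10000), 40)
  expect_equal(pct_difference(10000, 10000), 0)
  expect_equal(pct_difference(5000, 10000), -50)
  expect_error(pct_difference(1, 0), "positive")
})

test_that("aggregation reports the documented summaries per mode", {
  s <- data.frame(t_data = c(0, 0, 1), t_pred = c(1, 2, 2),
                  error_ratio = c(1, 3, 3), ln_ratio = c(0, 1.0986, -1.0986),
                  pct_diff = c(0, -66.7, 200))
  one <- aggregate_errors(s[3, ], "none")
  expect_equal(one$mean, 3); expect_equal(one$median, 3)
  expect_equal(one$sd, 0); expect_equal(one$n, 1)   # single sample: sd -> 0
  two <- aggregate_errors(s[1:2, ], "none")
  expect_equal(two$mean, 2); expect_equal(two$median, 2)
  by_td <- aggregate_errors(s, "per_tdata")
  expect_equal(sum(by_td$n), nrow(s))               # partition
  by_cell <- aggregate_errors(s, "per_tpred_tdata")
  expect_equal(sum(by_cell$n), nrow(s))
  expect_true(all(by_cell$p5 <= by_cell$p25 & by_cell$p25 <= by_cell$median &
                    by_cell$median <= by_cell$p75 & by_cell$p75 <= by_cell$p95))
})

test_that("band fractions are closed, monotone and degenerate-safe", {
  s <- data.frame(pct_diff = c(-30, 50))
  expect_equal(band_fractions(s, 40)$fraction, 0.5)
  bf <- band_fractions(s, c(40, 100))
  expect_lte(bf$fraction[1], bf$fraction[2])        # nested bands
  expect_equal(band_fractions(data.frame(pct_diff = c(0, 0)), c(40, 100))$fraction,
               c(1, 1))
  expect_equal(band_fractions(data.frame(pct_diff = 40), 40)$fraction, 1)
  expect_error(band_fractions(data.frame(pct_diff = numeric(0))), "no error")
})

test_that("summary tests behave at the null and at degenerate extremes", {
  all_under <- data.frame(ln_ratio = rep(c(0.2, 0.3, 0.4, 0.5), 5),
                          error_ratio = exp(rep(c(0.2, 0.3, 0.4, 0.5), 5)),
                          t_data = rep(1:4, 5))
  st <- summary_tests(all_under)
  expect_equal(st$binomial$prob_underprediction, 1)
  expect_equal(st$binomial$ties_excluded, 0)
  ties <- data.frame(ln_ratio = c(0, 0, 0.5, -0.2),
                     error_ratio = exp(abs(c(0, 0, 0.5, -0.2))),
                     t_data = c(0, 1, 2, 3))
  expect_equal(summary_tests(ties)$binomial$ties_excluded, 2)
  expect_equal(summary_tests(ties)$binomial$n, 2)
  expect_error(summary_tests(all_under[1, ]), "at least 2")

  # null calibration: N(0,1) ln_ratio, error ratio independent of t_data
  set.seed(7)
  reps <- 400
  cover <- logical(reps); t_p <- numeric(reps); under <- numeric(reps)
  for (i in seq_len(reps)) {
    s <- data.frame(ln_ratio = stats::rnorm(150), t_data = sample(0:9, 150, TRUE))
    s$error_ratio <- exp(abs(s$ln_ratio))
    st <- summary_tests(s)
    ci <- st$regression$slope + c(-1, 1) * stats::qt(0.975, 148) * st$regression$se
    cover[i] <- ci[1] < 0 && ci[2] > 0
    t_p[i] <- st$t_test$p
    under[i] <- st$binomial$prob_underprediction
  }
  expect_gt(mean(cover), 0.90)          # ~95% CI coverage of the null slope
  expect_lt(mean(cover), 0.99)
  expect_lt(abs(mean(under) - 0.5), 0.02)
  expect_lt(abs(mean(t_p < 0.05) - 0.05), 0.04)  # t-test p approx uniform
  expect_lt(abs(mean(t_p) - 0.5), 0.05)
})

test_that("mean error ratio dominates exp(|mean ln_ratio|) (Jensen)", {
  set.seed(11)
  for (i in 1:20) {
    ln <- stats::rnorm(100, mean = stats::runif(1, -1, 1))
    expect_gte(mean(exp(abs(ln))), exp(abs(mean(ln))))
  }
})

test_that("error samples derive exactly from the cells", {
  run <- small_run()
  s <- error_samples(run$cells)
  expect_true(all(!is.na(s$observed_eur)))
  expect_equal(s$error_ratio, exp(abs(s$ln_ratio)))
  expect_equal(nrow(s), sum(!is.na(run$cells$observed_eur)))
})

test_that("cap scenarios recompute metrics and conserve adjusted counts", {
  run <- small_run()
  sc <- scenario_caps(run$cells)
  expect_setequal(sc$scenario, c("base", "min_only", "max_only", "none"))
  base <- sc[sc$scenario == "base", ]
  expect_equal(base$n_min_adjusted + base$n_max_adjusted,
               sum(run$cells$capped != "none"))
  expect_equal(sc$n_max_adjusted[sc$scenario == "min_only"], 0)
  expect_equal(sc$n_min_adjusted[sc$scenario == "max_only"], 0)
  expect_equal(sc$n_min_adjusted[sc$scenario == "none"], 0)

  # with no cap breaches, all four scenarios coincide
  quiet <- run$cells[run$cells$capped == "none", ]
  attr(quiet, "min_cap") <- attr(run$cells, "min_cap")
  attr(quiet, "max_cap") <- attr(run$cells, "max_cap")
  sq <- scenario_caps(quiet)
  expect_equal(sq$mean_error, rep(sq$mean_error[1], 4))
  expect_equal(sq$within_40pct, rep(sq$within_40pct[1], 4))
})

test_that("the report writes every declared table and figure", {
  run <- small_run()
  out <- withr::local_tempdir()
  paths <- render_report(run$cells, out)
  expect_true(all(file.exists(paths)))
  expect_true(file.exists(file.path(out, "errors_per_tdata.csv")))
  expect_true(file.exists(file.path(out, "cap_scenarios.csv")))
  expect_true(file.exists(file.path(out, "heatmap_mean_error.png")))
  tab <- utils::read.csv(file.path(out, "errors_per_tpred_tdata.csv"))
  expect_true(all(tab$t_pred > tab$t_data))   # upper-triangular occupancy
  expect_error(render_report(run$cells[0, ], withr::local_tempdir()),
               "no validation cells")
})
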