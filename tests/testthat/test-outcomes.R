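test_that("payoff matches its closed form on all decision/outcome cells", {
  w <- payoff_weights(alpha = 1.7, beta = 0.4)
  expect_equal(payoff(0, 0, w), 0)
  expect_equal(payoff(1, 0, w), -0.4)
  expect_equal(payoff(1, 1, w), -0.4)   # prescribing always costs beta
  expect_equal(payoff(0, 1, w), -1.7)   # untreated infection costs alpha
  expect_error(payoff(0.5, 1, w), class = "abx_domain_error")
  expect_error(payoff_weights(0, 1), class = "abx_parameter_error")
})

test_that("aggregate payoff difference equals the record-wise sum", {
  for (seed in 1:25) {
    co <- rand_cohort(n = 30, seed = seed)
    df <- cohort_data(co)
    pol <- delegation_policy(stats::runif(1, 0, 0.5), stats::runif(1, 0.5, 1))
    asg <- apply_delegation(co, pol)
    w <- payoff_weights(stats::runif(1, 0.1, 3), stats::runif(1, 0.1, 3))
    pi_closed <- aggregate_payoff_diff(co, asg, w)
    pi_records <- sum(
      (-w$alpha * df$y * (1 - asg$delta) - w$beta * asg$delta) -
        (-w$alpha * df$y * (1 - df$d) - w$beta * df$d))
    expect_equal(pi_closed, pi_records)
  }
  co <- rand_cohort(20, seed = 99)
  sq <- apply_delegation(co, delegation_policy(-Inf, Inf))
  expect_equal(aggregate_payoff_diff(co, sq, payoff_weights(1, 1)), 0)
})

test_that("holding treated infections fixed while cutting use raises payoffs", {
  # the payoff-improvement guarantee for any positive weights
  for (seed in 26:50) {
    co <- rand_cohort(n = 40, seed = seed)
    pol <- optimize_delegation(co)
    asg <- apply_delegation(co, pol)
    df <- cohort_data(co)
    if (sum(df$y * (asg$delta - df$d)) != 0) next
    w <- payoff_weights(stats::runif(1, 0.01, 10), stats::runif(1, 0.01, 10))
    expect_gte(aggregate_payoff_diff(co, asg, w), 0)
  }
})

test_that("outcome accounting reproduces forced examples", {
  co <- tiny_cohort(m = c(0.2, 0.4, 0.6, 0.8), d = c(1, 1, 0, 0),
                    y = c(1, 0, 1, 0))
  asg <- structure(list(delta = c(1L, 0L, 1L, 0L),
                        delegated = c(TRUE, FALSE, FALSE, TRUE),
                        overruled = c(FALSE, TRUE, TRUE, FALSE),
                        policy = NULL),
                   class = "abx_assignment")
  rep <- evaluate_policy(co, asg)
  expect_equal(unname(rep$pct[["antibiotic_use"]]), 0)
  expect_equal(unname(rep$pct[["treated_uti"]]), 100)  # 1 -> 2 treated
  expect_equal(unname(rep$pct[["overruled"]]), 50)
  expect_equal(unname(rep$pct[["delegated"]]), 50)
  expect_equal(rep$counts$baseline, c(4, 2, 1, 2, 1))
  expect_equal(rep$counts$counterfactual, c(4, 2, 2, 2, 0))
})

test_that("status quo yields zero changes and zero overruling", {
  co <- rand_cohort(50, seed = 3)
  asg <- apply_delegation(co, delegation_policy(-Inf, Inf))
  rep <- evaluate_policy(co, asg)
  expect_equal(unname(rep$pct[c("treated_uti", "antibiotic_use",
                                "overprescribing", "overruled")]),
               rep(0, 4))
  expect_equal(unname(rep$pct[["delegated"]]), 100)
})

test_that("zero baseline denominators raise errors naming the quantity", {
  co <- tiny_cohort(m = c(0.2, 0.8), d = c(0, 0), y = c(0, 1))
  asg <- apply_automation(co, automation_policy(0.5))
  expect_error(evaluate_policy(co, asg), "treated_uti",
               class = "abx_undefined_percentage_error")
  rep <- evaluate_policy(co, asg, on_zero = "na")
  expect_true(is.na(rep$pct[["treated_uti"]]))
})

test_that("bootstrap is deterministic, degenerate on constant cohorts, and covers", {
  co <- default_test_cohort()
  sub <- as_cohort(cohort_data(co)[1:6000, ])
  pol <- optimize_delegation(sub)
  spec <- bootstrap_spec(n_samples = 120, seed = 42)
  r1 <- bootstrap_policy_ci(sub, pol, spec)
  r2 <- bootstrap_policy_ci(sub, pol, spec)
  expect_identical(r1$ci, r2$ci)
  expect_false(identical(
    r1$ci, bootstrap_policy_ci(sub, pol, bootstrap_spec(120, seed = 43))$ci))
  # point estimates inside their intervals
  for (nm in colnames(r1$ci)) {
    expect_gte(r1$pct[[nm]], r1$ci["low", nm] - 1e-9)
    expect_lte(r1$pct[[nm]], r1$ci["high", nm] + 1e-9)
  }

  same <- as_cohort(data.frame(m = rep(0.5, 40), d = rep(1, 40),
                               y = rep(1, 40)))
  r0 <- bootstrap_policy_ci(same, automation_policy(0.4),
                            bootstrap_spec(n_samples = 50, seed = 1))
  widths <- r0$ci["high", ] - r0$ci["low", ]
  expect_true(all(widths == 0, na.rm = TRUE))  # no resampling variance
  expect_gte(sum(!is.na(widths)), 3)
  # overprescribing has a zero baseline here, so its change is flagged NA
  expect_true(is.na(r0$pct[["overprescribing"]]))
})

test_that("bootstrap interval widths shrink like one over root n", {
  co <- cohort_data(default_test_cohort())
  pol <- delegation_policy(0.32, 0.60)
  spec <- bootstrap_spec(n_samples = 250, seed = 7)
  w <- vapply(c(5000, 20000), function(n) {
    r <- bootstrap_policy_ci(as_cohort(co[1:n, ]), pol, spec)
    unname(r$ci["high", "antibiotic_use"] - r$ci["low", "antibiotic_use"])
  }, numeric(1))
  expect_lt(abs(w[1] / w[2] - 2), 0.5)  # quadrupling n should halve widths
})

test_that("test-intensity strata partition the tested consultations", {
  co <- default_test_cohort()
  sub <- as_cohort(cohort_data(co)[1:8000, ])
  pol <- delegation_policy(0.32, 0.60)
  strata <- test_intensity_strata(sub, pol, thresholds = c(0, 0.8, 0.9))
  n_tested <- sum(cohort_data(sub)$tested)
  for (s in strata) {
    expect_equal(s$n_above + s$n_below, n_tested)
  }
  # threshold 0: the above stratum is every tested consultation
  expect_equal(strata[[1]]$n_above, n_tested)
  expect_null(strata[[1]]$below)

  nodata <- tiny_cohort(m = 0.5, d = 1, y = 1)
  expect_error(test_intensity_strata(nodata, pol, 0.5),
               class = "abx_parameter_error")
})
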