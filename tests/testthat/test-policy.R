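test_that("automation rule uses the strict prescribe-above convention", {
  co <- tiny_cohort(m = c(0.405, 0.1, 0.5, 0.9), d = c(1, 0, 1, 1),
                    y = c(1, 0, 0, 1))
  asg <- apply_automation(co, automation_policy(0.405))
  expect_identical(asg$delta, c(0L, 0L, 1L, 1L))  # delta = 0 at m == k
  expect_false(any(asg$delegated))
  expect_identical(asg$overruled, c(TRUE, FALSE, FALSE, FALSE))

  all_in <- apply_automation(co, automation_policy(-1))
  expect_identical(all_in$delta, rep(1L, 4))

  co3 <- tiny_cohort(m = c(0.1, 0.5, 0.9), d = c(0, 0, 0), y = c(0, 0, 1))
  expect_identical(apply_automation(co3, automation_policy(0.5))$delta,
                   c(0L, 0L, 1L))
})

test_that("delegation rule delays at k_L, prescribes at k_H, defers between", {
  pol <- delegation_policy(0.320, 0.601)
  co <- tiny_cohort(m = c(0.2, 0.5, 0.320, 0.601, 0.9),
                    d = c(1, 1, 1, 0, 0), y = c(1, 1, 0, 0, 1))
  asg <- apply_delegation(co, pol)
  expect_identical(asg$delta, c(0L, 1L, 0L, 1L, 1L))
  expect_identical(asg$delegated, c(FALSE, TRUE, FALSE, FALSE, FALSE))
  expect_identical(asg$overruled, c(TRUE, FALSE, TRUE, TRUE, TRUE))

  # full delegation is the status quo
  sq <- apply_delegation(co, delegation_policy(0, 1))
  expect_identical(sq$delta, as.integer(co$consultations$d))
  expect_true(all(sq$delegated))

  expect_error(delegation_policy(0.7, 0.3), class = "abx_parameter_error")
})

test_that("optimal automation matches forced analytic examples", {
  co <- tiny_cohort(m = c(0.1, 0.5, 0.9), d = c(0, 1, 1), y = c(0, 0, 1))
  pol <- optimize_automation(co)
  expect_equal(pol$k, 0.5)
  expect_equal(pol$objective, -1)
  expect_equal(pol$constraint, 0)

  # physician decisions already follow a threshold rule: status quo attainable
  co2 <- tiny_cohort(m = c(0.1, 0.3, 0.6, 0.8), d = c(0, 0, 1, 1),
                     y = c(0, 1, 1, 1))
  pol2 <- optimize_automation(co2)
  expect_equal(pol2$objective, 0)
  expect_equal(pol2$constraint, 0)
})

test_that("optimal delegation matches forced analytic examples", {
  # delaying the low-risk overprescription and delegating the rest saves one
  # prescription at no cost in treated infections
  co <- tiny_cohort(m = c(0.1, 0.5, 0.9), d = c(1, 1, 0), y = c(0, 1, 1))
  pol <- optimize_delegation(co)
  expect_equal(pol$objective, -1)
  expect_equal(pol$constraint, 0)
  expect_gte(pol$k_L, 0.1)
  expect_lt(pol$k_L, 0.5)
  asg <- apply_delegation(co, pol)
  expect_identical(asg$delta, c(0L, 1L, 0L))
  expect_equal(brute_delegation(co)$objective, -1)
})

test_that("optimizers agree with exhaustive candidate search on random cohorts", {
  for (seed in 1:200) {
    co <- rand_cohort(n = sample(3:12, 1), seed = seed)
    pa <- optimize_automation(co)
    ba <- brute_automation(co)
    expect_equal(pa$objective, ba$objective, info = paste("seed", seed))
    expect_equal(pa$constraint, ba$constraint, info = paste("seed", seed))
    pd <- optimize_delegation(co)
    bd <- brute_delegation(co)
    expect_equal(pd$objective, bd$objective, info = paste("seed", seed))
    expect_equal(pd$constraint, bd$constraint, info = paste("seed", seed))
  }
})

test_that("optimizer results are invariant to row order", {
  co <- rand_cohort(40, seed = 1234)
  df <- cohort_data(co)
  set.seed(1)
  shuffled <- as_cohort(df[sample.int(nrow(df)), ])
  expect_equal(optimize_automation(co)$k, optimize_automation(shuffled)$k)
  pd1 <- optimize_delegation(co)
  pd2 <- optimize_delegation(shuffled)
  expect_equal(c(pd1$k_L, pd1$k_H), c(pd2$k_L, pd2$k_H))
})

test_that("delegation never does worse than the status quo", {
  for (seed in 301:340) {
    co <- rand_cohort(n = sample(5:30, 1), seed = seed)
    expect_lte(optimize_delegation(co)$objective, 0)
  }
})

test_that("raising the automation threshold never increases prescriptions", {
  co <- rand_cohort(200, seed = 77)
  ks <- sort(unique(cohort_data(co)$m))
  presc <- vapply(ks, function(k) sum(apply_automation(co, automation_policy(k))$delta),
                  numeric(1))
  expect_true(all(diff(presc) <= 0))
})

test_that("exhaustive oracle handles degenerate and adversarial cohorts", {
  one <- tiny_cohort(m = 0.4, d = 1, y = 0)
  res <- oracle_best_assignment(one)
  expect_equal(res$objective, -1)
  expect_identical(res$delta, 0L)

  expect_error(oracle_best_assignment(rand_cohort(21, seed = 1)),
               class = "abx_size_error")

  # the oracle optimises a superset of threshold rules
  for (seed in 401:430) {
    co <- rand_cohort(n = sample(4:10, 1), seed = seed)
    orc <- oracle_best_assignment(co)
    expect_lte(orc$objective, optimize_automation(co)$objective)
    expect_lte(orc$objective, optimize_delegation(co)$objective)
  }
})

test_that("threshold rules attain the exhaustive optimum on monotone cohorts", {
  for (seed in 501:530) {
    co <- monotone_cohort(n = sample(5:12, 1), seed = seed)
    orc <- oracle_best_assignment(co)
    expect_equal(optimize_automation(co)$objective, orc$objective,
                 info = paste("seed", seed))
    expect_equal(optimize_delegation(co)$objective, orc$objective,
                 info = paste("seed", seed))
  }
})

test_that("sequential re-optimisation with no history is the status quo", {
  co <- generate_cohort(generator_config(n = 800, seed = 9))
  span <- as.numeric(diff(range(cohort_data(co)$date)))
  res <- sequential_reoptimize(co, window_days = 365,
                               frequency_days = span + 2)
  expect_equal(nrow(res$periods), 1L)
  expect_true(all(res$assignment$delegated))
  expect_equal(unname(res$report$pct[c("treated_uti", "antibiotic_use",
                                       "overprescribing", "overruled")]),
               rep(0, 4))
})

test_that("sequential periods reuse the previous period's in-sample optimum", {
  df1 <- cohort_data(generate_cohort(generator_config(n = 2000, seed = 4)))
  df1$date <- as.Date("2011-01-01")
  df2 <- df1
  df2$date <- as.Date("2011-02-15")
  df2$consultation_id <- paste0("p2", df2$consultation_id)
  co <- as_cohort(rbind(df1, df2))
  res <- sequential_reoptimize(co, window_days = 400, frequency_days = 45)
  in_sample <- optimize_delegation(as_cohort(df1))
  expect_equal(res$periods$k_L[2], in_sample$k_L)
  expect_equal(res$periods$k_H[2], in_sample$k_H)
  expect_error(sequential_reoptimize(as_cohort(df1[, c("m", "d", "y")])),
               class = "abx_parameter_error")
})

test_that("undated cohorts are rejected by sequential re-optimisation", {
  co <- tiny_cohort(m = c(0.2, 0.6), d = c(0, 1), y = c(0, 1))
  expect_error(sequential_reoptimize(co), "dates",
               class = "abx_parameter_error")
})
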