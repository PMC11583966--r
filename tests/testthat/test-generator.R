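test_that("generator configuration validation names the offending field", {
  expect_error(generator_config(n = 0), "field 'n'",
               class = "abx_parameter_error")
  expect_error(generator_config(risk_shape_a = -1), "risk_shape_a",
               class = "abx_parameter_error")
  expect_error(generator_config(target_bacterial_rate = 1.4),
               "target_bacterial_rate", class = "abx_parameter_error")
  expect_error(generator_config(target_auc = 0.4), "target_auc",
               class = "abx_parameter_error")
  expect_error(generator_config(physician_threshold_spread = 0),
               "physician_threshold_spread", class = "abx_parameter_error")
})

test_that("identical (config, seed) yields a bit-identical cohort", {
  cfg <- generator_config(n = 3000, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c2 <- generate_cohort(cfg, seed = 12)
  expect_false(identical(a$consultations$y, c2$consultations$y))
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(generate_cohort(generator_config(n = 500, seed = 2)))
  expect_identical(before, .Random.seed)
})

test_that("symmetric risk shapes give a bacterial rate near one half", {
  cfg <- generator_config(n = 40000, risk_shape_a = 3, risk_shape_b = 3,
                          seed = 8)
  df <- cohort_data(generate_cohort(cfg))
  se <- sqrt(0.25 / nrow(df))
  expect_lt(abs(mean(df$y) - 0.5), 3 * se)
})

test_that("risk scores are calibrated within bins of 100", {
  df <- cohort_data(default_test_cohort())[1:20000, ]
  bins <- risk_bins(as_cohort(df), bin_size = 100)$overall
  se <- sqrt(pmax(bins$mean_m * (1 - bins$mean_m), 0.002) / bins$n)
  ok <- abs(bins$mean_y - bins$mean_m) <= 4 * se
  expect_gte(mean(ok), 0.95)
})

test_that("the miscalibration knob shifts outcomes off the 45-degree line", {
  cfg <- generator_config(n = 30000, miscalibration_shift = 0.8, seed = 5)
  df <- cohort_data(generate_cohort(cfg))
  bins <- risk_bins(as_cohort(df), bin_size = 300)$overall
  # outcomes now sit systematically above the predictions
  expect_gt(mean(bins$mean_y - bins$mean_m), 0.05)
})

test_that("an uninformative signal leaves physicians no private information", {
  cfg <- generator_config(n = 100000, signal_accuracy_base = 0.5,
                          signal_accuracy_peak = 0, seed = 31)
  co <- generate_cohort(cfg)
  bins <- risk_bins(co, bin_size = 2000)$overall
  df <- cohort_data(co)
  ord <- order(df$m, df$consultation_id)
  iota <- private_info(df$m[ord], df$d[ord], df$y[ord])
  n_bins <- nrow(bins)
  se <- vapply(seq_len(n_bins), function(b) {
    v <- iota[((b - 1) * 2000 + 1):(b * 2000)]
    stats::sd(v) / sqrt(length(v))
  }, numeric(1))
  expect_true(all(bins$mean_iota <= 4 * se))
})

test_that("with an informative signal treated patients have higher outcome rates", {
  bins <- risk_bins(default_test_cohort(), bin_size = 1000)
  # compare treated and untreated bins at matched mean risk via interpolation
  matched <- approx(bins$untreated$mean_m, bins$untreated$mean_y,
                    xout = bins$treated$mean_m, rule = 2)$y
  gap <- bins$treated$mean_y - matched
  expect_gt(mean(gap), 0.05)
  expect_gt(mean(gap > 0), 0.9)
})

test_that("generator config round-trips through YAML and JSON", {
  cfg <- generator_config(n = 123, seed = 77)
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_generator_config(cfg, path)
    back <- read_generator_config(path)
    expect_equal(unclass(back), unclass(cfg))
  }
})

test_that("calibration returns an already-calibrated config unchanged", {
  cfg <- generator_config(seed = 19)
  out <- calibrate_generator(cfg, tolerance = 0.01, n_sim = 50000)
  expect_equal(unclass(out), unclass(cfg), ignore_attr = TRUE)
  mom <- attr(out, "moments")
  expect_lt(abs(mom[["bacterial_rate"]] - 0.38), 0.01)
})

test_that("calibration forces the mean of the risk distribution to the target", {
  cfg <- generator_config(risk_shape_a = 1.2, risk_shape_b = 1.2, seed = 3)
  out <- calibrate_generator(cfg, tolerance = 0.015, n_sim = 40000)
  mean_m <- out$risk_shape_a / (out$risk_shape_a + out$risk_shape_b)
  expect_lt(abs(mean_m - 0.38), 0.015)
})

test_that("cohort coercion validates invariants", {
  expect_error(as_cohort(data.frame(m = c(0.2, 1.2), d = 0, y = 0)),
               "rows: 2", class = "abx_validation_error")
  expect_error(as_cohort(data.frame(m = 0.5, d = 2, y = 0)),
               "'d'", class = "abx_validation_error")
  expect_error(
    as_cohort(data.frame(consultation_id = c("a", "a"), m = 0.5, d = 0, y = 0)),
    "unique", class = "abx_validation_error")
})
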