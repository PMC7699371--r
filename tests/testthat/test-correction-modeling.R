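# Mixed-effects correction models and the three-criterion variable test.

test_that("a noiseless identity sensor yields slope 1, intercept 0", {
  prof <- profile_transient(n_peaks = 1)
  ex <- simulate_experiment(prof, condition_set("ARD"),
                            sensor_response_spec(noise_cv = 0),
                            material_properties("ARD", 2.6),
                            seed = 1, ref_rel_sd = 0)
  m <- fit_model(as.data.frame(ex), model_spec())
  expect_equal(unname(m$coefficients), c(0, 1), tolerance = 1e-6)
  expect_equal(m$mae, 0, tolerance = 1e-6)
})

test_that("the no-random-effect fit equals ordinary least squares", {
  d <- simulate_model_data(n_per_cell = 100, seed = 3)
  m <- fit_model(d, model_spec(c("temperature", "pattern")))
  # independent OLS oracle on the same transformed frame
  fr <- pmevalkit:::prepare_model_frame(d, "log10")
  ols <- lm(y ~ x + x:temp_c + x:pattern_transient, data = fr)
  expect_equal(unname(m$coefficients), unname(coef(ols)), tolerance = 1e-8)
  expect_equal(m$aic, AIC(ols), tolerance = 1e-8)
  expect_length(m$variance_components, 0)
})

test_that("material random slopes recover generative slope ratios", {
  # per-material total slopes 1.05 / 1.00 / 0.95 at n = 3 x 2000 per pattern
  d <- simulate_model_data(n_per_cell = 1000,
                           material_slopes = c(ARD = 0.05, SiO2 = 0,
                                               Al2O3 = -0.05),
                           temp_levels = 20, temp_slope = 0,
                           pattern_slope = 0, sigma = 0.05, seed = 21)
  m <- fit_model(d, model_spec(random_slope_terms = "material"))
  sl <- m$coefficients[["x"]] + lme4::ranef(m$fit)$material[, "x"]
  names(sl) <- rownames(lme4::ranef(m$fit)$material)
  truth <- 1 + c(ARD = 0.05, SiO2 = 0, Al2O3 = -0.05)
  ratios <- (sl / sl[["SiO2"]])[names(truth)]
  expect_equal(unname(ratios), unname(truth / truth[["SiO2"]]),
               tolerance = 0.05)
  expect_true(all(m$variance_components >= 0))
})

test_that("fixed generative slopes are recovered without bias", {
  d <- simulate_model_data(n_per_cell = 700, temp_slope = 0.004,
                           pattern_slope = 0.03, seed = 31)
  m <- fit_model(d, model_spec(c("temperature", "pattern"), "material"))
  expect_equal(m$coefficients[["x:temp_c"]], 0.004, tolerance = 0.1)
  expect_equal(m$coefficients[["x:pattern_transient"]], 0.03,
               tolerance = 0.1)
})

test_that("MAE matches a brute-force back-transformed residual oracle", {
  d <- simulate_model_data(n_per_cell = 150, seed = 8)
  m <- fit_model(d, model_spec("pattern"))
  oracle <- mean(abs(10^fitted(m$fit) - m$frame$reference_raw))
  expect_identical(m$mae, oracle)
})

test_that("the three-criterion test detects real effects and rejects noise", {
  mats <- fixture_materials()
  # strong material effect: all three criteria pass with a clear MAE fold
  spec <- sensor_response_spec(noise_cv = 0.15)
  d <- simulate_variable_subset(c("ARD", "SiO2", "Al2O3"), "material",
                                spec, mats, seed = 101)
  res <- test_variable(d, "material")
  expect_true(res$passed)
  expect_lt(res$anova_p, 1e-6)
  expect_lt(res$delta_aic, 0)
  expect_gt(res$mae_fold, 1)
  expect_true(res$boundary_test)

  # null power effect: no gain from the extra slope
  d0 <- simulate_variable_subset(c("battery", "wired"), "power",
                                 sensor_response_spec(noise_cv = 0.15),
                                 fixture_materials(c(ARD = 1)), seed = 102)
  res0 <- test_variable(d0, "power")
  expect_false(res0$passed)

  # a variable that is constant in the subset cannot be tested
  expect_error(test_variable(d0, "temperature"), "constant")
  expect_error(test_variable(d0, "power", baseline_terms = "power"),
               "baseline")
})

test_that("a redundant copy of an included term is rejected by AIC", {
  # power arm constructed to duplicate the pattern indicator exactly
  d <- simulate_model_data(n_per_cell = 300, pattern_slope = 0.05, seed = 55)
  d$power <- ifelse(d$pattern == "transient", "battery", "wired")
  # the aliased slope column is dropped by the fitter, so the refit cannot
  # improve on the baseline
  res <- test_variable(d, "power", baseline_terms = "pattern")
  expect_gte(res$delta_aic, 0)
  expect_false(res$passed)
  expect_gte(res$anova_p, 0.05)
})

test_that("null-variable rejection rate sits at the nominal level", {
  # 200 simulated screenings of a zero-slope variable: the likelihood-ratio
  # criterion alone should reject at ~5%
  mats <- fixture_materials(c(ARD = 1))
  spec <- sensor_response_spec(noise_cv = 0.15)
  pvals <- vapply(1:200, function(s) {
    d <- simulate_variable_subset(c(20, 15, 25), "temperature", spec, mats,
                                  seed = 5000 + s,
                                  profile_args = list(peak_duration = 450,
                                                      n_peaks = 1))
    test_variable(d, "temperature")$anova_p
  }, 0)
  rate <- mean(pvals < 0.05)
  se3 <- 3 * sqrt(0.05 * 0.95 / 200)
  expect_lt(abs(rate - 0.05), se3)
})

test_that("likelihood-ratio p agrees with a parametric bootstrap null", {
  set.seed(77)
  n <- 60
  d <- simulate_model_data(n_per_cell = n, temp_slope = 0,
                           material_slopes = c(ARD = 0), pattern_slope = 0,
                           temp_levels = c(15, 25), sigma = 0.08, seed = 78)
  fr <- pmevalkit:::prepare_model_frame(d, "log10")
  m0 <- lm(y ~ x, data = fr)
  m1 <- lm(y ~ x + x:temp_c, data = fr)
  lr_obs <- 2 * as.numeric(logLik(m1) - logLik(m0))
  p_chisq <- pchisq(lr_obs, 1, lower.tail = FALSE)
  # brute-force null: refit both models on data simulated from m0
  lr_null <- vapply(1:200, function(i) {
    yb <- simulate(m0)[[1]]
    frb <- transform(fr, y = yb)
    2 * as.numeric(logLik(lm(y ~ x + x:temp_c, data = frb)) -
                     logLik(lm(y ~ x, data = frb)))
  }, 0)
  p_boot <- mean(lr_null >= lr_obs)
  expect_lt(abs(p_boot - p_chisq),
            3 * sqrt(p_chisq * (1 - p_chisq) / 200) + 0.01)
})

test_that("prioritized selection carries structural terms and builds the final model", {
  mats <- fixture_materials()
  spec <- sensor_response_spec(noise_cv = 0.15, pattern_shift = 0.15,
                               device_sd = 0.05)
  long <- fixture_long(fixture_screening_design(), spec, mats, seed = 201)
  sel <- select_variables(long)
  expect_true(all(c("material", "pattern") %in% sel$passed_variables))
  expect_false(any(c("drift", "power") %in% sel$passed_variables))
  final <- build_final_model(long, sel$passed_variables)
  expect_s3_class(final, "correction_model")
  expect_true(all(is.finite(predict_concentration(
    final, c(100, 1000), data.frame(material = "ARD")))))
  # no variables passed: base regression only
  base <- build_final_model(long, character(0))
  expect_length(base$variance_components, 0)
  expect_named(base$coefficients, c("(Intercept)", "x"))
})

test_that("predictions back-transform correctly and flag unseen levels", {
  # exact relation y = x + 0.3 on the log10 scale
  x <- 10^seq(1, 3.5, length.out = 100)
  d <- data.frame(reference = x * 10^0.3, monitor = x, material = "ARD",
                  temperature = 20, relative_humidity = 50,
                  power = "battery", pattern = "transient",
                  session_time = 0, unit_id = "u1")
  m <- fit_model(d, model_spec())
  p <- predict_concentration(m, 100, data.frame(material = "ARD"))
  expect_equal(as.numeric(p), 100 * 10^0.3, tolerance = 1e-6)

  dm <- simulate_model_data(n_per_cell = 200, seed = 91)
  mm <- fit_model(dm, model_spec(random_slope_terms = "material"))
  pu <- predict_concentration(mm, 500, data.frame(material = "quartzite"))
  expect_true(is.finite(pu))
  expect_match(attr(pu, "new_levels"), "quartzite")
  ps <- predict_concentration(mm, 500, data.frame(material = "ARD"))
  expect_length(attr(ps, "new_levels"), 0)

  expect_error(predict_concentration(m, 4000, data.frame(material = "ARD"),
                                     cutoff = 2500), "cutoff")
})
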