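# Verification: binning, bias/precision, relative uncertainty, comparison.

test_that("binning follows the half-open convention and a histogram oracle", {
  bb <- bin_by_reference(c(1, 2, 3), c(250, 750, 4999))
  expect_equal(bb$n, c(1L, 1L, 0L, 0L, 0L, 1L))
  # boundary value goes to the bin opening at that edge
  b500 <- bin_by_reference(9, 500)
  expect_equal(b500$n, c(0L, 1L, 0L, 0L, 0L, 0L))

  set.seed(3)
  ref <- runif(1e4, 0, 5000)
  bb2 <- bin_by_reference(ref, ref)
  edges <- default_bin_edges()
  oracle <- vapply(seq_len(length(edges) - 1L), function(i)
    sum(ref >= edges[i] & ref < edges[i + 1L]), 0L)
  expect_identical(bb2$n, oracle)
  expect_equal(sum(bb2$n) + bb2$n_excluded, 1e4)

  out <- bin_by_reference(c(1, 1), c(5200, 250))
  expect_equal(out$n_excluded, 1L)
  expect_error(bin_by_reference(1, 1, edges = c(0, 5, 5)), "increasing")
})

test_that("bias and precision separate systematic from random error", {
  ref <- runif(100, 100, 1000)
  ident <- bias_precision(ref, ref, ref_uncertainty = 0)
  expect_equal(ident$bias, 0)
  expect_equal(ident$precision, 0)

  pure_bias <- bias_precision(1.2 * ref, ref, ref_uncertainty = 0)
  expect_equal(pure_bias$bias, 0.2, tolerance = 1e-12)
  expect_equal(pure_bias$precision, 0)

  few <- bias_precision(ref[1:10], ref[1:10])
  expect_equal(few$status, "insufficient_data")
  expect_true(is.na(few$bias))

  # per-bin statistics equal the brute-force mean/SD of the ratio
  set.seed(9)
  pred <- ref * (1 + rnorm(100, 0.05, 0.2))
  bp <- bias_precision(pred, ref, ref_uncertainty = 0.1)
  r <- pred / ref
  expect_equal(bp$bias, mean(r) - 1, tolerance = 1e-12)
  expect_equal(bp$precision, sqrt(max(sd(r)^2 - 0.01, 0)),
               tolerance = 1e-12)
})

test_that("quadrature deconvolution recovers the monitor CV", {
  set.seed(12)
  n <- 1e5
  ref <- runif(n, 200, 2000)
  # observed relative spread built as the quadrature sum of reference (10%)
  # and monitor (5%) components
  pred <- ref * (1 + rnorm(n, 0, sqrt(0.10^2 + 0.05^2)))
  bp <- bias_precision(pred, ref, ref_uncertainty = 0.10)
  s_obs <- sqrt(0.10^2 + 0.05^2)
  se_s <- (s_obs / sqrt(2 * n)) * (s_obs / 0.05)   # delta-method SE
  expect_lt(abs(bp$precision - 0.05), 3 * se_s)
})

test_that("relative uncertainty combines bias and precision as a 95% band", {
  expect_equal(relative_uncertainty(0, 0), 0)
  expect_equal(relative_uncertainty(0.10, 0.05), 19.8)
  expect_error(relative_uncertainty(0, -0.1), ">= 0")

  # monotone in |bias| and in precision
  u <- relative_uncertainty(0.1, 0.05)
  expect_gt(relative_uncertainty(0.2, 0.05), u)
  expect_gt(relative_uncertainty(0.1, 0.10), u)
  expect_equal(relative_uncertainty(-0.1, 0.05), u)

  # coverage: with zero bias, ~95% of readings fall inside the band
  set.seed(13)
  n <- 1e5
  ref <- runif(n, 100, 1000)
  s <- 0.1
  pred <- ref * (1 + rnorm(n, 0, s))
  u95 <- relative_uncertainty(0, s) / 100
  cover <- mean(abs(pred - ref) / ref <= u95)
  expect_lt(abs(cover - 0.95), 3 * sqrt(0.95 * 0.05 / n))
})

test_that("uncertainty report judges bins against the target and flags NA", {
  set.seed(21)
  ref <- runif(5000, 0, 5200)
  pred <- ref * (1 + rnorm(5000, 0, sqrt(0.1^2 + 0.1^2)))
  rep <- uncertainty_report(pred, ref, target = 50)
  expect_equal(nrow(rep$bins), 6)
  expect_true(all(rep$bins$status == "ok"))
  expect_true(all(rep$bins$meets_target ==
                    (rep$bins$uncertainty <= 50)))
  # an empty low bin reports insufficient data, as NA
  high <- ref[ref > 600]
  rep2 <- uncertainty_report(high, high, n_min = 30)
  expect_equal(rep2$bins$status[1], "insufficient_data")
  expect_true(is.na(rep2$bins$uncertainty[1]))
})

test_that("comparing a model with itself gives unit folds", {
  d <- simulate_model_data(n_per_cell = 400, seed = 41,
                           conc_range = c(50, 4800))
  m <- fit_model(d, model_spec())
  cmp <- compare_corrections(m, m, d)
  expect_true(all(abs(cmp$folds$fold[cmp$folds$defined] - 1) < 1e-12))
  expect_equal(cmp$average_fold, 1, tolerance = 1e-12)
})

test_that("a well-behaved monitor's low-bin precision band matches its combined generative noise", {
  # gain 1, 10% multiplicative monitor noise, 10% reference noise, no
  # rollover: the raw precision band (deconvolution off, so the
  # prediction/reference spread keeps both noise components) should sit
  # near the combined generative value
  # 1.96 * sqrt(0.10^2 + 0.10^2) * 100 = 27.7%. The report's bias term is
  # excluded: it carries the small positive offsets intrinsic to the
  # operational estimator (log-log regression dilution from errors-in-x,
  # the Jensen effect of the noisy-reference denominator), which are not
  # part of the generative noise.
  mats <- fixture_materials(c(ARD = 1))
  spec <- sensor_response_spec(noise_cv = 0.10)
  u_low <- vapply(1:25, function(s) {
    fitd <- fixture_long(build_design(list(material = "ARD"), "factorial"),
                         spec, mats, seed = 300 + s,
                         profile_args = list(n_peaks = 2))
    verd <- fixture_long(build_design(list(material = "ARD",
                                           session_time = c(0, 0, 0)),
                                      "factorial"),
                         spec, mats, seed = 600 + s,
                         profile_args = list(n_peaks = 2))
    m <- fit_model(fitd, model_spec())
    keep <- verd$monitor > 0 & verd$reference > 0
    pred <- predict_concentration(m, verd$monitor[keep],
                                  data.frame(material = "ARD"))
    rep <- uncertainty_report(pred, verd$reference[keep],
                              ref_uncertainty = 0)
    196 * rep$bins$precision[1]
  }, 0)
  expect_lt(abs(mean(u_low) - 27.7) / 27.7, 0.20)
})

test_that("correcting real effects lowers bin uncertainty versus the average model", {
  mats <- fixture_materials()
  spec <- sensor_response_spec(noise_cv = 0.15, pattern_shift = 0.15)
  long <- fixture_long(fixture_screening_design(), spec, mats, seed = 61)
  sel <- select_variables(long)
  full <- build_final_model(long, sel$passed_variables)
  base <- build_final_model(long, character(0))
  ver <- fixture_long(build_design(list(material = c("ARD", "SiO2", "Al2O3"),
                                        temperature = c(15, 20, 25)),
                                   type = "factorial"),
                      spec, mats, seed = 62)
  cmp <- compare_corrections(full, base, ver)
  expect_gt(cmp$average_fold, 1)
})
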