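# Screening: loess smoothing, rollover detection, cutoffs, truncation,
# normalization selection.

# tent-shaped rollover curve: linear rise to the apex, then a decline
make_rollover_pairs <- function(apex_ref = 2500, apex_mon = NULL,
                                max_ref = 5000, decline = 1, n = 200) {
  ref <- seq(1, max_ref, length.out = n)
  apex_mon <- apex_mon %||% apex_ref
  slope_up <- apex_mon / apex_ref
  mon <- ifelse(ref <= apex_ref, slope_up * ref,
                pmax(0, apex_mon - decline * slope_up * (ref - apex_ref)))
  data.frame(reference = ref, monitor = mon)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("loess smooth recovers identity, turning point and flat noise", {
  ref <- seq(10, 5000, length.out = 300)
  sm <- smooth_experiment(ref, ref)
  expect_lt(max(abs(sm$fitted - sm$grid) / sm$grid), 0.01)

  roll <- make_rollover_pairs(apex_ref = 2500)
  sm2 <- smooth_experiment(roll$reference, roll$monitor)
  expect_lt(abs(sm2$grid[which.max(sm2$fitted)] - 2500) / 2500, 0.05)

  set.seed(1)
  sm3 <- smooth_experiment(seq_len(200), rnorm(200, 100, 5))
  drift <- diff(range(sm3$fitted)) / 100
  expect_lt(drift, 0.05)

  expect_warning(expect_null(smooth_experiment(1:10, 1:10)), "fewer than 20")
})

test_that("negative-correlation detection flags rollover, not noise wiggle", {
  ref <- seq(10, 5000, length.out = 300)
  inc <- detect_negative_correlation(smooth_experiment(ref, 0.9 * ref))
  expect_false(inc$flag)
  expect_equal(inc$limit, max(0.9 * ref))

  roll <- make_rollover_pairs(apex_mon = 3000, decline = 0.2)
  det <- detect_negative_correlation(
    smooth_experiment(roll$reference, roll$monitor))
  expect_true(det$flag)
  expect_equal(det$limit, 3000, tolerance = 0.03)  # corner smoothing bias

  # 1% post-apex decline under a 5% tolerance: not a rollover
  mild <- make_rollover_pairs(apex_mon = 3000, decline = 0.01)
  det2 <- detect_negative_correlation(
    smooth_experiment(mild$reference, mild$monitor), decline_tol = 0.05)
  expect_false(det2$flag)
})

test_that("rollover detection is invariant to uniform axis rescaling", {
  roll <- make_rollover_pairs(apex_mon = 3000, decline = 1)
  base <- detect_negative_correlation(
    smooth_experiment(roll$reference, roll$monitor))
  for (s in c(0.01, 1, 250)) {
    det <- detect_negative_correlation(
      smooth_experiment(roll$reference * s, roll$monitor * s))
    expect_true(det$flag)
    expect_equal(det$limit / s, base$limit, tolerance = 1e-6)
  }
})

test_that("cutoff pooling applies the p10 rule and the flagged-share gate", {
  expect_equal(pool_cutoff(rep(1000, 10), rep(TRUE, 10))$cutoff, 1000)

  # per-unit limits reported for a saturating optical sensor, p10 pooled;
  # brute-force type-7 oracle: sorted x, h = (n-1) p + 1
  lims <- c(2263, 2772, 3354, 3562)
  xs <- sort(lims); h <- (length(xs) - 1) * 0.10 + 1
  oracle <- xs[floor(h)] + (h - floor(h)) * (xs[floor(h) + 1] - xs[floor(h)])
  rep4 <- pool_cutoff(lims, rep(TRUE, 4))
  expect_equal(rep4$cutoff, oracle)
  expect_gte(rep4$cutoff, min(lims))
  expect_lte(rep4$cutoff, max(lims))

  # 1 of 20 flagged (5% < 10%): no cutoff
  none <- pool_cutoff(runif(20, 2000, 5000), c(TRUE, rep(FALSE, 19)))
  expect_true(is.na(none$cutoff))
  # exactly at the gate: cutoff present
  atgate <- pool_cutoff(rep(1000, 10), c(TRUE, rep(FALSE, 9)))
  expect_false(is.na(atgate$cutoff))
})

test_that("truncation equals the brute-force filter and reports removals", {
  set.seed(5)
  d <- data.frame(monitor = runif(100, 0, 2000), reference = runif(100))
  cutoff <- sort(d$monitor)[70]
  tr <- truncate_series(d, cutoff)
  expect_equal(tr$removed_count, 30)
  expect_identical(tr$data, d[d$monitor <= cutoff, ])  # filter oracle
  expect_equal(truncate_series(d, Inf)$removed_count, 0)
  expect_identical(truncate_series(d, NA)$data, d)
  expect_warning(empty <- truncate_series(d, -1), "all readings")
  expect_equal(nrow(empty$data), 0)
})

test_that("pooled cutoff recovers a known rollover limit on synthetic units", {
  mats <- fixture_materials()
  spec <- sensor_response_spec(noise_cv = 0.15, rollover_limit = 2500)
  hits <- vapply(1:8, function(s) {
    pairs <- lapply(1:8, function(i) {
      ex <- simulate_experiment(profile_transient(),
                                condition_set("ARD"), spec, mats$ARD,
                                seed = s * 100 + i)
      data.frame(reference = ex$reference, monitor = ex$monitor[, 1])
    })
    screen_unit(pairs, "u")$cutoff
  }, 0)
  expect_true(all(abs(hits - 2500) / 2500 < 0.10))

  # a monitor without rollover is never assigned a cutoff
  spec0 <- sensor_response_spec(noise_cv = 0.15)
  pairs0 <- lapply(1:8, function(i) {
    ex <- simulate_experiment(profile_transient(),
                              condition_set("ARD"), spec0, mats$ARD,
                              seed = 7000 + i)
    data.frame(reference = ex$reference, monitor = ex$monitor[, 1])
  })
  expect_true(is.na(screen_unit(pairs0, "u")$cutoff))
})

test_that("normalization selection identifies the generative transform", {
  # selection is itself stochastic (cross-validated scoring); assert the
  # generative transform wins in a clear majority of replicate samples
  ln_wins <- vapply(1:6, function(s) {
    set.seed(s)
    select_normalization(10^rnorm(3000, 2, 0.4))$name == "log10"
  }, NA)
  expect_gte(sum(ln_wins), 5)
  id_wins <- vapply(1:6, function(s) {
    set.seed(100 + s)
    select_normalization(rnorm(3000, 12, 4))$name == "identity"
  }, NA)
  expect_gte(sum(id_wins), 5)
  expect_error(select_normalization(rep(5, 100)), "constant")
  expect_error(select_normalization(rnorm(10)), "n >= 30")

  # non-positive data under log10: offset of half the smallest positive value
  set.seed(13)
  vals <- c(0, 10^rnorm(499, 1, 0.3))
  ch <- select_normalization(vals, candidates = "log10")
  expect_equal(ch$parameters$offset, min(vals[vals > 0]) / 2)
})

test_that("parametric transforms invert cleanly", {
  x <- c(3, 50, 720)
  for (nm in c("identity", "log10", "sqrt")) {
    expect_equal(invert_transform(nm, apply_transform(nm, x)), x,
                 tolerance = 1e-10)
  }
  ch <- structure(list(name = "box-cox", parameters = list(lambda = 0.3)),
                  class = "transform_choice")
  expect_equal(invert_transform(ch, apply_transform(ch, x)), x,
               tolerance = 1e-10)
  chy <- structure(list(name = "yeo-johnson",
                        parameters = list(lambda = 0.5)),
                   class = "transform_choice")
  xx <- c(-4, -0.5, 0, 2, 30)
  expect_equal(invert_transform(chy, apply_transform(chy, xx)), xx,
               tolerance = 1e-10)
})
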