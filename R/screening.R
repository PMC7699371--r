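# Screening: rollover ("half-circle") detection via local regression,
# pooled p10 concentration cutoffs, truncation, and selection of the
# normalization transform.

#' Local-regression fit of monitor versus reference
#'
#' Fits a loess curve of the monitor reading on the reference concentration
#' for one experiment and evaluates it on a regular grid of reference
#' values. Saturating optical sensors produce a curve that rises, peaks and
#' falls back ("half-circle"); this smooth is the input to
#' [detect_negative_correlation()].
#'
#' @param reference Reference concentrations (ug/m^3).
#' @param monitor Paired monitor readings (monitor-output ug/m^3).
#' @param span Loess span in (0, 1] (default 0.3).
#' @param degree Local polynomial degree (default 2; a locally quadratic
#'   fit tracks the curve's turning point, where a broad linear window
#'   flattens the apex and biases the concentration limit low).
#' @param n_grid Number of grid points (default 200).
#' @return An object of class `experiment_smooth`: list with `grid`
#'   (reference values), `fitted` (monitor values), `max_monitor` (largest
#'   observed monitor reading), `n`.
#' @export
smooth_experiment <- function(reference, monitor, span = 0.3, degree = 2,
                              n_grid = 200) {
  ok <- complete.cases(reference, monitor)
  reference <- reference[ok]; monitor <- monitor[ok]
  if (length(reference) < 20L) {
    warning("fewer than 20 paired points; experiment skipped")
    return(NULL)
  }
  check_number(span, "span", lower = 1e-6, upper = 1)
  fit <- loess(monitor ~ reference, span = span, degree = degree,
               family = "gaussian",
               control = stats::loess.control(surface = "direct"))
  grid <- seq(min(reference), max(reference), length.out = n_grid)
  structure(list(grid = grid, fitted = predict(fit, grid),
                 max_monitor = max(monitor), n = length(reference)),
            class = "experiment_smooth")
}

#' Detect a negative monitor-reference correlation (rollover)
#'
#' Flags an experiment when the smoothed monitor response declines by more
#' than `decline_tol` (a fraction of the apex value) after its maximum
#' while the reference keeps increasing — i.e. one reference value maps to
#' two monitor values. The per-experiment concentration limit is the apex
#' fitted monitor reading (the highest reading with no negative
#' correlation), expressed in monitor-output units; for unflagged
#' experiments it is the maximum observed monitor reading.
#'
#' @param smooth An [smooth_experiment()] result (or `NULL`, which yields
#'   an NA record).
#' @param decline_tol Post-apex decline tolerance as a fraction of the apex
#'   fitted value (default 0.05), separating true rollover from smoothing
#'   wiggle.
#' @param edge_frac Fraction of the grid adjacent to the upper reference
#'   boundary within which an apex is treated as a boundary artifact
#'   (default 0.15, half the default loess span): inside that final
#'   half-window the local fit is supported by few points and spurious
#'   dips are common, whereas a genuine half-circle turns over in the
#'   interior of the observed range.
#' @return List with `flag` (logical) and `limit` (ug/m^3, monitor-output
#'   units).
#' @export
detect_negative_correlation <- function(smooth, decline_tol = 0.05,
                                        edge_frac = 0.15) {
  if (is.null(smooth)) return(list(flag = NA, limit = NA_real_))
  stopifnot(inherits(smooth, "experiment_smooth"))
  f <- smooth$fitted
  apex <- which.max(f)
  decline <- if (apex < length(f)) (f[apex] - min(f[apex:length(f)])) else 0
  interior <- apex <= (1 - edge_frac) * length(f)
  flagged <- interior && f[apex] > 0 && decline > decline_tol * f[apex]
  list(flag = flagged,
       limit = if (flagged) f[apex] else smooth$max_monitor)
}

#' Pool per-experiment limits into a unit cutoff
#'
#' A unit receives a cutoff only when the share of its experiments flagged
#' for negative correlation reaches `flag_fraction` (default 0.10, so that
#' isolated outlier experiments do not impose a cutoff). The cutoff is then
#' the `percentile` quantile (default the 10th, type-7 interpolation) of
#' all pooled per-experiment limits — a conservative maximal reliable
#' concentration in monitor-output units.
#'
#' @param limits Per-experiment limits (monitor-output ug/m^3).
#' @param flags Per-experiment logical rollover flags, same length.
#' @param unit_id Unit label for the report.
#' @param flag_fraction Minimum flagged share for a cutoff (default 0.10).
#' @param percentile Quantile of pooled limits used as the cutoff
#'   (default 0.10).
#' @return An object of class `cutoff_report`: `unit_id`, `n_experiments`,
#'   `n_flagged`, `per_experiment_limits`, `cutoff` (ug/m^3 monitor-output
#'   units, or `NA` when below the flag fraction).
#' @examples
#' pool_cutoff(c(3562, 2772, 2263, 3354), rep(TRUE, 4), "opc1")
#' @export
pool_cutoff <- function(limits, flags, unit_id = "unit",
                        flag_fraction = 0.10, percentile = 0.10) {
  ok <- !is.na(limits) & !is.na(flags)
  limits <- limits[ok]; flags <- flags[ok]
  if (length(limits) == 0L) stopf("need at least one experiment")
  n_flagged <- sum(flags)
  cutoff <- if (n_flagged / length(limits) >= flag_fraction)
    unname(quantile(limits, percentile, type = 7)) else NA_real_
  structure(list(unit_id = unit_id, n_experiments = length(limits),
                 n_flagged = n_flagged, per_experiment_limits = limits,
                 cutoff = cutoff, flag_fraction = flag_fraction,
                 percentile = percentile),
            class = "cutoff_report")
}

#' @export
print.cutoff_report <- function(x, ...) {
  cat(sprintf("<cutoff_report> unit %s: %d/%d experiments flagged; %s\n",
              x$unit_id, x$n_flagged, x$n_experiments,
              if (is.na(x$cutoff)) "no cutoff"
              else sprintf("cutoff %.0f ug/m3 (monitor output, p%g)",
                           x$cutoff, 100 * x$percentile)))
  invisible(x)
}

#' Screen one unit across its experiments
#'
#' Convenience wrapper: smooths each experiment, detects negative
#' correlations and pools the limits into a [pool_cutoff()] report.
#'
#' The reference column of each experiment is smoothed over time with a
#' short running mean (`ref_smooth` samples, ~2-3 min at a 15 s cadence)
#' before the monitor-reference curve is fitted: chamber concentration
#' evolves on minute scales while per-sample reference noise is instrument
#' noise, and leaving it in attenuates the apex of the fitted curve
#' (errors-in-x regression dilution).
#'
#' @param experiment_pairs List of data.frames/lists with elements
#'   `reference` and `monitor` in time order (one per experiment for this
#'   unit).
#' @param unit_id Unit label.
#' @param span,decline_tol,flag_fraction,percentile Passed through.
#' @param ref_smooth Running-mean window (samples) applied to the
#'   reference before smoothing; 0 or 1 disables.
#' @return A `cutoff_report`.
#' @export
screen_unit <- function(experiment_pairs, unit_id = "unit", span = 0.3,
                        decline_tol = 0.05, flag_fraction = 0.10,
                        percentile = 0.10, ref_smooth = 11) {
  res <- lapply(experiment_pairs, function(p) {
    ref <- if (ref_smooth > 1L && length(p$reference) > ref_smooth)
      running_mean(p$reference, ref_smooth) else p$reference
    detect_negative_correlation(
      smooth_experiment(ref, p$monitor, span = span),
      decline_tol = decline_tol)
  })
  pool_cutoff(vapply(res, `[[`, 0, "limit"),
              vapply(res, function(r) isTRUE(r$flag), NA),
              unit_id = unit_id, flag_fraction = flag_fraction,
              percentile = percentile)
}

#' Truncate monitor readings above a cutoff
#'
#' Removes rows whose monitor reading exceeds the cutoff (monitor-output
#' units). An `NA` cutoff is the identity.
#'
#' @param data Data.frame with a `monitor` column.
#' @param cutoff Cutoff in monitor-output ug/m^3, or `NA`/`NULL`.
#' @return List with `data` (retained rows) and `removed_count`.
#' @export
truncate_series <- function(data, cutoff) {
  stopifnot(is.data.frame(data), "monitor" %in% names(data))
  if (is.null(cutoff) || is.na(cutoff))
    return(list(data = data, removed_count = 0L))
  keep <- data$monitor <= cutoff
  if (!any(keep)) warning("all readings above cutoff; empty series")
  list(data = data[keep, , drop = FALSE],
       removed_count = sum(!keep))
}

# ---- normalization transform selection --------------------------------

# Candidate transforms are scored by the Pearson chi-square normality
# statistic divided by its degrees of freedom (lower = more normal), the
# same figure of merit popularised by normalization-selection tools. The
# statistic is evaluated out-of-fold (repeated k-fold cross-validation with
# a fixed internal substream) so that the rank-based ordered-quantile map,
# which is perfectly normal in-sample by construction, is judged on held
# out data like every parametric candidate. Ties break by candidate order
# (identity first, log10 second).

transform_candidates <- c("identity", "log10", "sqrt", "box-cox",
                          "yeo-johnson", "ordered-quantile")

orq_map <- function(x) {
  xs <- sort(x)
  list(x_sorted = xs,
       z = qnorm((seq_along(xs) - 0.5) / length(xs)))
}

apply_transform_raw <- function(x, name, params) {
  off <- params$offset %||% 0
  switch(name,
    "identity" = x,
    "log10" = log10(x + off),
    "sqrt" = sqrt(x + off),
    "box-cox" = {
      lam <- params$lambda
      if (abs(lam) < 1e-8) log(x + off) else ((x + off)^lam - 1) / lam
    },
    "yeo-johnson" = car::yjPower(x, params$lambda),
    "ordered-quantile" = {
      if (is.null(params$x_sorted)) params <- orq_map(x)
      approx(params$x_sorted, params$z, xout = x, rule = 2)$y
    },
    stopf("unknown transform '%s'", name))
}

fit_transform_params <- function(x, name) {
  params <- list()
  needs_pos <- name %in% c("log10", "box-cox")
  if (needs_pos && min(x) <= 0) {
    pos <- x[x > 0]
    if (length(pos) == 0L) stopf("no positive values for '%s'", name)
    params$offset <- min(pos) / 2
  }
  if (name == "sqrt" && min(x) < 0) params$offset <- -min(x)
  if (name == "box-cox") {
    off <- params$offset %||% 0
    bc <- MASS::boxcox(y ~ 1, data = data.frame(y = x + off),
                       lambda = seq(-2, 2, 0.05), plotit = FALSE)
    params$lambda <- bc$x[which.max(bc$y)]
  }
  if (name == "yeo-johnson") {
    pt <- tryCatch(car::powerTransform(x, family = "yjPower"),
                   error = function(e) NULL)
    params$lambda <- if (is.null(pt)) 1 else unname(pt$lambda)
  }
  if (name == "ordered-quantile") params <- c(params, orq_map(x))
  params
}

normality_score <- function(z, n_fitted_params = 0) {
  z <- z[is.finite(z)]
  if (length(z) < 20L || sd(z) == 0) return(Inf)
  pt <- nortest::pearson.test((z - mean(z)) / sd(z))
  df <- max(1, pt$df - n_fitted_params)
  unname(pt$statistic / df)
}

# Degrees of freedom a candidate spends on shape parameters estimated from
# the data (the lambda of Box-Cox / Yeo-Johnson); charged against the
# score's denominator so a data-fitted lambda cannot edge out a fixed
# transform it merely imitates. The ordered-quantile map is instead
# penalised through its out-of-fold evaluation.
transform_n_params <- function(name) {
  if (name %in% c("box-cox", "yeo-johnson")) 1 else 0
}

# Mean out-of-fold Pearson score. Parametric transforms keep their
# full-sample parameters (low-dimensional, negligible overfit); the
# ordered-quantile map is refitted on each training fold and applied to the
# held-out fold by interpolation.
score_transform_cv <- function(x, name, params, folds, reps = 2) {
  np <- transform_n_params(name)
  if (folds < 2L)
    return(normality_score(apply_transform_raw(x, name, params), np))
  with_substream(8675309L, {
    total <- 0; cnt <- 0L
    for (r in seq_len(reps)) {
      idx <- sample(rep(seq_len(folds), length.out = length(x)))
      for (k in seq_len(folds)) {
        p <- if (name == "ordered-quantile") orq_map(x[idx != k]) else params
        sc <- suppressWarnings(
          normality_score(apply_transform_raw(x[idx == k], name, p), np))
        if (is.finite(sc)) { total <- total + sc; cnt <- cnt + 1L }
      }
    }
    if (cnt == 0L) Inf else total / cnt
  })
}

#' Select the normalization transform
#'
#' Applies each candidate transform (identity, log10, square root, Box-Cox,
#' Yeo-Johnson, ordered-quantile normal scores) to the data and scores the
#' result with the Pearson chi-square normality statistic divided by its
#' degrees of freedom; the lowest score wins, ties broken by candidate
#' order. Non-positive values under log10/Box-Cox are handled by an offset
#' of half the smallest positive value, recorded in the parameters.
#'
#' @param values Concentrations to normalize (n >= 30, non-constant).
#' @param candidates Character vector of candidate names (default all six).
#' @param folds Cross-validation folds for scoring (default up to 10,
#'   reduced so each held-out fold keeps at least 30 values).
#' @return An object of class `transform_choice`: `name`, `parameters`,
#'   `normality_score`, and the per-candidate `scores`.
#' @examples
#' set.seed(1)
#' select_normalization(10^rnorm(2000, 2, 0.4))$name   # "log10"
#' @export
select_normalization <- function(values, candidates = transform_candidates,
                                 folds = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 30L) stopf("need n >= 30 values, got %d",
                                  length(values))
  if (sd(values) == 0) stopf("values are constant; nothing to normalize")
  candidates <- match.arg(candidates, transform_candidates,
                          several.ok = TRUE)
  folds <- folds %||% min(10L, floor(length(values) / 30L))
  scores <- numeric(length(candidates))
  params <- vector("list", length(candidates))
  for (i in seq_along(candidates)) {
    nm <- candidates[i]
    params[[i]] <- tryCatch(fit_transform_params(values, nm),
                            error = function(e) NULL)
    scores[i] <- if (is.null(params[[i]])) Inf else
      tryCatch(score_transform_cv(values, nm, params[[i]], folds),
               error = function(e) Inf)
  }
  best <- which.min(scores)  # which.min takes the first minimum: tie rule
  structure(list(name = candidates[best], parameters = params[[best]],
                 normality_score = scores[best],
                 scores = setNames(scores, candidates)),
            class = "transform_choice")
}

#' @export
print.transform_choice <- function(x, ...) {
  cat(sprintf("<transform_choice> %s (normality score %.3f)\n",
              x$name, x$normality_score))
  invisible(x)
}

#' Apply / invert a chosen transform
#'
#' `apply_transform()` maps concentrations to the normalized scale;
#' `invert_transform()` maps model predictions back to ug/m^3. The
#' ordered-quantile transform is rank-based and not analytically
#' invertible; only the monotone parametric transforms support inversion.
#'
#' @param choice A `transform_choice` (or a transform name).
#' @param x Values to (back-)transform.
#' @return Transformed values.
#' @export
apply_transform <- function(choice, x) {
  if (is.character(choice))
    choice <- structure(list(name = choice, parameters = list()),
                        class = "transform_choice")
  apply_transform_raw(x, choice$name, choice$parameters)
}

#' @rdname apply_transform
#' @export
invert_transform <- function(choice, x) {
  if (is.character(choice))
    choice <- structure(list(name = choice, parameters = list()),
                        class = "transform_choice")
  off <- choice$parameters$offset %||% 0
  switch(choice$name,
    "identity" = x,
    "log10" = 10^x - off,
    "sqrt" = x^2 - off,
    "box-cox" = {
      lam <- choice$parameters$lambda
      if (abs(lam) < 1e-8) exp(x) - off else (lam * x + 1)^(1 / lam) - off
    },
    "yeo-johnson" = {
      lam <- choice$parameters$lambda
      pos <- x >= 0
      out <- numeric(length(x))
      out[pos] <- if (abs(lam) < 1e-8) expm1(x[pos])
                  else (lam * x[pos] + 1)^(1 / lam) - 1
      out[!pos] <- if (abs(lam - 2) < 1e-8) -expm1(-x[!pos])
                   else 1 - ((2 - lam) * (-x[!pos]) + 1)^(1 / (2 - lam))
      out
    },
    stopf("transform '%s' is not invertible", choice$name))
}
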