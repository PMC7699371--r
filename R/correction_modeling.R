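# Mixed-effects correction models and the three-criterion variable test.
#
# The correction model regresses the transformed reference concentration on
# the transformed monitor reading. Evaluation variables enter as slope
# modifiers of the monitor reading: fixed slopes for drift, temperature,
# humidity, exposure pattern and power supply; random slopes (no random
# intercept) for device unit and aerosol material. All models are fitted by
# maximum likelihood (not REML) so likelihood-ratio and AIC comparisons
# across fixed-effect structures are valid.

# Registry of evaluation-variable terms. `expr` is the formula fragment;
# fixed terms contribute one fixed-effect parameter, random terms one
# variance component.
variable_terms <- list(
  drift       = list(type = "fixed",  expr = "x:session_time"),
  temperature = list(type = "fixed",  expr = "x:temp_c"),
  humidity    = list(type = "fixed",  expr = "x:rh_c"),
  pattern     = list(type = "fixed",  expr = "x:pattern_transient"),
  power       = list(type = "fixed",  expr = "x:power_battery"),
  unit        = list(type = "random", expr = "(0 + x | unit_id)"),
  material    = list(type = "random", expr = "(0 + x | material)")
)

#' Evaluation variables in testing priority order
#'
#' Between-device variation is tested first, then within-device drift, then
#' material, then the remaining variables; variables found relevant early
#' are carried as structural terms in later tests.
#'
#' @return Character vector of variable names.
#' @export
variable_priority <- function() {
  c("unit", "drift", "material", "temperature", "humidity",
    "pattern", "power")
}

#' Model specification for a correction model
#'
#' @param fixed_slope_terms Subset of
#'   `c("drift","temperature","humidity","pattern","power")`.
#' @param random_slope_terms Subset of `c("unit","material")`.
#' @param transform A `transform_choice` or transform name (default
#'   `"log10"`, the transform selected for these data).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(fixed_slope_terms = character(),
                       random_slope_terms = character(),
                       transform = "log10") {
  all_terms <- c(fixed_slope_terms, random_slope_terms)
  if (anyDuplicated(all_terms)) stopf("duplicate model terms")
  bad <- setdiff(all_terms, names(variable_terms))
  if (length(bad)) stopf("unknown term(s): %s", paste(bad, collapse = ", "))
  for (tm in fixed_slope_terms)
    if (variable_terms[[tm]]$type != "fixed")
      stopf("'%s' is a random-slope term", tm)
  for (tm in random_slope_terms)
    if (variable_terms[[tm]]$type != "random")
      stopf("'%s' is a fixed-slope term", tm)
  structure(list(fixed_slope_terms = fixed_slope_terms,
                 random_slope_terms = random_slope_terms,
                 transform = transform),
            class = "model_spec")
}

# Prepare the modelling frame: transformed response/predictor, centred
# covariates and indicator codings. Rows non-positive under a log-type
# transform are dropped (with a count kept as an attribute).
prepare_model_frame <- function(data, transform = "log10") {
  need <- c("reference", "monitor", "material", "temperature",
            "relative_humidity", "power", "pattern", "session_time",
            "unit_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) stopf("data lacks column(s): %s",
                          paste(miss, collapse = ", "))
  tname <- if (is.character(transform)) transform else transform$name
  keep <- is.finite(data$reference) & is.finite(data$monitor)
  if (tname %in% c("log10", "box-cox"))
    keep <- keep & data$reference > 0 & data$monitor > 0
  dropped <- sum(!keep)
  d <- data[keep, , drop = FALSE]
  if (nrow(d) < 10L) stopf("too few usable rows (%d)", nrow(d))
  frame <- data.frame(
    y = apply_transform(transform, d$reference),
    x = apply_transform(transform, d$monitor),
    temp_c = d$temperature - 20,
    rh_c = d$relative_humidity - 50,
    pattern_transient = as.numeric(d$pattern == "transient"),
    power_battery = as.numeric(d$power == "battery"),
    session_time = d$session_time,
    unit_id = factor(d$unit_id),
    material = factor(d$material),
    reference_raw = d$reference,
    monitor_raw = d$monitor)
  attr(frame, "dropped") <- dropped
  frame
}

model_formula <- function(spec) {
  fixed <- vapply(spec$fixed_slope_terms,
                  function(tm) variable_terms[[tm]]$expr, "")
  random <- vapply(spec$random_slope_terms,
                   function(tm) variable_terms[[tm]]$expr, "")
  as.formula(paste("y ~ x",
                   paste(c("", fixed, random), collapse = " + ")),
             env = globalenv())
}

#' Fit a correction model
#'
#' Fits the (mixed) linear model given by `spec` to one monitor's truncated,
#' transformed experiment table. With random-slope terms the model is fitted
#' with `lme4::lmer` by maximum likelihood; with none it falls back to
#' ordinary least squares (`lm`), whose estimates coincide with the ML fit.
#' A singular random-effect fit (a variance component estimated at zero) is
#' refitted without the offending term and the removal recorded in
#' `fit_log`.
#'
#' @param data Long experiment table (see [as.data.frame.experiment_series()])
#'   with columns `reference`, `monitor` and the condition variables;
#'   monitor readings should already be truncated at the unit cutoff.
#' @param spec A [model_spec()].
#' @return An object of class `correction_model`: `spec`, `fit`, `formula`,
#'   `log_lik`, `aic`, `n_params`, `coefficients`, `variance_components`,
#'   `sigma`, `mae` (back-transformed scale), `fit_log`, `n`.
#' @examples
#' \donttest{
#' prof <- profile_transient()
#' ex <- simulate_experiment(prof, condition_set("ARD"),
#'                           sensor_response_spec(noise_cv = 0.1),
#'                           material_properties("ARD", 2.6), seed = 7)
#' m <- fit_model(as.data.frame(ex), model_spec())
#' }
#' @export
fit_model <- function(data, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  frame <- if (!is.null(attr(data, "prepared"))) data
           else prepare_model_frame(data, spec$transform)
  attr(frame, "prepared") <- TRUE
  fit_log <- character(0)
  random_terms <- spec$random_slope_terms

  repeat {
    spec_now <- model_spec(spec$fixed_slope_terms, random_terms,
                           spec$transform)
    form <- model_formula(spec_now)
    if (length(random_terms) == 0L) {
      fit <- lm(form, data = frame)
      break
    }
    fit <- lme4::lmer(form, data = frame, REML = FALSE,
                      control = lme4::lmerControl(
                        check.conv.singular = "ignore",
                        calc.derivs = FALSE))
    if (!lme4::isSingular(fit, tol = 1e-5)) break
    vc <- as.data.frame(lme4::VarCorr(fit))
    vc <- vc[is.na(vc$var2) & vc$grp != "Residual", , drop = FALSE]
    zero_grp <- vc$grp[which.min(vc$sdcor)]
    drop_term <- random_terms[vapply(random_terms, function(tm)
      grepl(if (tm == "unit") "unit_id" else tm, zero_grp), NA)]
    if (length(drop_term) == 0L) break
    fit_log <- c(fit_log, sprintf(
      "singular fit: random slope '%s' (variance ~ 0) removed",
      drop_term[1L]))
    random_terms <- setdiff(random_terms, drop_term[1L])
  }

  ll <- logLik(fit)
  is_mixed <- inherits(fit, "merMod")
  vc_out <- if (is_mixed) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    setNames(vc$vcov[vc$grp != "Residual" & is.na(vc$var2)],
             vc$grp[vc$grp != "Residual" & is.na(vc$var2)])
  } else numeric(0)
  preds_t <- fitted(fit)
  tr <- spec$transform
  mae <- mean(abs(invert_transform(tr, preds_t) - frame$reference_raw))

  structure(list(spec = model_spec(spec$fixed_slope_terms, random_terms,
                                   spec$transform),
                 requested_spec = spec, fit = fit, formula = form,
                 log_lik = as.numeric(ll),
                 n_params = attr(ll, "df"),
                 aic = AIC(fit),
                 coefficients = if (is_mixed) lme4::fixef(fit) else coef(fit),
                 variance_components = vc_out,
                 sigma = stats::sigma(fit),
                 mae = mae, fit_log = fit_log, n = nrow(frame),
                 frame = frame),
            class = "correction_model")
}

#' @export
print.correction_model <- function(x, ...) {
  cat(sprintf("<correction_model> %s | n = %d, AIC = %.1f, MAE = %.1f ug/m3\n",
              deparse(x$formula), x$n, x$aic, x$mae))
  if (length(x$fit_log)) cat("  ", paste(x$fit_log, collapse = "; "), "\n")
  invisible(x)
}

#' Test one evaluation variable by the three-criterion rule
#'
#' Fits the correction model with and without the tested variable on a data
#' subset in which all other (non-structural) variables sit at their
#' default levels, and assesses the variable by three criteria: (1) a
#' likelihood-ratio test between the nested maximum-likelihood fits must
#' give p < 0.05 (for a random slope the p-value uses the 50:50 chi-square
#' boundary mixture); (2) the AIC must decrease; (3) the mean absolute
#' error on the back-transformed (ug/m^3) scale must decrease. The variable
#' passes only if all three hold. `mae_fold` (MAE without / MAE with)
#' quantifies the accuracy gain from correcting the variable.
#'
#' @param data Data subset for the test (other variables at defaults,
#'   structural terms varied as carried).
#' @param variable One of `names(variable_terms)`: `"drift"`,
#'   `"temperature"`, `"humidity"`, `"pattern"`, `"power"`, `"unit"`,
#'   `"material"`.
#' @param baseline_terms Character vector of structural terms already
#'   confirmed and carried in both fits.
#' @param transform Transform for both axes (default `"log10"`).
#' @param alpha Significance level for criterion 1 (default 0.05).
#' @return An object of class `variable_test_result` (also a one-row
#'   data.frame via `as.data.frame`): `variable`, `anova_p`, `delta_aic`,
#'   `mae_without`, `mae_with`, `mae_fold`, `passed`, `boundary_test`.
#' @export
test_variable <- function(data, variable, baseline_terms = character(),
                          transform = "log10", alpha = 0.05) {
  if (!variable %in% names(variable_terms))
    stopf("unknown variable '%s'", variable)
  if (variable %in% baseline_terms)
    stopf("'%s' is already a baseline term", variable)
  frame <- if (!is.null(attr(data, "prepared"))) data
           else prepare_model_frame(data, transform)
  attr(frame, "prepared") <- TRUE
  col <- switch(variable, drift = "session_time", temperature = "temp_c",
                humidity = "rh_c", pattern = "pattern_transient",
                power = "power_battery", unit = "unit_id",
                material = "material")
  if (length(unique(frame[[col]])) < 2L)
    stopf("variable '%s' is constant in this subset; cannot be tested",
          variable)

  type <- variable_terms[[variable]]$type
  base_fixed <- intersect(baseline_terms,
    names(Filter(function(t) t$type == "fixed", variable_terms)))
  base_random <- intersect(baseline_terms,
    names(Filter(function(t) t$type == "random", variable_terms)))
  # a carried random slope needs >= 2 grouping levels in this subset
  base_random <- base_random[vapply(base_random, function(tm) {
    g <- if (tm == "unit") "unit_id" else "material"
    length(unique(frame[[g]])) >= 2L
  }, NA)]
  spec0 <- model_spec(base_fixed, base_random, transform)
  spec1 <- if (type == "fixed")
    model_spec(c(base_fixed, variable), base_random, transform)
  else model_spec(base_fixed, c(base_random, variable), transform)

  m0 <- fit_model(frame, spec0)
  m1 <- fit_model(frame, spec1)

  lr <- max(0, 2 * (m1$log_lik - m0$log_lik))
  df <- m1$n_params - m0$n_params
  p <- if (type == "random") {
    # variance component tested on the boundary of its parameter space:
    # 50:50 mixture of a point mass at zero and chi-square(1)
    0.5 * pchisq(lr, df = 1, lower.tail = FALSE)
  } else {
    pchisq(lr, df = max(1L, df), lower.tail = FALSE)
  }
  delta_aic <- m1$aic - m0$aic
  res <- list(variable = variable, type = type, anova_p = p,
              delta_aic = delta_aic, mae_without = m0$mae, mae_with = m1$mae,
              mae_fold = m0$mae / m1$mae,
              passed = (p < alpha) && (delta_aic < 0) && (m1$mae < m0$mae),
              boundary_test = (type == "random"),
              model_without = m0, model_with = m1)
  class(res) <- "variable_test_result"
  res
}

#' @export
print.variable_test_result <- function(x, ...) {
  cat(sprintf(
    "<variable_test_result> %s (%s): p = %.3g, dAIC = %.1f, MAE %.1f -> %.1f (%.2f-fold) => %s\n",
    x$variable, x$type, x$anova_p, x$delta_aic, x$mae_without, x$mae_with,
    x$mae_fold, if (x$passed) "included" else "excluded"))
  invisible(x)
}

#' @export
as.data.frame.variable_test_result <- function(x, ...) {
  data.frame(variable = x$variable, type = x$type, anova_p = x$anova_p,
             delta_aic = x$delta_aic, mae_without = x$mae_without,
             mae_with = x$mae_with, mae_fold = x$mae_fold,
             passed = x$passed)
}

#' Run the prioritized variable-selection procedure
#'
#' Tests the seven evaluation variables in priority order
#' ([variable_priority()]) on per-variable screening subsets, carrying each
#' structural variable (unit, drift, material) forward into later tests
#' once it passes.
#'
#' @param data Full screening experiment table with a `varied` column
#'   naming the design variable each experiment's arm exercises
#'   (`"default"` for the shared default arm; design labels `unit_id`,
#'   `session_time` and `relative_humidity` map to the model terms `unit`,
#'   `drift` and `humidity`).
#' @param transform Transform for both axes.
#' @param alpha Significance level.
#' @return List with `results` (data.frame over variables) and
#'   `passed_variables`.
#' @export
select_variables <- function(data, transform = "log10", alpha = 0.05) {
  stopifnot("varied" %in% names(data))
  design_label <- c(unit = "unit_id", drift = "session_time",
                    material = "material", temperature = "temperature",
                    humidity = "relative_humidity", pattern = "pattern",
                    power = "power")
  carried <- character(0)
  structural <- c("unit", "drift", "material")
  rows <- list()
  for (v in variable_priority()) {
    # the test subset: this variable's arms, the shared default arm, and
    # the arms of structural variables already carried (their term needs
    # level variation to stay estimable)
    labels <- c(design_label[[v]], "default", design_label[carried])
    subset <- data[data$varied %in% labels, , drop = FALSE]
    res <- tryCatch(
      test_variable(subset, v, baseline_terms = setdiff(carried, v),
                    transform = transform, alpha = alpha),
      error = function(e) NULL)
    if (is.null(res)) next
    rows[[v]] <- as.data.frame(res)
    if (res$passed && v %in% structural) carried <- c(carried, v)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  passed <- results$variable[results$passed]
  list(results = results, passed_variables = passed)
}

#' Build the final correction model
#'
#' Fits a single model containing every variable that passed the
#' three-criterion test, on the union of all screening experiments.
#'
#' @param all_experiments Long table over all screening experiments.
#' @param passed_variables Character vector of passed variable names.
#' @param transform Transform for both axes.
#' @return A `correction_model`.
#' @export
build_final_model <- function(all_experiments, passed_variables = character(),
                              transform = "log10") {
  fixed <- intersect(passed_variables,
    names(Filter(function(t) t$type == "fixed", variable_terms)))
  random <- intersect(passed_variables,
    names(Filter(function(t) t$type == "random", variable_terms)))
  fit_model(all_experiments, model_spec(fixed, random, transform))
}

#' Simulate data directly from a slope-coded correction model
#'
#' Generates a long experiment table whose transformed reference follows
#' the correction model exactly: `y = b0 + (b1 + u_m) x + b_T x (T - 20) +
#' b_P x 1{transient} + e`, with `x` the log10 monitor reading drawn
#' uniformly over a concentration range, per-material slope deviations
#' `u_m` as given, and normal residuals. Used to validate the fitting
#' machinery (parameter recovery, operating characteristics) against known
#' coefficients, which the chamber generator — whose gains act on the log
#' scale as intercept shifts — cannot provide exactly.
#'
#' @param n_per_cell Rows per design cell.
#' @param material_slopes Named numeric of per-material slope deviations
#'   (the random-slope effects); names become material levels.
#' @param temp_levels Temperatures of the design cells.
#' @param temp_slope Fixed slope modifier per degree C.
#' @param pattern_slope Fixed slope modifier for transient exposure.
#' @param intercept,base_slope Base regression coefficients.
#' @param sigma Residual SD on the log10 scale.
#' @param conc_range Monitor concentration range in ug/m^3.
#' @param seed Seed.
#' @return Long data.frame consumable by [fit_model()]; true coefficients
#'   attached as attribute `truth`.
#' @export
simulate_model_data <- function(n_per_cell = 500,
                                material_slopes = c(ARD = 0.05, SiO2 = 0,
                                                    Al2O3 = -0.05),
                                temp_levels = c(15, 20, 25),
                                temp_slope = 0.004, pattern_slope = 0.03,
                                intercept = 0.02, base_slope = 1,
                                sigma = 0.05, conc_range = c(50, 5000),
                                seed = 1) {
  cells <- expand.grid(material = names(material_slopes),
                       temperature = temp_levels,
                       pattern = c("transient", "stable"),
                       stringsAsFactors = FALSE)
  with_substream(substream_seed(seed, "model_data"), {
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      cl <- cells[i, ]
      x <- runif(n_per_cell, log10(conc_range[1]), log10(conc_range[2]))
      slope <- base_slope + material_slopes[[cl$material]] +
        temp_slope * (cl$temperature - 20) +
        pattern_slope * (cl$pattern == "transient")
      y <- intercept + slope * x + rnorm(n_per_cell, 0, sigma)
      data.frame(reference = 10^y, monitor = 10^x,
                 material = cl$material, temperature = cl$temperature,
                 relative_humidity = 50, power = "battery",
                 pattern = cl$pattern, session_time = 0,
                 unit_id = "unit1", stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    attr(out, "truth") <- list(intercept = intercept,
                               base_slope = base_slope,
                               material_slopes = material_slopes,
                               temp_slope = temp_slope,
                               pattern_slope = pattern_slope, sigma = sigma)
    out
  })
}

#' Predict reference concentration from monitor readings
#'
#' Applies a fitted correction model to new monitor readings under given
#' conditions and back-transforms to ug/m^3. Condition levels unseen by a
#' random-effect term get the population-level (zero random effect)
#' prediction, flagged in the result.
#'
#' @param model A `correction_model`.
#' @param monitor_reading Monitor readings (monitor-output ug/m^3).
#' @param conditions Data.frame (recycled length 1 or matching length) with
#'   the condition columns used by the model terms: `material`,
#'   `temperature`, `relative_humidity`, `power`, `pattern`,
#'   `session_time`, `unit_id`.
#' @param cutoff Optional unit cutoff; readings above it raise an error
#'   directing the caller back to screening.
#' @param bias_correct Apply the log-normal half-variance back-transform
#'   correction (default `FALSE`, mirroring a naive back-transform).
#' @return Numeric predictions in ug/m^3 with attribute `new_levels`
#'   (character vector of unseen random-effect levels, possibly empty).
#' @export
predict_concentration <- function(model, monitor_reading, conditions,
                                  cutoff = NULL, bias_correct = FALSE) {
  stopifnot(inherits(model, "correction_model"))
  if (!is.null(cutoff) && !is.na(cutoff) && any(monitor_reading > cutoff))
    stopf(paste("readings above the unit cutoff (%g); truncate via the",
                "screening stage first"), cutoff)
  n <- length(monitor_reading)
  cond <- as.data.frame(conditions, stringsAsFactors = FALSE)
  if (nrow(cond) == 1L && n > 1L) cond <- cond[rep(1L, n), , drop = FALSE]
  defaults <- list(material = "ARD", temperature = 20,
                   relative_humidity = 50, power = "battery",
                   pattern = "transient", session_time = 0,
                   unit_id = "unit1")
  for (nm in names(defaults))
    if (is.null(cond[[nm]])) cond[[nm]] <- defaults[[nm]]

  tr <- model$spec$transform
  nd <- data.frame(x = apply_transform(tr, monitor_reading),
                   temp_c = cond$temperature - 20,
                   rh_c = cond$relative_humidity - 50,
                   pattern_transient = as.numeric(cond$pattern == "transient"),
                   power_battery = as.numeric(cond$power == "battery"),
                   session_time = cond$session_time,
                   unit_id = cond$unit_id, material = cond$material)

  new_levels <- character(0)
  if (inherits(model$fit, "merMod")) {
    for (g in names(lme4::ranef(model$fit))) {
      seen <- rownames(lme4::ranef(model$fit)[[g]])
      unseen <- setdiff(unique(as.character(nd[[g]])), seen)
      if (length(unseen))
        new_levels <- c(new_levels, paste0(g, ":", unseen))
    }
    pred_t <- predict(model$fit, newdata = nd, allow.new.levels = TRUE)
  } else {
    pred_t <- predict(model$fit, newdata = nd)
  }
  out <- invert_transform(tr, pred_t)
  if (bias_correct) {
    tname <- if (is.character(tr)) tr else tr$name
    if (tname == "log10")
      out <- out * exp(0.5 * (model$sigma * log(10))^2)
  }
  attr(out, "new_levels") <- new_levels
  out
}
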