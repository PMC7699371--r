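# End-to-end pipeline: simulate -> screen -> fit -> verify, as a seeded,
# configured, logged run with plain CSV/JSON stage outputs.

#' Default run configuration
#'
#' A demo configuration mirroring the chamber study conditions: three
#' mineral dusts, temperatures 15/20/25 degrees C, humidities 25/50/75% RH,
#' battery/wired power, transient/stable exposure patterns, sessions at
#' 0/24/48 h, three device units; a monitor with material-dependent
#' response and a transient-pattern effect; a 3 x 3 x 3
#' material-temperature-humidity full-factorial verification design.
#' Series are generated at 15 s cadence. All simulated instruments share
#' that grid, so no block averaging is applied by default
#' (`averaging_s = 0`); set `averaging_s` (see [resample_average()]) when
#' aligning real instruments with different native cadences, and scale the
#' reference uncertainty passed to verification accordingly if reference
#' noise is independent between samples.
#'
#' @param seed Root seed.
#' @return Nested config list (serialisable to YAML).
#' @export
default_run_config <- function(seed = 1) {
  list(
    seed = seed,
    targets = list(concentration_min = 0, concentration_max = 5000,
                   target_uncertainty = 50, responsiveness_s = 60),
    materials = list(
      ARD   = list(density = 2.6,  shape_factor = 1.5, monitor_gain = 1.0),
      SiO2  = list(density = 2.6,  shape_factor = 1.5, monitor_gain = 1.3),
      Al2O3 = list(density = 3.95, shape_factor = 1.5, monitor_gain = 0.7)),
    sensor = list(base_gain = 1, temp_slope = 0.002, rh_slope = 0.001,
                  power_shift = 0, pattern_shift = 0.15, device_sd = 0.05,
                  drift_slope = 0, noise_cv = 0.15, rollover_limit = NULL),
    design = list(
      screening = list(material = c("ARD", "SiO2", "Al2O3"),
                       temperature = c(20, 15, 25),
                       relative_humidity = c(50, 25, 75),
                       power = c("battery", "wired"),
                       pattern = c("transient", "stable"),
                       session_time = c(0, 24, 48),
                       unit_id = c("unit1", "unit2", "unit3")),
      verification = list(material = c("ARD", "SiO2", "Al2O3"),
                          temperature = c(15, 20, 25),
                          relative_humidity = c(25, 50, 75))),
    profile = list(plateau_duration = 300, peak_duration = 900,
                   n_peaks = 2, dt = 15),
    screening = list(span = 0.3, decline_tol = 0.05, flag_fraction = 0.10,
                     percentile = 0.10, ref_smooth = 11),
    averaging_s = 0,
    transform = "log10")
}

config_materials <- function(config) {
  mats <- list()
  for (nm in names(config$materials)) {
    m <- config$materials[[nm]]
    mats[[nm]] <- material_properties(nm, density = m$density,
                                      shape_factor = m$shape_factor %||% 1.5,
                                      monitor_gain = m$monitor_gain %||% 1)
  }
  mats
}

config_sensor <- function(config) {
  do.call(sensor_response_spec, config$sensor)
}

#' Average a series onto a regular time grid
#'
#' Block averages onto windows of `width` seconds, aligning instruments
#' with different native cadences before modelling.
#'
#' @param time Sample times in seconds.
#' @param values Matrix or vector of readings.
#' @param width Window width in seconds (default 60).
#' @return List with `time` (window mid-points) and `values`.
#' @export
resample_average <- function(time, values, width = 60) {
  v <- as.matrix(values)
  win <- floor(time / width)
  keep <- !duplicated(win)
  agg <- apply(v, 2, function(col) tapply(col, win, mean))
  agg <- matrix(agg, ncol = ncol(v), dimnames = list(NULL, colnames(v)))
  list(time = unique(win) * width + width / 2, values = agg)
}

experiment_to_modeling_rows <- function(ex, id, varied, averaging_s) {
  df <- as.data.frame(ex)
  if (!is.null(averaging_s) && averaging_s > 0) {
    parts <- split(df, df$unit_id)
    df <- do.call(rbind, lapply(parts, function(p) {
      rs <- resample_average(p$time, cbind(true = p$true,
                                           reference = p$reference,
                                           monitor = p$monitor), averaging_s)
      out <- p[seq_len(nrow(rs$values)), , drop = FALSE]
      out$time <- rs$time
      out$true <- rs$values[, "true"]
      out$reference <- rs$values[, "reference"]
      out$monitor <- rs$values[, "monitor"]
      out
    }))
  }
  df$experiment_id <- id
  df$varied <- varied
  rownames(df) <- NULL
  df
}

design_to_long <- function(experiments, design, averaging_s = 60) {
  do.call(rbind, lapply(seq_len(nrow(design)), function(i) {
    id <- design$experiment_id[i]
    experiment_to_modeling_rows(experiments[[id]], id,
                                design$varied[i] %||% NA_character_,
                                averaging_s)
  }))
}

#' First-crossing responsiveness of a monitor
#'
#' Time the series takes to span from the minimum of its range to
#' `span_fraction` (default 0.8) of its maximum along the first rising
#' edge, compared against a responsiveness target of about one minute.
#'
#' @param time Sample times in seconds.
#' @param values Monitor readings.
#' @param span_fraction Fraction of the range maximum (default 0.8).
#' @return List with `seconds` (NA when not evaluable) and `status`
#'   (`"ok"` or `"not_evaluable"`).
#' @export
check_responsiveness <- function(time, values, span_fraction = 0.8) {
  stopifnot(length(time) == length(values))
  rng <- range(values, finite = TRUE)
  thresh <- rng[1] + span_fraction * (rng[2] - rng[1])
  if (rng[2] <= rng[1])
    return(list(seconds = NA_real_, status = "not_evaluable"))
  i_min <- which(values <= rng[1] + 1e-12 * max(1, abs(rng[1])))[1L]
  after <- which(values >= thresh & seq_along(values) > i_min)
  if (length(after) == 0L || is.na(i_min))
    return(list(seconds = NA_real_, status = "not_evaluable"))
  list(seconds = time[after[1L]] - time[i_min], status = "ok")
}

#' Run the full evaluation pipeline
#'
#' Simulates the screening and verification designs, screens each unit for
#' rollover and truncates, runs the prioritized three-criterion variable
#' selection, builds the final and the reduced (average) correction model,
#' and verifies accuracy as bin-wise relative uncertainty with
#' fold-improvement ratios. All stage outputs are written as plain
#' CSV/JSON under `out_dir`, with MD5 content hashes in the summary, and
#' the run is deterministic given `config$seed`.
#'
#' @param config Config list ([default_run_config()]) or path to a YAML
#'   file with the same structure.
#' @param out_dir Output directory.
#' @return Invisibly, a list with `cutoffs`, `selection`, `final_model`,
#'   `base_model`, `uncertainty`, `comparison`, `summary_path`.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  seed <- config$seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- proc.time()[["elapsed"]]
  stage_msg <- function(fmt, ...) {
    message(sprintf("[pmevalkit %6.1fs] %s",
                    proc.time()[["elapsed"]] - t0, sprintf(fmt, ...)))
  }

  materials <- config_materials(config)
  sensor <- config_sensor(config)
  prof_args <- config$profile %||% list()

  # --- simulate -------------------------------------------------------
  stage_msg("simulate: screening + verification designs")
  scr_design <- build_design(config$design$screening, type = "screening")
  ver_design <- build_design(config$design$verification, type = "factorial")
  ver_design$experiment_id <- sprintf("ver%03d", seq_len(nrow(ver_design)))
  scr_exp <- simulate_design(scr_design, sensor, materials,
                             seed = substream_seed(seed, "screening"),
                             profile_args = prof_args)
  ver_exp <- simulate_design(ver_design, sensor, materials,
                             seed = substream_seed(seed, "verification"),
                             profile_args = prof_args)
  sim_dir <- file.path(out_dir, "simulate")
  write_experiments(scr_exp, scr_design, file.path(sim_dir, "screening"))
  write_experiments(ver_exp, ver_design, file.path(sim_dir, "verification"))

  avg <- config$averaging_s %||% 0
  scr_long <- design_to_long(scr_exp, scr_design, avg)
  ver_long <- design_to_long(ver_exp, ver_design, avg)

  # --- screen ---------------------------------------------------------
  stage_msg("screen: rollover detection and truncation")
  scr_cfg <- config$screening %||% list()
  units <- unique(scr_long$unit_id)
  cutoffs <- lapply(units, function(u) {
    rows <- scr_long[scr_long$unit_id == u, ]
    pairs <- split(rows[, c("reference", "monitor")], rows$experiment_id)
    suppressWarnings(screen_unit(pairs, unit_id = u,
                span = scr_cfg$span %||% 0.3,
                decline_tol = scr_cfg$decline_tol %||% 0.05,
                flag_fraction = scr_cfg$flag_fraction %||% 0.10,
                percentile = scr_cfg$percentile %||% 0.10,
                ref_smooth = scr_cfg$ref_smooth %||% 11))
  })
  names(cutoffs) <- units
  cutoff_tab <- data.frame(
    unit_id = units,
    n_experiments = vapply(cutoffs, `[[`, 0L, "n_experiments"),
    n_flagged = vapply(cutoffs, `[[`, 0L, "n_flagged"),
    cutoff = vapply(cutoffs, `[[`, 0, "cutoff"))
  screen_dir <- file.path(out_dir, "screen")
  dir.create(screen_dir, showWarnings = FALSE)
  write.csv(cutoff_tab, file.path(screen_dir, "cutoffs.csv"),
            row.names = FALSE)
  jsonlite::write_json(lapply(cutoffs, unclass),
                       file.path(screen_dir, "cutoff_report.json"),
                       auto_unbox = TRUE, digits = NA)

  truncate_by_unit <- function(long) {
    do.call(rbind, lapply(unique(long$unit_id), function(u) {
      truncate_series(long[long$unit_id == u, ],
                      cutoff_tab$cutoff[cutoff_tab$unit_id == u][1L] %||%
                        NA_real_)$data
    }))
  }
  scr_trunc <- truncate_by_unit(scr_long)
  ver_trunc <- truncate_by_unit(ver_long)
  write.csv(scr_trunc, file.path(screen_dir, "screening_truncated.csv"),
            row.names = FALSE)

  # --- fit ------------------------------------------------------------
  stage_msg("fit: three-criterion variable selection + final model")
  transform <- config$transform %||% "log10"
  sel <- select_variables(scr_trunc, transform = transform)
  final <- build_final_model(scr_trunc, sel$passed_variables, transform)
  base <- build_final_model(scr_trunc, character(0), transform)
  fit_dir <- file.path(out_dir, "fit")
  dir.create(fit_dir, showWarnings = FALSE)
  write.csv(sel$results, file.path(fit_dir, "variable_selection.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(formula = deparse(final$formula),
         coefficients = as.list(final$coefficients),
         variance_components = as.list(final$variance_components),
         sigma = final$sigma, aic = final$aic, n = final$n,
         fit_log = final$fit_log,
         passed_variables = sel$passed_variables),
    file.path(fit_dir, "final_model.json"), auto_unbox = TRUE, digits = NA)

  # --- verify ---------------------------------------------------------
  stage_msg("verify: bin-wise uncertainty + fold comparison")
  target <- config$targets$target_uncertainty %||% 50
  cmp <- compare_corrections(final, base, ver_trunc, target = target)
  ver_dir <- file.path(out_dir, "verify")
  dir.create(ver_dir, showWarnings = FALSE)
  write.csv(cmp$full_report$bins, file.path(ver_dir, "uncertainty.csv"),
            row.names = FALSE)
  write.csv(cmp$folds, file.path(ver_dir, "fold_comparison.csv"),
            row.names = FALSE)

  # --- summary --------------------------------------------------------
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- outputs[basename(outputs) != "summary.json"]
  hashes <- tools::md5sum(outputs)
  names(hashes) <- sub(paste0("^", out_dir, "/?"), "", names(hashes))
  summary_path <- file.path(out_dir, "summary.json")
  jsonlite::write_json(
    list(seed = seed,
         cutoffs = cutoff_tab,
         variable_selection = sel$results,
         passed_variables = sel$passed_variables,
         uncertainty = cmp$full_report$bins,
         average_fold = cmp$average_fold,
         file_hashes = as.list(hashes)),
    summary_path, auto_unbox = TRUE, digits = NA, na = "null")
  stage_msg("done: %d variables selected, average fold %.2f",
            length(sel$passed_variables), cmp$average_fold)

  invisible(list(cutoffs = cutoffs, cutoff_table = cutoff_tab,
                 selection = sel, final_model = final, base_model = base,
                 uncertainty = cmp$full_report, comparison = cmp,
                 summary_path = summary_path))
}

#' Validate a run configuration
#'
#' @param config Config list.
#' @return Invisibly `TRUE`; errors name the offending field.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stopf("config must be a list")
  if (is.null(config$seed)) stopf("config$seed is required")
  check_number(config$seed, "config$seed")
  tg <- config$targets %||% list()
  if (!is.null(tg$target_uncertainty))
    check_number(tg$target_uncertainty, "targets$target_uncertainty",
                 lower = 1e-9)
  if (!is.null(tg$concentration_max) && !is.null(tg$concentration_min) &&
      tg$concentration_max <= tg$concentration_min)
    stopf("targets: concentration_max must exceed concentration_min")
  if (is.null(config$materials) || length(config$materials) == 0L)
    stopf("config$materials must list at least one material")
  if (is.null(config$sensor))
    stopf("config$sensor (sensor response spec) is required")
  if (is.null(config$design$screening))
    stopf("config$design$screening is required")
  if (is.null(config$design$verification))
    stopf("config$design$verification is required")
  invisible(TRUE)
}
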