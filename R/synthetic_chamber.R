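# Synthetic exposure-chamber experiments.
#
# The generator emulates the statistical structure of a controlled chamber
# evaluation of low-cost optical PM2.5 monitors: plateau and transient
# concentration profiles, a real-time reference with 10% relative
# uncertainty, material/temperature/humidity/power/pattern/drift/device
# effects on the monitor response (all acting multiplicatively on the
# expected reading, i.e. additively on the log scale), multiplicative
# log-normal reading noise, and an optional high-concentration rollover
# above which the expected response declines.

#' Aerosol material properties
#'
#' Bundle of the physical properties of a test aerosol that matter for
#' reference-instrument mass conversion, plus the material-specific
#' multiplicative response factor of an optical monitor (the generative
#' counterpart of a material random effect).
#'
#' @param name Material label, e.g. `"ARD"` (Arizona road dust).
#' @param density Particle density in g/cm^3 (> 0).
#' @param shape_factor Dynamic shape factor chi (>= 1); 1 for spheres.
#' @param monitor_gain Multiplicative monitor response factor for this
#'   material (> 0); 1 means the monitor responds nominally.
#' @return An object of class `material_properties`.
#' @examples
#' material_properties("ARD", density = 2.6, shape_factor = 1.5)
#' @export
material_properties <- function(name, density, shape_factor = 1.5,
                                monitor_gain = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  check_number(density, "density", lower = 1e-12)
  check_number(shape_factor, "shape_factor", lower = 1)
  check_number(monitor_gain, "monitor_gain", lower = 1e-12)
  structure(list(name = name, density = density,
                 shape_factor = shape_factor, monitor_gain = monitor_gain),
            class = "material_properties")
}

#' Default test materials
#'
#' The three mineral dusts used for the chamber evaluation: Arizona road
#' dust (ARD), quartz (SiO2) and aluminium oxide (Al2O3), all with dynamic
#' shape factor 1.5 and densities 2.6, 2.6 and 3.95 g/cm^3. Monitor gains
#' default to 1 (nominal response) and are typically overridden per monitor
#' under test.
#'
#' @param monitor_gains Optional named numeric vector of per-material
#'   monitor response factors.
#' @return Named list of [material_properties()] objects.
#' @export
default_materials <- function(monitor_gains = NULL) {
  mats <- list(
    ARD   = material_properties("ARD",   density = 2.6,  shape_factor = 1.5),
    SiO2  = material_properties("SiO2",  density = 2.6,  shape_factor = 1.5),
    Al2O3 = material_properties("Al2O3", density = 3.95, shape_factor = 1.5)
  )
  if (!is.null(monitor_gains)) {
    for (nm in names(monitor_gains)) {
      if (!nm %in% names(mats)) stopf("unknown material '%s'", nm)
      mats[[nm]]$monitor_gain <- check_number(monitor_gains[[nm]],
                                              nm, lower = 1e-12)
    }
  }
  mats
}

#' Experimental condition set
#'
#' The levels of the seven evaluation variables attached to one chamber
#' experiment: aerosol material, temperature, relative humidity, power
#' supply, exposure pattern, hours since the first session (drift), the
#' device unit(s) exposed, and a chamber-location tag.
#'
#' @param material Material label (must match a [material_properties()]
#'   name when simulating).
#' @param temperature Chamber temperature in degrees C (default 20).
#' @param relative_humidity Relative humidity in % (default 50).
#' @param power `"battery"` or `"wired"`.
#' @param pattern `"transient"` (0 to max and back peaks) or `"stable"`
#'   (held plateaus).
#' @param session_time Hours since the first measurement session
#'   (0, ~24, ~48 in the screening design).
#' @param unit_id Character vector of device unit labels; one monitor
#'   column is simulated per unit.
#' @param location_tag Chamber position label (default `"middle"`).
#' @return An object of class `condition_set`.
#' @export
condition_set <- function(material, temperature = 20, relative_humidity = 50,
                          power = c("battery", "wired"),
                          pattern = c("transient", "stable"),
                          session_time = 0, unit_id = "unit1",
                          location_tag = "middle") {
  power <- match.arg(power)
  pattern <- match.arg(pattern)
  check_number(temperature, "temperature")
  check_number(relative_humidity, "relative_humidity", lower = 0, upper = 100)
  check_number(session_time, "session_time", lower = 0)
  stopifnot(is.character(unit_id), length(unit_id) >= 1L)
  structure(list(material = material, temperature = temperature,
                 relative_humidity = relative_humidity, power = power,
                 pattern = pattern, session_time = session_time,
                 unit_id = unit_id, location_tag = location_tag),
            class = "condition_set")
}

#' Sensor response specification
#'
#' Generative description of how a monitor type responds to true
#' concentration and to the evaluation variables. The expected reading at
#' true concentration c (below any rollover limit) is `G * c` with
#'
#' \deqn{\log G = \log(\mathrm{base\_gain} \cdot \mathrm{monitor\_gain}) +
#'   t_s (T - 20) + h_s (RH - 50) + p_s 1\{battery\} + q_s 1\{transient\} +
#'   d_s \cdot \mathrm{session} + u,\; u \sim N(0, \mathrm{device\_sd}^2)}
#'
#' Readings are multiplied by mean-one log-normal noise with coefficient of
#' variation `noise_cv`. Above `rollover_limit` L the expected reading
#' declines as `G*L - k*(c - L)` (clipped at zero) with `k` defaulting to
#' the pre-rollover slope `G`, producing the characteristic "half-circle"
#' monitor-versus-reference curve of saturating optical sensors.
#'
#' @param base_gain Nominal multiplicative gain (default 1).
#' @param temp_slope Log-gain change per degree C away from 20.
#' @param rh_slope Log-gain change per % RH away from 50.
#' @param power_shift Log-gain shift when battery powered.
#' @param pattern_shift Log-gain shift under transient exposure.
#' @param device_sd SD of the per-unit log-gain random effect (>= 0).
#' @param drift_slope Log-gain change per hour of session time.
#' @param noise_cv Coefficient of variation of the multiplicative reading
#'   noise (>= 0; default 0.15, a mid-range value for consumer optical
#'   PM sensors).
#' @param rollover_limit True concentration (ug/m^3) above which the
#'   expected response declines, or `NULL` for none.
#' @param rollover_slope Decline rate above the limit; default `NULL`
#'   meaning the pre-rollover slope `G`.
#' @return An object of class `sensor_response_spec`.
#' @export
sensor_response_spec <- function(base_gain = 1, temp_slope = 0, rh_slope = 0,
                                 power_shift = 0, pattern_shift = 0,
                                 device_sd = 0, drift_slope = 0,
                                 noise_cv = 0.15, rollover_limit = NULL,
                                 rollover_slope = NULL) {
  check_number(base_gain, "base_gain", lower = 1e-12)
  check_number(noise_cv, "noise_cv", lower = 0)
  check_number(device_sd, "device_sd", lower = 0)
  check_number(rollover_limit, "rollover_limit", lower = 1e-12,
               allow_null = TRUE)
  check_number(rollover_slope, "rollover_slope", lower = 0, allow_null = TRUE)
  structure(list(base_gain = base_gain, temp_slope = temp_slope,
                 rh_slope = rh_slope, power_shift = power_shift,
                 pattern_shift = pattern_shift, device_sd = device_sd,
                 drift_slope = drift_slope, noise_cv = noise_cv,
                 rollover_limit = rollover_limit,
                 rollover_slope = rollover_slope),
            class = "sensor_response_spec")
}

#' Stable (plateau) concentration profile
#'
#' True-concentration time series visiting each requested plateau level in
#' order, with linear ramps between plateaus. Within-plateau samples are
#' exactly the requested level, so the within-plateau mean equals the level.
#'
#' @param levels Plateau concentrations in ug/m^3, all > 0. Default
#'   `c(333, 666, 1000, 2500, 5000)`, the plateau set of the screening
#'   experiments.
#' @param plateau_duration Plateau duration in seconds (default 900, i.e.
#'   the >= 15 min hold).
#' @param ramp_fraction Ramp duration between plateaus as a fraction of
#'   `plateau_duration` (default 0.25; 0 gives a step profile).
#' @param dt Sampling interval in seconds (default 15, the reference
#'   instrument cadence).
#' @return A data.frame with columns `time` (s, strictly increasing) and
#'   `true` (ug/m^3).
#' @examples
#' prof <- profile_stable(c(333, 666, 1000, 2500, 5000))
#' tapply(prof$true, prof$true, length)
#' @export
profile_stable <- function(levels = c(333, 666, 1000, 2500, 5000),
                           plateau_duration = 900, ramp_fraction = 0.25,
                           dt = 15) {
  if (length(levels) == 0L) stopf("'levels' must contain at least one level")
  if (any(!is.finite(levels)) || any(levels <= 0))
    stopf("'levels' must all be positive and finite")
  check_number(plateau_duration, "plateau_duration", lower = dt)
  check_number(ramp_fraction, "ramp_fraction", lower = 0)
  check_number(dt, "dt", lower = 1e-9)

  n_plat <- max(1L, round(plateau_duration / dt))
  n_ramp <- round(ramp_fraction * plateau_duration / dt)
  vals <- numeric(0)
  for (i in seq_along(levels)) {
    if (i > 1L && n_ramp > 0L) {
      # linear ramp strictly between the two plateau values
      frac <- seq_len(n_ramp) / (n_ramp + 1)
      vals <- c(vals, levels[i - 1L] + frac * (levels[i] - levels[i - 1L]))
    }
    vals <- c(vals, rep(levels[i], n_plat))
  }
  data.frame(time = dt * (seq_along(vals) - 1L), true = vals)
}

#' Transient (peak) concentration profile
#'
#' Repeated excursions from zero up to `peak_max` and back to zero,
#' emulating short workplace exposure peaks. The default is three
#' half-hour 0 to 5000 to 0 ug/m^3 peaks. The global maximum equals
#' `peak_max` exactly.
#'
#' @param peak_max Peak concentration in ug/m^3 (> 0; a value of 0 gives a
#'   degenerate all-zero trace).
#' @param peak_duration Duration of one full peak in seconds (default 1800).
#' @param n_peaks Number of consecutive peaks (default 3).
#' @param dt Sampling interval in seconds (default 15).
#' @param shape `"linear"` (triangular, the default) or `"exponential"`
#'   (log-smooth rise and fall). The triangular peak has time-average
#'   `peak_max / 2`.
#' @return A data.frame with columns `time` and `true`.
#' @export
profile_transient <- function(peak_max = 5000, peak_duration = 1800,
                              n_peaks = 3, dt = 15,
                              shape = c("linear", "exponential")) {
  shape <- match.arg(shape)
  check_number(peak_max, "peak_max", lower = 0)
  check_number(peak_duration, "peak_duration", lower = 1e-9)
  if (n_peaks < 1) stopf("'n_peaks' must be >= 1")
  check_number(dt, "dt", lower = 1e-9)

  n <- max(2L, round(peak_duration / dt))
  # one peak sampled on [0, T): both tails at zero, apex at the midpoint
  x <- (seq_len(n) - 1L) / n            # in [0, 1)
  tri <- 1 - abs(2 * x - 1)
  peak <- switch(shape,
    linear = tri,
    exponential = (exp(3 * tri) - 1) / (exp(3) - 1))
  # guarantee the apex sample sits exactly at peak_max
  peak[which.max(peak)] <- 1
  vals <- rep(peak, n_peaks) * peak_max
  data.frame(time = dt * (seq_along(vals) - 1L), true = vals)
}

# Expected monitor reading at true concentration `true` given total gain G
# and an optional rollover. Below the limit the response is linear (G*true);
# above it the expectation falls off linearly and is clipped at zero.
expected_monitor <- function(true, gain, rollover_limit = NULL,
                             rollover_slope = NULL) {
  mu <- gain * true
  if (!is.null(rollover_limit)) {
    k <- rollover_slope %||% gain
    over <- true > rollover_limit
    mu[over] <- pmax(0, gain * rollover_limit -
                        k * (true[over] - rollover_limit))
  }
  mu
}

#' Simulate one chamber experiment
#'
#' Generates reference and monitor readings for a true-concentration
#' profile under a condition set and a sensor response specification.
#' The reference carries i.i.d. zero-mean relative error with SD
#' `ref_rel_sd` (10% by default, the manufacturer-stated reference
#' uncertainty); monitor readings are the expected response (see
#' [sensor_response_spec()]) times mean-one multiplicative log-normal
#' noise. Per-unit random effects are drawn from a substream keyed by the
#' root seed and the unit label, so a unit keeps its effect across
#' experiments simulated under the same root seed. Identical seeds
#' reproduce identical series.
#'
#' @param profile Data.frame from [profile_stable()] or
#'   [profile_transient()] (columns `time`, `true`).
#' @param conditions A [condition_set()].
#' @param spec A [sensor_response_spec()].
#' @param material A [material_properties()] object (its `monitor_gain`
#'   multiplies the base gain).
#' @param seed Integer root seed (required).
#' @param unit_seed Seed governing per-unit random effects (defaults to
#'   `seed`); [simulate_design()] passes the design-level root seed here so
#'   a unit keeps one effect across all experiments of a design.
#' @param ref_rel_sd Relative SD of reference noise (default 0.10).
#' @param gravimetric_rel_sd Relative SD of the gravimetric time-average
#'   (default 0.03).
#' @return An object of class `experiment_series`: list with `time`,
#'   `true`, `reference`, `monitor` (matrix, one column per unit),
#'   `conditions`, `gravimetric`.
#' @examples
#' prof <- profile_transient(peak_max = 5000)
#' cond <- condition_set(material = "ARD")
#' spec <- sensor_response_spec(noise_cv = 0.1)
#' ex <- simulate_experiment(prof, cond, spec,
#'                           material_properties("ARD", 2.6), seed = 1)
#' @export
simulate_experiment <- function(profile, conditions, spec, material,
                                seed, unit_seed = seed, ref_rel_sd = 0.10,
                                gravimetric_rel_sd = 0.03) {
  stopifnot(inherits(conditions, "condition_set"),
            inherits(spec, "sensor_response_spec"),
            inherits(material, "material_properties"))
  if (missing(seed)) stopf("'seed' must be supplied")
  check_number(seed, "seed")
  if (!all(c("time", "true") %in% names(profile)))
    stopf("'profile' needs columns 'time' and 'true'")
  if (any(diff(profile$time) <= 0)) stopf("'time' must be strictly increasing")
  n <- nrow(profile)
  true <- profile$true

  ref <- with_substream(substream_seed(seed, "ref", conditions$material,
                                       conditions$session_time),
                        pmax(0, true * (1 + rnorm(n, 0, ref_rel_sd))))

  sdlog <- sqrt(log(1 + spec$noise_cv^2))
  units <- conditions$unit_id
  monitor <- matrix(0, n, length(units), dimnames = list(NULL, units))
  for (u in units) {
    unit_eff <- if (spec$device_sd > 0)
      with_substream(substream_seed(unit_seed, "unit", u),
                     rnorm(1, 0, spec$device_sd)) else 0
    log_gain <- log(spec$base_gain * material$monitor_gain) +
      spec$temp_slope * (conditions$temperature - 20) +
      spec$rh_slope * (conditions$relative_humidity - 50) +
      spec$power_shift * (conditions$power == "battery") +
      spec$pattern_shift * (conditions$pattern == "transient") +
      spec$drift_slope * conditions$session_time + unit_eff
    mu <- expected_monitor(true, exp(log_gain), spec$rollover_limit,
                           spec$rollover_slope)
    noise <- if (sdlog > 0)
      with_substream(substream_seed(seed, "noise", u, conditions$material,
                                    conditions$temperature,
                                    conditions$relative_humidity,
                                    conditions$power, conditions$pattern,
                                    conditions$session_time),
                     exp(rnorm(n, -sdlog^2 / 2, sdlog)))
      else rep(1, n)
    monitor[, u] <- mu * noise
  }

  grav <- with_substream(substream_seed(seed, "grav", conditions$material,
                                        conditions$session_time),
                         mean(true) * (1 + rnorm(1, 0, gravimetric_rel_sd)))

  structure(list(time = profile$time, true = true, reference = ref,
                 monitor = monitor, conditions = conditions,
                 gravimetric = max(0, grav)),
            class = "experiment_series")
}

#' @export
print.experiment_series <- function(x, ...) {
  cat(sprintf(
    "<experiment_series> %d samples, %d unit(s), material %s, %s pattern\n",
    length(x$time), ncol(x$monitor), x$conditions$material,
    x$conditions$pattern))
  cat(sprintf("  true range %.0f-%.0f ug/m3; gravimetric %.1f ug/m3\n",
              min(x$true), max(x$true), x$gravimetric))
  invisible(x)
}

#' Flatten an experiment series to a long data.frame
#'
#' One row per (time, unit) with the condition levels attached; the format
#' the modelling stage consumes.
#'
#' @param x An `experiment_series`.
#' @param ... Unused.
#' @return A data.frame with columns `time`, `true`, `reference`,
#'   `monitor`, `unit_id`, `material`, `temperature`, `relative_humidity`,
#'   `power`, `pattern`, `session_time`, `location_tag`.
#' @export
as.data.frame.experiment_series <- function(x, ...) {
  cs <- x$conditions
  units <- colnames(x$monitor)
  out <- do.call(rbind, lapply(units, function(u) {
    data.frame(time = x$time, true = x$true, reference = x$reference,
               monitor = x$monitor[, u], unit_id = u,
               material = cs$material, temperature = cs$temperature,
               relative_humidity = cs$relative_humidity, power = cs$power,
               pattern = cs$pattern, session_time = cs$session_time,
               location_tag = cs$location_tag,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build an experiment design
#'
#' Two design families are used in the evaluation: one-variable-at-a-time
#' *screening* designs, where each evaluation variable is varied while all
#' others sit at their defaults (battery power, 20 degrees C, 50% RH,
#' transient exposure, session 0, first material, first unit), and
#' *full-factorial* verification designs crossing every supplied level
#' combination (e.g. 3 materials x 3 temperatures x 3 humidities = 27
#' experiments).
#'
#' @param variables Named list of level vectors. Recognised names:
#'   `material`, `temperature`, `relative_humidity`, `power`, `pattern`,
#'   `session_time`, `unit_id`. Each variable needs at least one level.
#' @param type `"screening"` or `"factorial"`.
#' @param default_repeats For screening designs, how many repeats of the
#'   shared all-defaults arm to include (default 3).
#' @return A data.frame manifest, one row per experiment, with columns for
#'   every condition variable plus `experiment_id` and (for screening)
#'   `varied`, the name of the variable the arm exercises.
#' @examples
#' build_design(list(material = c("ARD", "SiO2", "Al2O3"),
#'                   temperature = c(15, 20, 25),
#'                   relative_humidity = c(25, 50, 75)),
#'              type = "factorial")
#' @export
build_design <- function(variables, type = c("screening", "factorial"),
                         default_repeats = 3) {
  type <- match.arg(type)
  known <- c("material", "temperature", "relative_humidity", "power",
             "pattern", "session_time", "unit_id")
  if (length(variables) == 0L) stopf("'variables' must not be empty")
  if (!all(names(variables) %in% known))
    stopf("unknown variable(s): %s",
          paste(setdiff(names(variables), known), collapse = ", "))
  if (any(lengths(variables) < 1L))
    stopf("every variable needs at least one level")

  defaults <- list(material = "ARD", temperature = 20,
                   relative_humidity = 50, power = "battery",
                   pattern = "transient", session_time = 0,
                   unit_id = "unit1")
  # a variable's default is its first supplied level when given
  for (nm in names(variables)) defaults[[nm]] <- variables[[nm]][1L]

  if (type == "factorial") {
    grid <- expand.grid(variables, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    for (nm in setdiff(known, names(grid))) grid[[nm]] <- defaults[[nm]]
    grid$varied <- NA_character_
  } else {
    rows <- list()
    for (nm in names(variables)) {
      extra <- setdiff(variables[[nm]], defaults[[nm]])
      for (lev in extra) {
        row <- defaults
        row[[nm]] <- lev
        row$varied <- nm
        rows[[length(rows) + 1L]] <- row
      }
    }
    for (i in seq_len(default_repeats)) {
      row <- defaults
      row$varied <- "default"
      rows[[length(rows) + 1L]] <- row
    }
    grid <- do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  }
  grid <- grid[, c(known, "varied")]
  grid$experiment_id <- sprintf("exp%03d", seq_len(nrow(grid)))
  rownames(grid) <- NULL
  grid
}

#' Simulate every experiment of a design manifest
#'
#' @param design Manifest from [build_design()].
#' @param spec A [sensor_response_spec()].
#' @param materials Named list of [material_properties()] covering every
#'   material level in the design.
#' @param seed Integer root seed; each experiment draws from a substream
#'   keyed by its `experiment_id`.
#' @param profile_args Optional list of overrides passed to the profile
#'   constructors (e.g. `list(plateau_duration = 300)`).
#' @return Named list of `experiment_series`, one per manifest row.
#' @export
simulate_design <- function(design, spec, materials, seed,
                            profile_args = list()) {
  stopifnot(is.data.frame(design), nrow(design) >= 1L)
  out <- vector("list", nrow(design))
  names(out) <- design$experiment_id
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    prof <- if (row$pattern == "stable")
      do.call(profile_stable,
              profile_args[intersect(names(profile_args),
                                     names(formals(profile_stable)))])
    else
      do.call(profile_transient,
              profile_args[intersect(names(profile_args),
                                     names(formals(profile_transient)))])
    cond <- condition_set(material = row$material,
                          temperature = row$temperature,
                          relative_humidity = row$relative_humidity,
                          power = row$power, pattern = row$pattern,
                          session_time = row$session_time,
                          unit_id = row$unit_id)
    mat <- materials[[row$material]]
    if (is.null(mat)) stopf("no material_properties for '%s'", row$material)
    out[[i]] <- simulate_experiment(prof, cond, spec, mat,
                                    seed = substream_seed(seed, "experiment",
                                                          row$experiment_id),
                                    unit_seed = seed)
  }
  out
}

#' Write simulated experiments to CSV
#'
#' One CSV per experiment (`time_s`, `true_ugm3`, `reference_ugm3`, one
#' column per unit) plus a `manifest.csv` of condition sets.
#'
#' @param experiments Named list from [simulate_design()].
#' @param design The matching manifest.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_experiments <- function(experiments, design, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(experiments)) {
    ex <- experiments[[id]]
    df <- data.frame(time_s = ex$time, true_ugm3 = ex$true,
                     reference_ugm3 = ex$reference)
    for (u in colnames(ex$monitor)) df[[u]] <- ex$monitor[, u]
    write.csv(df, file.path(dir, paste0(id, ".csv")), row.names = FALSE)
  }
  path <- file.path(dir, "manifest.csv")
  write.csv(design, path, row.names = FALSE)
  invisible(path)
}

#' Read experiments written by [write_experiments()]
#'
#' @param dir Directory holding `manifest.csv` and per-experiment CSVs.
#' @return List with elements `design` (manifest data.frame) and
#'   `experiments` (named list of `experiment_series`).
#' @export
read_experiments <- function(dir) {
  design <- read.csv(file.path(dir, "manifest.csv"),
                     stringsAsFactors = FALSE)
  experiments <- setNames(vector("list", nrow(design)),
                          design$experiment_id)
  for (i in seq_len(nrow(design))) {
    row <- design[i, ]
    df <- read.csv(file.path(dir, paste0(row$experiment_id, ".csv")))
    units <- setdiff(names(df), c("time_s", "true_ugm3", "reference_ugm3"))
    cond <- condition_set(material = row$material,
                          temperature = row$temperature,
                          relative_humidity = row$relative_humidity,
                          power = row$power, pattern = row$pattern,
                          session_time = row$session_time,
                          unit_id = units)
    experiments[[i]] <- structure(
      list(time = df$time_s, true = df$true_ugm3,
           reference = df$reference_ugm3,
           monitor = as.matrix(df[, units, drop = FALSE]),
           conditions = cond, gravimetric = NA_real_),
      class = "experiment_series")
  }
  list(design = design, experiments = experiments)
}
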