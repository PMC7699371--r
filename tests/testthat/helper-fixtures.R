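# Shared fixtures, built in code at test time.

# Materials with monitor response factors spanning the range seen for
# optical monitors across mineral dusts.
fixture_materials <- function(gains = c(ARD = 1, SiO2 = 1.3, Al2O3 = 0.7)) {
  default_materials(monitor_gains = gains)
}

# A compact screening design over all seven evaluation variables.
fixture_screening_design <- function() {
  build_design(list(material = c("ARD", "SiO2", "Al2O3"),
                    temperature = c(20, 15, 25),
                    relative_humidity = c(50, 25, 75),
                    power = c("battery", "wired"),
                    pattern = c("transient", "stable"),
                    session_time = c(0, 24, 48),
                    unit_id = c("unit1", "unit2", "unit3")),
               type = "screening")
}

# Simulate a design and flatten to the long modelling table.
fixture_long <- function(design, spec, materials, seed,
                         profile_args = list(peak_duration = 900,
                                             n_peaks = 1,
                                             plateau_duration = 300)) {
  exps <- simulate_design(design, spec, materials, seed = seed,
                          profile_args = profile_args)
  pmevalkit:::design_to_long(exps, design, averaging_s = 0)
}

# Material monitor log-gains drawn with SD 0.3, deterministically per seed.
with_seed_draw <- function(seed) {
  pmevalkit:::with_substream(seed, {
    setNames(exp(rnorm(3, 0, 0.3)), c("ARD", "SiO2", "Al2O3"))
  })
}

# Subset experiments simulated at the default arm plus the arms of one
# variable, as the variable-testing stage consumes them.
simulate_variable_subset <- function(variable_levels, variable, spec,
                                     materials, seed, n_default = 1,
                                     profile_args = list(peak_duration = 900,
                                                         n_peaks = 1)) {
  vars <- list()
  vars[[variable]] <- variable_levels
  design <- build_design(vars, type = "screening",
                         default_repeats = n_default)
  fixture_long(design, spec, materials, seed, profile_args)
}
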