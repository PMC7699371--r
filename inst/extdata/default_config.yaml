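seed: 1.0
targets:
  concentration_min: 0.0
  concentration_max: 5000.0
  target_uncertainty: 50.0
  responsiveness_s: 60.0
materials:
  ARD:
    density: 2.6
    shape_factor: 1.5
    monitor_gain: 1.0
  SiO2:
    density: 2.6
    shape_factor: 1.5
    monitor_gain: 1.3
  Al2O3:
    density: 3.95
    shape_factor: 1.5
    monitor_gain: 0.7
sensor:
  base_gain: 1.0
  temp_slope: 0.002
  rh_slope: 0.001
  power_shift: 0.0
  pattern_shift: 0.15
  device_sd: 0.05
  drift_slope: 0.0
  noise_cv: 0.15
  rollover_limit: ~
design:
  screening:
    material:
    - ARD
    - SiO2
    - Al2O3
    temperature:
    - 20.0
    - 15.0
    - 25.0
    relative_humidity:
    - 50.0
    - 25.0
    - 75.0
    power:
    - battery
    - wired
    pattern:
    - transient
    - stable
    session_time:
    - 0.0
    - 24.0
    - 48.0
    unit_id:
    - unit1
    - unit2
    - unit3
  verification:
    material:
    - ARD
    - SiO2
    - Al2O3
    temperature:
    - 15.0
    - 20.0
    - 25.0
    relative_humidity:
    - 25.0
    - 50.0
    - 75.0
profile:
  plateau_duration: 300.0
  peak_duration: 900.0
  n_peaks: 2.0
  dt: 15.0
screening:
  span: 0.3
  decline_tol: 0.05
  flag_fraction: 0.1
  percentile: 0.1
  ref_smooth: 11.0
averaging_s: 0.0
transform: log10
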