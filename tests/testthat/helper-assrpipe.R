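# Shared scaled-down world for simulation-based tests: a 24-site (48
# planar-gradiometer) helmet, 12 mm grid, 16 trials. Heavy objects are
# memoised per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

tiny_sensors <- function() memo("sens24", make_helmet_array(n_sites = 24))
tiny_sphere <- function() memo("sphere", sphere_head_model())
tiny_analysis <- function() memo("ana", analysis_config(grid_spacing = 0.012))

tiny_geometry <- function() memo("geom", study_geometry(
  tiny_sensors(), tiny_sphere(), tiny_analysis()))

tiny_geometry_full <- function() memo("geom_full", study_geometry(
  tiny_sensors(), tiny_sphere(), tiny_analysis(), full_grid = TRUE))

# one simulated control-template subject, reused across tests
tiny_subject_epochs <- function() memo("subj_epochs", {
  cfg <- subject_config("T01", "control", n_trials = 16, seed = 4242)
  simulate_subject(cfg, tiny_sensors(), tiny_sphere())
})

tiny_subject_measures <- function() memo("subj_measures", {
  run_subject(tiny_subject_epochs(), tiny_analysis(), tiny_geometry())
})

# noiseless single-source world for forward/beamformer ground truth
noiseless_config <- function(n_trials = 8, seed = 11, ...) {
  subject_config("N01", "control", n_trials = n_trials,
                 sources = bilateral_a1_sources(...),
                 noise = noise_config(sensor_noise_sd = 0,
                                      n_brain_noise_dipoles = 0),
                 seed = seed)
}

# scaled two-group study configuration used by study-level tests
small_study_config <- function(seed, n_per_group = 8, n_trials = 32) {
  group_study_config(n_per_group = n_per_group, master_seed = seed,
                     n_trials = n_trials, sensors = tiny_sensors())
}

expect_close <- function(object, expected, tol) {
  expect_true(all(abs(object - expected) <= tol),
              label = sprintf("max |diff| = %g (tol %g)",
                              max(abs(object - expected)), tol))
}
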