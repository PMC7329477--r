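# Synthetic data generation: clicktrain stimulus, phase-jittered dipole
# sources, subject/group simulation, behavioural scores.

test_that("clicktrain has the documented click geometry", {
  cfg <- stimulus_config()
  x <- make_clicktrain(cfg, sfreq = 1000)
  expect_equal(length(x), 1500)
  # 60 clicks of exactly 2 samples each
  r <- rle(as.numeric(x > 0))
  expect_equal(sum(r$values == 1), 60)
  expect_true(all(r$lengths[r$values == 1] == 2))
  expect_equal(clicktrain_rate(cfg), 40)
  # zero outside [0, train_duration)
  x2 <- make_clicktrain(stimulus_config(train_duration = 1.0), 1000)
  expect_equal(length(x2), 1000)
  expect_equal(sum(x2 > 0), 40 * 2)
})

test_that("clicktrain spectrum peaks at the click rate", {
  # oracle: FFT of the generated waveform; strongest non-DC line at 40 Hz
  x <- make_clicktrain(stimulus_config(), sfreq = 1000)
  sp <- Mod(fft(as.numeric(x)))[2:750]
  freqs <- (1:749) * 1000 / 1500
  expect_equal(freqs[which.max(sp)], 40, tolerance = 1e-9)
})

test_that("clicktrain errors when the rate cannot represent a click", {
  expect_error(make_clicktrain(stimulus_config(), sfreq = 400),
               "cannot represent")
})

test_that("phase jitter follows the von Mises model", {
  set.seed(1)
  # kappa = 0: mean resultant ~ 0 over many draws
  th <- rvonmises(10000, 0, 0)
  r0 <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  expect_lt(r0, 0.02)
  # calibration against the closed form I1/I0 at kappa in {0, 1, 4, 50}
  for (k in c(1, 4, 50)) {
    th <- rvonmises(20000, 0, k)
    r <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
    expect_close(r, vm_mean_resultant(k), tol = 0.015)
  }
  # kappa = Inf: perfectly locked
  expect_equal(rvonmises(5, 0.3, Inf), rep(0.3, 5))
})

test_that("trial sources are phase locked at infinite kappa and silent at zero amplitude", {
  stim <- stimulus_config()
  times <- seq(-2, 2 - 1e-3, by = 1e-3)
  spec <- source_spec(c(-0.052, -0.02, 0.02), phase_jitter_kappa = Inf,
                      tgbr_amplitude = 0)
  set.seed(2)
  trials <- replicate(10, as.numeric(
    simulate_trial_sources(spec, stim, times)))
  # identical phases: trial average preserves single-trial amplitude
  avg <- rowMeans(trials)
  sel <- times > 0.2 & times < 1.3
  expect_close(max(abs(avg[sel])), spec$assr_amplitude, tol = 0.01)
  expect_equal(max(abs(avg - trials[, 1])), 0)
  # baseline silent
  expect_equal(max(abs(avg[times < -0.01])), 0)
  # zero amplitudes: nothing anywhere
  null_spec <- source_spec(c(-0.052, -0.02, 0.02), assr_amplitude = 0,
                           tgbr_amplitude = 0)
  expect_equal(max(abs(simulate_trial_sources(null_spec, stim, times))), 0)
})

test_that("vectorised source matrix matches the per-trial model statistics", {
  stim <- stimulus_config()
  times <- seq(-2, 2 - 1e-3, by = 1e-3)
  spec <- source_spec(c(-0.052, -0.02, 0.02), phase_jitter_kappa = 4,
                      kappa_late = 2, tgbr_amplitude = 10)
  set.seed(3)
  sm <- assrpipe:::simulate_source_matrix(spec, stim, times, 4000)
  # drawn phases calibrate to their von Mises concentrations
  r_e <- Mod(mean(exp(1i * sm$phase_early)))
  r_l <- Mod(mean(exp(1i * sm$phase_late)))
  expect_close(r_e, vm_mean_resultant(4), tol = 0.02)
  expect_close(r_l, vm_mean_resultant(2), tol = 0.03)
  # burst confined to 0-0.1 s, RMS near the requested moment
  outside <- times < -1e-9 | times > 0.1 + 1e-9
  stim_only <- spec$assr_amplitude *
    assrpipe:::assr_envelope(spec, stim, times)
  expect_true(all(abs(sm$M[outside, 1:50]) <= stim_only[outside] + 1e-9))
})

test_that("simulate_subject is deterministic and linear in dipole moment", {
  sens <- make_helmet_array(n_sites = 12)
  sph <- sphere_head_model()
  cfg <- noiseless_config(n_trials = 3)
  ep1 <- simulate_subject(cfg, sens, sph)
  ep2 <- simulate_subject(cfg, sens, sph)
  expect_identical(ep1$data, ep2$data)        # bit-identical rerun
  expect_equal(dim(ep1$data), c(3, 24, 4000)) # 4 s at 1000 Hz
  expect_equal(length(ep1$times), 4000)
  # doubling every source amplitude doubles the noise-free sensor data
  cfg2 <- cfg
  cfg2$sources <- lapply(cfg$sources, function(s) {
    s$assr_amplitude <- 2 * s$assr_amplitude
    s$tgbr_amplitude <- 2 * s$tgbr_amplitude
    s
  })
  ep3 <- simulate_subject(cfg2, sens, sph)
  expect_close(ep3$data, 2 * ep1$data, tol = 1e-18)
})

test_that("group study construction follows the effect templates", {
  cfg <- group_study_config(n_per_group = 18)
  subj <- make_subject_configs(cfg)
  expect_length(subj, 36)
  expect_equal(sum(vapply(subj, `[[`, "", "group") == "ASD"), 18)
  # per-subject seeds all distinct
  expect_equal(anyDuplicated(vapply(subj, `[[`, 1L, "seed")), 0L)
  ctl <- subj[[1]]$sources$left
  asd <- subj[[19]]$sources$left
  # transient burst parameters identical between groups up to the shared
  # heterogeneity draw (ratio equals the response-gain ratio)
  gain_ratio <- asd$assr_amplitude / ctl$assr_amplitude
  expect_equal(asd$tgbr_amplitude / ctl$tgbr_amplitude, gain_ratio)
  # ASD sustained amplitude scaled 0.6 after 0.5 s, kappa halved
  expect_equal(asd$kappa_late, asd$phase_jitter_kappa * 0.5)
  expect_equal(ctl$kappa_late, ctl$phase_jitter_kappa)
  expect_equal(asd$amplitude_envelope(1.2), 0.6)
  expect_equal(asd$amplitude_envelope(0.2), 1)
  expect_null(ctl$amplitude_envelope)
})

test_that("per-subject seed derivation is order independent", {
  s10 <- derive_seeds(99, 10)
  s20 <- derive_seeds(99, 20)
  expect_identical(s10, s20[1:10])
  expect_equal(anyDuplicated(s20), 0L)
  expect_true(all(s20 >= 1 & s20 < 2^31))
})

test_that("behavioural scores reproduce the configured group parameters", {
  cfg <- group_study_config(n_per_group = 3000, subject_variability = 0)
  b <- simulate_behaviour(cfg, seed = 7)
  m <- aggregate(cbind(AQ, GSQ) ~ group, b, mean)
  s <- aggregate(cbind(AQ, GSQ) ~ group, b, sd)
  expect_close(m$AQ[m$group == "ASD"], 32.60, tol = 0.5)
  expect_close(m$AQ[m$group == "control"], 10.91, tol = 0.5)
  expect_close(s$AQ[s$group == "ASD"], 6.64, tol = 0.4)
  # GSQ ASD tail is clipped at 0, slightly raising the mean
  expect_close(m$GSQ[m$group == "ASD"], 65.33, tol = 1.5)
  expect_close(m$GSQ[m$group == "control"], 38.70, tol = 0.5)
  expect_true(all(b$AQ >= 0 & b$AQ <= 50))
  expect_true(all(b$GSQ >= 0 & b$GSQ <= 168))
})

test_that("zero-SD behavioural scores collapse to the group means", {
  cfg <- group_study_config(n_per_group = 4)
  cfg$behaviour$AQ$ASD["sd"] <- 0
  cfg$behaviour$AQ$control["sd"] <- 0
  b <- simulate_behaviour(cfg, seed = 1)
  expect_equal(unique(b$AQ[b$group == "ASD"]), 32.60)
  expect_equal(unique(b$AQ[b$group == "control"]), 10.91)
})

test_that("epochs container round-trips through disk", {
  ep <- tiny_subject_epochs()
  path <- file.path(tempdir(), "ep-roundtrip")
  write_epochs(ep, path)
  ep2 <- read_epochs(path)
  expect_equal(ep2$data, ep$data)
  expect_equal(ep2$times, ep$times)
  expect_equal(ep2$sfreq, ep$sfreq)
  expect_equal(ep2$channels$name, ep$channels$name)
  expect_equal(ep2$provenance$subject_id, ep$provenance$subject_id)
  unlink(path, recursive = TRUE)
})

test_that("behaviour table round-trips through CSV", {
  b <- simulate_behaviour(group_study_config(n_per_group = 4), seed = 3)
  p <- tempfile(fileext = ".csv")
  write_behaviour(b, p)
  expect_equal(read_behaviour(p), b)
  unlink(p)
})
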