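#' Noise model configuration
#'
#' @param sensor_noise_sd white sensor noise SD per sample, in the channel's
#'   units (Tesla/m for the default planar-gradiometer array).
#' @param n_brain_noise_dipoles number of randomly placed background brain
#'   dipoles with 1/f^alpha spectra.
#' @param brain_noise_spectrum_exponent alpha of the 1/f^alpha background.
#' @param brain_noise_amplitude RMS moment of each background dipole (nA m).
#' @return Object of class `"noise_config"`.
#' @export
noise_config <- function(sensor_noise_sd = 5e-12,
                         n_brain_noise_dipoles = 30,
                         brain_noise_spectrum_exponent = 1,
                         brain_noise_amplitude = 8) {
  stopifnot(sensor_noise_sd >= 0, n_brain_noise_dipoles >= 0,
            brain_noise_spectrum_exponent >= 0, brain_noise_amplitude >= 0)
  structure(list(sensor_noise_sd = sensor_noise_sd,
                 n_brain_noise_dipoles = as.integer(n_brain_noise_dipoles),
                 brain_noise_spectrum_exponent = brain_noise_spectrum_exponent,
                 brain_noise_amplitude = brain_noise_amplitude),
            class = "noise_config")
}

#' Single-subject simulation configuration
#'
#' @param subject_id character id.
#' @param group `"control"` or `"ASD"` (a label; effects are carried by the
#'   source specs, normally set through a group effect template).
#' @param n_trials number of clicktrain trials (default 64).
#' @param sources named list of [source_spec()]; default bilateral
#'   auditory-cortex pair.
#' @param noise a [noise_config()].
#' @param seed integer seed; every subject owns exactly one.
#' @param stimulus a [stimulus_config()].
#' @param sfreq simulation sampling rate in Hz (default 1000).
#' @param epoch_window analysis window in seconds (default `c(-1.5, 1.5)`).
#' @param pad padding either side in seconds (default 0.5, so epochs span
#'   4 s in total).
#' @return Object of class `"subject_config"`.
#' @export
subject_config <- function(subject_id, group = c("control", "ASD"),
                           n_trials = 64, sources = bilateral_a1_sources(),
                           noise = noise_config(), seed = 1,
                           stimulus = stimulus_config(), sfreq = 1000,
                           epoch_window = c(-1.5, 1.5), pad = 0.5) {
  group <- match.arg(group)
  stopifnot(n_trials >= 1, length(seed) == 1)
  structure(list(subject_id = subject_id, group = group,
                 n_trials = as.integer(n_trials), sources = sources,
                 noise = noise, seed = as.integer(seed),
                 stimulus = stimulus, sfreq = sfreq,
                 epoch_window = epoch_window, pad = pad),
            class = "subject_config")
}

# Gaussian noise with a 1/f^alpha amplitude spectrum, unit RMS, columns
# independent. n samples x m series.
one_over_f_noise <- function(n, m, alpha) {
  if (m == 0) return(matrix(0, n, 0))
  w <- matrix(rnorm(n * m), n, m)
  if (alpha == 0) return(w)
  sp <- stats::mvfft(w)
  f <- c(0, seq_len(n - 1))
  f <- pmin(f, n - f)            # two-sided frequency index
  g <- ifelse(f == 0, 0, f^(-alpha / 2))
  sp <- sp * g
  x <- Re(stats::mvfft(sp, inverse = TRUE)) / n
  sweep(x, 2, sqrt(colMeans(x^2)), `/`)
}

#' Simulate a subject's epoched sensor data
#'
#' Composes per-trial source moment time series, projects them through the
#' spherical forward model, and adds 1/f background brain noise (random
#' interior dipoles) and white sensor noise. Deterministic given the
#' config's seed.
#'
#' @param cfg a [subject_config()].
#' @param sensors a [make_helmet_array()] channel table.
#' @param head_model a [sphere_head_model()].
#' @return An [epoched_data()] object (`n_trials x n_channels x samples`)
#'   with per-trial drawn source phases in `$provenance$phases`.
#' @export
simulate_subject <- function(cfg, sensors, head_model) {
  stopifnot(inherits(cfg, "subject_config"))
  fs <- cfg$sfreq
  t0 <- cfg$epoch_window[1] - cfg$pad
  t1 <- cfg$epoch_window[2] + cfg$pad
  times <- seq(t0, t1 - 1 / fs, by = 1 / fs)
  nsamp <- length(times)
  nch <- nrow(sensors)
  gains <- lapply(cfg$sources, function(s)
    channel_gains(s$position, s$orientation * 1e-9, sensors, head_model))
  ntr <- cfg$n_trials
  with_seed(cfg$seed, {
    nz <- cfg$noise
    # sources first (all trials at once), then brain noise, then sensor
    # noise — a fixed draw order so output is reproducible from the seed
    D <- matrix(0, nch, nsamp * ntr)
    phases <- matrix(NA_real_, ntr, 2 * length(cfg$sources))
    for (si in seq_along(cfg$sources)) {
      sm <- simulate_source_matrix(cfg$sources[[si]], cfg$stimulus,
                                   times, ntr)
      D <- D + outer(gains[[si]], as.numeric(sm$M))
      phases[, 2 * si - 1] <- sm$phase_early
      phases[, 2 * si] <- sm$phase_late
    }
    if (nz$n_brain_noise_dipoles > 0) {
      ndip <- nz$n_brain_noise_dipoles
      npos <- random_interior_points(ndip, head_model)
      nori <- random_unit_vectors(ndip)
      ng <- vapply(seq_len(ndip), function(i)
        channel_gains(npos[i, ], nori[i, ] * 1e-9, sensors, head_model),
        numeric(nch))          # nch x ndip
      bn <- one_over_f_noise(nsamp, ndip * ntr,
                             nz$brain_noise_spectrum_exponent)
      dim(bn) <- c(nsamp, ndip, ntr)
      bstack <- matrix(aperm(bn, c(2, 1, 3)), ndip, nsamp * ntr)
      D <- D + (ng * nz$brain_noise_amplitude) %*% bstack
    }
    if (nz$sensor_noise_sd > 0)
      D <- D + rnorm(length(D), 0, nz$sensor_noise_sd)
    data <- aperm(array(D, dim = c(nch, nsamp, ntr)), c(3, 1, 2))
    epoched_data(data, times, fs, sensors,
                 provenance = list(
                   generator = "assrpipe::simulate_subject",
                   subject_id = cfg$subject_id, group = cfg$group,
                   seed = cfg$seed, phases = phases,
                   stimulus = unclass(cfg$stimulus),
                   noise = unclass(cfg$noise)))
  })
}

random_interior_points <- function(n, sphere, rmin = 0.02, rmax_frac = 0.85) {
  u <- random_unit_vectors(n)
  rad <- (runif(n, (rmin / sphere$radius)^3, rmax_frac^3))^(1 / 3) *
    sphere$radius
  sweep(u * rad, 2, sphere$centre, `+`)
}

random_unit_vectors <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Group effect template
#'
#' Multiplicative modifiers applied to every source of a group's subjects.
#' The default templates give controls an unmodified sustained response and
#' the ASD group a sustained amplitude scaled by 0.6 and a phase
#' concentration halved for the period after `change_time` — a single
#' parameterisation producing both the power and the phase-consistency
#' group phenomenology (the 0-0.1 s transient burst is left untouched).
#'
#' @param sustained_gain sustained-amplitude multiplier after `change_time`.
#' @param kappa_late_factor multiplier on the late-period von Mises
#'   concentration.
#' @param change_time time (s) after which the modifiers apply.
#' @param overrides named list of [source_spec()] fields to override
#'   outright (applied to every source).
#' @return Object of class `"effect_template"`.
#' @export
effect_template <- function(sustained_gain = 1, kappa_late_factor = 1,
                            change_time = 0.5, overrides = list()) {
  stopifnot(sustained_gain >= 0, kappa_late_factor >= 0)
  structure(list(sustained_gain = sustained_gain,
                 kappa_late_factor = kappa_late_factor,
                 change_time = change_time, overrides = overrides),
            class = "effect_template")
}

apply_template <- function(src, tpl) {
  stopifnot(inherits(src, "source_spec"), inherits(tpl, "effect_template"))
  for (nm in names(tpl$overrides)) src[[nm]] <- tpl$overrides[[nm]]
  src$kappa_late <- src$phase_jitter_kappa * tpl$kappa_late_factor
  src$kappa_change_time <- tpl$change_time
  if (tpl$sustained_gain != 1) {
    g <- tpl$sustained_gain; tc <- tpl$change_time
    prev <- src$amplitude_envelope
    src$amplitude_envelope <- function(t) {
      e <- 1 + (g - 1) * smooth_step(t, tc - 0.05, 0.1)
      if (!is.null(prev)) e <- e * prev(t)
      e
    }
  }
  src
}

#' Two-group study configuration
#'
#' @param n_per_group subjects per group (default 18).
#' @param master_seed integer; per-subject seeds are derived from it with
#'   [derive_seeds()], so the study is reproducible independent of
#'   generation order.
#' @param n_trials trials per subject (default 64).
#' @param stimulus shared [stimulus_config()].
#' @param noise shared [noise_config()].
#' @param sources base named list of [source_spec()] (before templates).
#' @param control_template,asd_template [effect_template()]s.
#' @param behaviour per-group mean/SD and instrument range for the AQ and
#'   GSQ questionnaires (defaults from the study's demographics table).
#' @param subject_variability sdlog of two per-subject lognormal factors:
#'   a response gain multiplying every source's `assr_amplitude` and
#'   `tgbr_amplitude`, and a noise gain multiplying the brain-noise and
#'   sensor-noise levels (default 0.2 each). Real cohorts never contain
#'   identical responders or identical noise floors; without this
#'   heterogeneity the subject-specific common beamformer filters can turn
#'   a pure 40 Hz power group difference into a spurious transient-gamma
#'   contrast (see the methods vignette).
#' @param sensors shared sensor array (default 102-site gradiometer helmet).
#' @param sphere shared [sphere_head_model()].
#' @return Object of class `"group_study_config"`.
#' @export
group_study_config <- function(n_per_group = 18, master_seed = 1,
                               n_trials = 64,
                               stimulus = stimulus_config(),
                               noise = noise_config(),
                               sources = bilateral_a1_sources(),
                               control_template = effect_template(),
                               asd_template = effect_template(
                                 sustained_gain = 0.6,
                                 kappa_late_factor = 0.5),
                               behaviour = default_behaviour_params(),
                               subject_variability = 0.2,
                               sensors = NULL, sphere = sphere_head_model()) {
  stopifnot(n_per_group >= 1, subject_variability >= 0)
  if (is.null(sensors)) sensors <- make_helmet_array()
  structure(list(n_per_group = as.integer(n_per_group),
                 master_seed = as.integer(master_seed),
                 n_trials = as.integer(n_trials), stimulus = stimulus,
                 noise = noise, sources = sources,
                 control_template = control_template,
                 asd_template = asd_template, behaviour = behaviour,
                 subject_variability = subject_variability,
                 sensors = sensors, sphere = sphere),
            class = "group_study_config")
}

#' Default behavioural score parameters
#'
#' Group means and SDs for the autism quotient (AQ, scored /50) and the
#' Glasgow sensory questionnaire (GSQ, scored /168).
#' @return Nested list of per-instrument, per-group `c(mean, sd)` plus range.
#' @export
default_behaviour_params <- function() {
  list(AQ = list(ASD = c(mean = 32.60, sd = 6.64),
                 control = c(mean = 10.91, sd = 5.43),
                 range = c(0, 50)),
       GSQ = list(ASD = c(mean = 65.33, sd = 27.69),
                  control = c(mean = 38.70, sd = 6.88),
                  range = c(0, 168)))
}

#' Per-subject configurations of a group study
#'
#' @param cfg a [group_study_config()].
#' @return List of [subject_config()], controls first; each already carries
#'   its group's effect template and derived seed.
#' @export
make_subject_configs <- function(cfg) {
  stopifnot(inherits(cfg, "group_study_config"))
  n <- cfg$n_per_group
  seeds <- derive_seeds(cfg$master_seed, 2 * n + 2)
  # per-subject response gain: lognormal heterogeneity shared by both
  # groups, drawn from its own derived seed so it is order-independent
  het <- if (cfg$subject_variability > 0) {
    with_seed(seeds[2 * n + 2],
              matrix(exp(rnorm(4 * n, 0, cfg$subject_variability)), 2 * n))
  } else matrix(1, 2 * n, 2)   # col 1: response gain, col 2: noise gain
  out <- vector("list", 2 * n)
  for (i in seq_len(2 * n)) {
    grp <- if (i <= n) "control" else "ASD"
    tpl <- if (grp == "control") cfg$control_template else cfg$asd_template
    srcs <- lapply(cfg$sources, function(s) {
      s <- apply_template(s, tpl)
      s$assr_amplitude <- s$assr_amplitude * het[i, 1]
      s$tgbr_amplitude <- s$tgbr_amplitude * het[i, 1]
      s
    })
    nz <- cfg$noise
    nz$brain_noise_amplitude <- nz$brain_noise_amplitude * het[i, 2]
    nz$sensor_noise_sd <- nz$sensor_noise_sd * het[i, 2]
    out[[i]] <- subject_config(
      subject_id = sprintf("S%02d", i), group = grp,
      n_trials = cfg$n_trials, sources = srcs, noise = nz,
      seed = seeds[i], stimulus = cfg$stimulus)
  }
  out
}

#' Simulate a complete two-group study
#'
#' @param cfg a [group_study_config()].
#' @param out_dir if non-`NULL`, each subject's epochs are written to a
#'   container under this directory (subject id as subdirectory name) and
#'   paths are returned instead of in-memory data — at full scale one
#'   subject occupies ~0.4 GB in memory.
#' @return List: `epochs` (list of [epoched_data()] or container paths),
#'   `subjects` (the per-subject configs), `behaviour` (table from
#'   [simulate_behaviour()]), `ground_truth` (every generating parameter).
#' @export
simulate_group_study <- function(cfg, out_dir = NULL) {
  subj <- make_subject_configs(cfg)
  epochs <- vector("list", length(subj))
  names(epochs) <- vapply(subj, `[[`, "", "subject_id")
  for (i in seq_along(subj)) {
    ep <- simulate_subject(subj[[i]], cfg$sensors, cfg$sphere)
    if (is.null(out_dir)) {
      epochs[[i]] <- ep
    } else {
      p <- file.path(out_dir, subj[[i]]$subject_id)
      write_epochs(ep, p)
      epochs[[i]] <- p
    }
  }
  behaviour <- simulate_behaviour(cfg)
  truth <- list(
    master_seed = cfg$master_seed, n_per_group = cfg$n_per_group,
    n_trials = cfg$n_trials,
    control_template = unclass(cfg$control_template),
    asd_template = unclass(cfg$asd_template),
    sources = lapply(cfg$sources, function(s)
      unclass(s)[c("position", "orientation", "assr_amplitude",
                   "assr_frequency", "phase_jitter_kappa", "tgbr_amplitude")]),
    noise = unclass(cfg$noise), stimulus = unclass(cfg$stimulus),
    subject_seeds = vapply(subj, `[[`, integer(1), "seed"),
    subject_variability = cfg$subject_variability,
    subject_assr_amplitude = vapply(subj, function(s)
      s$sources[[1]]$assr_amplitude, numeric(1)),
    effect_onset = cfg$asd_template$change_time)
  list(epochs = epochs, subjects = subj, behaviour = behaviour,
       ground_truth = truth)
}

#' Simulate behavioural questionnaire scores
#'
#' One row per subject; AQ and GSQ drawn from the per-group normal
#' distributions in the study config and clipped to the instrument range.
#'
#' @param cfg a [group_study_config()].
#' @param seed optional override; default is derived from the master seed.
#' @return `data.frame` with columns `subject_id`, `group`, `AQ`, `GSQ`.
#' @export
simulate_behaviour <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "group_study_config"))
  n <- cfg$n_per_group
  if (is.null(seed))
    seed <- derive_seeds(cfg$master_seed, 2 * n + 1)[2 * n + 1]
  groups <- rep(c("control", "ASD"), each = n)
  ids <- sprintf("S%02d", seq_len(2 * n))
  with_seed(seed, {
    draw <- function(inst) {
      p <- cfg$behaviour[[inst]]
      vals <- numeric(2 * n)
      for (g in c("control", "ASD")) {
        sel <- groups == g
        vals[sel] <- rnorm(sum(sel), p[[g]]["mean"], p[[g]]["sd"])
      }
      pmin(p$range[2], pmax(p$range[1], vals))
    }
    data.frame(subject_id = ids, group = groups,
               AQ = draw("AQ"), GSQ = draw("GSQ"))
  })
}

#' Write a behavioural table to CSV
#' @param behaviour table from [simulate_behaviour()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_behaviour <- function(behaviour, path) {
  write.csv(behaviour, path, row.names = FALSE)
  invisible(path)
}

#' Read a behavioural table from CSV
#' @param path CSV with columns `subject_id`, `group`, `AQ`, `GSQ`.
#' @return `data.frame`.
#' @export
read_behaviour <- function(path) {
  b <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "AQ", "GSQ")
  if (!all(need %in% names(b)))
    stop("behaviour CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  b
}
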