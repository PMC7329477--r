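#' Dipole source specification
#'
#' Describes one simulated neural source: a sustained steady-state
#' component entrained at `assr_frequency` with trial-to-trial von Mises
#' phase jitter, plus a broadband 30-60 Hz transient burst within 0.1 s of
#' stimulus onset. A time-resolved group effect enters through the
#' amplitude envelope and through a possibly different late-period phase
#' concentration `kappa_late` that takes over at `kappa_change_time`.
#'
#' @param position dipole position in metres (head coordinates), strictly
#'   inside the head sphere.
#' @param orientation unit moment direction; `NULL` picks a tangential
#'   orientation automatically (radial dipoles are silent in a spherical
#'   conductor).
#' @param assr_amplitude sustained dipole moment in nA m (default 15).
#' @param assr_frequency entrainment frequency in Hz (default 40).
#' @param phase_jitter_kappa von Mises concentration of the trial-wise
#'   entrained phase; `Inf` = perfectly phase locked, `0` = uniform phase.
#' @param kappa_late concentration governing the phase after
#'   `kappa_change_time` (default: same as `phase_jitter_kappa`).
#' @param kappa_change_time time (s) at which the late-phase regime starts.
#' @param tgbr_amplitude RMS dipole moment (nA m) of the 0-0.1 s broadband
#'   30-60 Hz burst (default 25).
#' @param onset_ramp raised-cosine onset/offset ramp in seconds.
#' @param amplitude_envelope optional function of peristimulus time
#'   returning a multiplicative gain for the sustained component (used by
#'   group effect templates); `NULL` = constant 1.
#' @return Object of class `"source_spec"`.
#' @export
source_spec <- function(position, orientation = NULL,
                        assr_amplitude = 15, assr_frequency = 40,
                        phase_jitter_kappa = 4, kappa_late = NULL,
                        kappa_change_time = 0.5,
                        tgbr_amplitude = 25, onset_ramp = 0.05,
                        amplitude_envelope = NULL) {
  stopifnot(length(position) == 3, assr_amplitude >= 0,
            phase_jitter_kappa >= 0, tgbr_amplitude >= 0)
  if (is.null(kappa_late)) kappa_late <- phase_jitter_kappa
  stopifnot(kappa_late >= 0)
  if (is.null(orientation)) orientation <- tangential_orientation(position)
  orientation <- orientation / sqrt(sum(orientation^2))
  structure(list(position = as.numeric(position),
                 orientation = as.numeric(orientation),
                 assr_amplitude = assr_amplitude,
                 assr_frequency = assr_frequency,
                 phase_jitter_kappa = phase_jitter_kappa,
                 kappa_late = kappa_late,
                 kappa_change_time = kappa_change_time,
                 tgbr_amplitude = tgbr_amplitude,
                 onset_ramp = onset_ramp,
                 amplitude_envelope = amplitude_envelope),
            class = "source_spec")
}

# a unit vector tangential to the sphere surface at `position`
tangential_orientation <- function(position, centre = c(0, 0, 0)) {
  r <- position - centre
  ref <- if (abs(r[3]) < 0.9 * sqrt(sum(r^2))) c(0, 0, 1) else c(1, 0, 0)
  t1 <- cross3(r, ref)
  t1 / sqrt(sum(t1^2))
}

#' Canonical bilateral auditory-cortex source pair
#'
#' Two tangentially oriented dipoles at geometric stand-ins for left and
#' right primary auditory cortex inside the default head sphere.
#'
#' @param ... overrides passed to [source_spec()] for both hemispheres.
#' @return Named list with elements `left` and `right`.
#' @export
bilateral_a1_sources <- function(...) {
  list(left = source_spec(position = c(-0.052, -0.02, 0.02), ...),
       right = source_spec(position = c(0.052, -0.02, 0.02), ...))
}

# raised-cosine step from 0 to 1 over [t0, t0 + width]
smooth_step <- function(t, t0, width) {
  u <- pmin(1, pmax(0, (t - t0) / width))
  0.5 - 0.5 * cos(pi * u)
}

# sustained-component gain over peristimulus time: 0 outside the train,
# raised-cosine on/off ramps, times any user envelope
assr_envelope <- function(spec, stimulus, t) {
  dur <- stimulus$train_duration
  ramp <- spec$onset_ramp
  env <- smooth_step(t, 0, max(ramp, 1e-6)) *
    (1 - smooth_step(t, dur, max(ramp, 1e-6)))
  env[t < 0 | t > dur + ramp] <- 0
  if (!is.null(spec$amplitude_envelope))
    env <- env * spec$amplitude_envelope(t)
  env
}

#' Simulate one trial of a source's dipole moment time series
#'
#' Baseline is silent (noise is added at the sensor level elsewhere); during
#' the clicktrain the moment is
#' `assr_amplitude * envelope(t) * cos(2 pi f t + phi(t))` with trial phase
#' `phi ~ von Mises(0, kappa)`, where `phi(t)` cross-fades from an
#' early-period draw to an independent late-period draw (concentration
#' `kappa_late`) around `kappa_change_time`; plus a Hann-windowed
#' band-limited 30-60 Hz burst over 0-0.1 s with RMS `tgbr_amplitude`.
#' Uses the current RNG stream.
#'
#' @param spec a [source_spec()].
#' @param stimulus a [stimulus_config()].
#' @param times peristimulus time vector in seconds spanning baseline and
#'   stimulus.
#' @return Numeric moment series in nA m (length of `times`), with the
#'   drawn phases in attributes `phase_early` / `phase_late`.
#' @export
simulate_trial_sources <- function(spec, stimulus, times) {
  stopifnot(inherits(spec, "source_spec"), inherits(stimulus, "stimulus_config"))
  if (min(times) > 0 || max(times) < stimulus$train_duration)
    warning("times do not span baseline and full stimulus period")
  f <- spec$assr_frequency
  phi_e <- rvonmises(1, 0, spec$phase_jitter_kappa)
  phi_l <- rvonmises(1, 0, spec$kappa_late)
  mix <- smooth_step(times, spec$kappa_change_time - 0.05, 0.1)
  # interpolate along the shorter arc so the cross-fade is rotation-free
  dphi <- wrap_pi(phi_l - phi_e)
  phi_t <- phi_e + mix * dphi
  env <- assr_envelope(spec, stimulus, times)
  x <- spec$assr_amplitude * env * cos(2 * pi * f * times + phi_t)
  if (spec$tgbr_amplitude > 0) {
    x <- x + tgbr_burst(spec, times)
  }
  attr(x, "phase_early") <- phi_e
  attr(x, "phase_late") <- phi_l
  x
}

# All-trials source moment matrix (samples x trials); vectorised
# equivalent of repeated simulate_trial_sources() calls, drawing all
# early phases, then all late phases, then all transient bursts.
simulate_source_matrix <- function(spec, stimulus, times, ntr) {
  ns <- length(times)
  phi_e <- rvonmises(ntr, 0, spec$phase_jitter_kappa)
  phi_l <- rvonmises(ntr, 0, spec$kappa_late)
  mix <- smooth_step(times, spec$kappa_change_time - 0.05, 0.1)
  dphi <- wrap_pi(phi_l - phi_e)
  Phi <- matrix(phi_e, ns, ntr, byrow = TRUE) + outer(mix, dphi)
  env <- assr_envelope(spec, stimulus, times)
  M <- (spec$assr_amplitude * env) *
    cos(2 * pi * spec$assr_frequency * times + Phi)
  if (spec$tgbr_amplitude > 0) {
    sel <- which(times >= 0 & times <= 0.1)
    if (length(sel)) {
      sfreq <- 1 / median(diff(times))
      nb <- length(sel)
      pad <- max(2 * nb, 200)
      wn <- matrix(rnorm((nb + 2 * pad) * ntr), nb + 2 * pad, ntr)
      sos <- butter_sos(4L, c(30, 60), "pass", sfreq)
      bn <- sosfiltfilt(wn, sos)[pad + seq_len(nb), , drop = FALSE]
      w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nb))
      burst <- bn * w
      rms <- sqrt(colMeans(burst^2))
      rms[rms == 0] <- 1
      burst <- sweep(burst, 2, spec$tgbr_amplitude / rms, `*`)
      M[sel, ] <- M[sel, ] + burst
    }
  }
  list(M = M, phase_early = phi_e, phase_late = phi_l)
}

# Hann-windowed 30-60 Hz noise burst over 0-0.1 s, RMS-calibrated
tgbr_burst <- function(spec, times) {
  sfreq <- 1 / median(diff(times))
  sel <- times >= 0 & times <= 0.1
  if (!any(sel)) return(numeric(length(times)))
  # band-limit a longer noise stretch to avoid filter edge effects
  nb <- sum(sel)
  pad <- max(2 * nb, 200)
  wn <- rnorm(nb + 2 * pad)
  sos <- butter_sos(4L, c(30, 60), "pass", sfreq)
  bn <- sosfiltfilt(wn, sos)[pad + seq_len(nb)]
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = nb))
  burst <- bn * w
  rms <- sqrt(mean(burst^2))
  if (rms > 0) burst <- burst * spec$tgbr_amplitude / rms
  out <- numeric(length(times))
  out[sel] <- burst
  out
}
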