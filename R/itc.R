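# Inter-trial coherence: the magnitude of the mean unit-normalised complex
# spectral coefficient across trials. 0 = no phase consistency across
# trials, 1 = perfect consistency; amplitude-normalised by construction.

#' Inter-trial coherence from multitaper complex spectra
#'
#' Per (frequency, time) bin the coefficients are normalised to unit
#' magnitude, averaged across trials, and the magnitude taken; this is
#' done per taper and then averaged over tapers (which preserves the
#' `[0, 1]` range and the uniform-phase null distribution). Bins where a
#' trial has an exactly zero coefficient exclude that trial at that bin
#' (count recorded in `n_excluded`).
#'
#' @param x a [mtm_tfr()] result or a complex array
#'   `trials x tapers x freqs x times`.
#' @return Object of class `"itc_result"`: `itc` and `z` (freqs x times),
#'   `times`, `freqs`, `n_trials`, `n_excluded`.
#' @export
compute_itc <- function(x) {
  if (inherits(x, "tfr_result")) {
    coef <- x$coef; times <- x$times; freqs <- x$freqs
  } else {
    coef <- x; times <- seq_len(dim(x)[4]); freqs <- seq_len(dim(x)[3])
  }
  stopifnot(length(dim(coef)) == 4)
  ntr <- dim(coef)[1]
  if (ntr < 2) stop("ITC needs at least 2 trials", call. = FALSE)
  mod <- Mod(coef)
  zero <- mod == 0
  n_excluded <- sum(zero)
  u <- coef
  u[!zero] <- coef[!zero] / mod[!zero]
  u[zero] <- 0 + 0i
  # mean over trials of unit vectors; denominator excludes zero bins
  sums <- apply(u, c(2, 3, 4), sum)
  ns <- apply(!zero, c(2, 3, 4), sum)
  r_k <- Mod(sums) / pmax(ns, 1)
  itc <- apply(r_k, c(2, 3), mean)     # average over tapers
  z <- itc_to_z(itc, ntr)
  structure(list(itc = itc, z = z, times = times, freqs = freqs,
                 n_trials = ntr, n_excluded = n_excluded),
            class = "itc_result")
}

#' @export
print.itc_result <- function(x, ...) {
  cat(sprintf("<itc_result> %d trials, %d freqs x %d times, ITC in [%.3f, %.3f]\n",
              x$n_trials, nrow(x$itc), ncol(x$itc),
              min(x$itc), max(x$itc)))
  invisible(x)
}

#' Rayleigh-style Z conversion of ITC
#'
#' `Z = n_trials * ITC^2`, the Rayleigh test statistic of the trial phase
#' distribution; under uniform phases Z is approximately unit-mean
#' exponential, which normalises ITC for parametric-style statistics.
#'
#' @param itc ITC value(s) in `[0, 1]`.
#' @param n_trials number of trials.
#' @return Z value(s), `>= 0`, `0` iff `itc = 0`.
#' @export
itc_to_z <- function(itc, n_trials) {
  stopifnot(n_trials >= 2, all(itc >= -1e-12), all(itc <= 1 + 1e-12))
  n_trials * itc^2
}

#' Band-averaged ITC time course (and its Z conversion)
#'
#' Averages ITC over a frequency band per window centre, then Z-converts
#' the band-averaged value (the alternative — Z first, average second — is
#' not used; see the methods vignette).
#'
#' @param itc_result a [compute_itc()] result.
#' @param band `c(low, high)` in Hz; default the full frequency range.
#' @return List with `itc` and `z` vectors over window centres, attribute
#'   `times`.
#' @export
itc_band_timecourse <- function(itc_result, band = NULL) {
  stopifnot(inherits(itc_result, "itc_result"))
  if (is.null(band)) band <- range(itc_result$freqs)
  fsel <- itc_result$freqs >= band[1] - 1e-9 &
    itc_result$freqs <= band[2] + 1e-9
  stopifnot(any(fsel))
  itc <- colMeans(itc_result$itc[fsel, , drop = FALSE])
  out <- list(itc = itc, z = itc_to_z(itc, itc_result$n_trials))
  attr(out, "times") <- itc_result$times
  out
}
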