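# DPSS multitaper sliding-window spectral estimation. Tapers are computed
# from the classical tridiagonal eigenproblem; per-taper complex spectra
# are retained so inter-trial coherence can be computed from the same
# decomposition as power.

#' Discrete prolate spheroidal sequence (Slepian) tapers
#'
#' Orthonormal tapers maximising spectral concentration in a
#' `+/- W = TW / n_samples` band, via the symmetric tridiagonal
#' formulation. Concentration eigenvalues are evaluated against the exact
#' sinc kernel.
#'
#' @param n_samples taper length.
#' @param TW time-bandwidth product (`window_length * half_bandwidth`).
#' @param K number of tapers; default `floor(2 TW) - 1`. A warning is
#'   issued above `2 TW - 1` where concentration degrades.
#' @return `n_samples x K` matrix with attribute `"concentration"`.
#' @export
dpss_tapers <- function(n_samples, TW, K = floor(2 * TW) - 1) {
  stopifnot(TW >= 1)
  if (K < 1) stop("K must be >= 1 (TW too small?)", call. = FALSE)
  if (K > 2 * TW - 1)
    warning("K > 2 TW - 1: highest tapers are poorly concentrated")
  N <- n_samples
  W <- TW / N
  t <- 0:(N - 1)
  dg <- ((N - 1 - 2 * t) / 2)^2 * cos(2 * pi * W)
  off <- t[-1] * (N - t[-1]) / 2
  A <- matrix(0, N, N)
  diag(A) <- dg
  A[cbind(1:(N - 1), 2:N)] <- off
  A[cbind(2:N, 1:(N - 1))] <- off
  eg <- eigen(A, symmetric = TRUE)
  tapers <- eg$vectors[, seq_len(K), drop = FALSE]
  # unit norm and standard polarity: symmetric tapers positive mean,
  # antisymmetric tapers positive initial slope
  for (k in seq_len(K)) {
    w <- tapers[, k]
    w <- w / sqrt(sum(w^2))
    if (abs(sum(w)) > 1e-8) {
      if (sum(w) < 0) w <- -w
    } else if (w[2] - w[1] < 0) w <- -w
    tapers[, k] <- w
  }
  # concentration via the exact kernel
  m <- outer(t, t, `-`)
  S <- ifelse(m == 0, 2 * W, sin(2 * pi * W * m) / (pi * m))
  conc <- vapply(seq_len(K), function(k)
    drop(crossprod(tapers[, k], S %*% tapers[, k])), numeric(1))
  attr(tapers, "concentration") <- conc
  tapers
}

#' Multitaper analysis specification
#'
#' @param window_length sliding-window length in seconds (default 0.5).
#' @param step window step in seconds (default 0.02).
#' @param half_bandwidth spectral smoothing half-width in Hz (default 5,
#'   i.e. +/- 5 Hz).
#' @param foi frequencies of interest in Hz (default 35:45, the
#'   steady-state band; use `30:60` for the transient gamma burst).
#' @param toi window-centre times in seconds; `NULL` = every step within
#'   the feasible span of `[-1.5, 1.5]`.
#' @return Object of class `"multitaper_spec"`. Taper count is
#'   `floor(2 TW) - 1` (4 at the defaults).
#' @export
multitaper_spec <- function(window_length = 0.5, step = 0.02,
                            half_bandwidth = 5, foi = 35:45, toi = NULL) {
  TW <- window_length * half_bandwidth
  if (TW < 1) stop("time-bandwidth product must be >= 1", call. = FALSE)
  structure(list(window_length = window_length, step = step,
                 half_bandwidth = half_bandwidth, foi = as.numeric(foi),
                 toi = toi, TW = TW, K = max(1L, floor(2 * TW) - 1L)),
            class = "multitaper_spec")
}

#' Sliding-window multitaper time-frequency transform
#'
#' Computes per-trial, per-taper complex Fourier coefficients at the
#' frequencies of interest in each sliding window, and a trial-averaged
#' power estimate calibrated so that a unit-amplitude sinusoid at a bin
#' frequency yields `amplitude^2 / 2 = 0.5`.
#'
#' @param trials matrix `trials x samples` (e.g. a virtual electrode from
#'   [virtual_electrode()]), with `times`/`sfreq` attributes, or supply
#'   them explicitly.
#' @param spec a [multitaper_spec()].
#' @param times,sfreq time axis (s) and sampling rate (Hz); defaults taken
#'   from attributes of `trials`.
#' @return Object of class `"tfr_result"`: `times` (window centres),
#'   `freqs`, `power` (freqs x times, trial-averaged, calibrated), `coef`
#'   (complex array trials x tapers x freqs x times), `n_trials`, `spec`.
#' @export
mtm_tfr <- function(trials, spec = multitaper_spec(), times = NULL,
                    sfreq = NULL) {
  if (is.null(dim(trials))) trials <- matrix(trials, nrow = 1)
  times <- times %||% attr(trials, "times")
  sfreq <- sfreq %||% attr(trials, "sfreq")
  if (is.null(times) || is.null(sfreq))
    stop("supply times and sfreq (attributes or arguments)", call. = FALSE)
  n_win <- round(spec$window_length * sfreq)
  half <- spec$window_length / 2
  toi <- spec$toi
  if (is.null(toi)) {
    lo <- max(-1.5, min(times) + half)
    hi <- min(1.5, max(times) - half + 1 / sfreq)
    toi <- seq(ceiling(lo / spec$step) * spec$step,
               floor(hi / spec$step) * spec$step, by = spec$step)
  }
  if (min(toi) - half < min(times) - 1e-9 ||
      max(toi) + half - 1 / sfreq > max(times) + 1e-9)
    stop("analysis window extends past the padded epoch; ",
         "shorten toi or provide more padding", call. = FALSE)
  tapers <- dpss_tapers(n_win, spec$TW, spec$K)
  K <- ncol(tapers)
  Fq <- length(spec$foi)
  ntr <- nrow(trials)
  # amplitude calibration: 2 / mean_k (sum_t w_k)^2
  cal <- 2 / mean(colSums(tapers)^2)
  tloc <- (seq_len(n_win) - (n_win + 1) / 2) / sfreq
  phase <- exp(-2i * pi * outer(tloc, spec$foi))   # n_win x F
  P <- matrix(0 + 0i, n_win, K * Fq)
  for (k in seq_len(K)) P[, (k - 1) * Fq + seq_len(Fq)] <-
    tapers[, k] * phase
  Pre <- Re(P); Pim <- Im(P)
  coef <- array(0 + 0i, dim = c(ntr, K, Fq, length(toi)))
  power <- matrix(0, Fq, length(toi))
  for (ci in seq_along(toi)) {
    i0 <- which.min(abs(times - (toi[ci] - half)))
    idx <- i0:(i0 + n_win - 1)
    X <- trials[, idx, drop = FALSE]
    Cc <- X %*% Pre + 1i * (X %*% Pim)       # ntr x (K*F)
    dim(Cc) <- c(ntr, Fq, K)
    coef[, , , ci] <- aperm(Cc, c(1, 3, 2))
    power[, ci] <- cal * apply(Mod(Cc)^2, 2, mean)
  }
  structure(list(times = toi, freqs = spec$foi, power = power, coef = coef,
                 n_trials = ntr, spec = spec, calibration = cal),
            class = "tfr_result")
}

#' @export
print.tfr_result <- function(x, ...) {
  cat(sprintf(
    "<tfr_result> %d trials, %d freqs (%g-%g Hz), %d windows, K = %d tapers\n",
    x$n_trials, length(x$freqs), min(x$freqs), max(x$freqs),
    length(x$times), dim(x$coef)[2]))
  invisible(x)
}

#' Band-averaged percent-change power time course
#'
#' Averages power over the band first (the literal order of the analysis),
#' then expresses each window centre as percent change from the mean over
#' baseline window centres.
#'
#' @param tfr a [mtm_tfr()] result.
#' @param band `c(low, high)` in Hz (default the full FOI range).
#' @param base_window baseline window-centre range in seconds (default
#'   `c(-1.5, 0)`).
#' @return Numeric vector over window centres with attribute `times`.
#' @export
percent_change_timecourse <- function(tfr, band = NULL,
                                      base_window = c(-1.5, 0)) {
  stopifnot(inherits(tfr, "tfr_result"))
  if (is.null(band)) band <- range(tfr$freqs)
  fsel <- tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9
  stopifnot(any(fsel))
  p <- colMeans(tfr$power[fsel, , drop = FALSE])
  bsel <- time_mask(tfr$times, base_window)
  if (!any(bsel)) stop("baseline window contains no window centres",
                       call. = FALSE)
  pb <- mean(p[bsel])
  if (pb <= 0) stop("zero baseline power", call. = FALSE)
  out <- 100 * (p - pb) / pb
  attr(out, "times") <- tfr$times
  out
}

#' Transient gamma-band percent change (scalar)
#'
#' Power averaged over the 30-60 Hz band and over window centres in the
#' transient window, as percent change from the pre-stimulus window.
#'
#' @param tfr a [mtm_tfr()] result computed over the 30-60 Hz band.
#' @param stim_window transient window in seconds (default `c(0, 0.1)`).
#' @param base_window baseline window in seconds (default `c(-0.1, 0)`).
#' @param band averaging band in Hz (default `c(30, 60)`).
#' @return Single percent-change value.
#' @export
tgbr_percent_change <- function(tfr, stim_window = c(0, 0.1),
                                base_window = c(-0.1, 0),
                                band = c(30, 60)) {
  stopifnot(inherits(tfr, "tfr_result"))
  fsel <- tfr$freqs >= band[1] - 1e-9 & tfr$freqs <= band[2] + 1e-9
  p <- colMeans(tfr$power[fsel, , drop = FALSE])
  ssel <- time_mask(tfr$times, stim_window)
  bsel <- time_mask(tfr$times, base_window)
  if (!any(ssel) || !any(bsel))
    stop("tGBR windows contain no window centres", call. = FALSE)
  pb <- mean(p[bsel])
  if (pb <= 0) stop("zero baseline power", call. = FALSE)
  100 * (mean(p[ssel]) - pb) / pb
}
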