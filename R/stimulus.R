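#' Clicktrain stimulus configuration
#'
#' Periodic train of brief square-wave clicks. With the defaults (2 ms
#' clicks every 25 ms for 1.5 s) the train carries a 40 Hz modulation rate,
#' the frequency at which auditory cortex entrains most strongly.
#'
#' @param click_duration click length in seconds (default 0.002).
#' @param inter_click_interval click period in seconds (default 0.025);
#'   its reciprocal is the entrainment frequency.
#' @param train_duration total train length in seconds (default 1.5).
#' @param amplitude click amplitude, arbitrary units.
#' @return Object of class `"stimulus_config"`.
#' @export
stimulus_config <- function(click_duration = 0.002,
                            inter_click_interval = 0.025,
                            train_duration = 1.5, amplitude = 1) {
  stopifnot(click_duration > 0, click_duration < inter_click_interval,
            train_duration > 0)
  structure(list(click_duration = click_duration,
                 inter_click_interval = inter_click_interval,
                 train_duration = train_duration, amplitude = amplitude),
            class = "stimulus_config")
}

#' Modulation (entrainment) frequency of a clicktrain
#' @param cfg a [stimulus_config()].
#' @return Frequency in Hz (`1 / inter_click_interval`).
#' @export
clicktrain_rate <- function(cfg) 1 / cfg$inter_click_interval

#' Sample a clicktrain waveform
#'
#' Rectangular pulses of `click_duration` at `inter_click_interval`
#' spacing, zero outside `[0, train_duration)`. The number of clicks is
#' `floor(train_duration / inter_click_interval)`.
#'
#' @param cfg a [stimulus_config()].
#' @param sfreq sampling rate in Hz; must satisfy
#'   `sfreq >= 2 / click_duration` so each click spans at least two samples.
#' @return Numeric vector sampled at `t = 0, 1/sfreq, ...,
#'   train_duration - 1/sfreq`, with a `"times"` attribute.
#' @export
make_clicktrain <- function(cfg, sfreq) {
  stopifnot(inherits(cfg, "stimulus_config"))
  if (sfreq < 2 / cfg$click_duration)
    stop(sprintf(
      "sfreq = %g Hz cannot represent a %g ms click (need >= %g Hz)",
      sfreq, 1000 * cfg$click_duration, 2 / cfg$click_duration),
      call. = FALSE)
  n <- round(cfg$train_duration * sfreq)
  idx <- seq_len(n) - 1L
  period <- cfg$inter_click_interval * sfreq
  click_len <- cfg$click_duration * sfreq
  n_clicks <- floor(cfg$train_duration / cfg$inter_click_interval)
  phase <- idx - period * floor(idx / period + 1e-9)
  x <- ifelse(phase < click_len - 1e-9 &
                idx < n_clicks * period - 1e-9,
              cfg$amplitude, 0)
  attr(x, "times") <- idx / sfreq
  x
}
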