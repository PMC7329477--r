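# Pre-processing chain: zero-phase Butterworth filtering, epoching with
# per-trial linear detrend, variance-based trial rejection, and
# anti-aliased resampling (1000 -> 200 Hz in the default pipeline).

#' Filter epoched (or continuous) data
#'
#' Applies a list of [filter_spec()]s in sequence, each as a zero-phase
#' forward-backward second-order-section Butterworth cascade. Epochs carry
#' their padding, and additional reflection padding is used internally, so
#' the analysis window stays free of edge transients.
#'
#' @param epochs an [epoched_data()] object.
#' @param specs a [filter_spec()] or list of them (default
#'   [default_filter_chain()]).
#' @return A filtered [epoched_data()] object.
#' @export
filter_data <- function(epochs, specs = default_filter_chain()) {
  stopifnot(inherits(epochs, "epoched_data"))
  if (inherits(specs, "filter_spec")) specs <- list(specs)
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(3, 2, 1)), d[3], d[2] * d[1])
  for (sp in specs) {
    for (sos in design_filter(sp, epochs$sfreq)) {
      m <- sosfiltfilt(m, sos)
    }
  }
  out <- epochs
  out$data <- aperm(array(m, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  out$provenance$filters <- c(out$provenance$filters,
                              lapply(specs, unclass))
  out
}

# remove per-column linear trend (implies demeaning); closed form
detrend_matrix <- function(m) {
  n <- nrow(m)
  tc <- seq_len(n) - (n + 1) / 2
  m <- sweep(m, 2, colMeans(m))
  m - tcrossprod(tc, drop(crossprod(tc, m)) / sum(tc^2))
}

#' Epoch continuous data and detrend each trial
#'
#' Cuts trials of `window + pad` around each event and removes a linear
#' trend (hence also the mean) from every trial and channel over the full
#' padded epoch. Events too close to the record edges are dropped with a
#' message.
#'
#' @param continuous list with `data` (channels x samples matrix), `sfreq`,
#'   and optionally `channels`.
#' @param event_samples integer sample indices of stimulus onsets (1-based).
#' @param window analysis window in seconds relative to onset, e.g.
#'   `c(-1.5, 1.5)`.
#' @param pad extra padding either side in seconds (default 0.5).
#' @return An [epoched_data()] object.
#' @export
epoch_and_detrend <- function(continuous, event_samples,
                              window = c(-1.5, 1.5), pad = 0.5) {
  fs <- continuous$sfreq
  pre <- round((window[1] - pad) * fs)
  post <- round((window[2] + pad) * fs) - 1L
  nsamp_rec <- ncol(continuous$data)
  ok <- (event_samples + pre >= 1) & (event_samples + post <= nsamp_rec)
  if (any(!ok))
    message(sum(!ok), " event(s) too close to the record edge; dropped")
  ev <- event_samples[ok]
  if (length(ev) == 0) stop("no epochable events", call. = FALSE)
  nsamp <- post - pre + 1L
  nch <- nrow(continuous$data)
  data <- array(0, dim = c(length(ev), nch, nsamp))
  for (i in seq_along(ev)) {
    seg <- continuous$data[, ev[i] + pre:post, drop = FALSE]
    data[i, , ] <- t(detrend_matrix(t(seg)))
  }
  times <- (pre:post) / fs
  epoched_data(data, times, fs, continuous$channels,
               provenance = list(epoching = list(window = window, pad = pad,
                                                 n_events_dropped = sum(!ok))))
}

#' Detrend each trial of epoched data
#'
#' Per-trial, per-channel linear detrend (implies demeaning) over the full
#' padded epoch; idempotent.
#'
#' @param epochs an [epoched_data()] object.
#' @return Detrended [epoched_data()].
#' @export
detrend_epochs <- function(epochs) {
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(3, 2, 1)), d[3], d[2] * d[1])
  m <- detrend_matrix(m)
  epochs$data <- aperm(array(m, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  epochs
}

#' Reject trials by excessive variance
#'
#' Summarises each trial's per-channel variance by its maximum over
#' channels (the sum is recorded too) and removes trials above a threshold.
#' `threshold = "auto"` (the default) sets it to `median + k * MAD` of the
#' per-trial summaries, a portable stand-in for an absolute Tesla-scale
#' screen; an absolute numeric threshold may be supplied instead.
#'
#' @param epochs an [epoched_data()] object.
#' @param threshold `"auto"` or a numeric variance threshold.
#' @param k MAD multiplier for auto mode (default 8).
#' @return List with elements `epochs` (kept trials) and `report`
#'   (class `"rejection_report"`: per-trial `var_max`/`var_sum`,
#'   `threshold`, logical `kept`).
#' @export
reject_trials_by_variance <- function(epochs, threshold = "auto", k = 8) {
  stopifnot(inherits(epochs, "epoched_data"), n_trials(epochs) >= 1)
  d <- dim(epochs$data)
  v <- matrix(0, d[1], d[2])
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, , , drop = FALSE]
    dim(x) <- d[2:3]
    mu <- rowMeans(x)
    v[tr, ] <- rowSums((x - mu)^2) / (d[3] - 1)
  }
  var_max <- apply(v, 1, max)
  var_sum <- rowSums(v)
  thr <- if (identical(threshold, "auto")) {
    median(var_max) + k * mad(var_max)
  } else as.numeric(threshold)
  kept <- var_max <= thr
  if (!any(kept)) stop("all trials rejected by variance screen",
                       call. = FALSE)
  report <- structure(list(var_max = var_max, var_sum = var_sum,
                           threshold = thr, kept = kept,
                           n_rejected = sum(!kept)),
                      class = "rejection_report")
  out <- epochs
  out$data <- epochs$data[kept, , , drop = FALSE]
  out$provenance$rejection <- list(threshold = thr, n_rejected = sum(!kept))
  list(epochs = out, report = report)
}

#' @export
print.rejection_report <- function(x, ...) {
  cat(sprintf("<rejection_report> %d/%d trials kept (threshold %.3g)\n",
              sum(x$kept), length(x$kept), x$threshold))
  invisible(x)
}

#' Write a rejection report as JSON
#' @param report a `"rejection_report"`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rejection_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Resample epoched data to a lower rate
#'
#' Applies a zero-phase anti-alias low-pass (Butterworth order 8 at 0.8 x
#' the new Nyquist) and decimates by an integer factor; the time axis is
#' recomputed exactly.
#'
#' @param epochs an [epoched_data()] object.
#' @param new_sfreq target rate in Hz; must divide `sfreq` and keep the
#'   35-45 Hz analysis band below the anti-alias edge.
#' @return Resampled [epoched_data()].
#' @export
resample_epochs <- function(epochs, new_sfreq) {
  stopifnot(inherits(epochs, "epoched_data"))
  fs <- epochs$sfreq
  if (new_sfreq >= fs) stop("new_sfreq must be below the current rate",
                            call. = FALSE)
  if (0.8 * new_sfreq / 2 <= 45)
    stop("new_sfreq = ", new_sfreq,
         " Hz would alias or attenuate the 35-45 Hz analysis band",
         call. = FALSE)
  factor <- fs / new_sfreq
  if (abs(factor - round(factor)) > 1e-9)
    stop("resampling requires an integer decimation factor (got ",
         fs, " -> ", new_sfreq, ")", call. = FALSE)
  factor <- as.integer(round(factor))
  sos <- butter_sos(8L, 0.8 * new_sfreq / 2, "low", fs)
  d <- dim(epochs$data)
  m <- matrix(aperm(epochs$data, c(3, 2, 1)), d[3], d[2] * d[1])
  m <- sosfiltfilt(m, sos)
  pick <- seq(1, d[3], by = factor)
  m <- m[pick, , drop = FALSE]
  out <- epochs
  out$data <- aperm(array(m, dim = c(length(pick), d[2], d[1])), c(3, 2, 1))
  out$times <- epochs$times[pick]
  out$sfreq <- new_sfreq
  out$provenance$resampled_from <- fs
  out
}
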