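# Butterworth IIR design in zero-pole-gain form, realised as second-order
# sections and applied forward-backward (zero-phase). Orders follow the
# acquisition convention: broadband 0.5-250 Hz as cascaded high-pass
# (order 3) and low-pass (order 4), band-stops at 49.5-50.5 and
# 99.5-100.5 Hz for line noise.

#' Specify a frequency-domain filter
#'
#' @param kind one of `"low"`, `"high"`, `"pass"`, `"stop"`.
#' @param edges numeric band edges in Hz: one value for `"low"`/`"high"`,
#'   two (low, high) for `"pass"`/`"stop"`.
#' @param order filter order. For `"pass"` a length-2 order
#'   `c(high_pass, low_pass)` requests a cascade of a high-pass and a
#'   low-pass Butterworth section instead of a true band-pass transform
#'   (the convention used for the broadband 0.5-250 Hz filter).
#' @return An object of class `"filter_spec"`.
#' @export
filter_spec <- function(kind = c("pass", "stop", "low", "high"),
                        edges, order = 4L) {
  kind <- match.arg(kind)
  edges <- as.numeric(edges)
  if (kind %in% c("pass", "stop")) {
    stopifnot(length(edges) == 2L, edges[1] > 0, edges[1] < edges[2])
  } else {
    stopifnot(length(edges) == 1L, edges > 0)
  }
  stopifnot(all(order >= 1))
  structure(list(kind = kind, edges = edges, order = as.integer(order)),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat(sprintf("<filter_spec> band-%s %s Hz, Butterworth order %s, zero-phase\n",
              x$kind, paste(x$edges, collapse = "-"),
              paste(x$order, collapse = "/")))
  invisible(x)
}

butter_proto_poles <- function(n) {
  k <- seq_len(n)
  exp(1i * pi * (2 * k + n - 1) / (2 * n))
}

# Returns list(sos = K x 6 matrix) for a digital Butterworth filter.
butter_sos <- function(order, edges, kind, sfreq) {
  nyq <- sfreq / 2
  if (any(edges <= 0) || any(edges >= nyq))
    stop("filter edges must lie strictly between 0 and Nyquist (",
         nyq, " Hz)", call. = FALSE)
  fs2 <- 2 * sfreq
  warp <- function(f) fs2 * tan(pi * f / sfreq)
  q <- butter_proto_poles(order)
  if (kind == "low") {
    wc <- warp(edges)
    p <- wc * q; z <- complex(0)
  } else if (kind == "high") {
    wc <- warp(edges)
    p <- wc / q; z <- rep(0 + 0i, order)
  } else {
    w1 <- warp(edges[1]); w2 <- warp(edges[2])
    w0 <- sqrt(w1 * w2); bw <- w2 - w1
    if (kind == "pass") {
      a <- q * bw / 2
      s <- sqrt(a^2 - w0^2)
      p <- c(a + s, a - s)
      z <- rep(0 + 0i, order)
    } else { # stop
      a <- (bw / 2) / q
      s <- sqrt(a^2 - w0^2)
      p <- c(a + s, a - s)
      z <- rep(c(1i * w0, -1i * w0), order)
    }
  }
  if (any(Re(p) >= 0))
    stop("unstable analog prototype (pole in right half-plane)", call. = FALSE)
  pd <- (fs2 + p) / (fs2 - p)
  zd <- (fs2 + z) / (fs2 - z)
  # bilinear maps the n_extra zeros at analog infinity to z = -1
  zd <- c(zd, rep(-1 + 0i, length(pd) - length(zd)))
  if (any(abs(pd) >= 1))
    stop("unstable digital filter at the requested order/edges; ",
         "use second-order sections with a milder design", call. = FALSE)
  sos <- zpk_to_sos(zd, pd)
  # unit gain at a reference frequency inside the passband
  fref <- switch(kind,
                 low = 0, stop = 0, high = nyq * (1 - 1e-9),
                 pass = atan(sqrt(warp(edges[1]) * warp(edges[2])) / fs2) *
                   sfreq / pi)
  h <- freqz_sos(sos, fref, sfreq)
  sos[1, 1:3] <- sos[1, 1:3] / abs(h)
  sos
}

# Pair conjugate poles/zeros into biquads. All designs here produce zeros in
# conjugate pairs or at +-1, so pairing is by sorted angle.
zpk_to_sos <- function(z, p) {
  pick_pairs <- function(r) {
    r <- r[order(abs(Im(r)) > 1e-9, Re(r), Im(r))]
    real_r <- r[abs(Im(r)) <= 1e-9]
    cplx <- r[abs(Im(r)) > 1e-9]
    cplx <- cplx[Im(cplx) > 0]
    pairs <- list()
    for (cc in cplx) pairs[[length(pairs) + 1L]] <- c(cc, Conj(cc))
    i <- 1L
    while (i <= length(real_r)) {
      if (i + 1L <= length(real_r)) {
        pairs[[length(pairs) + 1L]] <- real_r[i:(i + 1L)]
        i <- i + 2L
      } else {
        pairs[[length(pairs) + 1L]] <- real_r[i]
        i <- i + 1L
      }
    }
    pairs
  }
  pp <- pick_pairs(p)
  zz <- pick_pairs(z)
  K <- length(pp)
  stopifnot(length(zz) <= K)
  sos <- matrix(0, K, 6)
  for (k in seq_len(K)) {
    pk <- pp[[k]]
    zk <- if (k <= length(zz)) zz[[k]] else complex(0)
    a <- Re(poly_from_roots(pk))
    b <- Re(poly_from_roots(zk))
    a <- c(a, rep(0, 3 - length(a)))
    b <- c(b, rep(0, 3 - length(b)))
    sos[k, ] <- c(b, a)
  }
  sos
}

poly_from_roots <- function(r) {
  p <- 1 + 0i
  for (ri in r) p <- c(p, 0) - c(0, p * ri)
  p
}

#' Evaluate the frequency response of a second-order-section filter
#'
#' @param sos K x 6 matrix of biquad coefficients (`b0 b1 b2 a0 a1 a2`).
#' @param f frequencies in Hz at which to evaluate.
#' @param sfreq sampling rate in Hz.
#' @return Complex response values, one per frequency.
#' @export
freqz_sos <- function(sos, f, sfreq) {
  w <- 2 * pi * f / sfreq
  e1 <- exp(-1i * w); e2 <- exp(-2i * w)
  h <- rep(1 + 0i, length(f))
  for (k in seq_len(nrow(sos))) {
    h <- h * (sos[k, 1] + sos[k, 2] * e1 + sos[k, 3] * e2) /
      (sos[k, 4] + sos[k, 5] * e1 + sos[k, 6] * e2)
  }
  h
}

# Per-section steady-state (unit step) internal state for the cascade,
# used to suppress start-up transients.
sos_zi <- function(sos) {
  K <- nrow(sos)
  zi <- matrix(0, K, 2)
  g <- 1
  for (k in seq_len(K)) {
    b <- sos[k, 1:3]; a <- sos[k, 4:6]
    H1 <- sum(b) / sum(a)
    z2 <- (b[3] - a[3] * H1) * g
    z1 <- (b[2] - a[2] * H1) * g + z2
    zi[k, ] <- c(z1, z2)
    g <- g * H1
  }
  zi
}

#' Zero-phase forward-backward filtering of a matrix of time series
#'
#' Applies a cascaded biquad filter forward and backward along the rows
#' (time runs down the rows, each column is an independent series), with
#' odd-reflection end padding and steady-state initial conditions so the
#' analysis window is free of edge transients.
#'
#' @param x numeric matrix (samples x series) or vector.
#' @param sos K x 6 second-order-section coefficient matrix.
#' @param padlen reflection padding length in samples; the default uses
#'   the design's `padlen_hint` attribute (three time constants of the
#'   slowest band edge) when present, else 250, capped at `n - 1`.
#' @return Filtered data with the dimensions of `x`.
#' @export
sosfiltfilt <- function(x, sos, padlen = NULL) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  if (is.null(padlen))
    padlen <- min(n - 1L, max(250L, attr(sos, "padlen_hint") %||% 0L))
  y <- sosfiltfilt_cpp(x, sos, sos_zi(sos), as.integer(padlen))
  if (vec) drop(y) else y
}

# Expand a filter_spec into a list of sos matrices (a cascade).
design_filter <- function(spec, sfreq) {
  stopifnot(inherits(spec, "filter_spec"))
  # reflection padding scaled to the slowest time constant of each stage
  hint <- function(sos, f_low) {
    attr(sos, "padlen_hint") <- ceiling(3 * sfreq / f_low)
    sos
  }
  if (spec$kind == "pass" && length(spec$order) == 2L) {
    list(hint(butter_sos(spec$order[1], spec$edges[1], "high", sfreq),
              spec$edges[1]),
         hint(butter_sos(spec$order[2], spec$edges[2], "low", sfreq),
              spec$edges[2]))
  } else if (spec$kind == "stop") {
    # notch ringing decays within the epoch padding; default padding
    list(butter_sos(spec$order[1], spec$edges, "stop", sfreq))
  } else {
    list(hint(butter_sos(spec$order[1], spec$edges, spec$kind, sfreq),
              min(spec$edges)))
  }
}

#' Default broadband and line-noise filter chain
#'
#' Band-pass 0.5-250 Hz (high-pass order 3, low-pass order 4) plus
#' band-stop filters at 49.5-50.5 Hz and 99.5-100.5 Hz.
#'
#' @return List of [filter_spec()] objects.
#' @export
default_filter_chain <- function() {
  list(filter_spec("pass", c(0.5, 250), c(3L, 4L)),
       filter_spec("stop", c(49.5, 50.5), 4L),
       filter_spec("stop", c(99.5, 100.5), 4L))
}
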