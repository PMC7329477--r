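# LCMV beamforming: covariance estimation and regularisation, scalar
# (optimal-orientation) unit-gain spatial filters, whole-space
# percent-change power maps, ROI filter collapse by PCA, and virtual
# electrodes. Filters are "common": built once from data pooled across
# baseline and stimulus, then applied to both windows.

#' Trial-averaged sensor covariance
#'
#' Average over trials of the per-trial second-moment matrix of the
#' windowed, non-averaged data (averaging over trials first would
#' artificially correlate the sensors). The data are band-passed and
#' detrended upstream, so no additional demeaning is applied; this makes
#' the matrix exactly additive over sub-windows (sample-weighted pooling).
#'
#' @param epochs an [epoched_data()] object.
#' @param window time window in seconds (default the full epoch without
#'   padding is up to the caller; pass e.g. `c(-1.5, 1.5)`).
#' @return Object of class `"sensor_cov"`: `C` (channels x channels),
#'   `window`, `n_samples`, `rank_deficient` flag.
#' @export
compute_covariance <- function(epochs, window = NULL) {
  stopifnot(inherits(epochs, "epoched_data"))
  if (is.null(window)) window <- range(epochs$times)
  sel <- which(time_mask(epochs$times, window))
  if (length(sel) < 2) stop("covariance window contains < 2 samples",
                            call. = FALSE)
  d <- dim(epochs$data)
  C <- matrix(0, d[2], d[2])
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, , sel, drop = FALSE]
    dim(x) <- c(d[2], length(sel))
    C <- C + tcrossprod(x) / length(sel)
  }
  C <- C / d[1]
  C <- (C + t(C)) / 2
  deficient <- length(sel) * d[1] < d[2] ||
    kappa_rank_deficient(C)
  if (deficient)
    warning("covariance looks rank-deficient; regularise before inverting",
            call. = FALSE)
  structure(list(C = C, window = window,
                 n_samples = length(sel) * d[1],
                 n_trials = d[1], rank_deficient = deficient),
            class = "sensor_cov")
}

kappa_rank_deficient <- function(C, tol = 1e-10) {
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  min(ev) < tol * max(ev)
}

#' @export
print.sensor_cov <- function(x, ...) {
  cat(sprintf("<sensor_cov> %d channels, window [%.2f, %.2f] s, n = %d%s\n",
              nrow(x$C), x$window[1], x$window[2], x$n_samples,
              if (isTRUE(x$rank_deficient)) " (rank-deficient)" else ""))
  invisible(x)
}

#' Diagonal-loading regularisation
#'
#' `C + (lambda_pct / 100) * mean(diag(C)) * I` — the standard reading of
#' "lambda 5%". Every eigenvalue increases by exactly the loading term.
#'
#' @param cov a `"sensor_cov"` or plain matrix.
#' @param lambda_pct percentage of the mean sensor power to load
#'   (default 5).
#' @return Same type as `cov`.
#' @export
regularise <- function(cov, lambda_pct = 5) {
  stopifnot(lambda_pct >= 0)
  C <- if (inherits(cov, "sensor_cov")) cov$C else cov
  Cr <- C + (lambda_pct / 100) * mean(diag(C)) * diag(nrow(C))
  if (inherits(cov, "sensor_cov")) {
    cov$C <- Cr
    cov$lambda_pct <- lambda_pct
    cov$rank_deficient <- FALSE
    cov
  } else Cr
}

#' LCMV spatial filters for a leadfield
#'
#' Scalar (optimal-orientation) linearly constrained minimum-variance
#' filters: per vertex the source orientation minimising
#' `u' L' C^-1 L u` (maximum output power under the unit-gain constraint)
#' is found in the tangential subspace of the leadfield (the spherical
#' model's silent radial direction is excluded), then
#' `w = C^-1 l / (l' C^-1 l)`.
#'
#' @param leadfield a [compute_leadfield()] object.
#' @param cov_reg a regularised `"sensor_cov"` (or matrix); must be
#'   invertible.
#' @param band provenance tag, e.g. `"ASSR"` or `"tGBR"`, recorded so the
#'   separate filter banks cannot be cross-used silently.
#' @return Object of class `"spatial_filters"`: `W` (vertices x channels),
#'   `ori` (vertices x 3), `pos`, `band`.
#' @export
lcmv_filters <- function(leadfield, cov_reg, band = "ASSR") {
  stopifnot(inherits(leadfield, "leadfield"))
  C <- if (inherits(cov_reg, "sensor_cov")) cov_reg$C else cov_reg
  Ci <- tryCatch(solve(C), error = function(e)
    stop("covariance is singular; apply regularise() first", call. = FALSE))
  nv <- dim(leadfield$gain)[3]
  nch <- dim(leadfield$gain)[2]
  W <- matrix(0, nv, nch)
  ori <- matrix(0, nv, 3)
  for (v in seq_len(nv)) {
    L <- t(leadfield$gain[, , v])      # nch x 3
    sv <- svd(L)
    keep <- sv$d > 1e-6 * sv$d[1]
    V <- sv$v[, keep, drop = FALSE]
    Lr <- L %*% V                      # nch x k
    G <- crossprod(Lr, Ci %*% Lr)
    u <- eigen((G + t(G)) / 2, symmetric = TRUE)$vectors[, ncol(G)]
    o <- drop(V %*% u)
    if (o[which.max(abs(o))] < 0) o <- -o
    l <- drop(L %*% o)
    cil <- Ci %*% l
    W[v, ] <- cil / drop(crossprod(l, cil))
    ori[v, ] <- o
  }
  structure(list(W = W, ori = ori, pos = leadfield$pos, band = band,
                 sensors = leadfield$sensors),
            class = "spatial_filters")
}

#' @export
print.spatial_filters <- function(x, ...) {
  cat(sprintf("<spatial_filters> %d vertices x %d channels [%s band]\n",
              nrow(x$W), ncol(x$W), x$band))
  invisible(x)
}

#' Whole-space percent-change source power map
#'
#' Applies common filters to band-limited epochs and contrasts mean squared
#' filter output in a stimulus window against a baseline window:
#' `100 * (P_stim - P_base) / P_base` per vertex. The filters must have
#' been estimated from the pooled window of the same band-passed data
#' (common-filter contract).
#'
#' @param filters a [lcmv_filters()] object.
#' @param epochs band-passed [epoched_data()].
#' @param stim_window,base_window windows in seconds.
#' @return `data.frame` (class `"source_power_map"`): vertex positions and
#'   `pct_change`.
#' @export
source_power_map <- function(filters, epochs, stim_window, base_window) {
  stopifnot(inherits(filters, "spatial_filters"),
            inherits(epochs, "epoched_data"),
            ncol(filters$W) == n_channels(epochs))
  p_stim <- window_power(filters$W, epochs, stim_window)
  p_base <- window_power(filters$W, epochs, base_window)
  if (any(p_base <= 0)) stop("zero baseline power", call. = FALSE)
  out <- data.frame(x = filters$pos[, 1], y = filters$pos[, 2],
                    z = filters$pos[, 3],
                    pct_change = 100 * (p_stim - p_base) / p_base)
  class(out) <- c("source_power_map", "data.frame")
  out
}

# mean squared filter output per vertex over a window, averaged over trials
window_power <- function(W, epochs, window) {
  sel <- which(time_mask(epochs$times, window))
  d <- dim(epochs$data)
  acc <- numeric(nrow(W))
  for (tr in seq_len(d[1])) {
    x <- epochs$data[tr, , sel, drop = FALSE]
    dim(x) <- c(d[2], length(sel))
    y <- W %*% x
    acc <- acc + rowMeans(y^2)
  }
  acc / d[1]
}

#' Vertices within a radius of a point
#'
#' Geometric ROI definition: all source-grid vertices within `radius` of a
#' canonical position (stand-in for an atlas parcel).
#'
#' @param pos `n x 3` vertex positions (or a `"source_space"` /
#'   `"spatial_filters"` object).
#' @param centre length-3 position in metres.
#' @param radius inclusion radius in metres (default 0.015).
#' @return Integer vertex indices.
#' @export
roi_vertices <- function(pos, centre, radius = 0.015) {
  if (inherits(pos, "source_space")) pos <- pos$pos
  if (inherits(pos, "spatial_filters")) pos <- pos$pos
  d2 <- rowSums(sweep(pos, 2, centre)^2)
  idx <- which(d2 <= radius^2)
  if (length(idx) == 0) stop("empty ROI at the requested radius",
                             call. = FALSE)
  idx
}

#' Collapse the filters of an ROI into one spatial filter
#'
#' Stacks the ROI's vertex filters row-wise, right-multiplies by the sensor
#' covariance, and takes the first principal component of the resulting
#' matrix — its leading right singular vector — as the ROI weight vector
#' (sign-aligned with the mean ROI filter). The covariance weighting is
#' essential: it aligns the ROI electrode with the data-dominant source
#' component, and unlike a plain recombination of the unit-gain vertex
#' filters it does not self-normalise away amplitude differences between
#' subjects (minimum-variance electrodes trade noise gain against
#' interference power, which flattens percent-change contrasts when
#' bilateral sources are correlated). A one-vertex ROI therefore returns
#' its filter *in the covariance metric*, `C w`, not `w` itself.
#'
#' @param filters a [lcmv_filters()] object (or a vertices x channels
#'   matrix of filters).
#' @param cov the sensor covariance used to build the filters.
#' @param vertices ROI vertex indices (required when `filters` is a
#'   filter-bank object).
#' @return Object of class `"roi_filter"`: unit-norm weight vector `w`,
#'   `vertices`, `band`.
#' @export
roi_spatial_filter <- function(filters, cov, vertices = NULL) {
  C <- if (inherits(cov, "sensor_cov")) cov$C else cov
  if (inherits(filters, "spatial_filters")) {
    stopifnot(!is.null(vertices))
    Fm <- filters$W[vertices, , drop = FALSE]
    band <- filters$band
  } else {
    Fm <- as.matrix(filters)
    vertices <- seq_len(nrow(Fm))
    band <- NA_character_
  }
  if (nrow(Fm) == 0) stop("empty ROI", call. = FALSE)
  M <- Fm %*% C
  if (!all(is.finite(M)) || max(abs(M)) == 0)
    stop("degenerate ROI filters", call. = FALSE)
  w <- svd(M, nu = 0, nv = 1)$v[, 1]
  if (sum(w * colMeans(Fm)) < 0) w <- -w
  structure(list(w = w, vertices = vertices, band = band),
            class = "roi_filter")
}

#' Extract a virtual electrode time series
#'
#' Multiplies (typically broadband) sensor-level epochs by an ROI spatial
#' filter, giving one source time series per trial. Linear in the input.
#'
#' @param roi_filter a [roi_spatial_filter()] result (or plain weight
#'   vector).
#' @param epochs an [epoched_data()] object with matching channel count.
#' @return Matrix `trials x samples` with attributes `times` and `sfreq`.
#' @export
virtual_electrode <- function(roi_filter, epochs) {
  w <- if (inherits(roi_filter, "roi_filter")) roi_filter$w else
    as.numeric(roi_filter)
  if (length(w) != n_channels(epochs))
    stop("filter length (", length(w), ") does not match channel count (",
         n_channels(epochs), ")", call. = FALSE)
  d <- dim(epochs$data)
  ve <- matrix(0, d[1], d[3])
  for (ch in which(w != 0)) ve <- ve + w[ch] * epochs$data[, ch, ]
  attr(ve, "times") <- epochs$times
  attr(ve, "sfreq") <- epochs$sfreq
  ve
}

#' Write a source power map as CSV
#' @param map a [source_power_map()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_power_map <- function(map, path) {
  write.csv(as.data.frame(map), path, row.names = FALSE)
  invisible(path)
}
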