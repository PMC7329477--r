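#' Epoched multichannel sensor data
#'
#' The package's central container: a 3-D array of trials x channels x
#' samples plus a time axis, sampling rate, channel metadata and a free-form
#' provenance list. Analogous to an epochs object in any MEG toolbox.
#'
#' @param data numeric array `trials x channels x samples`.
#' @param times numeric vector of peristimulus times in seconds
#'   (length = samples); `0` is stimulus onset.
#' @param sfreq sampling rate in Hz.
#' @param channels `data.frame` with one row per channel; columns `name`,
#'   `kind` (`"grad"` or `"mag"`), positions `x y z` (m), coil normal
#'   `nx ny nz`, gradiometer sensitivity axis `dx dy dz` and `baseline` (m);
#'   non-geometry columns may be `NA` for externally supplied data.
#' @param provenance named list recording how the data were produced.
#' @return An object of class `"epoched_data"`.
#' @export
epoched_data <- function(data, times, sfreq, channels = NULL,
                         provenance = list()) {
  stopifnot(length(dim(data)) == 3L)
  stopifnot(length(times) == dim(data)[3])
  stopifnot(sfreq > 0)
  if (is.null(channels)) {
    channels <- data.frame(name = sprintf("CH%03d", seq_len(dim(data)[2])),
                           kind = "grad")
  }
  stopifnot(nrow(channels) == dim(data)[2])
  structure(list(data = data, times = as.numeric(times),
                 sfreq = as.numeric(sfreq), channels = channels,
                 provenance = provenance),
            class = "epoched_data")
}

#' @export
print.epoched_data <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_data> %d trials x %d channels x %d samples @ %g Hz, t = [%.3f, %.3f] s\n",
    d[1], d[2], d[3], x$sfreq, min(x$times), max(x$times)))
  invisible(x)
}

n_trials <- function(ep) dim(ep$data)[1]
n_channels <- function(ep) dim(ep$data)[2]
n_samples <- function(ep) dim(ep$data)[3]

#' @export
dim.epoched_data <- function(x) dim(x$data)

# index of the sample nearest each requested time
time_index <- function(ep, t) {
  vapply(t, function(ti) which.min(abs(ep$times - ti)), integer(1))
}

# logical mask of samples within [t0, t1]
time_mask <- function(times, window) {
  times >= window[1] - 1e-9 & times <= window[2] + 1e-9
}

#' Write epoched data to a directory container
#'
#' Plain sidecar format standing in for an HDF5 file (no HDF5 binding is
#' assumed): `meta.json` holds the time axis, sampling rate, channel table
#' and provenance; `data.bin` holds the data cube as little-endian float64
#' in trial-major order (sample fastest).
#'
#' @param ep an [epoched_data()] object.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(ep, path) {
  stopifnot(inherits(ep, "epoched_data"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dim(ep$data)
  meta <- list(format = "assrpipe-epochs-v1",
               shape = d, times = ep$times, sfreq = ep$sfreq,
               channels = ep$channels, provenance = ep$provenance)
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  con <- file(file.path(path, "data.bin"), "wb")
  on.exit(close(con))
  # sample fastest: store aperm so trial-major blocks are contiguous
  writeBin(as.vector(aperm(ep$data, c(3, 2, 1))), con,
           size = 8, endian = "little")
  invisible(path)
}

#' Read epoched data written by [write_epochs()]
#'
#' @param path container directory.
#' @return An [epoched_data()] object.
#' @export
read_epochs <- function(path) {
  meta <- jsonlite::read_json(file.path(path, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$format, "assrpipe-epochs-v1"))
    stop("not an assrpipe epochs container: ", path, call. = FALSE)
  d <- as.integer(meta$shape)
  con <- file(file.path(path, "data.bin"), "rb")
  on.exit(close(con))
  raw <- readBin(con, "double", n = prod(d), size = 8, endian = "little")
  data <- aperm(array(raw, dim = d[c(3, 2, 1)]), c(3, 2, 1))
  epoched_data(data, meta$times, meta$sfreq,
               as.data.frame(meta$channels),
               as.list(meta$provenance))
}
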