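# Analytic spherical-conductor MEG forward model. A current dipole inside a
# homogeneous conducting sphere produces an external field given by the
# classical closed form; radial dipoles are magnetically silent. This is a
# deliberate stand-in for a realistic single-shell model: it is analytic,
# dependency-free, and preserves every property the beamforming pipeline
# relies on (linearity, superposition, decay, silent radial orientation).

MU0_4PI <- 1e-7  # mu0 / (4 pi), T m / A

#' Spherical head conductor model
#'
#' @param centre sphere centre in metres (length-3).
#' @param radius sphere radius in metres (default 0.09).
#' @return Object of class `"sphere_head_model"`.
#' @export
sphere_head_model <- function(centre = c(0, 0, 0), radius = 0.09) {
  stopifnot(length(centre) == 3, radius > 0)
  structure(list(centre = as.numeric(centre), radius = radius),
            class = "sphere_head_model")
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' External magnetic field of a current dipole in a conducting sphere
#'
#' Closed-form field of a current dipole inside a homogeneous spherical
#' conductor, evaluated at points outside the sphere. Radially oriented
#' dipoles produce zero external field; a dipole at the sphere centre is
#' silent for every orientation (returned as exact zeros).
#'
#' @param dipole_pos dipole position in metres (length-3), strictly inside
#'   the sphere.
#' @param dipole_moment dipole moment vector in A m (length-3).
#' @param sensor_pos matrix `n x 3` (or length-3 vector) of field points in
#'   metres, strictly outside the sphere.
#' @param sphere a [sphere_head_model()].
#' @return `n x 3` matrix of magnetic field vectors in Tesla.
#' @export
sarvas_field <- function(dipole_pos, dipole_moment, sensor_pos, sphere) {
  stopifnot(inherits(sphere, "sphere_head_model"))
  if (is.null(dim(sensor_pos))) sensor_pos <- matrix(sensor_pos, ncol = 3)
  r0 <- as.numeric(dipole_pos) - sphere$centre
  r <- sweep(sensor_pos, 2, sphere$centre)
  if (sqrt(sum(r0^2)) >= sphere$radius)
    stop("dipole lies outside the head sphere", call. = FALSE)
  rn <- sqrt(rowSums(r^2))
  if (any(rn <= sphere$radius))
    stop("field point(s) inside the head sphere", call. = FALSE)
  q <- as.numeric(dipole_moment)
  if (sum(r0^2) == 0) return(matrix(0, nrow(r), 3))  # central dipole: silent
  a_vec <- r - matrix(r0, nrow(r), 3, byrow = TRUE)
  a <- sqrt(rowSums(a_vec^2))
  r0_dot_r <- drop(r %*% r0)
  f <- a * (rn * a + rn^2 - r0_dot_r)
  adotr <- rowSums(a_vec * r)
  c1 <- a^2 / rn + adotr / a + 2 * a + 2 * rn
  c2 <- a + 2 * rn + adotr / a
  grad_f <- r * c1 - matrix(r0, nrow(r), 3, byrow = TRUE) * c2
  qxr0 <- cross3(q, r0)
  qxr0_dot_r <- drop(r %*% qxr0)
  b <- (matrix(qxr0, nrow(r), 3, byrow = TRUE) * f - grad_f * qxr0_dot_r) *
    (MU0_4PI / f^2)
  b
}

#' Quasi-uniform helmet sensor array
#'
#' Places `n_sites` quasi-uniformly (golden-angle spiral) on the upper
#' hemisphere at radius `head_radius + standoff`. Each site carries either
#' two orthogonal first-order planar gradiometers (`kind = "grad"`, the
#' default, giving `2 * n_sites` channels in Tesla/metre) or one
#' magnetometer (`kind = "mag"`, `n_sites` channels in Tesla).
#'
#' @param n_sites number of helmet sites (>= 8; default 102).
#' @param head_radius head sphere radius in metres.
#' @param standoff sensor standoff above the scalp sphere in metres.
#' @param kind `"grad"` or `"mag"`.
#' @param baseline planar-gradiometer baseline in metres (default 0.0168).
#' @param centre sphere centre.
#' @return A `data.frame` channel table (class `"sensor_array"`): `name`,
#'   `kind`, coil position `x y z`, coil normal `nx ny nz`, gradiometer
#'   sensitivity axis `dx dy dz`, `baseline`.
#' @export
make_helmet_array <- function(n_sites = 102, head_radius = 0.09,
                              standoff = 0.02, kind = c("grad", "mag"),
                              baseline = 0.0168, centre = c(0, 0, 0)) {
  kind <- match.arg(kind)
  stopifnot(n_sites >= 8)
  rr <- head_radius + standoff
  i <- seq_len(n_sites)
  z <- 1 - (i - 0.5) / n_sites          # cap from pole to equator
  phi <- i * pi * (3 - sqrt(5))         # golden angle
  s <- sqrt(pmax(0, 1 - z^2))
  nrm <- cbind(s * cos(phi), s * sin(phi), z)
  pos <- sweep(rr * nrm, 2, centre, `+`)
  rows <- list()
  for (k in seq_len(n_sites)) {
    n_k <- nrm[k, ]
    ref <- if (abs(n_k[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
    e1 <- cross3(n_k, ref); e1 <- e1 / sqrt(sum(e1^2))
    e2 <- cross3(n_k, e1)
    if (kind == "grad") {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("GRAD%03d_1", k), kind = "grad",
        x = pos[k, 1], y = pos[k, 2], z = pos[k, 3],
        nx = n_k[1], ny = n_k[2], nz = n_k[3],
        dx = e1[1], dy = e1[2], dz = e1[3], baseline = baseline)
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("GRAD%03d_2", k), kind = "grad",
        x = pos[k, 1], y = pos[k, 2], z = pos[k, 3],
        nx = n_k[1], ny = n_k[2], nz = n_k[3],
        dx = e2[1], dy = e2[2], dz = e2[3], baseline = baseline)
    } else {
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("MAG%03d", k), kind = "mag",
        x = pos[k, 1], y = pos[k, 2], z = pos[k, 3],
        nx = n_k[1], ny = n_k[2], nz = n_k[3],
        dx = NA_real_, dy = NA_real_, dz = NA_real_, baseline = NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("sensor_array", "data.frame")
  out
}

#' Volumetric source grid inside the head sphere
#'
#' Regular grid of candidate source vertices strictly inside the sphere,
#' excluding a central region where the forward field vanishes.
#'
#' @param sphere a [sphere_head_model()].
#' @param spacing grid spacing in metres (default 0.01).
#' @param exclude_radius central exclusion radius in metres.
#' @param shrink retain vertices with radius below `shrink * radius`
#'   (sources hugging the skull are excluded).
#' @return List of class `"source_space"`: `pos` (`n x 3`), `spacing`.
#' @export
make_source_grid <- function(sphere, spacing = 0.01, exclude_radius = 0.02,
                             shrink = 0.92) {
  stopifnot(inherits(sphere, "sphere_head_model"))
  g <- seq(-sphere$radius, sphere$radius, by = spacing)
  pos <- as.matrix(expand.grid(x = g, y = g, z = g))
  rad <- sqrt(rowSums(pos^2))
  keep <- rad < shrink * sphere$radius & rad > exclude_radius
  pos <- sweep(pos[keep, , drop = FALSE], 2, sphere$centre, `+`)
  structure(list(pos = pos, spacing = spacing, sphere = sphere),
            class = "source_space")
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("<source_space> %d vertices, %g mm grid\n",
              nrow(x$pos), 1000 * x$spacing))
  invisible(x)
}

# Field component seen by each channel of a sensor array for a dipole with
# the given moment (A m). Magnetometers read B . n (Tesla); planar
# gradiometers read the two-point finite difference of B . n along their
# sensitivity axis divided by the baseline (Tesla / metre).
channel_gains <- function(dipole_pos, moment, sensors, sphere) {
  pos <- as.matrix(sensors[, c("x", "y", "z")])
  nr <- as.matrix(sensors[, c("nx", "ny", "nz")])
  is_grad <- sensors$kind == "grad"
  out <- numeric(nrow(sensors))
  if (any(!is_grad)) {
    b <- sarvas_field(dipole_pos, moment, pos[!is_grad, , drop = FALSE],
                      sphere)
    out[!is_grad] <- rowSums(b * nr[!is_grad, , drop = FALSE])
  }
  if (any(is_grad)) {
    dax <- as.matrix(sensors[is_grad, c("dx", "dy", "dz")])
    bl <- sensors$baseline[is_grad]
    p0 <- pos[is_grad, , drop = FALSE]
    pp <- p0 + dax * (bl / 2)
    pm <- p0 - dax * (bl / 2)
    bp <- sarvas_field(dipole_pos, moment, pp, sphere)
    bm <- sarvas_field(dipole_pos, moment, pm, sphere)
    nrg <- nr[is_grad, , drop = FALSE]
    out[is_grad] <- (rowSums(bp * nrg) - rowSums(bm * nrg)) / bl
  }
  out
}

#' Compute the leadfield of a source space
#'
#' Gain of a unit dipole moment of 1 nA m along each coordinate axis at
#' every vertex, for every channel. Gradiometer channels are computed as
#' two-point finite differences of the field along the channel's
#' sensitivity axis divided by the baseline.
#'
#' @param space a [make_source_grid()] source space, or a list with a `pos`
#'   matrix.
#' @param sensors a [make_helmet_array()] channel table.
#' @param sphere a [sphere_head_model()].
#' @return Object of class `"leadfield"`: `gain` array
#'   `3 x n_channels x n_vertices` (Tesla or Tesla/m per nA m), `pos`,
#'   `sensors`, `sphere`.
#' @export
compute_leadfield <- function(space, sensors, sphere) {
  pos <- space$pos
  nv <- nrow(pos)
  nch <- nrow(sensors)
  gain <- array(0, dim = c(3, nch, nv))
  unit <- diag(3) * 1e-9  # 1 nA m along each axis
  for (v in seq_len(nv)) {
    for (j in 1:3) {
      gain[j, , v] <- channel_gains(pos[v, ], unit[j, ], sensors, sphere)
    }
  }
  structure(list(gain = gain, pos = pos, sensors = sensors, sphere = sphere),
            class = "leadfield")
}

#' @export
print.leadfield <- function(x, ...) {
  cat(sprintf("<leadfield> %d vertices x %d channels\n",
              dim(x$gain)[3], dim(x$gain)[2]))
  invisible(x)
}
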