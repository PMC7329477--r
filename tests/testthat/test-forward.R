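# Spherical-conductor forward model: closed-form field properties and
# leadfield construction.

rot_z <- function(a) matrix(c(cos(a), sin(a), 0,
                              -sin(a), cos(a), 0, 0, 0, 1), 3, 3)

test_that("radial dipoles and central dipoles are silent", {
  sph <- sphere_head_model()
  pos <- c(-0.052, -0.02, 0.02)
  sens <- matrix(rnorm(30), 10, 3)
  sens <- 0.12 * sens / sqrt(rowSums(sens^2))
  radial <- 1e-9 * pos / sqrt(sum(pos^2))
  tang <- 1e-9 * assrpipe:::tangential_orientation(pos)
  b_rad <- sarvas_field(pos, radial, sens, sph)
  b_tan <- sarvas_field(pos, tang, sens, sph)
  expect_lt(max(abs(b_rad)), 1e-12 * max(abs(b_tan)))
  expect_equal(sarvas_field(c(0, 0, 0), tang, sens, sph),
               matrix(0, 10, 3))
})

test_that("field is linear in the moment and superposes over dipoles", {
  sph <- sphere_head_model()
  sens <- matrix(c(0, 0, 0.12, 0.08, 0.02, 0.09, -0.05, 0.07, 0.08),
                 3, 3, byrow = TRUE)
  p1 <- c(-0.05, -0.02, 0.02); q1 <- c(1e-9, 2e-9, -0.5e-9)
  p2 <- c(0.03, 0.04, 0.01);   q2 <- c(-2e-9, 0.5e-9, 1e-9)
  b1 <- sarvas_field(p1, q1, sens, sph)
  b2 <- sarvas_field(p2, q2, sens, sph)
  expect_equal(sarvas_field(p1, -q1, sens, sph), -b1)
  expect_equal(sarvas_field(p1, 3 * q1, sens, sph), 3 * b1,
               tolerance = 1e-12)
  # moment additivity at one site
  expect_equal(sarvas_field(p1, q1 + q2, sens, sph),
               b1 + sarvas_field(p1, q2, sens, sph), tolerance = 1e-10)
  # superposition over sources through the simulator (noise off,
  # phase-locked): two-source data equal the sum of single-source runs
  arr <- make_helmet_array(n_sites = 10)
  one <- function(srcs) {
    cfg <- subject_config("S", "control", n_trials = 2, sources = srcs,
                          noise = noise_config(0, 0, 0, 0), seed = 3,
                          stimulus = stimulus_config())
    cfg$sources <- lapply(cfg$sources, function(s) {
      s$phase_jitter_kappa <- Inf; s$kappa_late <- Inf
      s$tgbr_amplitude <- 0; s
    })
    simulate_subject(cfg, arr, sph)$data
  }
  pair <- bilateral_a1_sources()
  expect_close(one(pair), one(pair["left"]) + one(pair["right"]),
               tol = 1e-20)
})

test_that("field is invariant under joint rotation about the sphere centre", {
  sph <- sphere_head_model()
  sens <- matrix(c(0.01, 0.03, 0.115, -0.06, 0.05, 0.08), 2, 3,
                 byrow = TRUE)
  pos <- c(-0.05, -0.02, 0.02); q <- c(1e-9, -2e-9, 0.5e-9)
  b <- sarvas_field(pos, q, sens, sph)
  R <- rot_z(0.7) %*% matrix(c(1, 0, 0, 0, cos(0.3), sin(0.3),
                               0, -sin(0.3), cos(0.3)), 3, 3)
  b_rot <- sarvas_field(drop(R %*% pos), drop(R %*% q),
                        sens %*% t(R), sph)
  expect_close(b_rot, b %*% t(R), tol = 1e-10 * max(abs(b)))
})

test_that("field magnitude decays along an outward ray", {
  sph <- sphere_head_model()
  pos <- c(-0.05, -0.02, 0.02); q <- 1e-9 * c(0.3, 0.2, 0.9)
  dir <- c(0.2, -0.1, 0.97); dir <- dir / sqrt(sum(dir^2))
  radii <- seq(0.095, 0.25, by = 0.005)
  mags <- vapply(radii, function(r)
    sqrt(sum(sarvas_field(pos, q, r * dir, sph)^2)), numeric(1))
  expect_true(all(diff(mags) < 0))
})

test_that("closed form matches the scalar-potential gradient oracle", {
  # independent route: B = mu0/(4 pi) * grad[(Q x r0 . r) / F], evaluated
  # by central finite differences of the potential
  sph <- sphere_head_model()
  pos <- c(-0.045, -0.025, 0.03)
  q <- 1e-9 * c(0.5, 1.2, -0.8)
  r0 <- pos - sph$centre
  qxr0 <- assrpipe:::cross3(q, r0)
  U <- function(r) {
    a <- sqrt(sum((r - r0)^2)); rn <- sqrt(sum(r^2))
    f <- a * (rn * a + rn^2 - sum(r0 * r))
    sum(qxr0 * r) / f
  }
  sens <- matrix(c(0, 0.01, 0.12, 0.09, -0.03, 0.06, -0.07, 0.06, 0.07),
                 3, 3, byrow = TRUE)
  h <- 1e-6
  for (i in 1:3) {
    r <- sens[i, ]
    grad <- vapply(1:3, function(d) {
      e <- numeric(3); e[d] <- h
      (U(r + e) - U(r - e)) / (2 * h)
    }, numeric(1))
    b_num <- 1e-7 * grad
    b_cf <- drop(sarvas_field(pos, q, r, sph))
    expect_close(b_cf, b_num, tol = 1e-6 * max(abs(b_cf)))
  }
})

test_that("geometry preconditions are enforced", {
  sph <- sphere_head_model()
  expect_error(sarvas_field(c(0.1, 0, 0), c(1e-9, 0, 0),
                            c(0, 0, 0.12), sph), "outside the head")
  expect_error(sarvas_field(c(0.05, 0, 0), c(1e-9, 0, 0),
                            c(0, 0, 0.05), sph), "inside the head")
})

test_that("default helmet provides 204 planar gradiometers with the stated geometry", {
  sens <- make_helmet_array()
  expect_equal(nrow(sens), 204)
  expect_true(all(sens$kind == "grad"))
  r <- sqrt(sens$x^2 + sens$y^2 + sens$z^2)
  expect_close(r, 0.11, tol = 1e-9)
  # the two gradiometers of each site have orthogonal sensitivity axes
  d <- as.matrix(sens[, c("dx", "dy", "dz")])
  dots <- rowSums(d[seq(1, 203, 2), ] * d[seq(2, 204, 2), ])
  expect_lt(max(abs(dots)), 1e-9)
  expect_error(make_helmet_array(n_sites = 4))
  mags <- make_helmet_array(n_sites = 16, kind = "mag")
  expect_equal(nrow(mags), 16)
})

test_that("leadfield rows reduce to the bare field for magnetometers", {
  sph <- sphere_head_model()
  mags <- make_helmet_array(n_sites = 16, kind = "mag")
  space <- list(pos = matrix(c(-0.04, -0.02, 0.03), 1))
  lf <- compute_leadfield(space, mags, sph)
  nrm <- as.matrix(mags[, c("nx", "ny", "nz")])
  for (j in 1:3) {
    unit <- numeric(3); unit[j] <- 1e-9
    b <- sarvas_field(space$pos[1, ], unit,
                      as.matrix(mags[, c("x", "y", "z")]), sph)
    expect_equal(lf$gain[j, , 1], rowSums(b * nrm), tolerance = 1e-12)
  }
})

test_that("gradiometer gain vanishes faster than magnetometer gain as baseline shrinks", {
  sph <- sphere_head_model()
  pos <- c(-0.04, -0.02, 0.03)
  q <- 1e-9 * assrpipe:::tangential_orientation(pos)
  gain_at <- function(bl) {
    g <- make_helmet_array(n_sites = 16, baseline = bl)
    max(abs(assrpipe:::channel_gains(pos, q, g, sph)))
  }
  m <- make_helmet_array(n_sites = 16, kind = "mag")
  g_mag <- max(abs(assrpipe:::channel_gains(pos, q, m, sph)))
  # gradiometer output is a derivative: finite and stable as baseline -> 0,
  # and baseline * gain (the field difference itself) -> 0
  expect_close(gain_at(1e-4) * 1e-4 / (gain_at(1e-6) * 1e-6), 100,
               tol = 1)
  expect_gt(g_mag, gain_at(1e-6) * 1e-6)  # field difference << field
})

test_that("moving the array outward reduces every gain", {
  sph <- sphere_head_model()
  space <- list(pos = matrix(c(-0.04, -0.02, 0.03), 1))
  near <- compute_leadfield(space, make_helmet_array(n_sites = 16), sph)
  far <- compute_leadfield(space,
                           make_helmet_array(n_sites = 16, standoff = 0.06),
                           sph)
  # per-channel gain norms all decay (single components can sit on a
  # moving nodal line of the lead-field pattern)
  near_norm <- sqrt(apply(near$gain^2, 2, sum))
  far_norm <- sqrt(apply(far$gain^2, 2, sum))
  expect_true(all(far_norm < near_norm))
  expect_lt(max(abs(far$gain)), 0.7 * max(abs(near$gain)))
})

test_that("source grid stays inside the sphere with a central exclusion", {
  sph <- sphere_head_model()
  grid <- make_source_grid(sph, spacing = 0.015)
  r <- sqrt(rowSums(grid$pos^2))
  expect_true(all(r < sph$radius))
  expect_true(all(r > 0.02))
  expect_error(compute_leadfield(list(pos = matrix(c(0, 0, 0.2), 1)),
                                 make_helmet_array(n_sites = 16), sph))
})
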