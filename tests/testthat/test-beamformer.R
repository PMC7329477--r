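# Covariance estimation, regularisation, LCMV filters, power maps, ROI
# collapse and virtual electrodes.

iid_epochs <- function(n_trials = 30, n_ch = 8, n_samp = 400, sd = 1) {
  t <- seq(0, (n_samp - 1) / 1000, by = 1e-3) - 0.2
  epoched_data(array(rnorm(n_trials * n_ch * n_samp, 0, sd),
                     c(n_trials, n_ch, n_samp)), t, 1000)
}

test_that("covariance of independent channels is near identity", {
  set.seed(8)
  ep <- iid_epochs()
  cv <- compute_covariance(ep)
  n_eff <- 30 * 400
  expect_close(diag(cv$C), 1, tol = 5 / sqrt(n_eff) * 3)
  off <- cv$C[upper.tri(cv$C)]
  expect_lt(max(abs(off)), 5 / sqrt(n_eff))
  expect_true(isSymmetric(cv$C))
  expect_true(all(eigen(cv$C, only.values = TRUE)$values > 0))
})

test_that("duplicated channels are flagged as rank deficient", {
  set.seed(9)
  ep <- iid_epochs(n_ch = 4)
  ep$data[, 4, ] <- ep$data[, 3, ]
  expect_warning(cv <- compute_covariance(ep), "rank-deficient")
  expect_true(cv$rank_deficient)
})

test_that("covariance pools sub-windows by sample weight", {
  set.seed(10)
  ep <- iid_epochs(n_trials = 5, n_samp = 400)
  c_all <- compute_covariance(ep, c(-0.2, 0.1995))$C
  c_a <- compute_covariance(ep, c(-0.2, -0.0005))$C   # first 200 samples
  c_b <- compute_covariance(ep, c(0, 0.1995))$C       # last 200 samples
  expect_equal(c_all, (200 * c_a + 200 * c_b) / 400, tolerance = 1e-12)
})

test_that("regularisation is exact diagonal loading", {
  set.seed(11)
  A <- crossprod(matrix(rnorm(100), 20, 5)) / 20
  expect_equal(regularise(A, 0), A)
  expect_equal(regularise(diag(5), 5), 1.05 * diag(5))
  ev0 <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  ev5 <- eigen(regularise(A, 5), symmetric = TRUE,
               only.values = TRUE)$values
  expect_equal(ev5, ev0 + 0.05 * mean(diag(A)), tolerance = 1e-12)
})

test_that("LCMV filters satisfy unit gain and need an invertible covariance", {
  ep <- tiny_subject_epochs()
  bp <- filter_data(resample_epochs(detrend_epochs(ep), 200),
                    filter_spec("pass", c(35, 45), 5L))
  cv <- suppressWarnings(compute_covariance(bp, c(-1.5, 1.5)))
  lf <- tiny_geometry()$leadfield
  nch <- nrow(lf$sensors)
  expect_error(lcmv_filters(lf, matrix(0, nch, nch)), "singular")
  cvr <- regularise(cv, 5)
  filt <- lcmv_filters(lf, cvr, band = "ASSR")
  for (v in seq_len(nrow(filt$W))) {
    l <- t(lf$gain[, , v]) %*% filt$ori[v, ]
    expect_lt(abs(sum(filt$W[v, ] * l) - 1), 1e-9)
  }
  expect_equal(filt$band, "ASSR")
})

test_that("a single strong source is localised to its own neighbourhood", {
  sens <- tiny_sensors(); sph <- tiny_sphere()
  # on-grid source: the unit-gain constraint then applies exactly at the
  # true vertex (off-grid sources at extreme SNR hit the classic LCMV
  # mismatch-cancellation, bounded instead by the one-grid-step test below)
  src_pos <- c(-0.054, -0.018, 0.03)
  cfg <- subject_config(
    "L1", "control", n_trials = 12,
    sources = list(one = source_spec(src_pos, assr_amplitude = 30,
                                     tgbr_amplitude = 0,
                                     phase_jitter_kappa = Inf)),
    noise = noise_config(),
    seed = 21)
  ep <- simulate_subject(cfg, sens, sph)
  ep <- resample_epochs(detrend_epochs(ep), 200)
  geom <- tiny_geometry_full()
  map <- localise_power(ep, c(35, 45), geometry = geom)
  pk <- which.max(map$pct_change)
  pos <- geom$grid$pos
  d_true <- sqrt(sum((pos[pk, ] - src_pos)^2))
  expect_lte(d_true, tiny_analysis()$grid_spacing + 1e-9)
  # output dominates every vertex more than 2 cm away
  far <- sqrt(rowSums(sweep(pos, 2, src_pos)^2)) > 0.02
  expect_gt(map$pct_change[pk], max(map$pct_change[far]))
})

test_that("bilateral sources yield two separated maxima near the truth", {
  ep <- tiny_subject_epochs()
  ep2 <- resample_epochs(detrend_epochs(ep), 200)
  geom <- tiny_geometry_full()
  map <- localise_power(ep2, c(35, 45), geometry = geom)
  pos <- geom$grid$pos
  left_true <- c(-0.052, -0.02, 0.02); right_true <- c(0.052, -0.02, 0.02)
  pk_l <- which.max(ifelse(pos[, 1] < 0, map$pct_change, -Inf))
  pk_r <- which.max(ifelse(pos[, 1] > 0, map$pct_change, -Inf))
  step <- tiny_analysis()$grid_spacing
  expect_lte(sqrt(sum((pos[pk_l, ] - left_true)^2)), step * sqrt(3) + 1e-9)
  expect_lte(sqrt(sum((pos[pk_r, ] - right_true)^2)), step * sqrt(3) + 1e-9)
  # peak separation beyond half the true source separation (correlated
  # bilateral sources must not merge into a central ghost)
  sep <- sqrt(sum((pos[pk_l, ] - pos[pk_r, ])^2))
  expect_gt(sep, 0.052)
})

test_that("null data give a centred percent-change map and doubling the source raises the peak", {
  sens <- tiny_sensors(); sph <- tiny_sphere()
  null_cfg <- subject_config(
    "N", "control", n_trials = 10,
    sources = list(s = source_spec(c(-0.05, -0.02, 0.02),
                                   assr_amplitude = 0, tgbr_amplitude = 0)),
    noise = noise_config(), seed = 31)
  epn <- simulate_subject(null_cfg, sens, sph)
  epn <- resample_epochs(detrend_epochs(epn), 200)
  geom <- tiny_geometry_full()
  mapn <- localise_power(epn, c(35, 45), geometry = geom)
  z <- (mapn$pct_change - mean(mapn$pct_change)) / sd(mapn$pct_change)
  expect_lt(abs(mean(mapn$pct_change)), sd(mapn$pct_change) / 2)
  expect_lt(max(abs(z)), 6)
  # monotonicity in source strength at the true location (on-grid source)
  mk <- function(amp) {
    cfg <- subject_config(
      "M", "control", n_trials = 8,
      sources = list(s = source_spec(c(-0.054, -0.018, 0.03),
                                     assr_amplitude = amp,
                                     tgbr_amplitude = 0)),
      noise = noise_config(), seed = 33)
    ep <- simulate_subject(cfg, sens, sph)
    ep <- resample_epochs(detrend_epochs(ep), 200)
    max(localise_power(ep, c(35, 45), geometry = geom)$pct_change)
  }
  expect_gt(mk(30), mk(15))
})

base_power <- function(ve) {
  tt <- attr(ve, "times")
  mean(ve[, tt > -1.3 & tt < -0.3]^2)
}

test_that("ROI filter collapse behaves on degenerate and real ROIs", {
  geom <- tiny_geometry()
  ep <- tiny_subject_epochs()
  bp <- filter_data(resample_epochs(detrend_epochs(ep), 200),
                    filter_spec("pass", c(35, 45), 5L))
  cvr <- regularise(suppressWarnings(
    compute_covariance(bp, c(-1.5, 1.5))), 5)
  filt <- lcmv_filters(geom$leadfield, cvr)
  # single-vertex ROI: the vertex's filter in the covariance metric
  # (C w, the documented behaviour of the covariance-weighted PCA)
  rf1 <- roi_spatial_filter(filt, cvr, vertices = 3L)
  w3 <- filt$W[3, ]
  cw3 <- drop(cvr$C %*% w3)
  cosang <- sum(rf1$w * cw3) / sqrt(sum(rf1$w^2) * sum(cw3^2))
  expect_close(abs(cosang), 1, tol = 1e-9)
  # sign convention: positively correlated with the mean ROI filter
  expect_gt(sum(rf1$w * w3), 0)
  # ROI of identical filters: the same (covariance-weighted) filter again
  Fm <- rbind(w3, w3, w3)
  rf2 <- roi_spatial_filter(Fm, cvr)
  expect_close(abs(sum(rf2$w * cw3) / sqrt(sum(rf2$w^2) * sum(cw3^2))),
               1, tol = 1e-9)
  expect_error(roi_spatial_filter(matrix(0, 2, 48), cvr), "degenerate")
  # the collapsed ROI electrode captures at least 80% of the best
  # single-vertex 40 Hz stimulus response
  ve_roi <- virtual_electrode(
    roi_spatial_filter(filt, cvr, geom$roi$left), bp)
  stim_power <- function(ve) {
    tt <- attr(ve, "times")
    mean(ve[, tt > 0.3 & tt < 1.3]^2)
  }
  snr_roi <- stim_power(ve_roi) / base_power(ve_roi)
  best <- max(vapply(geom$roi$left, function(v) {
    ve <- virtual_electrode(filt$W[v, ], bp)
    stim_power(ve) / base_power(ve)
  }, numeric(1)))
  expect_gte(snr_roi, 0.8 * best)
})

test_that("virtual electrodes are linear channel projections", {
  ep <- tiny_subject_epochs()
  w <- numeric(n_channels <- dim(ep$data)[2])
  w[5] <- 1
  ve <- virtual_electrode(w, ep)
  expect_equal(ve[, ], ep$data[, 5, ], ignore_attr = TRUE)
  set.seed(12)
  w2 <- rnorm(n_channels)
  epB <- ep; epB$data <- ep$data[rev(seq_len(dim(ep$data)[1])), , ]
  lhs_ep <- ep; lhs_ep$data <- 2 * ep$data + 3 * epB$data
  expect_equal(virtual_electrode(w2, lhs_ep),
               2 * virtual_electrode(w2, ep) +
                 3 * virtual_electrode(w2, epB), tolerance = 1e-12)
  expect_error(virtual_electrode(w2[-1], ep), "does not match")
  # stimulus 40 Hz power well above baseline on the default simulation
  meas <- tiny_subject_measures()
  tt <- meas$times
  expect_gt(mean(meas$roi$left$assr_pct[tt > 0.3 & tt < 1.3]), 100)
})
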