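# Cluster-based permutation statistics.

smooth_series <- function(n_subj, n_time, shift = 0, window = NULL) {
  x <- matrix(rnorm(n_subj * (n_time + 10)), n_subj)
  x <- t(apply(x, 1, stats::filter, filter = rep(1 / 5, 5)))
  x <- x[, 6:(n_time + 5)]
  if (!is.null(window)) x[, window] <- x[, window] + shift
  x
}

test_that("pointwise t matches the textbook formula and its symmetries", {
  set.seed(40)
  a <- matrix(rnorm(5 * 8, 1), 5, 8)
  b <- matrix(rnorm(7 * 8), 7, 8)
  t_pkg <- pointwise_t(a, b)
  # independent oracle: explicit pooled-variance formula per column
  t_ref <- vapply(1:8, function(j) {
    sp <- ((5 - 1) * var(a[, j]) + (7 - 1) * var(b[, j])) / (5 + 7 - 2)
    (mean(a[, j]) - mean(b[, j])) / sqrt(sp * (1 / 5 + 1 / 7))
  }, numeric(1))
  expect_equal(as.numeric(t_pkg), t_ref, tolerance = 1e-12)
  expect_equal(attr(t_pkg, "df"), 10)
  expect_equal(as.numeric(pointwise_t(b, a)), -t_ref, tolerance = 1e-12)
  expect_equal(as.numeric(pointwise_t(a, a, paired = TRUE)), rep(0, 8))
  # two groups separated by 2 with common SD 1 at n = 18: t ~ 6
  set.seed(41)
  big_a <- matrix(rnorm(18 * 200, 2), 18)
  big_b <- matrix(rnorm(18 * 200, 0), 18)
  expect_close(mean(pointwise_t(big_a, big_b)), 6, tol = 0.5)
})

test_that("Monte-Carlo p converges to exact enumeration at n = 4 + 4", {
  set.seed(42)
  a <- smooth_series(4, 40, shift = 1.6, window = 15:30)
  b <- smooth_series(4, 40)
  spec_ex <- cluster_test_spec(n_permutations = 70, seed = 1)
  expect_message(res_ex <- permutation_cluster_test(a, b, spec_ex),
                 "exact enumeration of all 70")
  expect_true(res_ex$exact)
  spec_mc <- cluster_test_spec(n_permutations = 20000, seed = 2)
  res_mc <- permutation_cluster_test(a, b, spec_mc, enumerate = "never")
  expect_false(res_mc$exact)
  expect_equal(nrow(res_mc$clusters), nrow(res_ex$clusters))
  expect_close(res_mc$clusters$p, res_ex$clusters$p, tol = 0.02)
})

test_that("results are deterministic given the spec seed and labels swap sign", {
  set.seed(43)
  a <- smooth_series(6, 50, 1, 10:30); b <- smooth_series(6, 50)
  sp <- cluster_test_spec(n_permutations = 300, seed = 9)
  r1 <- permutation_cluster_test(a, b, sp)
  r2 <- permutation_cluster_test(a, b, sp)
  expect_identical(r1$clusters, r2$clusters)
  r3 <- permutation_cluster_test(b, a, sp)
  expect_equal(r3$clusters$stat, -r1$clusters$stat)
  expect_equal(r3$clusters$sign, -r1$clusters$sign)
})

test_that("cluster masks and extents follow the threshold definition", {
  set.seed(44)
  a <- smooth_series(10, 60, 2.5, 20:35)
  b <- smooth_series(10, 60)
  tm <- seq(0, 0.59, 0.01)
  r <- permutation_cluster_test(a, b, cluster_test_spec(
    n_permutations = 500, seed = 3), times = tm)
  expect_false(is.null(r$clusters))
  sig <- r$clusters[r$clusters$significant, ]
  expect_gte(nrow(sig), 1)
  # mask true exactly inside significant clusters
  inside <- rep(FALSE, 60)
  for (i in seq_len(nrow(sig)))
    inside[which(tm >= sig$start_time[i] & tm <= sig$end_time[i])] <- TRUE
  expect_equal(r$mask, inside)
  # clusters are maximal same-sign suprathreshold runs of the t series
  supra <- abs(r$t) > r$threshold
  expect_true(all(supra[unlist(Map(seq, r$clusters$start,
                                   r$clusters$end))]))
  expect_equal(sum(r$clusters$end - r$clusters$start + 1), sum(supra))
  expect_true(all(r$clusters$p >= 1 / (r$n_perm + 1)))
})

test_that("one-sample sign-flip variant recovers a vs-baseline effect", {
  set.seed(45)
  d <- smooth_series(8, 50, 1.5, 20:40)
  r <- permutation_cluster_test(d, spec = cluster_test_spec(
    n_permutations = 400, seed = 5))
  expect_true(r$exact)      # 2^8 = 256 <= 400
  sig <- r$clusters[r$clusters$significant & r$clusters$sign > 0, ]
  expect_gte(nrow(sig), 1)
  expect_true(any(sig$start <= 22 & sig$end >= 38))
})

test_that("increasing the effect never increases the cluster p", {
  set.seed(46)
  base_a <- smooth_series(8, 60); base_b <- smooth_series(8, 60)
  p_at <- vapply(c(0.5, 1, 2, 3), function(ef) {
    a <- base_a; a[, 20:40] <- a[, 20:40] + ef
    r <- permutation_cluster_test(a, base_b, cluster_test_spec(
      n_permutations = 800, seed = 7))
    if (is.null(r$clusters)) 1 else min(r$clusters$p[r$clusters$sign > 0])
  }, numeric(1))
  expect_true(all(diff(p_at) <= 0))
})

test_that("sum-t cluster mass is available as an option", {
  set.seed(47)
  a <- smooth_series(8, 50, 2, 10:30); b <- smooth_series(8, 50)
  r <- permutation_cluster_test(a, b, cluster_test_spec(
    n_permutations = 300, cluster_statistic = "sum-t", seed = 11))
  expect_equal(r$spec$cluster_statistic, "sum-t")
  big <- which.max(abs(r$clusters$stat))
  seg <- r$t[r$clusters$start[big]:r$clusters$end[big]]
  expect_equal(r$clusters$stat[big], sum(seg), tolerance = 1e-12)
})

test_that("a strong sustained effect is recovered with sharp edges", {
  # effect over 0.5-1.5 s on a 0.02 s grid; edges must match within
  # the 0.25 s multitaper half-window annotation
  set.seed(48)
  tm <- seq(0, 1.5, 0.02)
  win <- which(tm >= 0.5)
  a <- smooth_series(9, length(tm), 3, win)
  b <- smooth_series(9, length(tm))
  r <- permutation_cluster_test(a, b, cluster_test_spec(
    n_permutations = 500, seed = 13), times = tm)
  sig <- r$clusters[r$clusters$significant & r$clusters$sign > 0, ]
  expect_equal(nrow(sig), 1)
  overlap <- min(sig$end_time, 1.5) - max(sig$start_time, 0.5)
  expect_gte(overlap, 0.8 * 1.0)
  expect_lte(abs(sig$start_time - 0.5), 0.25)
})

test_that("family-wise error stays at the nominal level under the null", {
  set.seed(49)
  reps <- 300
  hits <- vapply(seq_len(reps), function(i) {
    a <- smooth_series(8, 60); b <- smooth_series(8, 60)
    r <- permutation_cluster_test(a, b, cluster_test_spec(
      n_permutations = 250, seed = i))
    !is.null(r$clusters) && any(r$clusters$significant)
  }, logical(1))
  rate <- mean(hits)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / reps))
})
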