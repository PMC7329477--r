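# Two-stage cluster-based permutation test for 1-D time courses:
# pointwise t tests thresholded at an uncorrected two-tailed alpha, runs of
# adjacent same-sign suprathreshold samples form clusters, and each
# cluster's statistic (max-t by default, sum-t optionally) is compared to
# the permutation distribution of the largest same-tail cluster statistic.

#' Cluster permutation test specification
#'
#' @param cluster_forming_alpha two-tailed pointwise alpha forming clusters
#'   (default 0.05).
#' @param n_permutations random label permutations (default 10000). When
#'   the design admits fewer unique relabellings, exact enumeration is used
#'   instead (with a message).
#' @param cluster_statistic `"max-t"` (default) or `"sum-t"`.
#' @param final_alpha_per_tail per-tail significance level after correction
#'   (default 0.025, i.e. 5% across both tails).
#' @param seed optional integer for reproducible permutations.
#' @return Object of class `"cluster_test_spec"`.
#' @export
cluster_test_spec <- function(cluster_forming_alpha = 0.05,
                              n_permutations = 10000,
                              cluster_statistic = c("max-t", "sum-t"),
                              final_alpha_per_tail = 0.025, seed = NULL) {
  cluster_statistic <- match.arg(cluster_statistic)
  stopifnot(cluster_forming_alpha > 0, cluster_forming_alpha < 1,
            final_alpha_per_tail > 0, final_alpha_per_tail < 1,
            n_permutations >= 1)
  structure(list(cluster_forming_alpha = cluster_forming_alpha,
                 n_permutations = as.integer(n_permutations),
                 cluster_statistic = cluster_statistic,
                 final_alpha_per_tail = final_alpha_per_tail, seed = seed),
            class = "cluster_test_spec")
}

#' Pointwise t statistic series
#'
#' Independent-samples (pooled variance) t per time point, or the paired
#' variant (`a - b` against zero) used for the within-group vs-baseline
#' contrasts. Zero-variance time points give infinite t, treated as
#' suprathreshold downstream (a note is attached).
#'
#' @param group_a,group_b matrices `subjects x times`; `group_b` may be
#'   `NULL` for a one-sample test of `group_a` against zero.
#' @param paired if `TRUE`, `group_a` and `group_b` are matched rows and a
#'   paired (one-sample difference) t is computed.
#' @return Numeric t series with attribute `df`.
#' @export
pointwise_t <- function(group_a, group_b = NULL, paired = FALSE) {
  a <- as.matrix(group_a)
  if (!is.null(group_b) && paired) {
    stopifnot(nrow(group_a) == nrow(group_b))
    a <- a - as.matrix(group_b)
    group_b <- NULL
  }
  if (is.null(group_b)) {
    n <- nrow(a)
    stopifnot(n >= 2)
    m <- colMeans(a)
    s <- apply(a, 2, sd)
    t <- m / (s / sqrt(n))
    t[s == 0 & m == 0] <- 0
    df <- n - 1
  } else {
    b <- as.matrix(group_b)
    n1 <- nrow(a); n2 <- nrow(b)
    stopifnot(n1 >= 2, n2 >= 2, ncol(a) == ncol(b))
    m1 <- colMeans(a); m2 <- colMeans(b)
    v1 <- apply(a, 2, var); v2 <- apply(b, 2, var)
    sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp * (1 / n1 + 1 / n2))
    t <- (m1 - m2) / se
    t[se == 0 & m1 == m2] <- 0
    df <- n1 + n2 - 2
  }
  if (any(is.infinite(t)))
    attr(t, "n_infinite") <- sum(is.infinite(t))
  attr(t, "df") <- df
  t
}

safe_quantile <- function(x, probs) {
  x <- x[is.finite(x)]
  if (length(x) == 0) return(rep(NA_real_, length(probs)))
  stats::quantile(x, probs, names = FALSE)
}

# runs of adjacent same-sign suprathreshold samples
extract_clusters <- function(t, thr, stat = "max-t") {
  code <- integer(length(t))
  code[t > thr] <- 1L
  code[t < -thr] <- -1L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 0L
  if (!any(keep)) return(NULL)
  out <- data.frame(start = starts[keep], end = ends[keep],
                    sign = r$values[keep])
  out$stat <- vapply(seq_len(nrow(out)), function(i) {
    seg <- t[out$start[i]:out$end[i]]
    if (stat == "max-t") {
      if (out$sign[i] > 0) max(seg) else min(seg)
    } else sum(seg)
  }, numeric(1))
  out
}

# largest positive / most negative cluster statistic of a t series
extreme_cluster_stats <- function(t, thr, stat) {
  if (stat == "max-t") {
    mx <- max(t); mn <- min(t)
    c(pos = if (mx > thr) mx else -Inf,
      neg = if (mn < -thr) mn else Inf)
  } else {
    cl <- extract_clusters(t, thr, stat)
    if (is.null(cl)) return(c(pos = -Inf, neg = Inf))
    pos <- cl$stat[cl$sign > 0]; neg <- cl$stat[cl$sign < 0]
    c(pos = if (length(pos)) max(pos) else -Inf,
      neg = if (length(neg)) min(neg) else Inf)
  }
}

# t matrix (B x T) for independent-design permutations given a 0/1
# selection matrix P (B x n) marking group-1 membership
perm_t_matrix <- function(X, P, n1, n2) {
  S1 <- P %*% X
  Q1 <- P %*% (X^2)
  St <- matrix(colSums(X), nrow(P), ncol(X), byrow = TRUE)
  Qt <- matrix(colSums(X^2), nrow(P), ncol(X), byrow = TRUE)
  S2 <- St - S1; Q2 <- Qt - Q1
  m1 <- S1 / n1; m2 <- S2 / n2
  v1 <- (Q1 - S1^2 / n1) / (n1 - 1)
  v2 <- (Q2 - S2^2 / n2) / (n2 - 1)
  sp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp * (1 / n1 + 1 / n2))
}

# t matrix for one-sample sign-flip permutations given a +-1 matrix G
signflip_t_matrix <- function(X, G) {
  n <- ncol(G)
  S <- G %*% X
  m <- S / n
  qt_row <- matrix(colSums(X^2), nrow(G), ncol(X), byrow = TRUE)
  v <- (qt_row - n * m^2) / (n - 1)
  m / sqrt(v / n)
}

#' Cluster-based permutation test on time courses
#'
#' Between-group (independent, label permutation) or within-group
#' (one-sample / paired, sign-flip permutation) cluster test. Per
#' permutation the largest positive and most negative cluster statistics
#' are recorded; each observed cluster's p is the proportion of same-tail
#' permutation extremes at least as extreme, with the +1 rule for
#' Monte-Carlo sampling. If the requested number of permutations exceeds
#' the number of unique relabellings, exact enumeration is used.
#'
#' @param group_a matrix `subjects x times`.
#' @param group_b second group, or `NULL` for a one-sample test.
#' @param spec a [cluster_test_spec()].
#' @param times time axis for reporting (default sample indices).
#' @param paired treat `group_a`/`group_b` as matched rows.
#' @param enumerate `"auto"` (exact when the design admits no more unique
#'   relabellings than `n_permutations`) or `"never"` (force Monte-Carlo
#'   sampling, e.g. to compare against the exact reference).
#' @return Object of class `"cluster_test_result"`: `clusters`
#'   (start/end time, sign, statistic, p, significant), `mask`, `t`,
#'   `threshold`, `null` (summary of permutation extremes), `n_perm`,
#'   `exact`, `spec`.
#' @export
permutation_cluster_test <- function(group_a, group_b = NULL,
                                     spec = cluster_test_spec(),
                                     times = NULL, paired = FALSE,
                                     enumerate = c("auto", "never")) {
  enumerate <- match.arg(enumerate)
  stopifnot(inherits(spec, "cluster_test_spec"))
  a <- as.matrix(group_a)
  if (!is.null(group_b) && paired) {
    a <- a - as.matrix(group_b)
    group_b <- NULL
  }
  one_sample <- is.null(group_b)
  t_obs <- if (one_sample) pointwise_t(a) else pointwise_t(a, group_b)
  df <- attr(t_obs, "df")
  thr <- qt(1 - spec$cluster_forming_alpha / 2, df)
  stat <- spec$cluster_statistic
  if (!is.null(times)) stopifnot(length(times) == length(t_obs))
  tx <- times %||% seq_along(t_obs)
  clusters <- extract_clusters(as.numeric(t_obs), thr, stat)

  run <- function() {
    if (one_sample) {
      n <- nrow(a)
      n_unique <- 2^n
      exact <- enumerate == "auto" && n_unique <= spec$n_permutations
      G <- if (exact) {
        message("exact enumeration of all ", n_unique, " sign flips")
        as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
      } else {
        matrix(sample(c(-1, 1), spec$n_permutations * n, replace = TRUE),
               spec$n_permutations, n)
      }
      tm <- signflip_t_matrix(a, G)
      list(tm = tm, exact = exact, B = nrow(G))
    } else {
      b <- as.matrix(group_b)
      X <- rbind(a, b)
      n1 <- nrow(a); n2 <- nrow(b); n <- n1 + n2
      n_unique <- choose(n, n1)
      exact <- enumerate == "auto" && n_unique <= spec$n_permutations
      P <- if (exact) {
        message("exact enumeration of all ", n_unique,
                " label assignments")
        combs <- utils::combn(n, n1)
        Pm <- matrix(0, ncol(combs), n)
        Pm[cbind(rep(seq_len(ncol(combs)), each = n1), as.vector(combs))] <- 1
        Pm
      } else {
        Pm <- matrix(0, spec$n_permutations, n)
        for (i in seq_len(spec$n_permutations))
          Pm[i, sample.int(n, n1)] <- 1
        Pm
      }
      tm <- perm_t_matrix(X, P, n1, n2)
      list(tm = tm, exact = exact, B = nrow(P))
    }
  }
  pr <- if (is.null(spec$seed)) run() else with_seed(spec$seed, run())
  tm <- pr$tm
  tm[is.nan(tm)] <- 0   # zero-variance, zero-difference permutations
  if (stat == "max-t") {
    row_max <- tm[cbind(seq_len(nrow(tm)), max.col(tm, "first"))]
    row_min <- tm[cbind(seq_len(nrow(tm)), max.col(-tm, "first"))]
    null_pos <- ifelse(row_max > thr, row_max, -Inf)
    null_neg <- ifelse(row_min < -thr, row_min, Inf)
  } else {
    ex <- t(apply(tm, 1, extreme_cluster_stats, thr = thr, stat = stat))
    null_pos <- ex[, "pos"]; null_neg <- ex[, "neg"]
  }
  if (!is.null(clusters)) {
    clusters$p <- vapply(seq_len(nrow(clusters)), function(i) {
      s <- clusters$stat[i]
      if (clusters$sign[i] > 0) {
        cnt <- sum(null_pos >= s)
      } else {
        cnt <- sum(null_neg <= s)
      }
      if (pr$exact) cnt / pr$B else (1 + cnt) / (pr$B + 1)
    }, numeric(1))
    clusters$significant <- clusters$p < spec$final_alpha_per_tail
    clusters$start_time <- tx[clusters$start]
    clusters$end_time <- tx[clusters$end]
  }
  mask <- logical(length(t_obs))
  if (!is.null(clusters)) {
    for (i in which(clusters$significant))
      mask[clusters$start[i]:clusters$end[i]] <- TRUE
  }
  structure(list(clusters = clusters, mask = mask,
                 t = as.numeric(t_obs), df = df, threshold = thr,
                 times = tx,
                 null = list(pos = safe_quantile(null_pos,
                                                 c(0.5, 0.95, 0.975)),
                             neg = safe_quantile(null_neg,
                                                 c(0.5, 0.05, 0.025)),
                             prop_pos_finite = mean(is.finite(null_pos))),
                 n_perm = pr$B, exact = pr$exact, spec = spec),
            class = "cluster_test_result")
}

#' @export
print.cluster_test_result <- function(x, ...) {
  cat(sprintf("<cluster_test_result> %s, threshold |t| > %.3f (df = %d), %s%d permutations\n",
              x$spec$cluster_statistic, x$threshold, x$df,
              if (x$exact) "exact, " else "", x$n_perm))
  if (is.null(x$clusters)) {
    cat("  no suprathreshold clusters\n")
  } else {
    for (i in seq_len(nrow(x$clusters))) {
      cl <- x$clusters[i, ]
      cat(sprintf("  %s cluster %.3f-%.3f: stat = %.2f, p = %.4f%s\n",
                  if (cl$sign > 0) "positive" else "negative",
                  cl$start_time, cl$end_time, cl$stat, cl$p,
                  if (cl$significant) " *" else ""))
    }
  }
  invisible(x)
}
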