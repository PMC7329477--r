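#' @useDynLib assrpipe, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif qt pt var median mad sd cor fft
#' @importFrom utils write.csv read.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that generators are pure functions of
#' their `(config, seed)` arguments without disturbing the caller's RNG
#' stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive per-subject seeds from a master seed
#'
#' Counter-based derivation: `seed_i = (master * 48271 + i * 2654435) mod
#' (2^31 - 1)`, so subject streams are reproducible independently of the
#' order in which subjects are generated.
#'
#' @param master_seed integer master seed.
#' @param n number of seeds.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master_seed, n) {
  m <- 2147483647
  s <- (as.numeric(master_seed) %% m) * 48271 %% m
  out <- (s + (seq_len(n)) * 2654435) %% m
  as.integer(out %% (m - 1) + 1)
}

stop_ctx <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

#' Sample from a von Mises distribution
#'
#' Best-Fisher (1979) rejection sampler. `kappa = 0` returns uniform angles;
#' very large `kappa` falls back to the wrapped-normal limit
#' `sd = 1/sqrt(kappa)`.
#'
#' @param n number of draws.
#' @param mu mean direction (radians).
#' @param kappa concentration parameter, `>= 0`. `Inf` gives `mu` exactly.
#' @return Numeric vector of angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(kappa >= 0)
  if (n == 0) return(numeric(0))
  if (is.infinite(kappa)) return(rep(wrap_pi(mu), n))
  if (kappa == 0) return(runif(n, -pi, pi))
  if (kappa > 700) return(wrap_pi(mu + rnorm(n, 0, 1 / sqrt(kappa))))
  tau <- 1 + sqrt(1 + 4 * kappa^2)
  rho <- (tau - sqrt(2 * tau)) / (2 * kappa)
  r <- (1 + rho^2) / (2 * rho)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    if (any(ok)) {
      th <- sign(u3[ok] - 0.5) * acos(pmin(1, pmax(-1, f[ok])))
      take <- min(sum(ok), n - got)
      out[got + seq_len(take)] <- th[seq_len(take)]
      got <- got + take
    }
  }
  wrap_pi(mu + out)
}

wrap_pi <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

#' Ratio of modified Bessel functions I1(kappa)/I0(kappa)
#'
#' Closed-form mean resultant length of a von Mises distribution with
#' concentration `kappa`; the ground-truth link between the simulator's
#' phase-jitter parameter and expected inter-trial coherence.
#'
#' @param kappa concentration, `>= 0` (vectorised).
#' @return Numeric vector in `[0, 1)`.
#' @export
vm_mean_resultant <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}
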