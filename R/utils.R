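# Internal helpers shared across modules.

#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible sub-stream seed (< 2^31) from a master seed and a
# stream index, so cohort sampling, noise and permutations never share a
# stream.
#' @keywords internal
#' @noRd
sub_seed <- function(master, stream) {
  master <- as.double(master) %% 2147483647
  ((master * 7919 + as.double(stream) * 104729) %% 2147483629) + 1
}

# Inverse-CDF sampler for a normal truncated to [lo, hi]; exact and
# vectorized, no rejection loop.
#' @keywords internal
#' @noRd
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(stats::runif(n, p_lo, p_hi), mean, sd)
  pmin(pmax(q, lo), hi)
}

#' @keywords internal
#' @noRd
truncnorm_moments <- function(mu, s, lo, hi) {
  a <- (lo - mu) / s; b <- (hi - mu) / s
  Z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a); db <- stats::dnorm(b)
  m <- mu + s * (da - db) / Z
  v <- s^2 * (1 + (a * da - b * db) / Z - ((da - db) / Z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

# Parent (mu, sigma) of a truncated normal whose truncated moments are as
# close as the family allows to the requested class moments. Requested
# dispersions near the theoretical bound for the interval are matched in
# the least-squares sense (the mean takes priority via the optimizer's
# objective); deterministic.
#' @keywords internal
#' @noRd
truncnorm_parent <- function(target_mean, target_sd, lo, hi) {
  obj <- function(p) {
    mm <- truncnorm_moments(p[1], exp(p[2]), lo, hi)
    (mm[["mean"]] - target_mean)^2 + (mm[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      control = list(maxit = 500, reltol = 1e-12))
  c(mean = fit$par[1], sd = exp(fit$par[2]))
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
#' @noRd
stop_ff <- function(class, fmt, ...) {
  stop(structure(class = c(class, "focalflow_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
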