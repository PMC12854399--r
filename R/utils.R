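# Internal numeric helpers shared by the generator and the PSA engine.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Truncated-normal random draws
#'
#' Inverse-CDF sampler for a normal distribution truncated to
#' \code{[lower, upper]}. \code{mean} and \code{sd} parameterize the parent
#' (untruncated) normal, the convention used throughout the package for both
#' cohort generation and probabilistic sensitivity analysis.
#'
#' @param n number of draws.
#' @param mean,sd parent normal mean and standard deviation (\code{sd >= 0};
#'   \code{sd = 0} gives a point mass at \code{mean}, clamped to the bounds).
#' @param lower,upper truncation bounds, \code{lower < upper}.
#' @return numeric vector of length \code{n}, all values in
#'   \code{[lower, upper]}.
#' @examples
#' x <- rtnorm(1000, mean = 72.7, sd = 11.6, lower = 0, upper = 100)
#' range(x)
#' @export
rtnorm <- function(n, mean, sd, lower = 0, upper = 100) {
  if (sd < 0) stopf("sd must be >= 0, got %g", sd)
  if (lower >= upper) stopf("lower (%g) must be < upper (%g)", lower, upper)
  if (sd == 0) return(rep(min(max(mean, lower), upper), n))
  qtnorm(stats::runif(n), mean, sd, lower, upper)
}

# Truncated-normal quantile function (u in [0,1] -> value in [lower,upper]).
qtnorm <- function(u, mean, sd, lower = 0, upper = 100) {
  if (sd == 0) return(rep(min(max(mean, lower), upper), length(u)))
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  x <- stats::qnorm(pl + u * (pu - pl), mean, sd)
  pmin(pmax(x, lower), upper) # guard rounding at extreme quantiles
}

#' Moments of a truncated normal distribution
#'
#' Closed-form mean and standard deviation of a normal distribution with
#' parent parameters \code{mean}, \code{sd} truncated to
#' \code{[lower, upper]}. Used to express what the cohort generator actually
#' targets once truncation at the 0 and 100 bounds is accounted for.
#'
#' @inheritParams rtnorm
#' @return named list with elements \code{mean} and \code{sd}.
#' @export
tnorm_moments <- function(mean, sd, lower = 0, upper = 100) {
  if (sd == 0) {
    return(list(mean = min(max(mean, lower), upper), sd = 0))
  }
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- stats::pnorm(b) - stats::pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / z
  v <- sd^2 * (1 + (a * da - b * db) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

# Moment-matched gamma draws for cost parameters:
# shape = (mean/sd)^2, scale = sd^2/mean. sd = 0 yields a point mass.
rgamma_mm <- function(n, mean, sd) {
  if (mean <= 0) stopf("gamma mean must be > 0, got %g", mean)
  if (sd < 0) stopf("sd must be >= 0, got %g", sd)
  if (sd == 0) return(rep(mean, n))
  stats::rgamma(n, shape = (mean / sd)^2, scale = sd^2 / mean)
}

# Largest-remainder apportionment of `total` integer units proportional to
# nonnegative weights; ties broken by index order (deterministic).
largest_remainder <- function(weights, total) {
  if (any(weights < 0)) stopf("negative weight in largest-remainder rounding")
  s <- sum(weights)
  if (s == 0) stopf("all weights zero in largest-remainder rounding")
  quota <- weights / s * total
  base <- floor(quota)
  left <- total - sum(base)
  if (left > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Weighted mean / sample SD (frequency-style weights, n-1 analogue).
wtd_mean <- function(x, w) sum(w * x) / sum(w)
wtd_sd <- function(x, w) {
  m <- wtd_mean(x, w)
  sw <- sum(w)
  v <- sum(w * (x - m)^2) / (sw - sum(w^2) / sw) # reliability-weighted n-1
  sqrt(max(v, 0))
}
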