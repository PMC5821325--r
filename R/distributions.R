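# Internal samplers and moment calibration for the synthetic generator.
#
# Two building blocks recur: a truncated normal on a finite interval for
# plastid lengths, and a rounded-then-clamped normal for integer chloroplast
# counts. Both are calibrated by solving for the location parameter whose
# *post-truncation* mean equals the published target, so truncation bias
# never leaks into the generated moments.

# Mean of N(mu, sigma) truncated to [lo, hi]. When mu sits many sigmas
# outside the interval the normalising mass underflows; the truncated mean
# is then the nearest endpoint to working precision.
tnorm_mean <- function(mu, sigma, lo, hi) {
  a <- (lo - mu) / sigma
  b <- (hi - mu) / sigma
  z <- pnorm(b) - pnorm(a)
  if (z < 1e-12) return(if (mu < lo) lo else hi)
  mu + sigma * (dnorm(a) - dnorm(b)) / z
}

# Location mu such that the truncated mean equals `target` (lo < target < hi).
tnorm_solve_mu <- function(target, sigma, lo, hi) {
  if (!(target > lo && target < hi)) {
    abort(sprintf("target mean %.3f not inside (%.3f, %.3f).", target, lo, hi))
  }
  stats::uniroot(
    function(mu) tnorm_mean(mu, sigma, lo, hi) - target,
    interval = c(lo - 8 * sigma, hi + 8 * sigma),
    tol = 1e-10
  )$root
}

# Inverse-CDF sampler for the truncated normal.
rtnorm <- function(n, mu, sigma, lo, hi) {
  p_lo <- pnorm(lo, mu, sigma)
  p_hi <- pnorm(hi, mu, sigma)
  qnorm(runif(n, p_lo, p_hi), mu, sigma)
}

# pmf of round(N(mu, sigma)) clamped to the integers lo..hi.
count_pmf <- function(mu, sigma, lo, hi) {
  k <- lo:hi
  p <- pnorm(k + 0.5, mu, sigma) - pnorm(k - 0.5, mu, sigma)
  p[1] <- pnorm(lo + 0.5, mu, sigma)
  p[length(p)] <- 1 - pnorm(hi - 0.5, mu, sigma)
  setNames(p, k)
}

count_mean <- function(mu, sigma, lo, hi) {
  sum((lo:hi) * count_pmf(mu, sigma, lo, hi))
}

# Location mu such that the clamped-count mean equals `target`.
count_solve_mu <- function(target, sigma, lo, hi) {
  if (!(target > lo && target < hi)) {
    abort(sprintf("target count mean %.3f not inside (%d, %d).", target, lo, hi))
  }
  stats::uniroot(
    function(mu) count_mean(mu, sigma, lo, hi) - target,
    interval = c(lo - 10 * sigma, hi + 10 * sigma),
    tol = 1e-9
  )$root
}

rcount <- function(n, mu, sigma, lo, hi) {
  pmin(pmax(round(stats::rnorm(n, mu, sigma)), lo), hi)
}
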