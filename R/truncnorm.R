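# Truncated-normal draws and moments by the inverse-CDF method.
# Exact, vectorised, no rejection loop; adequate over the mild truncation
# ranges that trait tables in this domain use (bounds within ~2-3 SD).

rtnorm <- function(n, mean = 0, sd = 1, lower = -Inf, upper = Inf) {
  stopifnot(all(sd >= 0), all(lower <= upper))
  if (any(sd == 0)) {
    out <- rep_len(mean, n)
    # degenerate draws must still respect the bounds
    bad <- out < lower | out > upper
    if (any(bad)) abort("degenerate truncated normal: mean outside [lower, upper]")
    runif(n) # keep the RNG stream advancing consistently with the sd > 0 path
    return(out)
  }
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# Closed-form mean and variance of N(mean, sd^2) truncated to [lower, upper].
tnorm_moments <- function(mean, sd, lower, upper) {
  if (sd == 0) return(list(mean = mean, var = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  Z <- pnorm(b) - pnorm(a)
  da <- stats::dnorm(a)
  db <- stats::dnorm(b)
  m <- mean + sd * (da - db) / Z
  # standard truncated-normal variance identity
  aa <- if (is.finite(a)) a * da else 0
  bb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (aa - bb) / Z - ((da - db) / Z)^2)
  list(mean = m, var = v)
}
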