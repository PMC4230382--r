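# Independent oracles used across the suite.  Each deliberately takes a
# different computational route from the package implementation.

# Largest-remainder apportionment by explicit candidate enumeration: assign
# floor quotas, then hand out the leftover one unit at a time to the largest
# remaining fractional part (ties by index).
oracle_largest_remainder <- function(requests, resource) {
  quota <- resource * requests / sum(requests)
  out <- floor(quota)
  frac <- quota - out
  while (sum(out) < resource) {
    i <- which(frac == max(frac))[1]
    out[i] <- out[i] + 1
    frac[i] <- -1
  }
  as.integer(out)
}

# Beta method-of-moments by numerical inversion: the fitted mean pins
# alpha/(alpha+beta) at the sample mean, and the total concentration s is
# found by root-solving the variance equation on the log scale (the
# analytic beta variance is monotone decreasing in s).  Independent of the
# closed-form inversion in the package; precise to near machine epsilon.
oracle_beta_moments <- function(x) {
  m <- mean(x)
  v <- mean((x - m)^2)
  g <- function(u) {
    s <- exp(u)
    a <- m * s; b <- (1 - m) * s
    log(a * b / ((a + b)^2 * (a + b + 1))) - log(v)
  }
  u <- stats::uniroot(g, c(-20, 30), tol = 1e-14)$root
  s <- exp(u)
  c(m * s, (1 - m) * s)
}

# Pearson chi-square from first principles: observed vs expected cell counts.
oracle_chi_square <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Flat engine configuration for pipeline tests: a large, capped resource so
# that requests are always fulfillable and the resource regime is stable.
flat_config <- function() {
  engine_config(initial_resource = 5000L, resource_cap = 5000,
                max_trials = 109L)
}
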