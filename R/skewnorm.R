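# Skew-normal utilities for the onset-of-birth distribution.
# The standard skew-normal with shape alpha has density 2*phi(z)*Phi(alpha*z).
# Only sampling and quantiles are needed; quantiles are obtained numerically
# from the integrated density, which keeps the generator free of external
# distribution packages and is exact to integrate()/uniroot() tolerance.

.dsn <- function(z, alpha) 2 * dnorm(z) * pnorm(alpha * z)

.psn <- function(q, alpha) {
  vapply(q, function(x) {
    integrate(.dsn, -Inf, x, alpha = alpha, rel.tol = 1e-10)$value
  }, numeric(1))
}

.qsn <- function(p, alpha) {
  vapply(p, function(pp) {
    uniroot(function(x) .psn(x, alpha) - pp,
            interval = c(-12, 12), tol = 1e-9)$root
  }, numeric(1))
}

# Draw n standard skew-normal deviates via the delta representation:
# Z = delta*|U0| + sqrt(1-delta^2)*U1 with U0, U1 iid N(0,1).
.rsn <- function(n, alpha) {
  delta <- alpha / sqrt(1 + alpha^2)
  u0 <- rnorm(n)
  u1 <- rnorm(n)
  delta * abs(u0) + sqrt(1 - delta^2) * u1
}

# Location for a skew-normal parameterized by its median:
# X = xi + omega*Z has median xi + omega*median(Z).
.sn_location_for_median <- function(median_days, omega, alpha) {
  median_days - omega * .qsn(0.5, alpha)
}
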