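# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: closed forms, polynomial root finding, plain-R
# Euler recursions, and sign-scan bracketing.

# exact travel time between x0 and x1 for the nu = 1 factorized threshold
# model dx/dt = -r x (1 - x/A)(1 - x/K), by partial fractions
erm1_time_closed_form <- function(x0, x1, r, A, K) {
  a <- 1 / (A * K); b <- 1 / (A * (K - A)); cc <- -1 / (K * (K - A))
  Fx <- function(x) a * log(x) - b * log(abs(A - x)) - cc * log(abs(K - x))
  -(A * K / r) * (Fx(x1) - Fx(x0))
}

# threshold/capacity of ERM1 via polynomial roots in u = x^(1/nu):
# the per-capita factor is r - mu u + gamma u^2
erm1_AK_polyroot <- function(nu, r, mu, gamma) {
  u <- polyroot(c(r, -mu, gamma))
  u <- sort(Re(u[abs(Im(u)) < 1e-8 * max(1, abs(u))]))
  if (length(u) < 2 || any(u <= 0)) return(NULL)
  # polish each root with a few Newton steps on q(u) = r - mu u + gamma u^2
  for (i in 1:4) u <- u - (r - mu * u + gamma * u^2) / (-mu + 2 * gamma * u)
  u^nu
}

# stationary points of the constant-s model by log-grid sign scan plus
# bisection (independent of the package's bracketing strategy)
erm2_roots_scan <- function(nu, r, mu, s, lo = 1e-8, hi = 1e18) {
  g <- function(x) nu * r * x - nu * mu * x^((nu + 1) / nu) - s
  xs <- 10^seq(log10(lo), log10(hi), length.out = 4000)
  sg <- sign(g(xs))
  flips <- which(sg[-1] * sg[-length(sg)] < 0)
  vapply(flips, function(i) uniroot(g, c(xs[i], xs[i + 1]), tol = 1e-12)$root,
         numeric(1))
}

# plain-R daily Euler recursion of the complete-model drift
euler_drift_R <- function(x0, nu, r, mu, s, m, n_days) {
  x <- numeric(n_days + 1)
  x[1] <- x0
  for (t in seq_len(n_days)) {
    Fx <- x[t] + (nu * r * x[t] - nu * mu * x[t]^((nu + 1) / nu) - s[t]) + m[t]
    x[t + 1] <- max(Fx, 0)
  }
  x
}

# effective threshold of the phase-frozen daily map (constant s, constant
# mutation influx m_bar): bisection on the initial condition separating
# decay to 0 from sustained growth past an escape size
frozen_map_threshold <- function(nu, r, mu, s, m_bar, n_days = 20000,
                                 lo = 1e-3, hi = 1e7, escape = 5e7) {
  fate <- function(x0) {
    x <- x0
    for (t in seq_len(n_days)) {
      x <- max(x + nu * r * x - nu * mu * x^((nu + 1) / nu) - s + m_bar, 0)
      if (x > escape) return(1L)
      if (x < lo) return(-1L)
    }
    0L
  }
  if (fate(lo) >= 0 || fate(hi) <= 0) return(NA_real_)
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (fate(mid) >= 0) hi <- mid else lo <- mid
    if (hi / lo < 1 + 1e-6) break
  }
  sqrt(lo * hi)
}

# random valid parameter generators (fixed seeds set by callers)
random_erm1_params <- function() {
  nu <- 10^runif(1, -0.3, 1.5)
  r <- 10^runif(1, -2, 0)
  A <- 10^runif(1, 0, 2)
  K <- A * 10^runif(1, 0.5, 5)
  list(nu = nu, r = r, A = A, K = K,
       params = erm1_params_from_AK(r = r, A = A, K = K, nu = nu))
}

random_richards_params <- function(nu_range = c(0.5, 100)) {
  nu <- exp(runif(1, log(nu_range[1]), log(nu_range[2])))
  r <- 10^runif(1, -2, 0)
  K <- 10^runif(1, 2, 8)
  growth_params("richards", nu = nu, r = r, mu = r / K^(1 / nu))
}
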