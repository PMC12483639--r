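#' Parameters of the daily binomial mutation process
#'
#' Each of `n` healthy stem cells mutates independently on a given day with
#' probability `p(t)`; the number of new mutated cells per day is therefore
#' binomial with expected value `n p(t)` and variance `n p(t)(1 - p(t))`.
#' The per-cell probability drifts linearly over a lifetime,
#' \deqn{p(t) = p_0 (1 + \delta t / (100 T)),}
#' starting from `p0` at birth and reaching a `delta` per-cent increase at
#' the life expectancy `T`.
#'
#' @param n number of healthy stem cells at risk (fixed count, >= 1).
#' @param p0 per-cell daily mutation probability at birth (0 < p0 < 1).
#' @param delta per-cent increase of `p` over a lifetime (>= 0).
#' @param life_expectancy_years life expectancy `T`, in years (stored in
#'   days internally; 1 year = 365 days).
#' @return an object of class `mutation_params`.
#' @export
mutation_params <- function(n, p0, delta = 0, life_expectancy_years = 80) {
  stopifnot(is.numeric(n), n >= 1, is.numeric(p0), is.numeric(delta),
            life_expectancy_years > 0)
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be in (0, 1)")
  if (delta < 0) stop("'delta' must be >= 0")
  structure(list(n = n, p0 = p0, delta = delta,
                 T_days = life_expectancy_years * 365),
            class = "mutation_params")
}

#' @export
print.mutation_params <- function(x, ...) {
  cat(sprintf("<mutation_params: n = %g, p0 = %g, delta = %g%%, T = %g y>\n",
              x$n, x$p0, x$delta, x$T_days / 365))
  cat(sprintf("  expected mutations/day at birth: %g\n", x$n * x$p0))
  invisible(x)
}

#' Age-dependent per-cell mutation probability
#'
#' @param t age in days (>= 0); vectorized.
#' @param params a [mutation_params()] object.
#' @return `p(t)`, clipped at 1 (with a one-time warning; unattainable in
#'   sensible configurations but must not crash parameter sweeps).
#' @export
mutation_probability <- function(t, params) {
  stopifnot(inherits(params, "mutation_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  p <- params$p0 * (1 + params$delta * t / (100 * params$T_days))
  if (any(p > 1)) {
    warning("mutation probability clipped at 1")
    p <- pmin(p, 1)
  }
  p
}

#' Probability mass of m mutations among n cells
#'
#' Exact binomial mass, evaluated in log space by [stats::dbinom()] so it
#' is stable up to `n` of order 1e9.
#'
#' @param m number of mutated cells (0 <= m <= n); vectorized.
#' @param n number of cells.
#' @param p per-cell mutation probability.
#' @return `P(m; n, p)`.
#' @export
mutation_pmf <- function(m, n, p) {
  if (any(m > n)) stop("'m' must not exceed 'n'")
  if (any(p < 0 | p > 1)) stop("'p' must be in [0, 1]")
  stats::dbinom(m, size = n, prob = p)
}

#' Draw the number of new mutations for given ages
#'
#' One exact binomial draw `m(t) ~ Binomial(n, p(t))` per element of `t`,
#' using R's exact binomial sampler (no normal/Poisson approximation: with
#' `n p` of a few hundred per day, the tail behaviour drives threshold
#' crossings). Reproducible under a fixed RNG state.
#'
#' @param t age in days; vectorized (one draw per element).
#' @param params a [mutation_params()] object.
#' @return integer vector of mutation counts.
#' @export
sample_daily_mutations <- function(t, params) {
  p <- mutation_probability(t, params)
  stats::rbinom(length(t), size = params$n, prob = p)
}
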