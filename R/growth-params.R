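#' Parameters of a growth model with or without an extinction threshold
#'
#' Constructs and validates the parameter set of one of the three growth
#' models used throughout the package:
#'
#' * `"richards"` -- generalized logistic growth
#'   \deqn{dx/dt = \nu r x - \nu\mu x^{(\nu+1)/\nu} = \nu r x (1 - (x/K)^{1/\nu}),}
#'   with carrying capacity \eqn{K = (r/\mu)^\nu} and no extinction threshold.
#' * `"erm1"` -- the classical threshold extension (Volterra-type when
#'   \eqn{\nu = 1}),
#'   \deqn{dx/dt = -\nu^2 r x + \nu^2\mu x^{(\nu+1)/\nu} - \nu^2\gamma x^{(\nu+2)/\nu}
#'        = -\nu^2 r x (1 - (x/A)^{1/\nu})(1 - (x/K)^{1/\nu}),}
#'   which has an extinction threshold \eqn{A} whenever \eqn{\mu^2 > 4 r \gamma}.
#' * `"erm2"` -- Richards growth with a constant immune kill term `s`
#'   (cells removed per day), kept non-negative by a piecewise branch at
#'   \eqn{x = 0}:
#'   \deqn{dx/dt = \nu r x - \nu\mu x^{(\nu+1)/\nu} - s \;(x > 0), \qquad 0 \;(x=0).}
#'
#' Units: `x` is a cell count, time is measured in days (or dimensionless
#' time units for the illustrative parameterizations), `r` in day^-1,
#' `mu` in day^-1 cells^(-1/nu), `gamma` in day^-1 cells^(-2/nu), `s` in
#' cells day^-1.
#'
#' @param model one of `"richards"`, `"erm1"`, `"erm2"`.
#' @param nu shape parameter \eqn{\nu > 0} (dimensionless). Controls the
#'   asymmetry between early growth and late saturation.
#' @param r per-capita rate scale (day^-1, > 0).
#' @param mu death/birth rate parameter (>= 0).
#' @param gamma large-population death parameter (ERM1 only, >= 0).
#' @param s constant immune response (ERM2 only, cells day^-1, >= 0).
#' @return an object of class `growth_params`.
#' @seealso [growth_rate()], [growth_equilibria()], [integrate_growth()],
#'   [erm1_params_from_AK()], [erm2_params_for_AK()]
#' @examples
#' p <- growth_params("erm1", nu = 1, r = 0.12, mu = 0.120012, gamma = 1.2e-5)
#' growth_equilibria(p)
#' @export
growth_params <- function(model = c("richards", "erm1", "erm2"),
                          nu, r, mu = 0, gamma = NULL, s = NULL) {
  model <- match.arg(model)
  stopifnot(is.numeric(nu), length(nu) == 1L, is.finite(nu),
            is.numeric(r), length(r) == 1L, is.finite(r),
            is.numeric(mu), length(mu) == 1L, is.finite(mu))
  if (nu <= 0) stop("'nu' must be > 0")
  if (r <= 0) stop("'r' must be > 0")
  if (mu < 0) stop("'mu' must be >= 0")
  if (model == "erm1") {
    if (is.null(gamma)) stop("ERM1 requires 'gamma'")
    stopifnot(is.numeric(gamma), length(gamma) == 1L, is.finite(gamma))
    if (gamma < 0) stop("'gamma' must be >= 0")
  } else {
    gamma <- NULL
  }
  if (model == "erm2") {
    if (is.null(s)) s <- 0
    stopifnot(is.numeric(s), length(s) == 1L, is.finite(s))
    if (s < 0) stop("'s' must be >= 0")
  } else {
    s <- NULL
  }
  structure(list(model = model, nu = nu, r = r, mu = mu,
                 gamma = gamma, s = s),
            class = "growth_params")
}

#' @export
print.growth_params <- function(x, ...) {
  cat(sprintf("<growth_params: %s>\n", x$model))
  cat(sprintf("  nu = %g, r = %g, mu = %g", x$nu, x$r, x$mu))
  if (!is.null(x$gamma)) cat(sprintf(", gamma = %g", x$gamma))
  if (!is.null(x$s)) cat(sprintf(", s = %g", x$s))
  cat("\n")
  if (x$model == "richards" && x$mu > 0)
    cat(sprintf("  K = (r/mu)^nu = %g cells\n", (x$r / x$mu)^x$nu))
  invisible(x)
}

#' ERM1 parameters from a threshold/capacity parameterization
#'
#' Converts the intuitive `(r, A, K)` parameterization of the factorized
#' threshold model (with `nu = 1`) into the rate parameterization
#' `(r, mu, gamma)` via `mu = r (1/A + 1/K)` and `gamma = r / (A K)`.
#'
#' @param r per-capita decay rate of small populations (day^-1).
#' @param A extinction threshold (cells), `0 < A < K`.
#' @param K carrying capacity (cells).
#' @param nu shape parameter; the conversion generalizes through the
#'   substitution `u = x^(1/nu)`, so `A` and `K` are matched for any `nu`.
#' @return a `growth_params` object with `model = "erm1"`.
#' @export
erm1_params_from_AK <- function(r, A, K, nu = 1) {
  stopifnot(A > 0, K > A, r > 0, nu > 0)
  uA <- A^(1 / nu); uK <- K^(1 / nu)
  growth_params("erm1", nu = nu, r = r,
                mu = r * (1 / uA + 1 / uK),
                gamma = r / (uA * uK))
}

#' ERM2 parameters hitting prescribed equilibria
#'
#' Solves for the pair `(mu, s)` such that the constant-immune-response
#' model has stationary points exactly at `A` and `K` for the given `nu`
#' and `r`. The two stationarity conditions are linear in `(mu, s)`:
#' `mu = r (K - A) / (K^((nu+1)/nu) - A^((nu+1)/nu))` and
#' `s = nu r A - nu mu A^((nu+1)/nu)`.
#'
#' @inheritParams erm1_params_from_AK
#' @return a `growth_params` object with `model = "erm2"`, or an error if
#'   the implied `s` is not positive (the `(A, K)` target is unreachable).
#' @export
erm2_params_for_AK <- function(r, A, K, nu = 1) {
  stopifnot(A > 0, K > A, r > 0, nu > 0)
  mu <- r * (K - A) / (K^((nu + 1) / nu) - A^((nu + 1) / nu))
  s <- nu * r * A - nu * mu * A^((nu + 1) / nu)
  if (!is.finite(s) || s <= 0)
    stop("(A, K) target unreachable for erm2 at this (nu, r)")
  growth_params("erm2", nu = nu, r = r, mu = mu, s = s)
}

#' Instantaneous growth rate dx/dt
#'
#' Evaluates the right-hand side of the chosen growth model at population
#' size `x`. For ERM2 the piecewise branch returns 0 at `x = 0`, so the
#' constant kill term cannot drive the population negative.
#'
#' @param x population size (cells, >= 0); vectorized.
#' @param params a [growth_params()] object.
#' @param s optional time-varying immune response overriding `params$s`
#'   (ERM2 only).
#' @return dx/dt in cells day^-1, same length as `x`.
#' @export
growth_rate <- function(x, params, s = NULL) {
  stopifnot(inherits(params, "growth_params"))
  if (any(x < 0)) stop("'x' must be non-negative")
  nu <- params$nu; r <- params$r; mu <- params$mu
  switch(params$model,
    richards = nu * r * x - nu * mu * x^((nu + 1) / nu),
    erm1 = -nu^2 * r * x + nu^2 * mu * x^((nu + 1) / nu) -
      nu^2 * params$gamma * x^((nu + 2) / nu),
    erm2 = {
      if (is.null(s)) s <- params$s
      ifelse(x == 0, 0, nu * r * x - nu * mu * x^((nu + 1) / nu) - s)
    })
}
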