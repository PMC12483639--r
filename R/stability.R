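#' Equilibria and linear stability of a growth model
#'
#' Locates the non-negative stationary points of the model, linearizes the
#' right-hand side at each, and computes the asymmetry ratio
#' \eqn{|\lambda_{grow}/\lambda_{sat}|} between the divergence rate at the
#' point feeding growth (the extinction threshold `A` where one exists,
#' otherwise `x = 0`) and the saturation rate at the carrying capacity `K`.
#' Known cancers progress with ratio >= 1 (small tumours grow at least as
#' fast as large ones saturate); the classical threshold extension ERM1 is
#' pinned below 1 since its ratio equals `(A/K)^(1/nu)`.
#'
#' Closed forms are used where they exist: Richards has equilibria
#' `{0, K}` with rates `(nu*r, -r)`; ERM1 has
#' `A = ((mu - sqrt(mu^2 - 4 r gamma)) / (2 gamma))^nu` (and `K` with `+`),
#' existing iff `mu^2 > 4 r gamma`. ERM2 equilibria have no closed form and
#' are found by bracketed root finding on
#' `g(x) = nu*r*x - nu*mu*x^((nu+1)/nu) - s`, which is unimodal on `x > 0`
#' with maximum at `x* = (nu r / ((nu+1) mu))^nu`; the smaller root is `A`,
#' the larger `K`.
#'
#' @param params a [growth_params()] object.
#' @param numeric_rates if `TRUE`, compute linearization rates by a
#'   central-difference derivative of the right-hand side instead of the
#'   analytic formulas (used for cross-checking).
#' @return an object of class `stability_report`: a list with `equilibria`
#'   (ascending, always containing 0), `rates` (linearization rate at each
#'   equilibrium; positive = unstable), `lambda_grow`, `lambda_sat`
#'   (reported as a negative number), `defining_feature`
#'   (`|lambda_grow/lambda_sat|`), and `A`, `K` where defined.
#' @examples
#' growth_equilibria(erm1_params_from_AK(r = 0.12, A = 1, K = 1e4))
#' @export
growth_equilibria <- function(params, numeric_rates = FALSE) {
  stopifnot(inherits(params, "growth_params"))
  nu <- params$nu; r <- params$r; mu <- params$mu
  A <- NA_real_; K <- NA_real_
  eq <- 0
  if (params$model == "richards") {
    if (mu > 0) {
      K <- (r / mu)^nu
      eq <- c(0, K)
    }
  } else if (params$model == "erm1") {
    g <- params$gamma
    disc <- mu^2 - 4 * r * g
    if (g > 0 && disc > 0) {
      # rationalized form of (mu - sqrt(disc))/(2 gamma): avoids the
      # catastrophic cancellation when 4 r gamma << mu^2 (A << K)
      A <- (2 * r / (mu + sqrt(disc)))^nu
      K <- ((mu + sqrt(disc)) / (2 * g))^nu
      eq <- c(0, A, K)
    } else if (g == 0 && mu > 0) {
      # degenerates to an inverted Richards: single positive equilibrium
      A <- (r / mu)^nu
      eq <- c(0, A)
    }
  } else { # erm2
    s <- params$s
    if (s == 0) {
      if (mu > 0) { K <- (r / mu)^nu; eq <- c(0, K) }
    } else if (mu > 0) {
      roots <- erm2_positive_roots(nu, r, mu, s)
      if (!is.null(roots)) {
        A <- roots[1]; K <- roots[2]
        eq <- c(0, A, K)
      }
    }
  }
  rate_at <- function(x) {
    if (numeric_rates || params$model == "erm2") {
      numeric_rate(params, x)
    } else {
      analytic_rate(params, x)
    }
  }
  rates <- vapply(eq, rate_at, numeric(1))
  lg <- NA_real_; ls <- NA_real_
  if (params$model == "richards") {
    lg <- rates[1]
    if (length(eq) > 1) ls <- rates[2]
  } else if (!is.na(A) && !is.na(K)) {
    lg <- rates[match(A, eq)]
    ls <- rates[match(K, eq)]
  }
  structure(list(model = params$model, params = params,
                 equilibria = eq, rates = rates,
                 A = A, K = K,
                 lambda_grow = lg, lambda_sat = ls,
                 defining_feature = if (is.na(lg) || is.na(ls)) NA_real_
                                    else abs(lg / ls)),
            class = "stability_report")
}

# positive roots of g(x) = nu r x - nu mu x^((nu+1)/nu) - s, or NULL if s
# exceeds the maximum of g (extinction-only regime)
erm2_positive_roots <- function(nu, r, mu, s, tol = 1e-12) {
  xstar <- (nu * r / ((nu + 1) * mu))^nu
  g <- function(x) nu * r * x - nu * mu * x^((nu + 1) / nu) - s
  if (!is.finite(xstar) || g(xstar) <= 0) return(NULL)
  # lower root in (0, xstar): g(0) = -s < 0
  lo <- stats::uniroot(g, c(0, xstar), tol = tol * max(1, xstar))$root
  # upper root in (xstar, K_richards); s > 0 pulls K below the Richards value
  K0 <- (r / mu)^nu
  hi <- stats::uniroot(g, c(xstar, K0), tol = tol * max(1, K0))$root
  c(lo, hi)
}

# analytic linearization rates (Richards, ERM1)
analytic_rate <- function(params, x) {
  nu <- params$nu; r <- params$r; mu <- params$mu
  if (params$model == "richards") {
    if (x == 0) return(nu * r)
    # f'(x) = nu r - (nu+1) mu x^(1/nu); at K this is -r
    return(nu * r - (nu + 1) * mu * x^(1 / nu))
  }
  g <- params$gamma
  if (x == 0) return(-nu^2 * r)
  u <- x^(1 / nu)
  -nu^2 * r + nu * (nu + 1) * mu * u - nu * (nu + 2) * g * u^2
}

# central-difference derivative of the rhs; step scales with the equilibrium
numeric_rate <- function(params, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * max(1, x)
  xm <- max(x - h, 0)
  (growth_rate(x + h, params) - growth_rate(xm, params)) / (x + h - xm)
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("<stability_report: %s>\n", x$model))
  df <- data.frame(equilibrium = x$equilibria, rate = x$rates)
  print(df, row.names = FALSE)
  if (!is.na(x$defining_feature))
    cat(sprintf("  |lambda_grow / lambda_sat| = %g\n", x$defining_feature))
  invisible(x)
}

#' Approximate stationary extinction threshold of ERM2
#'
#' The stationary threshold `A ~ 10^a` of the constant-immune-response
#' model can be approximated by
#' \deqn{A \approx \frac{s}{\nu r - \mu(\nu + a \ln 10)},}
#' a first-order expansion of `A^(1/nu)` around `10^(a/nu)`. The decade
#' exponent `a` is resolved self-consistently: starting from `a`, iterate
#' `a <- log10(A_approx)` until the update falls below `1e-3` (at most 50
#' iterations).
#'
#' @param params an ERM2 [growth_params()] object (constant `s`).
#' @param a starting guess for the decade exponent `log10(A)`; default 2.
#' @param s_override optional immune response replacing `params$s`.
#' @return the approximate threshold in cells, with attribute `"a"` (the
#'   converged exponent) and `"converged"`.
#' @export
erm2_threshold_approx <- function(params, a = 2, s_override = NULL) {
  stopifnot(inherits(params, "growth_params"), params$model == "erm2")
  s <- if (is.null(s_override)) params$s else s_override
  if (s == 0) {
    out <- 0
    attributes(out) <- list(a = -Inf, converged = TRUE)
    return(out)
  }
  nu <- params$nu; r <- params$r; mu <- params$mu
  converged <- FALSE
  A <- NA_real_
  for (i in seq_len(50)) {
    den <- nu * r - mu * (nu + a * log(10))
    if (!is.finite(den) || den <= 0)
      stop("threshold approximation invalid: non-positive denominator")
    A <- s / den
    anew <- log10(A)
    if (abs(anew - a) < 1e-3) { converged <- TRUE; a <- anew; break }
    a <- anew
  }
  if (!converged)
    warning("threshold exponent iteration did not converge in 50 steps")
  attributes(A) <- list(a = a, converged = converged)
  A
}

#' Asymmetry ratio versus the shape parameter
#'
#' Evaluates the defining asymmetry ratio `|lambda_grow/lambda_sat|` over a
#' grid of shape parameters `nu`, holding the equilibria fixed: for ERM1
#' and ERM2 the remaining parameters (`mu`, `gamma`) or (`mu`, `s`) are
#' re-solved at each `nu` so the threshold stays at `A` and the carrying
#' capacity at `K`. Richards needs no re-solve and its ratio equals `nu`.
#'
#' @param model one of `"richards"`, `"erm1"`, `"erm2"`.
#' @param nu_grid vector of shape parameters (> 0).
#' @param r rate scale (only sets the time unit; the ratio is invariant).
#' @param A,K fixed threshold and carrying capacity targets (ignored for
#'   Richards except that `K` sets `mu`).
#' @return a data frame with columns `nu`, `ratio`, and `ok` (`FALSE` where
#'   the `(A, K)` target was unreachable; the ratio is `NA` there).
#' @export
asymmetry_curve <- function(model = c("richards", "erm1", "erm2"),
                            nu_grid, r = 1, A = 1, K = 100) {
  model <- match.arg(model)
  one <- function(nu) {
    p <- tryCatch(switch(model,
      richards = growth_params("richards", nu = nu, r = r, mu = r / K^(1 / nu)),
      erm1 = erm1_params_from_AK(r = r, A = A, K = K, nu = nu),
      erm2 = erm2_params_for_AK(r = r, A = A, K = K, nu = nu)),
      error = function(e) NULL)
    if (is.null(p)) return(NA_real_)
    growth_equilibria(p)$defining_feature
  }
  ratio <- vapply(nu_grid, one, numeric(1))
  data.frame(nu = nu_grid, ratio = ratio, ok = is.finite(ratio))
}
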