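#' Convert tumour volume to cell count
#'
#' Uses a cancer cell density of 1e9 cells per cm^3.
#'
#' @param volume tumour volume (>= 0).
#' @param unit `"cm3"` or `"mm3"`.
#' @return cell count.
#' @export
volume_to_cells <- function(volume, unit = c("cm3", "mm3")) {
  unit <- match.arg(unit)
  if (any(volume < 0)) stop("'volume' must be >= 0")
  volume * switch(unit, cm3 = 1e9, mm3 = 1e6)
}

#' @rdname volume_to_cells
#' @param cells cell count (>= 0).
#' @export
cells_to_volume <- function(cells, unit = c("cm3", "mm3")) {
  unit <- match.arg(unit)
  if (any(cells < 0)) stop("'cells' must be >= 0")
  cells / switch(unit, cm3 = 1e9, mm3 = 1e6)
}

# free-parameter catalogue per model; erm1 is fitted in its threshold
# parameterization (r, A, K) as in the four-way model comparison
fit_par_names <- function(model) {
  switch(model,
    richards = c("nu", "r", "mu"),
    erm1 = c("nu", "r", "A", "K"),
    erm2 = c("nu", "r", "mu", "s"))
}

fit_params_build <- function(model, pars) {
  switch(model,
    richards = growth_params("richards", nu = pars[["nu"]], r = pars[["r"]],
                             mu = pars[["mu"]]),
    erm1 = erm1_params_from_AK(r = pars[["r"]], A = pars[["A"]],
                               K = pars[["K"]], nu = pars[["nu"]]),
    erm2 = growth_params("erm2", nu = pars[["nu"]], r = pars[["r"]],
                         mu = pars[["mu"]], s = pars[["s"]]))
}

#' Fit a growth model to a tumour time series by shooting
#'
#' Integrates the chosen model from the first observation (the shooting
#' start: `x(0)` is pinned to the first data point) and minimizes squared
#' residuals against the remaining observations with the
#' Levenberg-Marquardt algorithm, multi-started over a grid of initial
#' shape parameters. Residuals are taken on the log scale by default,
#' since tumour sizes span decades and a linear-scale loss would let the
#' largest points dominate; set `log_scale = FALSE` for linear residuals.
#' All parameters are optimized on the log scale, which enforces
#' positivity and handles the decades-wide plausible ranges
#' (`nu` bounded in `[0.1, 1e6]`).
#'
#' @param data data frame with columns `day` (first must be 0) and `size`
#'   (cells, > 0); an optional `replicate` column is allowed (all points
#'   are fitted).
#' @param model `"richards"`, `"erm1"` or `"erm2"`.
#' @param free character vector of parameters to fit; defaults to all of
#'   the model's parameters (`nu, r, mu` / `nu, r, A, K` / `nu, r, mu, s`).
#' @param fixed named list of parameters to hold (e.g. `list(nu = 1)`).
#' @param init optional named list of starting values; defaults follow a
#'   multi-start recipe: `nu` in `{1, 10, 1e3, 1e5}`, `r` from the
#'   early-time log-slope, and `mu`/`s` (or `A`, `K`) from the threshold
#'   re-parameterization at plausible `A` in `{1e2, 1e4}` and
#'   `K = 2 * max(data)`.
#' @param bounds named list of length-2 vectors overriding the default
#'   box constraints.
#' @return an object of class `growth_fit` with components `params`
#'   (fitted [growth_params()]), `coefficients`, `free`, `fixed`, `sse`
#'   (on the fitted scale), `K`, `A`, `K_below_data` (fitted carrying
#'   capacity below the largest observation -- inconsistent with the host
#'   dying before the tumour saturates), `fitted`, `data`, `log_scale`,
#'   `starts` (per-start diagnostics).
#' @seealso [compare_growth_models()]
#' @export
fit_growth_model <- function(data, model = c("erm2", "erm1", "richards"),
                             free = NULL, fixed = list(), init = NULL,
                             bounds = list(), log_scale = TRUE) {
  model <- match.arg(model)
  stopifnot(is.data.frame(data), all(c("day", "size") %in% names(data)))
  data <- data[order(data$day), , drop = FALSE]
  if (any(data$day < 0) || data$day[1] != 0)
    stop("'day' must be non-negative with the first observation at day 0")
  if (any(data$size <= 0)) stop("'size' must be positive")
  pn <- fit_par_names(model)
  if (is.null(free)) free <- setdiff(pn, names(fixed))
  if (!all(free %in% pn))
    stop(sprintf("free parameters for %s must be among: %s", model,
                 paste(pn, collapse = ", ")))
  if (length(data$day) < length(free) + 1)
    stop("need more observations than free parameters")
  x0 <- mean(data$size[data$day == 0])
  obs_t <- data$day
  obs_y <- data$size
  maxobs <- max(obs_y)

  defaults <- default_bounds(maxobs)
  for (nm in names(bounds)) defaults[[nm]] <- bounds[[nm]]
  lb <- log(vapply(free, function(nm) defaults[[nm]][1], numeric(1)))
  ub <- log(vapply(free, function(nm) defaults[[nm]][2], numeric(1)))

  starts <- if (is.null(init)) {
    fit_start_grid(model, free, fixed, data, x0)
  } else {
    list(unlist(init)[free])
  }

  resid_fun <- function(logp) {
    pars <- stats::setNames(exp(logp), free)
    allp <- c(as.list(pars), fixed)
    p <- tryCatch(fit_params_build(model, allp), error = function(e) NULL)
    if (is.null(p)) return(rep(1e6, length(obs_y)))
    pred <- tryCatch(shoot(p, x0, obs_t), error = function(e) NULL)
    if (is.null(pred) || anyNA(pred)) return(rep(1e6, length(obs_y)))
    if (log_scale) {
      pred <- pmax(pred, 1e-12)
      log(pred) - log(obs_y)
    } else {
      pred - obs_y
    }
  }

  best <- NULL
  diag <- list()
  for (st in starts) {
    p0 <- pmin(pmax(log(st[free]), lb), ub)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = lb, upper = ub, fn = resid_fun,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) {
      diag[[length(diag) + 1]] <- list(start = st, sse = NA_real_,
                                       message = "start failed")
      next
    }
    sse <- sum(fit$fvec^2)
    diag[[length(diag) + 1]] <- list(start = st, sse = sse,
                                     message = fit$message)
    if (is.null(best) || sse < best$sse) best <- list(fit = fit, sse = sse)
  }
  if (is.null(best)) stop("no start converged; see per-start diagnostics")

  coefs <- stats::setNames(exp(best$fit$par), free)
  allp <- c(as.list(coefs), fixed)
  params <- fit_params_build(model, allp)
  eqr <- growth_equilibria(params)
  pred <- shoot(params, x0, obs_t)
  structure(list(params = params,
                 coefficients = unlist(allp)[fit_par_names(model)],
                 free = free, fixed = fixed,
                 sse = best$sse,
                 K = eqr$K, A = eqr$A,
                 K_below_data = is.finite(eqr$K) && eqr$K < maxobs,
                 fitted = pred, data = data, x0 = x0,
                 log_scale = log_scale, starts = diag),
            class = "growth_fit")
}

default_bounds <- function(maxobs) {
  list(nu = c(0.1, 1e6), r = c(1e-6, 10), mu = c(1e-30, 10),
       s = c(1e-12, 1e12), A = c(1e-3, maxobs * 10), K = c(1, maxobs * 1e4))
}

# integrate the model from the first observation and read off the grid;
# solver complaints during optimizer excursions are muted (a failed
# integration surfaces as large residuals, not as a warning storm)
shoot <- function(params, x0, times) {
  co <- utils::capture.output(tr <- suppressWarnings(
    integrate_growth(params, x0 = x0, t_end = max(max(times), 1e-6),
                     times = sort(unique(c(0, times))),
                     rtol = 1e-8, atol = 1e-8 * max(1, x0))))
  stats::approx(tr$times, tr$values, xout = times, rule = 2)$y
}

fit_start_grid <- function(model, free, fixed, data, x0) {
  # early-time log-slope as a growth-rate guess
  k <- min(nrow(data), max(4, ceiling(nrow(data) / 3)))
  sl <- tryCatch(stats::coef(stats::lm(log(size) ~ day,
                                       data = data[seq_len(k), ]))[2],
                 error = function(e) 0.2)
  sl <- max(min(unname(sl), 5), 1e-3)
  nus <- if ("nu" %in% free) c(1, 10, 1e3, 1e5) else fixed$nu %||% 1
  Kg <- 2 * max(data$size)
  # plausible thresholds: two fixed decades plus a data-scale guess
  Ags <- unique(c(1e2, 1e4, x0 / 2))
  Ags <- Ags[Ags < x0 | Ags == x0 / 2]
  starts <- list()
  for (nu in nus) {
    for (Ag in Ags) {
      st <- c(nu = nu, r = sl / nu)
      if (model == "richards") {
        st["mu"] <- st[["r"]] / Kg^(1 / nu)
      } else if (model == "erm1") {
        st["A"] <- Ag
        st["K"] <- Kg
      } else {
        p <- tryCatch(erm2_params_for_AK(r = st[["r"]], A = Ag, K = Kg, nu = nu),
                      error = function(e) NULL)
        if (is.null(p)) next
        st["mu"] <- p$mu
        st["s"] <- p$s
      }
      starts[[length(starts) + 1]] <- st
    }
  }
  # de-duplicate starts that only differ in unused entries
  unique(lapply(starts, function(s) s[intersect(names(s), free)]))
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: %s, %d points, sse = %.4g (%s scale)>\n",
              x$params$model, nrow(x$data), x$sse,
              if (x$log_scale) "log" else "linear"))
  print(signif(x$coefficients, 6))
  if (is.finite(x$K)) cat(sprintf("  K = %.4g cells", x$K))
  if (is.finite(x$A)) cat(sprintf(", A = %.4g cells", x$A))
  cat("\n")
  if (x$K_below_data)
    cat("  warning: fitted K is below the largest observation\n")
  invisible(x)
}

#' @export
summary.growth_fit <- function(object, ...) {
  res <- stats::residuals(object)
  structure(list(fit = object, residual_summary = summary(res),
                 sigma = stats::sd(res)), class = "summary.growth_fit")
}

#' @export
print.summary.growth_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual sd (fitted scale): %.4g\n", x$sigma))
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.growth_fit <- function(object, ...) object$coefficients

#' @export
residuals.growth_fit <- function(object, ...) {
  if (object$log_scale) log(object$fitted) - log(object$data$size)
  else object$fitted - object$data$size
}

#' @export
predict.growth_fit <- function(object, newdata = NULL, ...) {
  times <- if (is.null(newdata)) object$data$day else newdata$day
  shoot(object$params, object$x0, times)
}

#' @export
plot.growth_fit <- function(x, log = "y", ...) {
  graphics::plot(x$data$day, x$data$size, log = log,
                 xlab = "day", ylab = "cells", ...)
  tt <- seq(0, max(x$data$day), length.out = 200)
  graphics::lines(tt, shoot(x$params, x$x0, tt), col = 2)
  if (is.finite(x$K)) graphics::abline(h = x$K, lty = 2)
  invisible(x)
}

#' @export
simulate.growth_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sig <- stats::sd(residuals(object))
  n <- nrow(object$data)
  out <- replicate(nsim, object$fitted *
                     exp(stats::rnorm(n, 0, if (is.finite(sig)) sig else 0)))
  as.data.frame(out)
}

#' Fit and rank several candidate growth models
#'
#' Fits each candidate to the same dataset and ranks by the residual sum
#' of squares on the common fitting scale, mirroring the four-way
#' comparison (ERM1 with `nu = 1`, ERM1 with free `nu`, ERM2, ...)
#' applied to the mouse datasets. Failed fits are excluded from the
#' ranking with a note.
#'
#' @param data as in [fit_growth_model()].
#' @param candidates list of candidate specs, each a list with `model`
#'   and optionally `free`, `fixed`.
#' @param ... passed to [fit_growth_model()].
#' @return an object of class `growth_fit_ranking`: `table` (one row per
#'   candidate: model, sse, K, A, K_below_data, rank), `fits` (list of
#'   `growth_fit` objects or `NULL`), `failures` (messages).
#' @export
compare_growth_models <- function(data, candidates, ...) {
  fits <- vector("list", length(candidates))
  notes <- character(length(candidates))
  for (i in seq_along(candidates)) {
    cd <- candidates[[i]]
    fits[[i]] <- tryCatch(
      fit_growth_model(data, model = cd$model, free = cd$free,
                       fixed = cd$fixed %||% list(), ...),
      error = function(e) { notes[i] <<- conditionMessage(e); NULL })
  }
  lab <- vapply(seq_along(candidates), function(i) {
    cd <- candidates[[i]]
    fx <- cd$fixed %||% list()
    if (length(fx)) sprintf("%s (%s)", cd$model,
                            paste(names(fx), unlist(fx), sep = "=",
                                  collapse = ", "))
    else cd$model
  }, character(1))
  tab <- data.frame(
    candidate = lab,
    sse = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$sse, 1),
    K = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$K, 1),
    A = vapply(fits, function(f) if (is.null(f)) NA_real_ else f$A, 1),
    K_below_data = vapply(fits, function(f) if (is.null(f)) NA else f$K_below_data, TRUE))
  tab$rank <- rank(tab$sse, na.last = "keep")
  o <- order(tab$rank)
  structure(list(table = tab[o, ], fits = fits[o], failures = notes),
            class = "growth_fit_ranking")
}

#' @export
print.growth_fit_ranking <- function(x, ...) {
  cat("<growth_fit_ranking>\n")
  print(x$table, row.names = FALSE, digits = 4)
  bad <- x$failures[nzchar(x$failures)]
  if (length(bad)) cat("  failed fits:", paste(bad, collapse = "; "), "\n")
  invisible(x)
}
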