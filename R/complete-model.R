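#' One daily step of the complete cancer-development model
#'
#' The complete model is a non-autonomous stochastic difference equation
#' with a one-day time step,
#' \deqn{x(t+1) = \max(F(x,t), 0), \quad
#'       F(x,t) = x + [\nu r x - \nu\mu x^{(\nu+1)/\nu} - s_m(t)] + m(t),}
#' combining the deterministic threshold-growth drift, the time-varying
#' immune response `s_m` and the day's new mutations `m`. The clamp at 0
#' keeps the mutated-cell cluster non-negative: the immune term cannot
#' remove more cells than exist plus the day's influx.
#'
#' @param x cluster size (cells, >= 0).
#' @param growth a [growth_params()] object supplying `nu`, `r`, `mu` (the
#'   drift uses the Richards-with-kill form whatever the `model` label).
#' @param s_m immune response for the day (cells day^-1).
#' @param m new mutations for the day (count, >= 0).
#' @return the next-day cluster size.
#' @export
model_step <- function(x, growth, s_m, m) {
  stopifnot(inherits(growth, "growth_params"), x >= 0, m >= 0)
  nu <- growth$nu
  F <- x + (nu * growth$r * x - nu * growth$mu * x^((nu + 1) / nu) - s_m) + m
  pmax(F, 0)
}

#' Moving extinction threshold
#'
#' Instantaneous position of the extinction threshold when the immune
#' response and the mutation influx vary over time:
#' \deqn{\bar A(t) \approx \frac{s_m(t) - \bar m(t)}{\nu r - \mu(\nu + a\ln 10)},}
#' where `m_bar` is the average mutation influx over a window in which
#' `s_m` does not change appreciably (here: the current cycle phase). With
#' `m_bar = 0` and constant `s` this reduces term-by-term to the stationary
#' ERM2 threshold approximation. The decade exponent `a` is resolved
#' self-consistently (vectorized fixed-point iteration) unless supplied.
#'
#' A non-positive numerator means the mutation influx exceeds the immune
#' capacity and the threshold has vanished: 0 is returned. A non-positive
#' denominator makes the approximation invalid and yields `NA` with a
#' warning.
#'
#' @param s_m immune response (cells day^-1; vectorized).
#' @param m_bar phase-averaged mutation influx (cells day^-1; vectorized).
#' @param growth a [growth_params()] object.
#' @param a optional fixed decade exponent `log10(A)`; default resolves it
#'   self-consistently.
#' @return threshold position(s) in cells.
#' @export
moving_threshold <- function(s_m, m_bar, growth, a = NULL) {
  stopifnot(inherits(growth, "growth_params"))
  nu <- growth$nu; r <- growth$r; mu <- growth$mu
  num <- s_m - m_bar
  out <- numeric(length(num))
  pos <- which(num > 0)
  if (length(pos)) {
    av <- if (is.null(a)) rep(2, length(pos)) else rep_len(a, length(pos))
    A <- num[pos]
    for (i in seq_len(if (is.null(a)) 30 else 1)) {
      den <- nu * r - mu * (nu + av * log(10))
      A <- ifelse(den > 0, num[pos] / den, NA_real_)
      anew <- log10(A)
      if (all(is.na(A)) || max(abs(anew - av), na.rm = TRUE) < 1e-3) {
        av <- anew; break
      }
      av <- anew
    }
    if (anyNA(A)) warning("moving threshold invalid (non-positive denominator) on part of the input")
    out[pos] <- A
  }
  out
}

#' Simulate one lifetime of the complete model
#'
#' Iterates the daily step over a whole (simulated) life: each day draws
#' `m(t) ~ Binomial(n, p(t))`, looks up the immune response from the
#' woman's cycle schedule, advances the cluster, and tracks the moving
#' extinction threshold. The per-phase mutation average entering the
#' threshold is the realized mean of `m(t)` over the current immune phase
#' (28-day blocks outside the cycling years). The run stops at the horizon
#' or at the first *confirmed transition*: an upward threshold crossing
#' whose excursion reaches `conf_mult * max(A_bar, 1)` cells before
#' returning below the threshold (the operational definition of
#' carcinogenesis used for risk counting; progression to the carrying
#' capacity is not simulated).
#'
#' @param growth a [growth_params()] object (drift parameters).
#' @param mutation a [mutation_params()] object.
#' @param life a [sample_life_history()] object.
#' @param immune an [immune_params()] object.
#' @param horizon_years length of the simulation (<= 110).
#' @param x0 initial cluster size (cells, default 0).
#' @param conf_mult confirmation multiple for the transition rule
#'   (default 10).
#' @param record keep the full daily trajectory (default `TRUE`; the risk
#'   pipeline switches it off).
#' @return an object of class `lifetime_trajectory`: integer `days`, and
#'   per-day `x`, `s_m`, `m`, `A_bar` (when `record`), plus
#'   `transition_day` (`NA` if none), `transition_age` (years), and the
#'   inputs.
#' @export
simulate_lifetime <- function(growth, mutation, life, immune,
                              horizon_years = 85, x0 = 0, conf_mult = 10,
                              record = TRUE) {
  stopifnot(inherits(growth, "growth_params"),
            inherits(mutation, "mutation_params"),
            inherits(life, "life_history"),
            inherits(immune, "immune_params"),
            horizon_years > 0, horizon_years <= 110)
  H <- round(horizon_years * 365)
  sched <- immune_schedule_days(life, immune, H)
  tdays <- seq_len(H) - 1L
  m <- sample_daily_mutations(tdays, mutation)
  mbar <- stats::ave(m, sched$segment)
  abar <- moving_threshold(sched$s, mbar, growth)
  res <- .lifetime_loop(x0, growth$nu, growth$r, growth$mu,
                        sched$s, as.numeric(m), abar,
                        conf_mult, record, 1e15)
  td <- if (res$transition_day < 0) NA_integer_ else res$transition_day
  n_kept <- res$stop_day
  structure(list(
    days = 0:n_kept,
    x = if (record) res$x else NULL,
    s_m = sched$s[seq_len(n_kept)],
    m = m[seq_len(n_kept)],
    A_bar = abar[seq_len(n_kept)],
    luteal = sched$luteal[seq_len(n_kept)],
    transition_day = td,
    transition_age = if (is.na(td)) NA_real_ else td / 365,
    final_x = res$final_x,
    growth = growth, mutation = mutation, life = life, immune = immune,
    conf_mult = conf_mult, horizon_years = horizon_years),
    class = "lifetime_trajectory")
}

#' @export
print.lifetime_trajectory <- function(x, ...) {
  cat(sprintf("<lifetime_trajectory: %d days (%.1f y)>\n",
              max(x$days), max(x$days) / 365))
  if (is.na(x$transition_day)) {
    cat("  no transition to cancer within the horizon\n")
  } else {
    cat(sprintf("  transition to cancer at day %d (age %.2f y)\n",
                x$transition_day, x$transition_age))
  }
  invisible(x)
}

#' @export
plot.lifetime_trajectory <- function(x, log = "y", ...) {
  if (is.null(x$x)) stop("trajectory was simulated with record = FALSE")
  v <- x$x[-1]
  a <- x$A_bar
  if (grepl("y", log)) { v[v <= 0] <- NA; a[a <= 0] <- NA }
  days <- x$days[-1]
  graphics::plot(days / 365, v, type = "l", log = log,
                 xlab = "age [years]", ylab = "cells", ...)
  graphics::lines(days / 365, a, col = 2)
  graphics::legend("topleft", legend = c("cluster x(t)", "threshold A_bar(t)"),
                   col = c(1, 2), lty = 1, bty = "n")
  invisible(x)
}

#' Classify threshold-crossing events of a trajectory
#'
#' Scans a daily trajectory against a per-day threshold and labels:
#' upward `crossing`s (from at-or-below to above); each crossing as a
#' `rescue` if the trajectory returns below the threshold within
#' `rescue_window` days (the rising threshold outruns the cluster and the
#' transition to cancer is avoided), otherwise as a `transition`; and
#' `extinction`s (hits of 0 from above).
#'
#' @param x numeric vector of daily cluster sizes.
#' @param threshold per-day threshold, same length as `x`.
#' @param rescue_window days an excursion may last and still count as a
#'   rescue (default 365).
#' @return data frame with columns `type` and `day` (0-based day index).
#' @export
detect_events <- function(x, threshold, rescue_window = 365) {
  stopifnot(length(x) == length(threshold))
  above <- x > threshold
  n <- length(x)
  ev <- list()
  ups <- which(above & !c(FALSE, above[-n]))
  for (u in ups) {
    back <- which(!above[seq(u, n)])[1]
    if (!is.na(back) && back - 1 <= rescue_window) {
      ev[[length(ev) + 1]] <- data.frame(type = "crossing", day = u - 1L)
      ev[[length(ev) + 1]] <- data.frame(type = "rescue", day = u - 1L)
    } else {
      ev[[length(ev) + 1]] <- data.frame(type = "crossing", day = u - 1L)
      ev[[length(ev) + 1]] <- data.frame(type = "transition", day = u - 1L)
    }
  }
  zero <- which(x == 0 & c(FALSE, x[-n] > 0))
  for (z in zero)
    ev[[length(ev) + 1]] <- data.frame(type = "extinction", day = z - 1L)
  if (!length(ev))
    return(data.frame(type = character(0), day = integer(0)))
  out <- do.call(rbind, ev)
  out[order(out$day), , drop = FALSE]
}
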