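#' Generate a synthetic tumour-progression dataset
#'
#' Integrates a growth model, samples it on a measurement grid, applies
#' multiplicative lognormal noise (caliper-style measurement error scales
#' with size), and returns volumes or cell counts. Fully specified by a
#' serializable spec, so any fixture is regenerable bit-exactly from its
#' seed.
#'
#' @param spec a list with elements `params` (a [growth_params()] object),
#'   `x0` (cells), `days` (measurement days, first = 0), `n_replicates`
#'   (animals measured per day, default 1), `noise_sdlog` (lognormal sigma
#'   of the multiplicative noise, 0 = noiseless), `per_day_means` (report
#'   the replicate mean per day instead of individual points), `unit`
#'   (`"cells"`, `"cm3"` or `"mm3"`) and `seed` (mandatory).
#' @return data frame with columns `day`, `size` and (for individual
#'   points) `replicate`, with attributes `unit` and `spec`. A trajectory
#'   that goes extinct before the end of the grid is flagged via attribute
#'   `extinct` (and a warning).
#' @export
make_tumour_dataset <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$seed),
            inherits(spec$params, "growth_params"))
  days <- spec$days
  stopifnot(days[1] == 0, !is.unsorted(days))
  nrep <- spec$n_replicates %||% 1L
  sdlog <- spec$noise_sdlog %||% 0
  unit <- spec$unit %||% "cells"
  tr <- integrate_growth(spec$params, x0 = spec$x0, t_end = max(days, 1),
                         times = unique(days))
  truth <- stats::approx(tr$times, tr$values, xout = days, rule = 2)$y
  extinct <- !is.na(tr$extinct_at) && tr$extinct_at <= max(days)
  if (extinct) warning("trajectory extinct before the end of the grid; fixture flagged")
  set.seed(spec$seed)
  size <- rep(truth, each = nrep) *
    exp(stats::rnorm(length(days) * nrep, 0, sdlog))
  out <- data.frame(day = rep(days, each = nrep),
                    replicate = rep(seq_len(nrep), times = length(days)),
                    size = size)
  if (isTRUE(spec$per_day_means)) {
    m <- tapply(out$size, out$day, mean)
    out <- data.frame(day = as.numeric(names(m)), size = as.numeric(m))
  }
  if (unit != "cells") out$size <- cells_to_volume(out$size, unit)
  structure(out, unit = unit, spec = spec, extinct = extinct)
}

#' Canned synthetic tumour specs
#'
#' Two ready-made specs emulating the shapes of the mouse experiments the
#' fitting routines target: a dense individual-measurement design (many
#' animals followed over ~38 days, strongly asymmetric large-`nu` growth,
#' as in immunodeficient-mouse xenografts) and a sparse per-day-mean
#' design (8 time points averaged over 10 animals, symmetric `nu = 1`
#' growth, as in immunocompetent mice). Sizes are reported in mm^3.
#'
#' @param seed RNG seed for the noise.
#' @return a spec list for [make_tumour_dataset()].
#' @export
tumour_spec_dataset1_like <- function(seed = 1) {
  list(params = erm2_params_for_AK(r = 0.0263, A = 2e2, K = 2e9, nu = 1e5),
       x0 = 1e6, days = seq(0, 38, 2), n_replicates = 30,
       noise_sdlog = 0.25, per_day_means = FALSE, unit = "mm3", seed = seed)
}

#' @rdname tumour_spec_dataset1_like
#' @export
tumour_spec_dataset2_like <- function(seed = 1) {
  list(params = erm2_params_for_AK(r = 0.25, A = 3e5, K = 2e9, nu = 1),
       x0 = 1e6, days = c(0, 4, 8, 12, 16, 21, 26, 33), n_replicates = 10,
       noise_sdlog = 0.15, per_day_means = TRUE, unit = "mm3", seed = seed)
}

#' Generate a synthetic age-specific incidence table
#'
#' Emulates registry-style 5-year incidence bands under one of two
#' qualitative shapes: `"exponential"` (log-rate linear in age, typical of
#' most cancers) or `"breast"` (steep polynomial rise up to a change
#' point near age 47, linear above it -- the atypical shape of female
#' breast cancer).
#'
#' @param shape `"exponential"`, `"breast"` or `"zero"`.
#' @param peak_rate incidence per person-year at the oldest band.
#' @param edges band edges (default 5-year bands to 85).
#' @return data frame with columns `age_lo`, `age_hi`, `rate` (per
#'   person-year).
#' @export
make_incidence_table <- function(shape = c("exponential", "breast", "zero"),
                                 peak_rate = 5e-3, edges = seq(0, 85, 5)) {
  shape <- match.arg(shape)
  lo <- edges[-length(edges)]; hi <- edges[-1]
  mid <- (lo + hi) / 2
  rate <- switch(shape,
    zero = rep(0, length(mid)),
    exponential = peak_rate * exp(0.08 * (mid - max(mid))),
    breast = {
      chg <- 47
      poly <- (pmin(mid, chg) / chg)^7
      lin <- pmax(mid - chg, 0) / (max(mid) - chg)
      base <- poly + 0.6 * lin
      peak_rate * base / max(base)
    })
  data.frame(age_lo = lo, age_hi = hi, rate = rate)
}
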