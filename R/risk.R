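#' Reproducible per-woman RNG substreams
#'
#' Derives `n` independent L'Ecuyer-CMRG streams from one master seed so
#' cohort simulations are reproducible woman-by-woman regardless of
#' scheduling, and adding random consumers does not shift existing draws.
#'
#' @param seed master integer seed.
#' @param n number of streams.
#' @return list of `.Random.seed` states.
#' @keywords internal
rng_substreams <- function(seed, n) {
  old_kind <- RNGkind()
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    RNGkind(old_kind[1], old_kind[2], old_kind[3])
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed, kind = "L'Ecuyer-CMRG")
  s <- get(".Random.seed", globalenv())
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    streams[[i]] <- s
    s <- parallel::nextRNGStream(s)
  }
  streams
}

with_rng_state <- function(state, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", state, envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  expr
}

# an all-s_max life history (no cycling) for constant-immune-response runs
constant_life_history <- function(horizon_years) {
  structure(list(menarche_age = horizon_years + 1,
                 menopause_age = horizon_years + 1, hrt_years = 0,
                 effective_menopause = horizon_years + 1,
                 phases = data.frame(phase = character(0),
                                     length_days = integer(0))),
            class = "life_history")
}

#' Simulate a cohort and estimate the age-specific cumulative risk
#'
#' Runs the complete daily-step model for `n_women` independent women.
#' Each woman draws her own life history (per the configured immune
#' scenario) and mutation stream from a dedicated RNG substream; her
#' transition age (if any) is recorded. The theoretical age-specific
#' cumulative risk at age `t` is the percentage of women whose transition
#' age is `<= t`, reported at 5-year registry band edges with a
#' Clopper-Pearson binomial confidence band.
#'
#' @param config a model configuration, e.g. [breast_config()]; the
#'   `case` element selects the immune scenario (0 = constant `s_max`,
#'   1-3 = the menstrual-cycle scenarios).
#' @param n_women cohort size (>= 100).
#' @param seed master seed.
#' @param age_band_edges band edges in years (default `seq(5, 85, 5)`).
#' @param conf_level confidence level of the binomial band.
#' @return an object of class `cohort_risk`: data frame `curve` with
#'   columns `age`, `n_transitions`, `risk_pct`, `ci_lo`, `ci_hi`; vector
#'   `transition_ages` (NA for cancer-free women); `luteal_at_transition`;
#'   plus the inputs.
#' @export
simulate_cohort <- function(config, n_women, seed,
                            age_band_edges = seq(5, 85, 5),
                            conf_level = 0.95) {
  stopifnot(n_women >= 100)
  streams <- rng_substreams(seed, n_women)
  horizon <- config$horizon_years
  ages <- rep(NA_real_, n_women)
  luteal <- rep(NA, n_women)
  for (i in seq_len(n_women)) {
    res <- with_rng_state(streams[[i]], simulate_one_woman(config))
    ages[i] <- res$age
    luteal[i] <- res$luteal
  }
  curve <- risk_curve_from_ages(ages, n_women, age_band_edges, conf_level)
  structure(list(curve = curve, transition_ages = ages,
                 luteal_at_transition = luteal,
                 n_women = n_women, seed = seed, config = config),
            class = "cohort_risk")
}

simulate_one_woman <- function(config) {
  # the woman's stream is split: the life history uses the stream itself,
  # the mutation draws use a sub-stream. Immune scenarios that consume
  # different numbers of life-history draws therefore share identical
  # mutation streams woman-for-woman (common random numbers across Cases).
  life_state <- get(".Random.seed", globalenv())
  life <- if (config$case == 0) {
    constant_life_history(config$horizon_years)
  } else {
    sample_life_history(case = config$case, params = config$immune,
                        fixed_follicular_days = config$fixed_follicular_days %||% NULL)
  }
  assign(".Random.seed", parallel::nextRNGSubStream(life_state),
         envir = globalenv())
  tr <- simulate_lifetime(config$growth, config$mutation, life,
                          config$immune, horizon_years = config$horizon_years,
                          record = FALSE)
  list(age = tr$transition_age,
       luteal = if (is.na(tr$transition_day)) NA else tr$luteal[tr$transition_day])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

risk_curve_from_ages <- function(ages, n, edges, conf_level = 0.95) {
  k <- vapply(edges, function(e) sum(!is.na(ages) & ages <= e), integer(1))
  alpha <- 1 - conf_level
  lo <- ifelse(k == 0, 0, stats::qbeta(alpha / 2, k, n - k + 1))
  hi <- ifelse(k == n, 1, stats::qbeta(1 - alpha / 2, k + 1, n - k))
  data.frame(age = edges, n_transitions = k,
             risk_pct = 100 * k / n,
             ci_lo = 100 * lo, ci_hi = 100 * hi)
}

#' @export
print.cohort_risk <- function(x, ...) {
  cat(sprintf("<cohort_risk: %d women, immune case %s, seed %s>\n",
              x$n_women, x$config$case, x$seed))
  print(x$curve, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.cohort_risk <- function(x, ...) {
  graphics::plot(x$curve$age, x$curve$risk_pct, type = "s",
                 xlab = "age [years]", ylab = "cumulative risk [%]", ...)
  graphics::lines(x$curve$age, x$curve$ci_lo, lty = 3)
  graphics::lines(x$curve$age, x$curve$ci_hi, lty = 3)
  invisible(x)
}

#' Actual cumulative risk from an age-specific incidence table
#'
#' The standard actuarial transform of registry incidence rates:
#' \deqn{R(t) = 100\,(1 - \exp(-\sum_{bands \le t} rate \times width)).}
#'
#' @param table data frame with columns `age_lo`, `age_hi` (years) and
#'   `rate` (incidence per person-year). Contiguous bands required.
#' @return data frame with columns `age` (band upper edge) and `risk_pct`,
#'   non-decreasing and bounded by 100.
#' @export
cumulative_risk_from_incidence <- function(table) {
  stopifnot(all(c("age_lo", "age_hi", "rate") %in% names(table)))
  if (any(table$rate < 0)) stop("incidence rates must be >= 0")
  if (any(table$age_hi <= table$age_lo)) stop("bands must have positive width")
  o <- order(table$age_lo)
  table <- table[o, ]
  if (nrow(table) > 1 &&
      any(abs(table$age_lo[-1] - table$age_hi[-nrow(table)]) > 1e-9))
    stop("incidence bands must be contiguous")
  cumhaz <- cumsum(table$rate * (table$age_hi - table$age_lo))
  data.frame(age = table$age_hi, risk_pct = 100 * (1 - exp(-cumhaz)))
}

#' Risk versus follicular-phase length
#'
#' Re-runs the cohort simulation over a grid of fixed follicular lengths
#' `tf` (the luteal phase stays at 14 days), reporting the cumulative risk
#' by `age_cut` and the split of transitions between cycle phases. Shorter
#' cycles expose women to more (weak-immunity) luteal days per unit time,
#' raising both the risk and the luteal share of transitions.
#'
#' @param config a Case-3 style configuration (see [breast_config()]).
#' @param tf_grid follicular lengths in days.
#' @param age_cut risk horizon in years (default 51).
#' @param n_women cohort size per grid point.
#' @param seed master seed (each grid point uses the same substreams, so
#'   the comparison across `tf` is paired).
#' @return data frame with columns `tf`, `cycle_days`, `risk_pct`,
#'   `luteal_share_pct`, `follicular_share_pct`, `n_transitions`. Shares
#'   are `NA` when no transitions occurred at a grid point.
#' @export
cycle_length_sweep <- function(config, tf_grid, age_cut = 51, n_women, seed) {
  rows <- lapply(tf_grid, function(tf) {
    cfg <- config
    cfg$fixed_follicular_days <- tf
    cfg$horizon_years <- min(cfg$horizon_years, age_cut) # onset-by-age_cut only
    cr <- simulate_cohort(cfg, n_women, seed, age_band_edges = age_cut)
    hit <- !is.na(cr$transition_ages) & cr$transition_ages <= age_cut
    nt <- sum(hit)
    lut <- cr$luteal_at_transition[hit]
    data.frame(tf = tf, cycle_days = tf + 14,
               risk_pct = 100 * nt / n_women,
               luteal_share_pct = if (nt) 100 * mean(lut) else NA_real_,
               follicular_share_pct = if (nt) 100 * mean(!lut) else NA_real_,
               n_transitions = nt)
  })
  do.call(rbind, rows)
}

#' Bucketed cycle-length risk ratio
#'
#' Averages the sweep's risk-by-`age_cut` over integer follicular lengths
#' whose total cycle (14 + tf days) falls in each of two buckets, and
#' returns the ratio (short-cycle over long-cycle risk).
#'
#' @param sweep output of [cycle_length_sweep()].
#' @param short_range,long_range total cycle-length buckets in days
#'   (defaults 22-25 and 25-31).
#' @return list with `short`, `long` (mean risks, %) and `ratio`.
#' @export
cycle_bucket_ratio <- function(sweep, short_range = c(22, 25),
                               long_range = c(25, 31)) {
  inb <- function(rg) sweep$cycle_days >= rg[1] & sweep$cycle_days <= rg[2]
  s <- mean(sweep$risk_pct[inb(short_range)])
  l <- mean(sweep$risk_pct[inb(long_range)])
  list(short = s, long = l, ratio = s / l)
}
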