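#' Immune-response parameters over the menstrual cycle
#'
#' The immune response `s_m(t)` removes a fixed number of mutated cells per
#' day and switches between two levels: `s_min` during the high-progesterone
#' luteal phases (weaker immunity) and `s_max` otherwise -- before menarche,
#' during follicular phases, and after the effective menopause. Hormone
#' replacement therapy (HRT) extends the cycling period past natural
#' menopause for a fraction of women.
#'
#' @param s_min immune response in luteal phases (cells day^-1).
#' @param s_max immune response otherwise (cells day^-1, >= `s_min`).
#' @param hrt_fraction probability that a woman uses HRT (default 0.26).
#' @param hrt_mode mode of the gamma-distributed HRT duration (years,
#'   default 6).
#' @param hrt_sd standard deviation of the HRT duration (years, default 4.8).
#' @return an object of class `immune_params`.
#' @export
immune_params <- function(s_min, s_max, hrt_fraction = 0.26,
                          hrt_mode = 6, hrt_sd = 4.8) {
  stopifnot(s_min >= 0, s_max >= s_min,
            hrt_fraction >= 0, hrt_fraction <= 1,
            hrt_mode > 0, hrt_sd > 0)
  structure(list(s_min = s_min, s_max = s_max,
                 hrt_fraction = hrt_fraction,
                 hrt_mode = hrt_mode, hrt_sd = hrt_sd),
            class = "immune_params")
}

#' Gamma distribution parameters from mode and standard deviation
#'
#' Solves `(k - 1) theta = mode` and `k theta^2 = sd^2` exactly: the pair
#' reduces to the quadratic `theta^2 + mode * theta - sd^2 = 0`, whose
#' positive root gives `theta`, and `k = mode/theta + 1 > 1`.
#'
#' @param mode distribution mode (> 0).
#' @param sd standard deviation (> 0).
#' @return list with `shape` (k) and `scale` (theta).
#' @export
gamma_from_mode_sd <- function(mode, sd) {
  stopifnot(is.numeric(mode), is.numeric(sd), sd > 0)
  if (mode <= 0) stop("'mode' must be > 0 (shape must exceed 1)")
  theta <- (-mode + sqrt(mode^2 + 4 * sd^2)) / 2
  list(shape = mode / theta + 1, scale = theta)
}

#' Sample one woman's reproductive life history
#'
#' Draws menarche-to-menopause cycle structure under one of three scenarios:
#'
#' * Case 1 -- fixed average menopause, `M = 51` years, no HRT;
#' * Case 2 -- menopause age normally distributed, `N(51, 4.86^2)` years,
#'   no HRT;
#' * Case 3 -- as Case 2, and with probability `hrt_fraction` (0.26) the
#'   cycling period is extended by a gamma-distributed HRT duration
#'   (mode 6 y, sd 4.8 y).
#'
#' Each cycle is a follicular phase (length drawn per cycle from
#' `N(14, 2.4^2)` days, rounded to whole days and truncated at 1 day)
#' followed by a fixed 14-day luteal phase; menstruation and ovulation are
#' folded into the follicular (`s_max`) branch. The last partial cycle is
#' cut at the effective menopause. The menopause draw is truncated below at
#' menarche + 1 year.
#'
#' @param case scenario 1, 2 or 3.
#' @param params an [immune_params()] object (HRT settings).
#' @param menarche_age menarche age in years (default 12).
#' @param luteal_days fixed luteal length (default 14).
#' @param follicular_mean,follicular_sd follicular length distribution
#'   (days; defaults 14 and 2.4).
#' @param fixed_follicular_days optional fixed follicular length overriding
#'   the per-cycle draw (used by cycle-length sweeps).
#' @param menopause_mean,menopause_sd natural menopause distribution
#'   (years; defaults 51 and 4.86).
#' @return an object of class `life_history`: menarche_age, menopause_age,
#'   hrt_years, effective_menopause (years), and `phases`, a data frame of
#'   ordered phases (`phase`, `length_days`) covering menarche to effective
#'   menopause.
#' @export
sample_life_history <- function(case = 1, params = immune_params(0, 0),
                                menarche_age = 12, luteal_days = 14,
                                follicular_mean = 14, follicular_sd = 2.4,
                                fixed_follicular_days = NULL,
                                menopause_mean = 51, menopause_sd = 4.86) {
  if (!case %in% 1:3) stop("'case' must be 1, 2 or 3")
  M <- if (case == 1) menopause_mean else {
    m <- stats::rnorm(1, menopause_mean, menopause_sd)
    max(m, menarche_age + 1)
  }
  hrt_years <- 0
  if (case == 3 && stats::runif(1) < params$hrt_fraction) {
    gp <- gamma_from_mode_sd(params$hrt_mode, params$hrt_sd)
    hrt_years <- stats::rgamma(1, shape = gp$shape, scale = gp$scale)
  }
  M_eff <- M + hrt_years
  cyc_days <- round((M_eff - menarche_age) * 365)
  phases <- make_cycle_phases(cyc_days, luteal_days, follicular_mean,
                              follicular_sd, fixed_follicular_days)
  structure(list(menarche_age = menarche_age, menopause_age = M,
                 hrt_years = hrt_years, effective_menopause = M_eff,
                 phases = phases),
            class = "life_history")
}

# alternating follicular/luteal phases totalling exactly total_days
make_cycle_phases <- function(total_days, luteal_days, follicular_mean,
                              follicular_sd, fixed_follicular_days) {
  if (total_days <= 0)
    return(data.frame(phase = character(0), length_days = integer(0)))
  # expected cycle ~28 d; draw enough cycles, then trim
  n_cycles <- ceiling(total_days / (luteal_days + 1)) + 2
  tf <- if (is.null(fixed_follicular_days)) {
    pmax(1L, as.integer(round(stats::rnorm(n_cycles, follicular_mean,
                                           follicular_sd))))
  } else {
    rep(max(1L, as.integer(round(fixed_follicular_days))), n_cycles)
  }
  lens <- as.integer(rbind(tf, rep(luteal_days, n_cycles)))
  types <- rep(c("follicular", "luteal"), n_cycles)
  cum <- cumsum(lens)
  keep <- which(cum < total_days)
  k <- length(keep)
  lens <- lens[seq_len(k + 1)]
  types <- types[seq_len(k + 1)]
  lens[k + 1] <- total_days - if (k > 0) cum[k] else 0L
  data.frame(phase = types, length_days = lens)
}

#' @export
print.life_history <- function(x, ...) {
  cat(sprintf("<life_history: menarche %g y, menopause %.1f y, HRT %.1f y (effective %.1f y), %d phases>\n",
              x$menarche_age, x$menopause_age, x$hrt_years,
              x$effective_menopause, nrow(x$phases)))
  invisible(x)
}

#' Immune response at given ages
#'
#' Evaluates the piecewise-constant, right-continuous lifetime immune
#' schedule: `s_max` before menarche, the luteal/follicular square wave
#' between menarche and effective menopause, and `s_max` after.
#'
#' @param t age in days since birth (vectorized).
#' @param life a [sample_life_history()] object.
#' @param params an [immune_params()] object.
#' @return immune response in cells day^-1, same length as `t`.
#' @export
immune_response_at <- function(t, life, params) {
  stopifnot(inherits(life, "life_history"), inherits(params, "immune_params"))
  if (any(t < 0)) stop("'t' must be >= 0")
  menarche_day <- round(life$menarche_age * 365)
  stop_day <- menarche_day + sum(life$phases$length_days)
  out <- rep(params$s_max, length(t))
  inside <- t >= menarche_day & t < stop_day
  if (any(inside)) {
    bounds <- menarche_day + c(0, cumsum(life$phases$length_days))
    idx <- findInterval(t[inside], bounds, rightmost.closed = FALSE)
    lut <- life$phases$phase[idx] == "luteal"
    out[inside] <- ifelse(lut, params$s_min, params$s_max)
  }
  out
}

#' Day-indexed immune schedule and averaging segments
#'
#' Expands a life history into per-day vectors over `horizon_days` days:
#' the immune response `s` and a segment id used to average the mutation
#' influx when evaluating the moving extinction threshold. Cycle phases
#' are their own segments; the constant stretches before menarche and
#' after the effective menopause are chunked into 28-day blocks so the
#' average tracks the slow drift of the mutation probability.
#'
#' @param life a [sample_life_history()] object.
#' @param params an [immune_params()] object.
#' @param horizon_days number of days from birth.
#' @return list with numeric `s` and integer `segment` (both of length
#'   `horizon_days`) and logical `luteal`.
#' @export
immune_schedule_days <- function(life, params, horizon_days) {
  stopifnot(inherits(life, "life_history"), horizon_days >= 1)
  menarche_day <- round(life$menarche_age * 365)
  menarche_day <- min(menarche_day, horizon_days)
  ph <- life$phases
  # truncate phases to the horizon
  if (nrow(ph) > 0) {
    cum <- menarche_day + cumsum(ph$length_days)
    last <- which(cum - ph$length_days < horizon_days)
    ph <- ph[last, , drop = FALSE]
    if (nrow(ph) > 0) {
      over <- (menarche_day + sum(ph$length_days)) - horizon_days
      if (over > 0) ph$length_days[nrow(ph)] <- ph$length_days[nrow(ph)] - over
    }
  }
  stop_day <- menarche_day + sum(ph$length_days)
  chunk <- function(n) if (n <= 0) integer(0) else rep(seq_len(ceiling(n / 28)), each = 28)[seq_len(n)]
  pre <- chunk(menarche_day)
  post <- chunk(horizon_days - stop_day)
  seg <- integer(horizon_days)
  s <- numeric(horizon_days)
  lut <- logical(horizon_days)
  nseg <- 0L
  if (menarche_day > 0) {
    seg[seq_len(menarche_day)] <- pre
    s[seq_len(menarche_day)] <- params$s_max
    nseg <- max(pre)
  }
  if (nrow(ph) > 0 && sum(ph$length_days) > 0) {
    ids <- rep(seq_len(nrow(ph)), ph$length_days)
    rng <- (menarche_day + 1):stop_day
    seg[rng] <- nseg + ids
    isl <- rep(ph$phase == "luteal", ph$length_days)
    s[rng] <- ifelse(isl, params$s_min, params$s_max)
    lut[rng] <- isl
    nseg <- nseg + nrow(ph)
  }
  if (stop_day < horizon_days) {
    rng <- (stop_day + 1):horizon_days
    seg[rng] <- nseg + post
    s[rng] <- params$s_max
  }
  list(s = s, segment = seg, luteal = lut)
}
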