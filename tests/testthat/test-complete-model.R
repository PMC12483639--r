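test_that("the daily step applies drift, kill, influx and the zero clamp", {
  g <- growth_params("erm2", nu = 1, r = 0.1, mu = 0, s = 0)
  expect_equal(model_step(0, g, s_m = 40, m = 0), 0)
  expect_equal(model_step(0, g, s_m = 40, m = 5), 0)   # F = 5 - 40 < 0
  expect_equal(model_step(0, g, s_m = 2, m = 5), 3)
  expect_equal(model_step(100, g, s_m = 0, m = 7), 117)
  g2 <- growth_params("erm2", nu = 2, r = 0.05, mu = 1e-4, s = 0)
  x <- 400
  expect_equal(model_step(x, g2, s_m = 10, m = 3),
               x + 2 * 0.05 * x - 2 * 1e-4 * x^1.5 - 10 + 3)
})

test_that("with no mutations and constant immunity the model is explicit Euler", {
  g <- growth_params("erm2", nu = 1, r = 0.1, mu = 1e-8, s = 0)
  ip <- immune_params(500, 500)
  mp <- mutation_params(n = 10, p0 = 1e-300, delta = 0)
  set.seed(11)
  life <- sample_life_history(case = 1, params = ip)
  tr <- simulate_lifetime(g, mp, life, ip, horizon_years = 2, x0 = 2e4)
  oracle <- euler_drift_R(2e4, 1, 0.1, 1e-8, rep(500, 730), rep(0, 730), 730)
  expect_equal(tr$x, oracle, tolerance = 0)
  expect_true(all(tr$m == 0))
  # equilibria of the frozen model sort the fates: below the threshold the
  # cluster dies out, above it the cluster saturates near K
  eq <- growth_equilibria(growth_params("erm2", nu = 1, r = 0.1, mu = 1e-8,
                                        s = 500))
  below <- simulate_lifetime(g, mp, life, ip, horizon_years = 2,
                             x0 = 0.5 * eq$A)
  expect_equal(below$x[length(below$x)], 0)
  above <- simulate_lifetime(g, mp, life, ip, horizon_years = 2,
                             x0 = 2 * eq$A, conf_mult = 1e12)
  expect_gt(above$final_x, 0.9 * eq$K)
  expect_lt(abs(above$final_x - eq$K) / eq$K, 0.05) # Euler-scale error
})

test_that("an empty cluster with no mutations stays empty", {
  g <- growth_params("erm2", nu = 1, r = 0.1, mu = 1e-9, s = 0)
  ip <- immune_params(300, 400)
  mp <- mutation_params(n = 10, p0 = 1e-300, delta = 0)
  set.seed(12)
  life <- sample_life_history(case = 2, params = ip)
  tr <- simulate_lifetime(g, mp, life, ip, horizon_years = 3, x0 = 0)
  expect_true(all(tr$x == 0))
  expect_true(is.na(tr$transition_day))
})

test_that("lifetimes are reproducible and non-negative", {
  cfg <- breast_config(3)
  run <- function() {
    set.seed(99)
    life <- sample_life_history(case = 3, params = cfg$immune)
    simulate_lifetime(cfg$growth, cfg$mutation, life, cfg$immune,
                      horizon_years = 20)
  }
  a <- run(); b <- run()
  expect_identical(a$x, b$x)
  expect_identical(a$m, b$m)
  expect_true(all(a$x >= 0))
  expect_equal(a$days, 0:(length(a$x) - 1))
})

test_that("the moving threshold tracks immunity and mutation influx", {
  g <- growth_params("erm2", nu = 1, r = 0.1, mu = 1e-10, s = 0)
  # with m_bar = 0 and constant s it reduces to the stationary approximation
  s <- 1300
  expect_equal(moving_threshold(s, 0, g),
               as.numeric(erm2_threshold_approx(
                 growth_params("erm2", nu = 1, r = 0.1, mu = 1e-10, s = s))),
               tolerance = 1e-6)
  # vanishes when the influx balances the immune kill
  expect_equal(moving_threshold(1000, 1000, g), 0)
  expect_equal(moving_threshold(1000, 1200, g), 0)
  # weaker immunity (luteal) sits at a lower threshold
  expect_lt(moving_threshold(1262, 900, g), moving_threshold(1354, 900, g))
})

test_that("the threshold approximation agrees with the frozen-map separatrix", {
  set.seed(21)
  for (i in 1:8) {
    r <- 10^runif(1, -1.5, -0.5)
    g <- growth_params("erm2", nu = 1, r = r, mu = 1e-10, s = 0)
    s <- 10^runif(1, 1, 4)
    mbar <- s * runif(1, 0, 0.8)
    A_approx <- moving_threshold(s, mbar, g)
    A_true <- frozen_map_threshold(1, r, 1e-10, s, mbar)
    if (!is.finite(A_true) || A_true < 10 || A_true > 1e6) next
    expect_lt(abs(log(A_approx / A_true)), log(3))
  }
})

test_that("crossings are classified into transitions and rescues", {
  thr <- rep(100, 50)
  rising <- c(seq(10, 90, length.out = 20), seq(110, 500, length.out = 30))
  ev <- detect_events(rising, thr, rescue_window = 10)
  expect_true("transition" %in% ev$type)
  expect_false("rescue" %in% ev$type)
  bump <- c(rep(50, 10), 120, 130, 120, rep(60, 37))
  ev2 <- detect_events(bump, thr, rescue_window = 10)
  expect_true("rescue" %in% ev2$type)
  expect_false("transition" %in% ev2$type)
  expect_equal(nrow(detect_events(rep(10, 50), thr)), 0)
  # extinction from above
  ev3 <- detect_events(c(5, 3, 0, 0), rep(100, 4))
  expect_true("extinction" %in% ev3$type)
})

test_that("transitions occur in some lifetimes under the lifetime configuration", {
  cfg <- breast_config(3)
  hits <- 0
  for (sd in 1:40) {
    set.seed(sd)
    life <- sample_life_history(case = 3, params = cfg$immune)
    tr <- simulate_lifetime(cfg$growth, cfg$mutation, life, cfg$immune,
                            horizon_years = 85, record = FALSE)
    if (!is.na(tr$transition_day)) hits <- hits + 1
  }
  expect_gt(hits, 0)
  expect_lt(hits, 40) # and not every seed transitions
})
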