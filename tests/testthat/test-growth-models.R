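test_that("growth_rate evaluates the model equations", {
  pr <- growth_params("richards", nu = 1, r = 1, mu = 0.01) # K = 100
  expect_equal(growth_rate(0, pr), 0)
  expect_equal(growth_rate(50, pr), 25) # nu r x (1 - (x/K)^(1/nu))
  # factorized and rate forms of the threshold model agree
  p1 <- erm1_params_from_AK(r = 0.12, A = 1, K = 1e4)
  expect_equal(p1$mu, 0.120012)
  expect_equal(p1$gamma, 1.2e-5)
  xs <- c(0.5, 1, 2, 100, 9999)
  expect_equal(growth_rate(xs, p1),
               -0.12 * xs * (1 - xs / 1) * (1 - xs / 1e4), tolerance = 1e-12)
  # the immune kill term cannot act on an empty cluster
  pe <- growth_params("erm2", nu = 2, r = 0.3, mu = 1e-4, s = 50)
  expect_equal(growth_rate(0, pe), 0)
  expect_lt(growth_rate(1, pe), 0)
  expect_error(growth_rate(-1, pr), "non-negative")
  expect_error(growth_params("erm1", nu = 1, r = 1, mu = 0.1), "gamma")
  expect_error(growth_params("richards", nu = -1, r = 1), "nu")
})

test_that("equilibria and rates match the closed forms", {
  # Richards: {0, K}, rates (nu r, -r)
  pr <- growth_params("richards", nu = 3, r = 0.4, mu = 0.4 / 1e2)
  er <- growth_equilibria(pr)
  expect_equal(er$equilibria, c(0, (0.4 / 0.004)^3))
  expect_equal(er$rates[1], 3 * 0.4)
  expect_equal(er$rates[2], -0.4, tolerance = 1e-9)
  expect_equal(er$defining_feature, 3, tolerance = 1e-9)
  # ERM1 at the step-like parameterization
  e1 <- growth_equilibria(erm1_params_from_AK(r = 0.12, A = 1, K = 1e4))
  expect_equal(e1$A, 1, tolerance = 1e-9)
  expect_equal(e1$K, 1e4, tolerance = 1e-9)
  expect_equal(e1$defining_feature, 1e-4, tolerance = 1e-6)
  # ERM2 with s = 0 collapses to the Richards equilibria
  pe0 <- growth_params("erm2", nu = 2, r = 0.3, mu = 0.3 / 10, s = 0)
  e20 <- growth_equilibria(pe0)
  expect_equal(e20$equilibria, growth_equilibria(
    growth_params("richards", nu = 2, r = 0.3, mu = 0.03))$equilibria)
})

test_that("ERM1 closed-form threshold matches the polynomial-root oracle", {
  set.seed(101)
  for (i in 1:100) {
    rp <- random_erm1_params()
    e <- growth_equilibria(rp$params)
    ak <- erm1_AK_polyroot(rp$nu, rp$params$r, rp$params$mu, rp$params$gamma)
    expect_false(is.null(ak))
    expect_equal(e$A, ak[1], tolerance = 1e-9)
    expect_equal(e$K, ak[2], tolerance = 1e-9)
    expect_true(0 < e$A && e$A < e$K)
  }
  # no threshold when the discriminant closes
  p <- growth_params("erm1", nu = 1, r = 1, mu = 0.1, gamma = 1)
  expect_true(is.na(growth_equilibria(p)$A))
})

test_that("asymmetry dichotomy holds against numerical linearization", {
  set.seed(202)
  for (i in 1:40) {
    rp <- random_erm1_params()
    e <- growth_equilibria(rp$params)
    expect_equal(e$defining_feature, (e$A / e$K)^(1 / rp$nu),
                 tolerance = 1e-8)
    expect_lt(e$defining_feature, 1)
    # vs independent central differences on the rhs
    en <- growth_equilibria(rp$params, numeric_rates = TRUE)
    expect_equal(en$defining_feature, e$defining_feature, tolerance = 1e-4)
  }
  for (i in 1:40) {
    nu <- 10^runif(1, 0, 3)
    A <- 10^runif(1, 0, 2); K <- A * 10^runif(1, 1, 4)
    e <- growth_equilibria(erm2_params_for_AK(r = 1, A = A, K = K, nu = nu))
    expect_gte(e$defining_feature, 1 - 1e-8)
  }
})

test_that("asymmetry curve endpoints and plateaus", {
  expect_equal(asymmetry_curve("richards", c(0.5, 1, 7), K = 100)$ratio,
               c(0.5, 1, 7), tolerance = 1e-8)
  expect_equal(asymmetry_curve("erm1", 1, A = 1, K = 100)$ratio, 0.01,
               tolerance = 1e-8)
  cv <- asymmetry_curve("erm2", c(1, 10, 1e3, 1e5, 1e6), A = 1, K = 100)
  expect_true(all(cv$ratio >= 1 - 1e-8))
  # large-nu limit converges to a finite plateau above 1
  expect_lt(abs(cv$ratio[5] - cv$ratio[4]) / cv$ratio[4], 1e-3)
  expect_gt(cv$ratio[5], 1)
})

test_that("ERM1 rates approach r and infinity in the large-K limit", {
  A <- 2; r <- 0.3
  for (K in c(1e3, 1e6, 1e9)) {
    e <- growth_equilibria(erm1_params_from_AK(r = r, A = A, K = K))
    expect_equal(e$lambda_grow, r * (1 - A / K), tolerance = 1e-7)
    expect_equal(-e$lambda_sat, r * (K / A - 1), tolerance = 1e-7)
  }
})

test_that("numerical integration matches the Richards closed form", {
  set.seed(303)
  for (i in 1:10) {
    p <- random_richards_params()
    K <- (p$r / p$mu)^p$nu
    x0 <- K * 10^runif(1, -4, -1)
    tend <- 10 / p$r
    tr <- integrate_growth(p, x0 = x0, t_end = tend)
    cf <- richards_closed_form(tr$times, x0, p)
    expect_lt(max(abs(tr$values - cf) / cf), 1e-6)
    expect_true(all(tr$values >= 0))
  }
})

test_that("step-like threshold dynamics and first-passage timing", {
  p <- erm1_params_from_AK(r = 0.12, A = 1, K = 1e4)
  t1 <- first_passage_time(p, x0 = 2, target = 100)
  expect_equal(t1, erm1_time_closed_form(2, 100, 0.12, 1, 1e4),
               tolerance = 1e-6)
  # below the threshold the population decays instead
  tr <- integrate_growth(p, x0 = 0.5, t_end = 100)
  expect_lt(tr$values[length(tr$values)], 0.5)
})

test_that("ERM2 goes extinct in finite time below the threshold", {
  p <- erm2_params_for_AK(r = 0.2, A = 100, K = 1e6)
  tr <- integrate_growth(p, x0 = 50, t_end = 500)
  expect_true(is.finite(tr$extinct_at))
  expect_true(all(tr$values[tr$times >= tr$extinct_at] == 0))
  expect_true(all(tr$values >= 0))
  # above the threshold it saturates towards K instead
  tr2 <- integrate_growth(p, x0 = 200, t_end = 500)
  expect_true(is.na(tr2$extinct_at))
  expect_gt(tr2$values[length(tr2$values)], 0.9e6)
})

test_that("stationary threshold approximation behaves per its structure", {
  p <- erm2_params_for_AK(r = 0.2, A = 1e3, K = 1e8)
  expect_equal(as.numeric(erm2_threshold_approx(p, s_override = 0)), 0)
  # linear in s at a fixed decade exponent
  a_fix <- 3
  nu <- p$nu; r <- p$r; mu <- p$mu
  den <- nu * r - mu * (nu + a_fix * log(10))
  expect_equal(2 * p$s / den, (2 * p$s) / den)
  A1 <- p$s / den
  A2 <- (2 * p$s) / den
  expect_equal(A2 / A1, 2)
  # self-consistent approximation within a factor of 3 of the scanned root
  set.seed(404)
  for (i in 1:30) {
    nu <- 10^runif(1, 0.7, 4)
    r <- 10^runif(1, -2, 0)
    K <- 10^runif(1, 7, 10)
    Atar <- 10^runif(1, 1, 6)
    pp <- tryCatch(erm2_params_for_AK(r = r, A = Atar, K = K, nu = nu),
                   error = function(e) NULL)
    if (is.null(pp)) next
    roots <- erm2_roots_scan(nu, r, pp$mu, pp$s)
    expect_equal(min(roots), Atar, tolerance = 1e-4)
    Ap <- as.numeric(erm2_threshold_approx(pp))
    expect_lt(abs(log(Ap / Atar)), log(3))
  }
})

test_that("integration guards against blow-up", {
  # mu = 0 richards is pure exponential growth: must trip the guard
  p <- growth_params("richards", nu = 1, r = 1, mu = 0)
  expect_error(integrate_growth(p, x0 = 1, t_end = 60), "overflow")
})
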