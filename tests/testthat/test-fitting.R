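test_that("volume and cell-count conversions", {
  expect_equal(volume_to_cells(1, "cm3"), 1e9)
  expect_equal(volume_to_cells(1, "mm3"), 1e6)
  expect_equal(volume_to_cells(0), 0)
  expect_equal(cells_to_volume(1e9, "cm3"), 1)
  expect_equal(cells_to_volume(volume_to_cells(2.5, "mm3"), "mm3"), 2.5)
  expect_error(volume_to_cells(-1), "volume")
})

make_noiseless <- function(params, x0 = 1e6, days = 0:30) {
  tr <- integrate_growth(params, x0 = x0, t_end = max(days), times = days)
  data.frame(day = days, size = tr$values)
}

test_that("noiseless threshold-model parameters are recovered to 1%", {
  true <- erm2_params_for_AK(r = 0.25, A = 3e5, K = 2e9, nu = 1)
  dat <- make_noiseless(true)
  fit <- fit_growth_model(dat, "erm2", free = c("r", "mu", "s"),
                          fixed = list(nu = 1))
  expect_lt(abs(coef(fit)["r"] - true$r) / true$r, 0.01)
  expect_lt(abs(coef(fit)["mu"] - true$mu) / true$mu, 0.01)
  expect_lt(abs(coef(fit)["s"] - true$s) / true$s, 0.01)
  expect_lt(abs(fit$K - 2e9) / 2e9, 0.01)
  expect_lt(abs(fit$A - 3e5) / 3e5, 0.02)
  expect_false(fit$K_below_data)
})

test_that("noiseless ERM1 refits recover the threshold parameterization", {
  true <- erm1_params_from_AK(r = 0.1, A = 1e6, K = 1e8, nu = 1)
  dat <- make_noiseless(true, x0 = 2e6, days = 0:30)
  fit <- fit_growth_model(dat, "erm1", free = c("r", "A", "K"),
                          fixed = list(nu = 1))
  expect_lt(fit$sse, 1e-6)
  expect_lt(abs(coef(fit)["A"] - 1e6) / 1e6, 0.01)
  expect_lt(abs(coef(fit)["K"] - 1e8) / 1e8, 0.01)
  expect_lt(abs(coef(fit)["r"] - 0.1) / 0.1, 0.01)
})

test_that("fits are deterministic and scale-consistent through file units", {
  true <- erm2_params_for_AK(r = 0.25, A = 3e5, K = 2e9, nu = 1)
  dat <- make_noiseless(true)
  f1 <- fit_growth_model(dat, "erm2", free = c("r", "mu", "s"),
                         fixed = list(nu = 1))
  f2 <- fit_growth_model(dat, "erm2", free = c("r", "mu", "s"),
                         fixed = list(nu = 1))
  expect_identical(coef(f1), coef(f2))
  # writing in mm3 and reading back converts to cells, so estimates match
  tmp <- tempfile(fileext = ".csv")
  write_tumour_csv(dat, tmp, unit = "mm3")
  dat2 <- read_tumour_csv(tmp)
  expect_equal(dat2$size, dat$size, tolerance = 1e-12)
  f3 <- fit_growth_model(dat2, "erm2", free = c("r", "mu", "s"),
                         fixed = list(nu = 1))
  expect_equal(coef(f3), coef(f1), tolerance = 1e-8)
})

test_that("a capacity pinned below the data raises the consistency flag", {
  true <- erm2_params_for_AK(r = 0.25, A = 3e5, K = 2e9, nu = 1)
  dat <- make_noiseless(true)
  fit <- fit_growth_model(dat, "erm1", free = c("r", "A"),
                          fixed = list(nu = 1, K = max(dat$size) / 2))
  expect_true(fit$K_below_data)
})

test_that("model comparison ranks by fit quality", {
  # symmetric (nu = 1) data: the threshold models should both do well,
  # and the flexible model must rank at least as well as the classical one
  true <- erm2_params_for_AK(r = 0.25, A = 3e5, K = 2e9, nu = 1)
  dat <- make_noiseless(true)
  cmp <- compare_growth_models(dat, list(
    list(model = "erm2", free = c("r", "mu", "s"), fixed = list(nu = 1)),
    list(model = "erm1", free = c("r", "A", "K"), fixed = list(nu = 1))))
  sse_erm2 <- cmp$table$sse[grepl("erm2", cmp$table$candidate)]
  sse_erm1 <- cmp$table$sse[grepl("erm1", cmp$table$candidate)]
  expect_lte(sse_erm2, sse_erm1 + 1e-8)
  # single candidate passes through with rank 1
  one <- compare_growth_models(dat, list(
    list(model = "erm2", free = c("r", "mu", "s"), fixed = list(nu = 1))))
  expect_equal(one$table$rank, 1)
})

test_that("the classical threshold model fails on strongly asymmetric data", {
  spec <- tumour_spec_dataset1_like(seed = 8)
  spec$noise_sdlog <- 0
  spec$n_replicates <- 1
  spec$unit <- "cells"
  dat <- make_tumour_dataset(spec)
  cmp <- compare_growth_models(dat, list(
    list(model = "erm1", free = c("r", "A", "K"), fixed = list(nu = 1)),
    list(model = "erm2", free = c("nu", "r", "mu", "s"))))
  tab <- cmp$table
  expect_equal(tab$candidate[1], "erm2")
  expect_gt(tab$sse[tab$candidate != "erm2"][1], 5 * tab$sse[1])
})

test_that("fit methods expose the usual modelling interface", {
  true <- erm2_params_for_AK(r = 0.25, A = 3e5, K = 2e9, nu = 1)
  dat <- make_noiseless(true)
  fit <- fit_growth_model(dat, "erm2", free = c("r", "mu", "s"),
                          fixed = list(nu = 1))
  expect_named(coef(fit), c("nu", "r", "mu", "s"))
  expect_length(residuals(fit), nrow(dat))
  expect_lt(max(abs(residuals(fit))), 1e-4)
  pr <- predict(fit, newdata = data.frame(day = c(0, 15.5, 31)))
  expect_length(pr, 3)
  expect_true(all(diff(pr) > 0))
  sm <- summary(fit)
  expect_s3_class(sm, "summary.growth_fit")
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(nrow(dat), 2))
})
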