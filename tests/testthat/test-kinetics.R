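make_curve <- function(f_bound, thalf_fast, thalf_slow, noise = 0,
                       seed = 1L, ...) {
  normalize_bleach(simulate_bleach_curve(
    kinetics_spec(f_bound, thalf_fast, thalf_slow, noise_sigma = noise,
                  seed = seed, ...)))
}

test_that("normalization follows the background-corrected equation", {
  # spot(0)=100, background 10 throughout, spot(t)=50 -> 40/90
  s <- bleach_series(times = seq(-9, 10), spot = c(rep(100, 10),
                                                   rep(50, 10)),
                     background = rep(10, 20), n_prebleach = 10L)
  nc <- normalize_bleach(s)
  expect_equal(nc$values[1], 1)
  expect_equal(nc$values[-1], rep(40 / 90, 10), tolerance = 1e-12)
  # background 0, constant spot: all values 1
  s2 <- bleach_series(seq(-9, 10), rep(7, 20), rep(0, 20), 10L)
  expect_true(all(normalize_bleach(s2)$values == 1))
  # zero denominator is a normalization error
  s3 <- bleach_series(seq(-9, 10), rep(10, 20), rep(10, 20), 10L)
  expect_error(normalize_bleach(s3), "normalization failed")
})

test_that("normalization is idempotent on normalized curves", {
  nc <- make_curve(0.37, 3, 52, noise = 0.02, seed = 3L)
  nc2 <- normalize_bleach(nc)
  expect_equal(nc2$values, nc$values, tolerance = 1e-12)
  expect_identical(nc2, nc)
})

test_that("unit-interval rescale maps min/max and preserves order", {
  expect_equal(rescale_unit_interval(c(1, 0.2, 0.6)), c(1, 0, 0.5))
  v <- c(0, 0.4, 1)
  expect_equal(rescale_unit_interval(v), v)  # idempotent on [0,1] span
  mono <- cumsum(runif(20))
  expect_true(all(diff(rescale_unit_interval(mono)) > 0))
  expect_error(rescale_unit_interval(rep(1, 5)), "constant")
})

test_that("noiseless bi-exponential parameters are recovered exactly", {
  fit <- fit_biexponential(make_curve(0.37, 3, 52))
  expect_true(fit$converged)
  expect_equal(fit$f_slow, 0.37, tolerance = 1e-4)
  expect_equal(fit$thalf_slow, 52, tolerance = 52 * 1e-4)
  expect_equal(fit$thalf_fast, 3, tolerance = 3 * 1e-4)
  expect_equal(fit$f_fast + fit$f_slow, 1, tolerance = 1e-9)
})

test_that("degenerate limits: mono-exponential and flat curves", {
  # no bound pool: single exponential, fast fraction 1
  fit1 <- fit_biexponential(make_curve(0, 3, 52))
  expect_equal(fit1$f_fast, 1, tolerance = 1e-3)
  # flat curve: zero rates, infinite half-times, flagged
  flat <- structure(list(times = seq(0, 160, by = 2),
                         values = rep(1, 81), mode = "FLIP"),
                    class = "normalized_curve")
  fit2 <- fit_biexponential(flat)
  expect_identical(fit2$flag, "no_decay")
  expect_identical(fit2$thalf_fast, Inf)
  expect_identical(fit2$thalf_slow, Inf)
  # too few points is an error
  short <- structure(list(times = seq(0, 8, by = 2), values = exp(-0:4),
                          mode = "FLIP"), class = "normalized_curve")
  expect_error(fit_biexponential(short), "8 post-bleach")
})

test_that("multi-start order does not change the selected fit", {
  nc <- make_curve(0.37, 3, 52, noise = 0.02, seed = 5L)
  grid <- expand.grid(l1 = log(2) / c(1, 3, 10),
                      l2 = log(2) / c(30, 60, 120))
  f1 <- fit_biexponential(nc, start_grid = grid)
  f2 <- fit_biexponential(nc, start_grid = grid[rev(seq_len(nrow(grid))), ])
  expect_equal(coef(f1), coef(f2), tolerance = 1e-8)
})

test_that("fit methods behave like a model object", {
  nc <- make_curve(0.37, 3, 52, noise = 0.02, seed = 8L)
  fit <- fit_biexponential(nc)
  expect_named(coef(fit), c("N1", "lambda1", "N2", "lambda2"))
  expect_length(fitted(fit), length(fit$times))
  expect_equal(fitted(fit) + residuals(fit), fit$values)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, 0), fit$N1 + fit$N2)
  sims <- simulate(fit, nsim = 3, seed = 1L)
  expect_equal(dim(sims), c(length(fit$times), 3L))
  expect_identical(simulate(fit, nsim = 3, seed = 1L), sims)
  s <- summary(fit)
  expect_s3_class(s, "summary.biexp_fit")
  expect_gt(s$sigma, 0)
})

test_that("fits converge to generating values as noise vanishes", {
  for (fb in c(0.1, 0.22, 0.37, 0.5)) {
    ch <- fit_cohort(simulate_flip_cohort(fb, 3, 52, noise_sigma = 0.02,
                                          n_curves = 50L,
                                          master_seed = 20L))
    expect_lt(abs(ch$summary["f_slow", "mean"] - fb), 0.03)
    expect_lt(abs(ch$summary["thalf_slow", "mean"] / 52 - 1), 0.10)
  }
})

test_that("nearly-free scenarios recover a small bound fraction", {
  for (fb in c(0.02, 0.03)) {
    ch <- fit_cohort(simulate_flip_cohort(fb, 3, 52, noise_sigma = 0.01,
                                          n_curves = 20L,
                                          master_seed = 30L))
    expect_gte(ch$summary["f_slow", "mean"], 0)
    expect_lte(ch$summary["f_slow", "mean"], 0.08)
  }
})

test_that("pool summary maps fast to free and slow to bound", {
  fit <- fit_biexponential(make_curve(0.37, 3, 52))
  ps <- pool_summary(fit)
  expect_equal(ps$bound_percent, 37, tolerance = 0.1)
  expect_equal(ps$bound_thalf, 52, tolerance = 0.1)
  expect_equal(ps$free_percent + ps$bound_percent, 100, tolerance = 1e-9)
})

test_that("cohort aggregation handles single and duplicated curves", {
  nc <- make_curve(0.37, 3, 52, noise = 0.02, seed = 2L)
  single <- fit_cohort(list(nc))
  expect_equal(single$summary["f_slow", "mean"],
               fit_biexponential(nc)$f_slow, tolerance = 1e-10)
  expect_equal(single$summary["f_slow", "n"], 1)
  dup <- fit_cohort(list(nc, nc, nc))
  expect_equal(dup$summary["f_slow", "sd"], 0, tolerance = 1e-12)
  expect_error(fit_cohort(list()), "at least one")
})

test_that("FRAP curves fit through the unrecovered fraction", {
  spec <- kinetics_spec(0.37, 3, 52, noise_sigma = 0, n_frames = 60L)
  fit <- fit_biexponential(normalize_bleach(
    simulate_bleach_curve(spec, "FRAP")))
  expect_true(fit$converged)
  expect_equal(fit$f_slow, 0.37, tolerance = 0.02)
  expect_equal(fit$thalf_slow, 52, tolerance = 52 * 0.05)
})
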