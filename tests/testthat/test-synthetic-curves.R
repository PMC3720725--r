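test_that("kinetics specs enforce the two-pool ordering", {
  expect_error(kinetics_spec(0.3, thalf_fast = 60, thalf_slow = 50),
               "smaller")
  expect_error(kinetics_spec(1.2, 3, 52), "\\[0, 1\\]")
  expect_error(kinetics_spec(0.3, 3, 52, sampling_interval = 0),
               "positive")
  expect_silent(kinetics_spec(1, 3, Inf))
})

test_that("noiseless FLIP curves follow the closed-form kernel", {
  spec <- kinetics_spec(f_bound = 0.37, thalf_fast = 3, thalf_slow = 52,
                        noise_sigma = 0)
  s <- simulate_bleach_curve(spec, "FLIP")
  # pre-bleach frames and the t = 0 limit sit at the pre-bleach level
  expect_equal(s$spot[seq_len(spec$n_prebleach)],
               rep(spec$prebleach_level, spec$n_prebleach))
  # value at t = 52 s: direct evaluation of the generating expression
  A <- spec$prebleach_level - spec$background_level
  expected_52 <- spec$background_level +
    A * (0.63 * exp(-log(2) * 52 / 3) + 0.37 * exp(-log(2) * 52 / 52))
  i52 <- which(s$times == 52)
  expect_equal(s$spot[i52], expected_52, tolerance = 1e-12)
  # normalized value at t = 52 equals the kernel
  nc <- normalize_bleach(s)
  expect_equal(nc$values[nc$times == 52],
               0.63 * 2^(-52 / 3) + 0.37 * 2^(-1), tolerance = 1e-12)
})

test_that("fully bound molecules with infinite residence give a flat curve", {
  spec <- kinetics_spec(f_bound = 1, thalf_fast = 3, thalf_slow = Inf,
                        noise_sigma = 0)
  s <- simulate_bleach_curve(spec, "FLIP")
  expect_equal(s$spot, rep(spec$prebleach_level, length(s$spot)))
})

test_that("noiseless curves are monotone in the expected direction", {
  spec <- kinetics_spec(f_bound = 0.3, thalf_fast = 5, thalf_slow = 60,
                        noise_sigma = 0)
  post <- function(s) s$spot[s$times > 0]
  expect_true(all(diff(post(simulate_bleach_curve(spec, "FLIP"))) <= 0))
  expect_true(all(diff(post(simulate_bleach_curve(spec, "FRAP"))) >= 0))
})

test_that("curve simulation is seed-deterministic", {
  spec <- kinetics_spec(0.37, 3, 52, noise_sigma = 0.05, seed = 17L)
  a <- simulate_bleach_curve(spec)
  b <- simulate_bleach_curve(spec)
  expect_identical(a$spot, b$spot)
  spec$seed <- 18L
  expect_false(identical(simulate_bleach_curve(spec)$spot, a$spot))
})

test_that("bleach CSV round trip preserves the series", {
  s <- simulate_bleach_curve(kinetics_spec(0.37, 3, 52, seed = 4L))
  p <- withr::local_tempfile(fileext = ".csv")
  write_bleach_csv(s, p)
  s2 <- read_bleach_csv(p, "FLIP")
  expect_equal(s2$spot, s$spot)
  expect_equal(s2$n_prebleach, s$n_prebleach)
  expect_equal(s2$times, s$times)
})
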