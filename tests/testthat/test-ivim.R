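test_that("ivim_signal evaluates the biexponential decay", {
  p <- list(d_slow = 1.0e-3, d_fast = 50e-3, f_p = 0.3)
  expect_identical(ivim_signal(p, 0), 1.0)
  expect_equal(ivim_signal(list(d_slow = 1.0e-3, d_fast = 50e-3, f_p = 0), 1000),
               exp(-1), tolerance = 1e-12)
  expect_equal(ivim_signal(p, 100), 0.3 * exp(-5) + 0.7 * exp(-0.1),
               tolerance = 1e-12)
  expect_equal(round(ivim_signal(p, 100), 5), 0.63541)
  expect_error(ivim_signal(list(d_slow = 2e-3, d_fast = 1e-3, f_p = 0.2), 10),
               "invalid")
})

test_that("ivim_signal is strictly decreasing in b for valid parameters", {
  set.seed(7)
  b <- sort(c(0, runif(20, 1, 1000)))
  for (i in 1:25) {
    p <- list(d_slow = runif(1, 0.2e-3, 2.5e-3),
              d_fast = runif(1, 5e-3, 200e-3), f_p = runif(1, 0, 0.6))
    p$d_fast <- max(p$d_fast, p$d_slow * 1.1)
    s <- ivim_signal(p, b)
    expect_true(all(diff(s) < 0))
    expect_true(all(s > 0 & s <= 1))
  }
})

test_that("3x3 median filter matches a brute-force sliding-window oracle", {
  set.seed(11)
  m <- matrix(rnorm(64), 8, 8)
  got <- median_filter_slicewise(m)
  # independent oracle: explicit window median with the same reflection
  # (edge-duplication) padding
  pm <- m[c(1, 1:8, 8), c(1, 1:8, 8)]
  want <- m
  for (i in 1:8) for (j in 1:8)
    want[i, j] <- median(pm[i:(i + 2), j:(j + 2)])
  expect_equal(got, want)
})

test_that("median filter removes impulses and preserves constants and shape", {
  const <- array(3.5, dim = c(6, 6, 2))
  expect_identical(median_filter_slicewise(const), const)
  hot <- matrix(0, 7, 7); hot[4, 4] <- 100
  expect_identical(median_filter_slicewise(hot), matrix(0, 7, 7))
  tr <- make_phantom_truth(tiny_config(), "healthy", seed = 2)
  d <- simulate_dwi(tr, noise_sd = 0.05)
  f <- median_filter_slicewise(d)
  expect_identical(dim(f$signal), dim(d$signal))
  expect_identical(median_filter_slicewise(matrix(2, 1, 1)), matrix(2, 1, 1))
})

test_that("in-plane resampling preserves constants and is an identity at source shape", {
  const <- matrix(4.2, 340, 218)
  down <- resample_inplane(const, c(128, 128), "down_for_fit")
  expect_identical(dim(down), c(128L, 128L))
  expect_true(all(abs(down - 4.2) < 1e-12))
  up <- resample_inplane(matrix(1.3, 128, 128), c(340, 218), "up_for_maps")
  expect_true(all(abs(up - 1.3) < 1e-12))
  x <- matrix(rnorm(12 * 10), 12, 10)
  expect_identical(resample_inplane(x, c(12, 10), "down_for_fit"), x)
})

test_that("down-then-up round trip on a smooth gradient stays within 2% of range", {
  x <- outer(seq(0, 1, length.out = 340), seq(0, 2, length.out = 218), `+`)
  down <- resample_inplane(x, c(128, 128), "down_for_fit")
  up <- resample_inplane(down, c(340, 218), "up_for_maps")
  rmse <- sqrt(mean((up - x)^2))
  expect_lt(rmse, 0.02 * diff(range(x)))
})

test_that("resampling leaves slice and b axes untouched", {
  arr <- array(rnorm(20 * 18 * 3 * 4), c(20, 18, 3, 4))
  out <- resample_inplane(arr, c(10, 9), "down_for_fit")
  expect_identical(dim(out), c(10L, 9L, 3L, 4L))
  # each (z, b) plane resampled independently: matches 2D call
  expect_equal(out[, , 2, 3],
               resample_inplane(arr[, , 2, 3], c(10, 9), "down_for_fit"))
})

test_that("segmented LSQ recovers noise-free parameters", {
  ser <- series_from_params(1.0e-3, 50e-3, 0.25)
  fit <- fit_ivim_lsq(ser)
  i <- which(ser$mask)
  expect_lt(abs(fit$d_slow[i] / 1.0e-3 - 1), 0.01)
  expect_lt(abs(fit$d_fast[i] / 50e-3 - 1), 0.01)
  expect_lt(abs(fit$f_p[i] / 0.25 - 1), 0.01)
  # monoexponential input yields a near-zero perfusion fraction
  mono <- fit_ivim_lsq(series_from_params(1.0e-3, 50e-3, 0))
  expect_lt(mono$f_p[which(mono$mask)], 0.01)
})

test_that("LSQ flags degenerate voxels and rejects empty masks", {
  ser <- series_from_params(c(1.0e-3, 1.2e-3), c(50e-3, 60e-3), c(0.2, 0.3))
  ser$signal[2, 1, 1, ] <- 0  # second in-mask voxel all-zero
  fit <- fit_ivim_lsq(ser)
  expect_identical(fit$n_failed, 1L)
  expect_true(is.na(fit$d_slow[2, 1, 1]))
  expect_false(is.na(fit$d_slow[1, 1, 1]))
  empty <- array(FALSE, dim(ser$signal)[1:3])
  expect_error(fit_ivim_lsq(ser, empty), "empty")
})

test_that("the pseudo-diffusion coefficient is the least stable LSQ estimate", {
  set.seed(21)
  nv <- 500
  ser <- series_from_params(rep(0.96e-3, nv), rep(36.4e-3, nv),
                            rep(0.216, nv), noise_sd = 1 / 30, seed = 77)
  fit <- fit_ivim_lsq(ser)
  i <- which(ser$mask)
  rel_rmse <- function(map, tru) sqrt(mean((map[i] / tru - 1)^2, na.rm = TRUE))
  expect_gt(rel_rmse(fit$d_fast, 36.4e-3), rel_rmse(fit$d_slow, 0.96e-3))
})

test_that("Bayesian fit concentrates on the truth for noise-free data", {
  set.seed(5)
  nv <- 25
  ds <- runif(nv, 0.7e-3, 1.3e-3)
  df <- runif(nv, 30e-3, 140e-3)
  fp <- runif(nv, 0.1, 0.45)
  ser <- series_from_params(ds, df, fp)
  fit <- fit_ivim_bayes(ser, config = mcmc_config(n_iterations = 2500,
                                                  n_burn_in = 1200, seed = 9))
  i <- which(ser$mask)
  expect_lt(max(abs(fit$maps$d_slow[i] / ds - 1)), 0.02)
  expect_lt(max(abs(fit$maps$d_fast[i] / df - 1)), 0.02)
  expect_lt(max(abs(fit$maps$f_p[i] / fp - 1)), 0.02)
  # posterior intervals are ordered
  s <- fit$posterior$summary$d_fast
  expect_true(all(s$lower <= s$median & s$median <= s$upper))
})

test_that("Bayesian maps are bitwise-reproducible under a fixed seed", {
  ser <- series_from_params(c(1.0e-3, 1.1e-3), c(60e-3, 80e-3), c(0.25, 0.3),
                            noise_sd = 0.05, seed = 3)
  cfg <- mcmc_config(n_iterations = 800, n_burn_in = 400, seed = 42)
  f1 <- fit_ivim_bayes(ser, config = cfg)
  f2 <- fit_ivim_bayes(ser, config = cfg)
  expect_identical(f1$maps$d_fast, f2$maps$d_fast)
  expect_identical(f1$posterior$summary, f2$posterior$summary)
})

test_that("truth outside the prior support pins the estimate at the bound and flags it", {
  # f_p = 0.7 exceeds the 0.6 support ceiling
  ser <- series_from_params(1.0e-3, 60e-3, 0.7)
  fit <- fit_ivim_bayes(ser, config = mcmc_config(n_iterations = 2000,
                                                  n_burn_in = 1000, seed = 2))
  i <- which(ser$mask)
  expect_gt(fit$maps$f_p[i], 0.58)
  expect_lte(fit$maps$f_p[i], 0.6)
  expect_true(fit$posterior$flagged[1])
})

test_that("Bayesian fit shrinks the noisy pseudo-diffusion map relative to LSQ", {
  nv <- 150
  ser <- series_from_params(rep(1.02e-3, nv), rep(73.5e-3, nv),
                            rep(0.292, nv), noise_sd = 0.05, seed = 13)
  bay <- fit_ivim_bayes(ser, config = mcmc_config(n_iterations = 2000,
                                                  n_burn_in = 1000, seed = 4))
  lsq <- fit_ivim_lsq(ser)
  i <- which(ser$mask)
  expect_lt(sd(bay$maps$d_fast[i]), sd(lsq$d_fast[i], na.rm = TRUE))
})

test_that("global summary reports reporting units and handles NaN", {
  shape <- c(4L, 4L, 1L)
  mask <- array(TRUE, shape)
  v <- array(1.0e-3, shape)
  maps <- ivim_maps(v, array(50e-3, shape), array(0.25, shape),
                    array(1, shape), mask)
  gs <- global_liver_summary(maps)
  expect_equal(gs$mean[gs$parameter == "d_slow"], 1.0)
  expect_equal(gs$sd[gs$parameter == "d_slow"], 0)
  expect_equal(gs$mean[gs$parameter == "f_p"], 25)
  # two-voxel mask {1, 3}: mean 2, median 2, sample SD sqrt(2)
  m2 <- array(FALSE, shape); m2[1:2] <- TRUE
  v2 <- array(NA_real_, shape); v2[1:2] <- c(1e-3, 3e-3)
  maps2 <- ivim_maps(v2, array(50e-3, shape), array(0.25, shape),
                     array(1, shape), m2)
  gs2 <- global_liver_summary(maps2)
  row <- gs2[gs2$parameter == "d_slow", ]
  expect_equal(row$mean, 2); expect_equal(row$median, 2)
  expect_equal(row$sd, sqrt(2))
  # NaN voxel inside the mask is excluded and counted
  v2[2] <- NaN
  maps3 <- ivim_maps(v2, array(50e-3, shape), array(0.25, shape),
                     array(1, shape), m2)
  gs3 <- global_liver_summary(maps3)
  row3 <- gs3[gs3$parameter == "d_slow", ]
  expect_equal(row3$n, 1L); expect_equal(row3$n_nan, 1L)
  expect_error(global_liver_summary(
    ivim_maps(v, v, v, v, array(FALSE, shape))), "empty")
})

test_that("unit conversions compose to the identity", {
  x <- c(0.96e-3, 73.5e-3, 1)
  expect_identical(report_to_si(si_to_report(x, "diffusivity"), "diffusivity"), x)
  f <- c(0, 0.292, 1)
  expect_identical(report_to_si(si_to_report(f, "fraction"), "fraction"), f)
  expect_equal(si_to_report(0.292, "fraction"), 29.2)
})
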