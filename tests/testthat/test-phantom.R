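test_that("b-value scheme defaults match the 13-b liver protocol and are validated", {
  sch <- bvalue_scheme()
  expect_length(sch$b_values, 13)
  expect_identical(sch$b_values[1], 0)
  expect_true(all(diff(sch$b_values) > 0))
  expect_identical(sch$averages, c(rep(1L, 6), rep(2L, 6), 3L))
  expect_error(bvalue_scheme(c(10, 20), c(1, 1)), "first b-value")
  expect_error(bvalue_scheme(c(0, 20, 20), c(1, 1, 1)), "increasing")
  expect_error(bvalue_scheme(c(0, 10), 1L), "equal length")
})

test_that("phantom truth satisfies its invariants across cohorts and seeds", {
  cfg <- tiny_config()
  for (cohort in c("healthy", "patient")) {
    for (seed in c(3, 17, 91)) {
      tr <- make_phantom_truth(cfg, cohort, seed = seed)
      expect_true(validate_phantom_truth(tr))
      expect_true(all(is.na(tr$d_slow[!tr$liver_mask])))
    }
  }
})

test_that("phantom generation is deterministic and rejects bad input", {
  cfg <- tiny_config()
  a <- make_phantom_truth(cfg, "healthy", seed = 5)
  b <- make_phantom_truth(cfg, "healthy", seed = 5)
  expect_identical(a, b)
  expect_error(make_phantom_truth(cfg, "sick"), "arg")
  expect_error(cohort_config(shape = c(8, 8, 2)), "at least 16")
  gp <- default_group_params()
  gp$healthy$f_p["median"] <- -0.1
  expect_error(cohort_config(group_params = gp), "location")
})

test_that("zero cohort scales degenerate to homogeneous livers at the median", {
  gp <- default_group_params()
  for (cohort in names(gp))
    for (p in names(gp[[cohort]])) gp[[cohort]][[p]]["sd"] <- 0
  cfg <- tiny_config(group_params = gp)
  tr <- make_phantom_truth(cfg, "healthy", seed = 2)
  m <- tr$liver_mask
  expect_equal(unique(tr$f_p[m]), 0.292)
  expect_equal(unique(tr$d_slow[m]), 1.02e-3)
  expect_equal(unique(tr$d_fast[m]), 73.5e-3)
})

test_that("cohort medians converge to the configured medians", {
  cfg <- cohort_config(n_healthy = 200L, n_patient = 200L,
                       shape = c(16L, 16L, 3L), seed = 11L)
  study <- make_cohort(cfg, simulate = FALSE)
  cohorts <- vapply(study$subjects, `[[`, "", "cohort")
  for (cohort in c("healthy", "patient")) {
    vals <- t(vapply(study$subjects[cohorts == cohort],
                     function(s) s$truth$subject_values, numeric(6)))
    gp <- cfg$group_params[[cohort]]
    for (p in c("d_slow", "d_fast", "f_p")) {
      expect_lt(abs(median(vals[, p]) / gp[[p]]["median"] - 1), 0.02,
                label = sprintf("%s %s median", cohort, p))
    }
  }
  # the in-field median targets the cohort median too (subject-level
  # normalisation): healthy f_p
  fmed <- median(vapply(study$subjects[cohorts == "healthy"], function(s)
    median(s$truth$f_p[s$truth$liver_mask]), numeric(1)))
  expect_lt(abs(fmed / 0.292 - 1), 0.02)
})

test_that("noise-free DWI equals the forward model exactly", {
  tr <- make_phantom_truth(tiny_config(), "patient", seed = 4)
  d <- simulate_dwi(tr, noise_sd = 0)
  b <- d$scheme$b_values
  im <- which(tr$liver_mask)
  S <- matrix(d$signal, prod(tr$shape), length(b))[im, ]
  M <- t(vapply(im, function(i)
    ivim_signal(list(d_slow = tr$d_slow[i], d_fast = tr$d_fast[i],
                     f_p = tr$f_p[i]), b), numeric(length(b))))
  expect_lt(max(abs(S - M)), 1e-12)
  expect_true(all(d$signal[rep(!tr$liver_mask, length(b))] == 0))
})

test_that("rician noise at zero SD reduces to the gaussian noiseless output", {
  tr <- make_phantom_truth(tiny_config(), "healthy", seed = 8)
  g <- simulate_dwi(tr, noise_sd = 0, noise_model = "gaussian", seed = 1)
  r <- simulate_dwi(tr, noise_sd = 0, noise_model = "rician", seed = 1)
  expect_identical(g$signal, r$signal)
  expect_error(simulate_dwi(tr, noise_sd = -1), ">= 0")
})

test_that("per-b averaging reduces noise as the mean of independent excitations", {
  # 4 averages should halve the noise SD of a single excitation
  gp <- default_group_params()
  for (p in names(gp$healthy)) gp$healthy[[p]]["sd"] <- 0
  cfg <- tiny_config(group_params = gp)
  tr <- make_phantom_truth(cfg, "healthy", seed = 3)
  sch <- bvalue_scheme(c(0, 10, 20, 30, 40), rep(4L, 5))
  b <- sch$b_values
  clean <- ivim_signal(list(d_slow = 1.02e-3, d_fast = 73.5e-3, f_p = 0.292), b)
  resid <- c()
  for (seed in 1:12) {
    d <- simulate_dwi(tr, sch, noise_sd = 0.05, seed = seed)
    S <- matrix(d$signal, prod(tr$shape), length(b))[which(tr$liver_mask), ]
    resid <- c(resid, sweep(S, 2, clean))
  }
  expect_equal(sd(resid), 0.05 / 2, tolerance = 0.03)
})

test_that("SPGR simulation matches the closed-form signal and contrast ordering", {
  gp <- default_group_params()
  for (p in names(gp$patient)) gp$patient[[p]]["sd"] <- 0
  gp$patient$t1_pre["median"] <- 800
  gp$patient$t1_post["median"] <- 400
  cfg <- tiny_config(group_params = gp, heterogeneity = 0)
  tr <- make_phantom_truth(cfg, "patient", seed = 6)
  acq <- simulate_spgr_pair(tr, "pre", tr = 5.08, noise_sd = 0, m0 = 1000)
  im <- which(tr$liver_mask)
  # direct evaluation of the SPGR equation at t1 = 800 ms
  e1 <- exp(-5.08 / 800)
  for (k in 1:2) {
    a <- c(3, 15)[k] * pi / 180
    expected <- 1000 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
    expect_equal(unique(acq$signals[[k]][im]), expected, tolerance = 1e-12)
  }
  # shorter T1 post contrast gives a larger 15-degree signal
  post <- simulate_spgr_pair(tr, "post", tr = 5.08, noise_sd = 0, m0 = 1000)
  expect_true(all(post$signals[[2]][im] > acq$signals[[2]][im]))
  # sin(alpha) factor: signal scales to zero with the flip angle
  lo <- simulate_spgr_pair(tr, "pre", flip_angles = c(0.01, 15), noise_sd = 0)
  expect_lt(max(lo$signals[[1]][im]), 0.01 * max(lo$signals[[2]][im]))
  expect_error(simulate_spgr_pair(tr, "pre", tr = -1), "positive")
})

test_that("DCE simulation is the discrete convolution of AIF and retention", {
  gp <- default_group_params()
  for (p in names(gp$patient)) gp$patient[[p]]["sd"] <- 0
  gp$patient$hef["median"] <- 0.6
  cfg <- tiny_config(group_params = gp)
  tr <- make_phantom_truth(cfg, "patient", seed = 9)
  times <- default_dce_times()
  dce <- simulate_dce(tr, times, noise_sd = 0)
  A <- build_convolution_matrix(dce$aif, times)
  r <- (1 - 0.6) * exp(-times / 60) + 0.6 * exp(-times / 2e4)
  expected <- as.vector(A %*% r)
  i <- which(tr$liver_mask)[1]
  idx <- arrayInd(i, tr$shape)
  expect_lt(max(abs(dce$signal[idx[1], idx[2], idx[3], ] - expected)), 1e-12)
  expect_error(simulate_dce(tr, tau_fast = 100, tau_slow = 50), "tau_fast")
})

test_that("delta-like input function returns the retention function itself", {
  times <- seq(0, 120, by = 10)
  aif <- c(1, rep(0, length(times) - 1))
  A <- build_convolution_matrix(aif, times)
  r <- exp(-times / 40)
  out <- as.vector(A %*% r)
  # A is (dt/2)-scaled identity-like: proportional to r beyond the first sample
  expect_equal(out[-1], 5 * r[-1], tolerance = 1e-12)
})

test_that("cohort bundles follow the study design", {
  cfg <- cohort_config(n_healthy = 2L, n_patient = 2L,
                       shape = c(16L, 16L, 3L), seed = 3L)
  study <- make_cohort(cfg)
  expect_length(study$subjects, 4)
  cohorts <- vapply(study$subjects, `[[`, "", "cohort")
  expect_identical(as.integer(table(cohorts)[c("healthy", "patient")]),
                   c(2L, 2L))
  healthy <- study$subjects[[which(cohorts == "healthy")[1]]]
  patient <- study$subjects[[which(cohorts == "patient")[1]]]
  # no contrast data for healthy volunteers
  expect_null(healthy$dce)
  expect_null(healthy$spgr_post)
  expect_false(is.null(patient$dce))
  expect_false(is.null(patient$spgr_post))
  # degenerate single-subject cohort
  solo <- make_cohort(cohort_config(n_healthy = 1L, n_patient = 0L,
                                    shape = c(16L, 16L, 3L)))
  expect_length(solo$subjects, 1)
  expect_null(solo$subjects[[1]]$dce)
  expect_error(make_cohort(cohort_config(n_healthy = 0L, n_patient = 0L,
                                         shape = c(16L, 16L, 3L))),
               "at least one")
  # determinism of the whole bundle
  s1 <- make_cohort(cfg)
  expect_identical(study$subjects$S03$dwi$signal, s1$subjects$S03$dwi$signal)
  expect_identical(study$subjects$S03$dce$signal, s1$subjects$S03$dce$signal)
})

test_that("default cohort sizes mirror the study population", {
  cfg <- cohort_config()
  expect_identical(cfg$n_healthy, 10L)
  expect_identical(cfg$n_patient, 12L)
})

test_that("rescan jitter perturbs parameters at the requested scale", {
  tr <- make_phantom_truth(tiny_config(), "healthy", seed = 12)
  tr2 <- jitter_truth(tr, cv = 0.1, seed = 99)
  expect_true(validate_phantom_truth(tr2))
  m <- tr$liver_mask
  expect_false(identical(tr$d_slow[m], tr2$d_slow[m]))
  expect_identical(jitter_truth(tr, cv = 0, seed = 1)$d_slow, tr$d_slow)
})
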