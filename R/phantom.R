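#' Diffusion-weighting scheme
#'
#' Container binding an ordered list of b-values (s/mm^2) to the number of
#' signal excitations averaged at each b. The default is the 13-b-value
#' liver protocol: b = 0..50 acquired once, 60..400 twice and 800 three
#' times.
#'
#' @param b_values Strictly increasing numeric vector starting at 0 (s/mm^2).
#' @param averages Integer vector (>= 1) of excitations per b, same length.
#' @return An object of class `bvalue_scheme`.
#' @export
bvalue_scheme <- function(b_values = c(0, 10, 20, 30, 40, 50, 60, 70, 80,
                                       100, 200, 400, 800),
                          averages = c(rep(1L, 6), rep(2L, 6), 3L)) {
  if (length(b_values) != length(averages))
    stop("b_values and averages must have equal length")
  if (b_values[1] != 0) stop("first b-value must be 0")
  if (any(diff(b_values) <= 0)) stop("b-values must be strictly increasing")
  if (any(averages < 1) || any(averages != round(averages)))
    stop("averages must be integers >= 1")
  structure(list(b_values = as.numeric(b_values),
                 averages = as.integer(averages)),
            class = "bvalue_scheme")
}

#' @export
print.bvalue_scheme <- function(x, ...) {
  cat("b-value scheme:", length(x$b_values), "values,",
      paste(x$b_values, collapse = " "), "s/mm^2\n")
  cat("excitations:  ", paste(x$averages, collapse = " "), "\n")
  invisible(x)
}

#' Default per-cohort parameter distributions
#'
#' Location (median) and scale (SD) of each tissue parameter per cohort.
#' Diffusivities in mm^2/s, fractions in [0,1], T1 in ms. The IVIM entries
#' follow the two-cohort global statistics of the study population
#' (healthy: D_slow 1.02e-3 +- 0.15e-3, F_p 29.2% +- 5.1%, D_fast 73.5e-3
#' +- 25.5e-3; CP-A patients: 0.96e-3 +- 0.13e-3, 21.6% +- 4.0%, 36.4e-3
#' +- 14.2e-3); T1 and HEF locations are literature-informed (3T liver,
#' gadoxetate at 15 min).
#'
#' @return Nested list `cohort -> parameter -> c(median, sd)`.
#' @export
default_group_params <- function() {
  list(
    healthy = list(
      d_slow = c(median = 1.02e-3, sd = 0.15e-3),
      f_p    = c(median = 0.292,   sd = 0.051),
      d_fast = c(median = 73.5e-3, sd = 25.5e-3),
      t1_pre  = c(median = 810,  sd = 60),
      t1_post = c(median = 290,  sd = 40),
      hef    = c(median = 0.85, sd = 0.07)),
    patient = list(
      d_slow = c(median = 0.96e-3, sd = 0.13e-3),
      f_p    = c(median = 0.216,   sd = 0.040),
      d_fast = c(median = 36.4e-3, sd = 14.2e-3),
      t1_pre  = c(median = 860,  sd = 70),
      t1_post = c(median = 480,  sd = 60),
      hef    = c(median = 0.55, sd = 0.12))
  )
}

#' Configuration for a synthetic two-cohort liver study
#'
#' Defines subject counts, per-cohort parameter distributions (location =
#' median, scale = SD), phantom grid, acquisition noise and the master seed.
#' Defaults reproduce the study conditions: 10 healthy volunteers and 12
#' patients with mild (CP-A) liver-function impairment, with IVIM parameter
#' distributions matching the reported global medians and SDs.
#'
#' @param n_healthy,n_patient Subject counts (>= 0, at least one subject
#'   overall when building a cohort).
#' @param shape Phantom grid dimensions, at least 16 x 16 x 3 voxels.
#' @param group_params Nested list `cohort -> parameter -> c(median, sd)`.
#' @param noise_sd Acquisition noise SD in signal units (b0 signal is 1, so
#'   the default 0.05 corresponds to SNR 20).
#' @param heterogeneity Within-liver heterogeneity knob: region-wise
#'   variation is drawn with log/logit-scale SD equal to
#'   `heterogeneity * sd/median` of the cohort distribution, so degenerate
#'   cohort scales (`sd = 0`) yield perfectly homogeneous livers.
#' @param n_regions Number of segment-like angular regions in the phantom.
#' @param scheme A [bvalue_scheme()].
#' @param seed Master integer seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_healthy = 10L, n_patient = 12L,
                          shape = c(64L, 64L, 8L),
                          group_params = default_group_params(),
                          noise_sd = 0.05,
                          heterogeneity = 0.3,
                          n_regions = 4L,
                          scheme = bvalue_scheme(),
                          seed = 1L) {
  if (n_healthy < 0 || n_patient < 0) stop("subject counts must be >= 0")
  if (length(shape) != 3L || any(shape < c(16, 16, 3)))
    stop("shape must be 3D and at least 16 x 16 x 3")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (heterogeneity < 0) stop("heterogeneity must be >= 0")
  for (cohort in names(group_params)) {
    gp <- group_params[[cohort]]
    for (p in names(gp)) {
      if (gp[[p]]["sd"] < 0)
        stop(sprintf("negative scale for %s/%s", cohort, p))
      if (gp[[p]]["median"] <= 0)
        stop(sprintf("non-positive location for %s/%s", cohort, p))
    }
    if (gp$f_p["median"] >= 1 || gp$hef["median"] >= 1)
      stop("fraction locations must be < 1")
    if (gp$d_fast["median"] <= gp$d_slow["median"])
      stop("d_fast location must exceed d_slow location")
    if (gp$t1_post["median"] > gp$t1_pre["median"])
      stop("t1_post location must not exceed t1_pre (gadoxetate shortens T1)")
  }
  structure(list(n_healthy = as.integer(n_healthy),
                 n_patient = as.integer(n_patient),
                 shape = as.integer(shape),
                 group_params = group_params,
                 noise_sd = noise_sd,
                 heterogeneity = heterogeneity,
                 n_regions = as.integer(n_regions),
                 scheme = scheme,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

# inverse-CDF draw at quantile u for one parameter, respecting the
# distribution family chosen per parameter class:
#   log-normal for diffusivities, logit-normal for fractions,
#   positively-truncated normal for T1.
param_quantile <- function(param, med, sd, u) {
  if (sd == 0) return(med)
  if (param %in% c("d_slow", "d_fast")) {
    # solve lognormal sdlog from target SD at given median
    cc <- (sd / med)^2
    sdlog <- sqrt(log((1 + sqrt(1 + 4 * cc)) / 2))
    stats::qlnorm(u, meanlog = log(med), sdlog = sdlog)
  } else if (param %in% c("f_p", "hef")) {
    sigma <- sd / (med * (1 - med))  # delta-method logit scale
    stats::plogis(stats::qnorm(u, mean = stats::qlogis(med), sd = sigma))
  } else {
    pmax(stats::qnorm(u, mean = med, sd = sd), 1)
  }
}

# relative (log/logit-scale) dispersion of the cohort distribution,
# reused to scale within-liver heterogeneity
param_rel_sd <- function(param, med, sd) {
  if (sd == 0) return(0)
  if (param %in% c("f_p", "hef")) sd / (med * (1 - med)) else sd / med
}

# separable box smoothing with edge replication, repeated `passes` times
smooth3d <- function(x, width = 5L, passes = 2L) {
  smooth1 <- function(v, w) {
    n <- length(v)
    if (n < 2L) return(v)
    h <- w %/% 2L
    pad <- c(rep(v[1], h), v, rep(v[n], h))
    cs <- cumsum(c(0, pad))
    (cs[(w + 1):(n + w)] - cs[1:n]) / w
  }
  for (p in seq_len(passes)) {
    x <- apply(x, c(2, 3), smooth1, w = width)
    x <- aperm(apply(x, c(1, 3), smooth1, w = width), c(2, 1, 3))
    if (dim(x)[3] >= 3) {
      x <- aperm(apply(x, c(1, 2), smooth1, w = 3L), c(2, 3, 1))
    }
  }
  x
}

# ellipsoidal liver mask and angular segment-like regions
phantom_geometry <- function(shape, n_regions) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2; cz <- (nz + 1) / 2
  gx <- (seq_len(nx) - cx) / (0.42 * nx)
  gy <- (seq_len(ny) - cy) / (0.38 * ny)
  gz <- (seq_len(nz) - cz) / (0.52 * nz)
  r2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  mask <- r2 <= 1
  ang <- atan2(rep(gy, each = nx), rep(gx, times = ny))
  lab2d <- ceiling(n_regions * (ang + pi + 1e-9) / (2 * pi + 2e-9))
  labels <- array(0L, dim = shape)
  for (z in seq_len(nz)) labels[, , z] <- lab2d
  labels[!mask] <- 0L
  list(mask = mask, labels = labels)
}

#' Generate ground-truth parameter fields for one synthetic liver
#'
#' Draws a subject-level value for each tissue parameter from the cohort's
#' distribution (log-normal for diffusivities, logit-normal for fractions,
#' truncated normal for T1), then modulates it across segment-like regions
#' with smoothed multiplicative offsets. The modulation field is
#' renormalised so the in-mask median of every field equals the drawn
#' subject value exactly.
#'
#' @param config A [cohort_config()].
#' @param cohort `"healthy"` or `"patient"`.
#' @param seed Integer seed; identical seeds give bitwise-identical output.
#' @param quantiles Optional named vector of quantiles in (0,1), one per
#'   parameter, used for stratified cohort sampling; defaults to
#'   independent uniform draws.
#' @return An object of class `phantom_truth` with fields `shape`,
#'   `liver_mask`, `region_labels`, `d_slow`, `d_fast`, `f_p`, `t1_pre`,
#'   `t1_post`, `hef`, `cohort`, `subject_values`.
#' @export
make_phantom_truth <- function(config, cohort = c("healthy", "patient"),
                               seed = config$seed, quantiles = NULL) {
  cohort <- match.arg(cohort)
  if (!inherits(config, "cohort_config")) stop("config must be a cohort_config")
  gp <- config$group_params[[cohort]]
  if (is.null(gp)) stop("invalid cohort label")
  set.seed(seed)
  geom <- phantom_geometry(config$shape, config$n_regions)
  params <- names(gp)
  if (is.null(quantiles)) {
    quantiles <- stats::setNames(stats::runif(length(params)), params)
  }
  subject_values <- vapply(params, function(p) {
    param_quantile(p, gp[[p]]["median"], gp[[p]]["sd"], quantiles[[p]])
  }, numeric(1))
  # enforce joint invariants at the subject level
  subject_values["d_fast"] <- max(subject_values["d_fast"],
                                  1.5 * subject_values["d_slow"])
  subject_values["t1_post"] <- min(subject_values["t1_post"],
                                   subject_values["t1_pre"])

  fields <- list()
  inmask <- which(geom$mask)
  for (p in params) {
    rel <- config$heterogeneity * param_rel_sd(p, gp[[p]]["median"], gp[[p]]["sd"])
    offsets <- stats::rnorm(config$n_regions, 0, rel)
    g <- array(0, dim = config$shape)
    for (k in seq_len(config$n_regions)) g[geom$labels == k] <- offsets[k]
    g <- smooth3d(g)
    g <- g - stats::median(g[inmask])
    f <- array(NA_real_, dim = config$shape)
    v <- subject_values[[p]]
    if (p %in% c("f_p", "hef")) {
      f[inmask] <- stats::plogis(stats::qlogis(v) + g[inmask])
    } else {
      f[inmask] <- v * exp(g[inmask])
    }
    fields[[p]] <- f
  }
  # voxelwise joint invariants
  fix <- which(fields$d_fast[inmask] <= fields$d_slow[inmask])
  if (length(fix))
    fields$d_fast[inmask][fix] <- 1.5 * fields$d_slow[inmask][fix]
  fields$t1_post[inmask] <- pmin(fields$t1_post[inmask], fields$t1_pre[inmask])

  structure(c(list(shape = config$shape, liver_mask = geom$mask,
                   region_labels = geom$labels, cohort = cohort,
                   subject_values = subject_values, seed = seed),
              fields),
            class = "phantom_truth")
}

#' Check ground-truth invariants of a phantom
#'
#' Asserts positivity and ordering of the diffusion coefficients, the [0,1]
#' range of fractions and T1 shortening after contrast, within the liver
#' mask.
#'
#' @param truth A `phantom_truth`.
#' @return Invisibly `TRUE`; stops on violation.
#' @export
validate_phantom_truth <- function(truth) {
  m <- truth$liver_mask
  stopifnot(all(truth$f_p[m] >= 0 & truth$f_p[m] <= 1),
            all(truth$hef[m] >= 0 & truth$hef[m] <= 1),
            all(truth$d_slow[m] > 0),
            all(truth$d_fast[m] > truth$d_slow[m]),
            all(truth$t1_pre[m] > 0),
            all(truth$t1_post[m] <= truth$t1_pre[m]))
  invisible(TRUE)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("phantom_truth: %s, grid %s, %d liver voxels\n", x$cohort,
              paste(x$shape, collapse = "x"), sum(x$liver_mask)))
  v <- x$subject_values
  cat(sprintf("  D_slow %.3f  D_fast %.1f (x1e-3 mm2/s)  F_p %.1f%%\n",
              v["d_slow"] * 1e3, v["d_fast"] * 1e3, v["f_p"] * 100))
  cat(sprintf("  T1 pre %.0f ms  post %.0f ms  HEF %.2f\n",
              v["t1_pre"], v["t1_post"], v["hef"]))
  invisible(x)
}

#' Simulate a diffusion-weighted series from ground truth
#'
#' Evaluates the biexponential IVIM forward model at every b-value and adds
#' acquisition noise, averaging the configured number of independent noisy
#' excitations per b. Voxels outside the liver mask contain background
#' noise only. Gaussian noise matches the additive error term of the signal
#' model; Rician noise (magnitude of a complex Gaussian) is available since
#' magnitude MR data is Rician.
#'
#' @param truth A `phantom_truth`.
#' @param scheme A [bvalue_scheme()].
#' @param noise_sd Noise SD per excitation, in signal units (b0 signal 1).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed Integer seed.
#' @return A `dwi_series` (see [dwi_series()]).
#' @export
simulate_dwi <- function(truth, scheme = bvalue_scheme(), noise_sd = 0.05,
                         noise_model = c("gaussian", "rician"), seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  shape <- truth$shape
  b <- scheme$b_values
  nb <- length(b)
  sig <- array(0, dim = c(shape, nb))
  inmask <- which(truth$liver_mask)
  clean <- ivim_signal_matrix(truth$d_slow[inmask], truth$d_fast[inmask],
                              truth$f_p[inmask], b)  # V x B, S0 = 1
  nvox <- prod(shape)
  for (j in seq_len(nb)) {
    vol <- numeric(nvox)
    vol[inmask] <- clean[, j]
    if (noise_sd > 0) {
      acc <- numeric(nvox)
      for (a in seq_len(scheme$averages[j])) {
        if (noise_model == "gaussian") {
          acc <- acc + vol + stats::rnorm(nvox, 0, noise_sd)
        } else {
          acc <- acc + sqrt((vol + stats::rnorm(nvox, 0, noise_sd))^2 +
                              stats::rnorm(nvox, 0, noise_sd)^2)
        }
      }
      vol <- acc / scheme$averages[j]
    }
    sig[, , , j] <- pmax(vol, 0)
  }
  dwi_series(sig, scheme, mask = truth$liver_mask)
}

#' Smooth multiplicative B1 transmit-field inhomogeneity
#'
#' Low-order polynomial surface (linear + quadratic in-plane terms with
#' random coefficients) rescaled into `range`, constant along z. Models the
#' smooth flip-angle scaling that B1 inhomogeneity imposes at 3T.
#'
#' @param shape 3D grid dimensions.
#' @param range Field range, default `c(0.8, 1.2)`.
#' @param seed Integer seed.
#' @return 3D array of multiplicative flip-angle factors.
#' @export
make_b1_field <- function(shape, range = c(0.8, 1.2), seed = 1L) {
  set.seed(seed)
  nx <- shape[1]; ny <- shape[2]
  x <- seq(-1, 1, length.out = nx)
  y <- seq(-1, 1, length.out = ny)
  cf <- stats::rnorm(5, 0, 1)
  surf <- outer(x, y, function(u, v)
    cf[1] * u + cf[2] * v + cf[3] * u^2 + cf[4] * v^2 + cf[5] * u * v)
  rng <- max(surf) - min(surf)
  if (rng < 1e-12) {
    surf[] <- mean(range)
  } else {
    surf <- range[1] + (surf - min(surf)) / rng * (range[2] - range[1])
  }
  array(rep(surf, shape[3]), dim = shape)
}

#' Simulate a dual-flip-angle SPGR volume pair
#'
#' Spoiled gradient-echo steady-state signal at each flip angle, with the
#' effective angle scaled voxelwise by the B1 field and the T1 field chosen
#' by acquisition phase (pre or post contrast).
#'
#' @param truth A `phantom_truth`.
#' @param phase `"pre"` or `"post"` gadoxetate.
#' @param tr Repetition time, ms.
#' @param flip_angles Nominal flip angles in degrees, default `c(3, 15)`.
#' @param b1_field 3D multiplicative field (default homogeneous 1).
#' @param noise_sd Gaussian noise SD in signal units.
#' @param m0 Equilibrium magnetisation (signal units).
#' @param seed Integer seed.
#' @return An `spgr_acquisition` (see [spgr_acquisition()]).
#' @export
simulate_spgr_pair <- function(truth, phase = c("pre", "post"), tr = 5.08,
                               flip_angles = c(3, 15), b1_field = NULL,
                               noise_sd = 0, m0 = 1000, seed = 1L) {
  phase <- match.arg(phase)
  if (tr <= 0) stop("TR must be positive")
  if (length(flip_angles) < 1L) stop("need at least one flip angle")
  if (any(flip_angles <= 0 | flip_angles > 90))
    stop("flip angles must be in (0, 90] degrees")
  set.seed(seed)
  shape <- truth$shape
  if (is.null(b1_field)) b1_field <- array(1, dim = shape)
  if (any(b1_field <= 0)) stop("b1_field must be positive")
  t1 <- if (phase == "pre") truth$t1_pre else truth$t1_post
  inmask <- which(truth$liver_mask)
  signals <- lapply(flip_angles, function(a) {
    vol <- array(0, dim = shape)
    vol[inmask] <- spgr_signal(m0, t1[inmask], tr, a, b1_field[inmask])
    if (noise_sd > 0) vol <- vol + array(stats::rnorm(prod(shape), 0, noise_sd),
                                         dim = shape)
    vol
  })
  spgr_acquisition(signals, flip_angles, tr, b1_map = b1_field,
                   mask = truth$liver_mask)
}

#' Default low-temporal-resolution DCE sampling grid
#'
#' Breath-hold-spaced time points (s) covering 20 minutes after injection.
#' @return Numeric vector of times in seconds.
#' @export
default_dce_times <- function() {
  c(0, 30, 60, 90, 120, 180, 240, 300, 420, 600, 780, 900, 1050, 1200)
}

#' Gamma-variate arterial input function
#'
#' `(t - t0)^alpha * exp(-(t - t0)/beta)` for `t > t0`, zero before arrival,
#' normalised to unit peak.
#'
#' @param times Times in seconds.
#' @param t0 Arrival delay (s).
#' @param alpha Shape exponent.
#' @param beta Decay constant (s).
#' @return Input-function values at `times`.
#' @export
gamma_variate_aif <- function(times, t0 = 10, alpha = 2, beta = 30) {
  tt <- pmax(times - t0, 0)
  a <- tt^alpha * exp(-tt / beta)
  pk <- (alpha * beta)^alpha * exp(-alpha)
  a / pk
}

# two-compartment impulse retention function: a fast vascular washout and a
# slow hepatocyte retention pool weighted by the extraction fraction
retention_function <- function(hef, times, tau_fast, tau_slow) {
  (1 - hef) * exp(-times / tau_fast) + hef * exp(-times / tau_slow)
}

#' Simulate a low-temporal-resolution DCE series
#'
#' Per voxel, the tissue curve is the discrete convolution (trapezoid
#' quadrature on the possibly non-uniform grid, via
#' [build_convolution_matrix()]) of the input function with a
#' two-compartment impulse retention function
#' `R(t) = (1 - HEF) exp(-t/tau_fast) + HEF exp(-t/tau_slow)`.
#'
#' @param truth A `phantom_truth` (its `hef` field drives the kinetics).
#' @param times Strictly increasing times starting at 0 (s).
#' @param aif Input-function values at `times`; default gamma-variate.
#' @param tau_fast,tau_slow Washout time constants (s), `tau_fast < tau_slow`.
#' @param noise_sd Gaussian noise SD in signal units.
#' @param seed Integer seed.
#' @return A `dce_series` (see [dce_series()]).
#' @export
simulate_dce <- function(truth, times = default_dce_times(), aif = NULL,
                         tau_fast = 60, tau_slow = 2e4, noise_sd = 0,
                         seed = 1L) {
  if (any(times < 0) || times[1] != 0 || any(diff(times) <= 0))
    stop("times must be strictly increasing and start at 0")
  if (!(tau_fast > 0 && tau_fast < tau_slow))
    stop("need 0 < tau_fast < tau_slow")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  set.seed(seed)
  if (is.null(aif)) aif <- gamma_variate_aif(times)
  A <- build_convolution_matrix(aif, times)
  shape <- truth$shape
  nt <- length(times)
  inmask <- which(truth$liver_mask)
  R <- outer(1 - truth$hef[inmask], exp(-times / tau_fast)) +
       outer(truth$hef[inmask],     exp(-times / tau_slow))   # V x T
  curves <- R %*% t(A)
  sig <- array(0, dim = c(shape, nt))
  nvox <- prod(shape)
  for (j in seq_len(nt)) {
    vol <- numeric(nvox)
    vol[inmask] <- curves[, j]
    if (noise_sd > 0) vol <- vol + stats::rnorm(nvox, 0, noise_sd)
    sig[, , , j] <- vol
  }
  dce_series(sig, times, aif, mask = truth$liver_mask)
}

#' Generate a complete synthetic two-cohort study
#'
#' Builds `n_healthy + n_patient` subjects with reproducible per-subject
#' seeds. Subject-level parameter draws use randomized stratified quantiles
#' (Latin-hypercube style) per cohort so that small cohorts represent the
#' configured distributions. Healthy volunteers carry IVIM data only (no
#' contrast administration), mirroring a protocol where DCE and
#' post-contrast T1 are acquired in patients alone.
#'
#' @param config A [cohort_config()].
#' @param simulate Set `FALSE` to generate ground truth only (no signal
#'   simulation), e.g. for distribution checks over large cohorts.
#' @return An object of class `liver_study`: list of subjects, each with
#'   `truth`, `dwi`, masks and (patients only) `spgr_pre`, `spgr_post`,
#'   `dce`, plus the config.
#' @export
make_cohort <- function(config = cohort_config(), simulate = TRUE) {
  n_total <- config$n_healthy + config$n_patient
  if (n_total < 1L) stop("need at least one subject")
  subjects <- list()
  idx <- 0L
  for (cohort in c("healthy", "patient")) {
    n <- if (cohort == "healthy") config$n_healthy else config$n_patient
    if (n == 0L) next
    params <- names(config$group_params[[cohort]])
    set.seed(derive_seed(config$seed, if (cohort == "healthy") 1L else 2L))
    # randomized stratified quantiles: one draw per stratum, scrambled
    U <- vapply(params, function(p) {
      (sample.int(n) - stats::runif(n)) / n
    }, numeric(n))
    if (n == 1L) U <- matrix(U, nrow = 1, dimnames = list(NULL, params))
    for (i in seq_len(n)) {
      idx <- idx + 1L
      sseed <- derive_seed(config$seed, 10L + idx)
      truth <- make_phantom_truth(config, cohort, seed = sseed,
                                  quantiles = U[i, ])
      subj <- list(id = sprintf("S%02d", idx), cohort = cohort, seed = sseed,
                   truth = truth, mask = truth$liver_mask)
      if (simulate)
        subj$dwi <- simulate_dwi(truth, config$scheme, config$noise_sd,
                                 seed = derive_seed(sseed, 1L))
      if (simulate && cohort == "patient") {
        b1 <- make_b1_field(config$shape, seed = derive_seed(sseed, 2L))
        subj$spgr_pre <- simulate_spgr_pair(truth, "pre", b1_field = b1,
                                            noise_sd = config$noise_sd * 10,
                                            seed = derive_seed(sseed, 3L))
        subj$spgr_post <- simulate_spgr_pair(truth, "post", b1_field = b1,
                                             noise_sd = config$noise_sd * 10,
                                             seed = derive_seed(sseed, 4L))
        subj$dce <- simulate_dce(truth, noise_sd = config$noise_sd / 5,
                                 seed = derive_seed(sseed, 5L))
      }
      subjects[[subj$id]] <- subj
    }
  }
  structure(list(subjects = subjects, config = config, seed = config$seed),
            class = "liver_study")
}

#' @export
print.liver_study <- function(x, ...) {
  cohorts <- vapply(x$subjects, `[[`, "", "cohort")
  cat(sprintf("liver_study: %d subjects (%d healthy, %d patient), grid %s\n",
              length(x$subjects), sum(cohorts == "healthy"),
              sum(cohorts == "patient"),
              paste(x$config$shape, collapse = "x")))
  invisible(x)
}

#' Rescan perturbation of a phantom for repeatability studies
#'
#' Returns a copy of the truth whose parameter fields are multiplied by a
#' subject-level log-normal factor with the given coefficient of variation,
#' emulating day-to-day physiologic variation between scan sessions.
#'
#' @param truth A `phantom_truth`.
#' @param cv Relative SD of the perturbation (e.g. 0.05 for 5%).
#' @param seed Integer seed.
#' @return A perturbed `phantom_truth`.
#' @export
jitter_truth <- function(truth, cv = 0.05, seed = 1L) {
  if (cv < 0) stop("cv must be >= 0")
  set.seed(seed)
  out <- truth
  m <- truth$liver_mask
  for (p in c("d_slow", "d_fast", "f_p", "t1_pre", "t1_post", "hef")) {
    fac <- exp(stats::rnorm(1, 0, cv))
    if (p %in% c("f_p", "hef")) {
      out[[p]][m] <- stats::plogis(stats::qlogis(truth[[p]][m]) + log(fac))
    } else {
      out[[p]][m] <- truth[[p]][m] * fac
    }
  }
  fix <- which(out$d_fast[m] <= out$d_slow[m])
  if (length(fix)) out$d_fast[m][fix] <- 1.5 * out$d_slow[m][fix]
  out$t1_post[m] <- pmin(out$t1_post[m], out$t1_pre[m])
  out$seed <- seed
  out
}
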