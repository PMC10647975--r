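#' Diffusion-weighted series container
#'
#' Binds a 4D signal array (x, y, z, b) to its b-value scheme, voxel size
#' and an optional liver mask. Signals are non-negative magnitude data in
#' arbitrary units; the b = 0 volume plays the role of S0.
#'
#' @param signal 4D numeric array.
#' @param scheme A [bvalue_scheme()]; its length must equal `dim(signal)[4]`.
#' @param voxel_size Voxel dimensions in mm.
#' @param mask Optional binary 3D array.
#' @return An object of class `dwi_series`.
#' @export
dwi_series <- function(signal, scheme, voxel_size = c(1.176, 1.176, 5),
                       mask = NULL) {
  if (length(dim(signal)) != 4L) stop("signal must be a 4D array")
  if (dim(signal)[4] != length(scheme$b_values))
    stop(sprintf("b-axis length (%d) does not match scheme length (%d)",
                 dim(signal)[4], length(scheme$b_values)))
  if (any(signal < 0, na.rm = TRUE)) stop("signal must be non-negative")
  if (!is.null(mask) && !all(dim(mask) == dim(signal)[1:3]))
    stop("mask grid does not match signal grid")
  structure(list(signal = signal, scheme = scheme,
                 voxel_size = voxel_size, mask = mask),
            class = "dwi_series")
}

#' @export
print.dwi_series <- function(x, ...) {
  cat(sprintf("dwi_series: %s voxels x %d b-values\n",
              paste(dim(x$signal)[1:3], collapse = "x"),
              dim(x$signal)[4]))
  invisible(x)
}

#' Biexponential IVIM signal model
#'
#' Normalised signal fraction at diffusion weighting b:
#' `S/S0 = f_p exp(-b d_fast) + (1 - f_p) exp(-b d_slow)`,
#' the sum of a perfusion (pseudo-diffusion) compartment and a tissue
#' water-diffusion compartment.
#'
#' @param params List or named vector with `d_slow`, `d_fast` (mm^2/s) and
#'   `f_p` (fraction); must satisfy `d_fast > d_slow > 0`, `0 <= f_p <= 1`.
#' @param b b-values in s/mm^2 (vectorised).
#' @return Signal fractions in (0, 1].
#' @export
ivim_signal <- function(params, b) {
  p <- as.list(params)
  if (!(p$d_slow > 0 && p$d_fast > p$d_slow && p$f_p >= 0 && p$f_p <= 1))
    stop("invalid IVIM parameters: need d_fast > d_slow > 0 and f_p in [0,1]")
  if (any(b < 0)) stop("b must be >= 0")
  p$f_p * exp(-b * p$d_fast) + (1 - p$f_p) * exp(-b * p$d_slow)
}

# vectorised forward model over voxels: V x B matrix of signal fractions
ivim_signal_matrix <- function(d_slow, d_fast, f_p, b) {
  f_p * exp(-outer(d_fast, b)) + (1 - f_p) * exp(-outer(d_slow, b))
}

#' Parameter map container for IVIM fits
#'
#' 3D fields of the fitted parameters in SI units (mm^2/s, fraction), NaN
#' outside the mask or where the fit failed.
#'
#' @param d_slow,d_fast,f_p,s0 3D numeric arrays.
#' @param mask Binary 3D array.
#' @param n_failed Count of in-mask voxels where fitting failed.
#' @param method Fit method label.
#' @return An object of class `ivim_maps`.
#' @export
ivim_maps <- function(d_slow, d_fast, f_p, s0, mask, n_failed = 0L,
                      method = "lsq") {
  structure(list(d_slow = d_slow, d_fast = d_fast, f_p = f_p, s0 = s0,
                 mask = mask, n_failed = n_failed, method = method,
                 units = "mm2/s (SI); report with si_to_report()"),
            class = "ivim_maps")
}

#' @export
print.ivim_maps <- function(x, ...) {
  cat(sprintf("ivim_maps (%s fit): grid %s, %d mask voxels, %d failed\n",
              x$method, paste(dim(x$d_slow), collapse = "x"),
              sum(x$mask), x$n_failed))
  invisible(x)
}

# --- 3x3 slicewise median filter ------------------------------------------

# median of 9 via a minimax selection network, vectorised with pmin/pmax
median_of_9 <- function(v) {
  s2 <- function(i, j) {
    lo <- pmin(v[[i]], v[[j]]); hi <- pmax(v[[i]], v[[j]])
    v[[i]] <<- lo; v[[j]] <<- hi
  }
  s2(2, 3); s2(5, 6); s2(8, 9); s2(1, 2); s2(4, 5); s2(7, 8)
  s2(2, 3); s2(5, 6); s2(8, 9); s2(1, 4); s2(6, 9); s2(5, 8)
  s2(4, 7); s2(2, 5); s2(3, 6); s2(5, 8); s2(5, 3); s2(7, 5)
  s2(5, 3)
  v[[5]]
}

median3x3 <- function(m) {
  n <- nrow(m); p <- ncol(m)
  if (n < 2L || p < 2L) return(m)
  # reflection padding (edge value duplicated)
  pm <- m[c(1, 1:n, n), c(1, 1:p, p)]
  v <- vector("list", 9)
  k <- 0
  for (dj in 0:2) for (di in 0:2) {
    k <- k + 1
    v[[k]] <- as.vector(pm[(1 + di):(n + di), (1 + dj):(p + dj)])
  }
  matrix(median_of_9(v), n, p)
}

#' Slicewise 3 x 3 median filter
#'
#' Replaces each axial 2D slice of every volume with its 3 x 3 sliding-
#' window median, the standard noise-reduction step applied to the
#' diffusion series before fitting. Edges are handled by reflection
#' (edge-value duplication); output shape is unchanged.
#'
#' @param x A `dwi_series`, 3D array or 2D matrix.
#' @return Same type as the input, filtered.
#' @export
median_filter_slicewise <- function(x) {
  if (inherits(x, "dwi_series")) {
    s <- x$signal
    for (j in seq_len(dim(s)[4]))
      for (z in seq_len(dim(s)[3]))
        s[, , z, j] <- median3x3(s[, , z, j])
    x$signal <- s
    return(x)
  }
  if (is.matrix(x)) return(median3x3(x))
  if (length(dim(x)) == 3L) {
    for (z in seq_len(dim(x)[3])) x[, , z] <- median3x3(x[, , z])
    return(x)
  }
  if (length(dim(x)) == 4L) {
    for (j in seq_len(dim(x)[4]))
      for (z in seq_len(dim(x)[3]))
        x[, , z, j] <- median3x3(x[, , z, j])
    return(x)
  }
  stop("unsupported input type")
}

# --- in-plane resampling ---------------------------------------------------

# area-overlap (mean-preserving) 1D resampling operator, rows sum to 1
area_weights <- function(n_src, n_tgt) {
  W <- matrix(0, n_tgt, n_src)
  r <- n_src / n_tgt
  for (i in seq_len(n_tgt)) {
    a <- (i - 1) * r; b <- i * r
    j0 <- floor(a) + 1; j1 <- ceiling(b)
    for (j in j0:min(j1, n_src)) {
      W[i, j] <- max(0, min(b, j) - max(a, j - 1))
    }
  }
  W / rowSums(W)
}

# linear-interpolation 1D operator at target pixel centres, edge clamped
linear_weights <- function(n_src, n_tgt) {
  W <- matrix(0, n_tgt, n_src)
  r <- n_src / n_tgt
  for (i in seq_len(n_tgt)) {
    p <- (i - 0.5) * r       # target centre in source length coordinates
    j <- floor(p + 0.5)      # source pixel whose centre (j - 0.5) is left of p
    frac <- p - (j - 0.5)
    if (j < 1) {
      W[i, 1] <- 1
    } else if (j >= n_src) {
      W[i, n_src] <- 1
    } else {
      W[i, j] <- 1 - frac
      W[i, j + 1] <- frac
    }
  }
  W
}

resample_slice <- function(M, Wx, Wy) {
  fin <- is.finite(M)
  M0 <- ifelse(fin, M, 0)
  num <- Wx %*% M0 %*% t(Wy)
  den <- Wx %*% (fin + 0) %*% t(Wy)
  out <- num / den
  out[den <= 1e-12] <- NA_real_
  out
}

#' In-plane resampling of volumes and maps
#'
#' Resamples the first two (in-plane) axes only; slice and b/t axes are
#' untouched. `down_for_fit` uses mean-preserving area-overlap averaging,
#' appropriate for reducing the signal grid before voxelwise fitting;
#' `up_for_maps` uses bilinear interpolation, appropriate for returning
#' parameter maps to the native matrix. Constant fields are preserved
#' exactly and non-finite voxels are excluded from the local averages.
#'
#' @param field 2D, 3D or 4D numeric array.
#' @param target_inplane Target `c(nx, ny)`, each >= 2.
#' @param kind `"down_for_fit"` or `"up_for_maps"`.
#' @return Resampled array with the same number of axes.
#' @export
resample_inplane <- function(field, target_inplane,
                             kind = c("down_for_fit", "up_for_maps")) {
  kind <- match.arg(kind)
  if (any(target_inplane < 2)) stop("target dimensions must be >= 2")
  d <- dim(field)
  if (is.null(d)) stop("field must be an array")
  nx <- d[1]; ny <- d[2]
  tx <- target_inplane[1]; ty <- target_inplane[2]
  if (tx == nx && ty == ny) return(field)
  mk <- if (kind == "down_for_fit") area_weights else linear_weights
  Wx <- mk(nx, tx); Wy <- mk(ny, ty)
  if (length(d) == 2L) return(resample_slice(field, Wx, Wy))
  if (length(d) == 3L) {
    out <- array(NA_real_, dim = c(tx, ty, d[3]))
    for (z in seq_len(d[3])) out[, , z] <- resample_slice(field[, , z], Wx, Wy)
    return(out)
  }
  if (length(d) == 4L) {
    out <- array(NA_real_, dim = c(tx, ty, d[3], d[4]))
    for (j in seq_len(d[4]))
      for (z in seq_len(d[3]))
        out[, , z, j] <- resample_slice(field[, , z, j], Wx, Wy)
    return(out)
  }
  stop("field must be 2D, 3D or 4D")
}

# --- segmented least-squares fit ------------------------------------------

#' Segmented least-squares IVIM fit
#'
#' The classic two-step estimator used as the baseline against the Bayesian
#' fit: a log-linear fit over the high-b regime (`b >= b_threshold`, where
#' the perfusion compartment has decayed) yields `d_slow` and the
#' extrapolated tissue intercept; the perfusion fraction follows from the
#' gap between that intercept and the measured b0 signal; `d_fast` is then
#' obtained by a one-parameter nonlinear fit of the low-b residual fast
#' component. Estimates are clipped to [ivim_bounds()]; voxels that cannot
#' be fit (non-positive signals) are NaN and counted.
#'
#' @param series A `dwi_series`.
#' @param mask Optional binary 3D array (defaults to the series mask).
#' @param b_threshold Segmentation threshold in s/mm^2, default 200.
#' @return An `ivim_maps` object (`method = "lsq"`).
#' @export
fit_ivim_lsq <- function(series, mask = NULL, b_threshold = 200) {
  mask <- mask %||% series$mask
  if (is.null(mask)) stop("a mask is required")
  if (!any(mask)) stop("mask is empty")
  b <- series$scheme$b_values
  if (length(unique(b)) < 4L) stop("need at least 4 distinct b-values")
  hi <- which(b >= b_threshold)
  lo <- which(b < b_threshold & b > 0)
  if (length(hi) < 2L) stop("need >= 2 b-values at or above b_threshold")
  bounds <- ivim_bounds()
  shape <- dim(series$signal)[1:3]
  inmask <- which(mask)
  V <- length(inmask)
  S <- matrix(series$signal, prod(shape), length(b))[inmask, , drop = FALSE]
  s0_meas <- S[, which(b == 0)[1]]

  ok <- s0_meas > 0 & apply(S[, hi, drop = FALSE] > 0, 1, all)
  ds <- fp <- df <- s0 <- rep(NA_real_, V)
  if (any(ok)) {
    Y <- log(S[ok, hi, drop = FALSE])
    bh <- b[hi]
    bc <- bh - mean(bh)
    slope <- as.vector(Y %*% bc) / sum(bc^2)
    intercept <- rowMeans(Y) - slope * mean(bh)
    ds_ok <- clip(-slope, bounds$d_slow[1], bounds$d_slow[2])
    s0_slow <- exp(intercept)
    fp_ok <- clip(1 - s0_slow / s0_meas[ok], bounds$f_p[1], bounds$f_p[2])
    ds[ok] <- ds_ok
    fp[ok] <- fp_ok
    s0[ok] <- s0_meas[ok]
    # one-parameter fast-component fit on the low-b residuals
    idx_ok <- which(ok)
    bl <- b[lo]
    for (k in seq_along(idx_ok)) {
      i <- idx_ok[k]
      amp <- s0_meas[i] * fp[i]
      if (amp < 1e-9 * max(s0_meas[i], 1e-12)) next  # no fast component
      resid <- S[i, lo] - s0_slow[k] * exp(-bl * ds[i])
      obj <- function(ldf) sum((resid - amp * exp(-bl * exp(ldf)))^2)
      opt <- stats::optimize(obj, log(bounds$d_fast), tol = 1e-10)
      df[i] <- exp(opt$minimum)
    }
    # keep the joint ordering invariant where a fast estimate exists
    bad <- !is.na(df) & df <= ds
    df[bad] <- pmin(1.5 * ds[bad], bounds$d_fast[2])
  }
  n_failed <- sum(!ok)
  mk <- function(v) { a <- array(NA_real_, shape); a[inmask] <- v; a }
  ivim_maps(mk(ds), mk(df), mk(fp), mk(s0), mask, n_failed, method = "lsq")
}

# --- Bayesian voxelwise fit ------------------------------------------------

#' MCMC configuration for the Bayesian IVIM fit
#'
#' The sampler is an independent per-voxel Metropolis-within-Gibbs on
#' transformed parameters `(log d_slow, log d_fast - log d_slow, logit
#' f_p/0.6, log s0)` with flat priors inside finite bounds, and a conjugate
#' inverse-gamma step for the Gaussian noise variance. Proposal scales are
#' adapted during burn-in towards 35% acceptance.
#'
#' @param n_iterations Total iterations per voxel.
#' @param n_burn_in Burn-in iterations (< `n_iterations`).
#' @param adapt_window Iterations between proposal-scale adaptations.
#' @param estimator Point-map estimator: `"median"` (robust default for
#'   skewed posteriors) or `"mean"`.
#' @param seed Integer seed; fixed seed gives bitwise-identical maps.
#' @param prior_a,prior_b Inverse-gamma shape/rate hyperparameters for the
#'   noise variance (near-Jeffreys defaults).
#' @param max_stored Cap on stored post-burn-in samples per voxel (thinning
#'   is derived from it).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(n_iterations = 10000L, n_burn_in = 5000L,
                        adapt_window = 50L,
                        estimator = c("median", "mean"), seed = 1L,
                        prior_a = 1e-3, prior_b = 1e-8,
                        max_stored = 2000L) {
  estimator <- match.arg(estimator)
  if (n_burn_in >= n_iterations) stop("burn-in must be < iterations")
  if (n_burn_in < adapt_window) stop("burn-in must cover >= 1 adapt window")
  structure(list(n_iterations = as.integer(n_iterations),
                 n_burn_in = as.integer(n_burn_in),
                 adapt_window = as.integer(adapt_window),
                 estimator = estimator, seed = as.integer(seed),
                 prior_a = prior_a, prior_b = prior_b,
                 max_stored = as.integer(max_stored)),
            class = "mcmc_config")
}

#' Bayesian voxelwise IVIM fit
#'
#' Fits the biexponential model to each voxel independently under a
#' Gaussian likelihood with unknown noise variance, by Metropolis-within-
#' Gibbs sampling on transformed parameters (see [mcmc_config()]). The
#' ordering `d_fast > d_slow` is enforced by the log-gap parameterisation.
#' Point maps are the per-voxel posterior median (or mean); a posterior
#' summary with central 95% intervals, the noise-variance estimate and
#' sampler diagnostics is returned alongside. Voxels whose post-burn-in
#' acceptance rate falls outside [0.1, 0.6] are flagged as non-converged
#' (their estimates are retained, not silently replaced).
#'
#' @param series A `dwi_series`.
#' @param mask Optional binary 3D array (defaults to the series mask).
#' @param config An [mcmc_config()].
#' @return List with elements `maps` (an `ivim_maps`, `method = "bayes"`)
#'   and `posterior` (class `posterior_summary`).
#' @export
fit_ivim_bayes <- function(series, mask = NULL, config = mcmc_config()) {
  mask <- mask %||% series$mask
  if (is.null(mask)) stop("a mask is required")
  if (!any(mask)) stop("mask is empty")
  b <- series$scheme$b_values
  nb <- length(b)
  if (nb < 6L) warning("fewer than 6 b-values: posterior may be weakly identified")
  bounds <- ivim_bounds()
  set.seed(config$seed)

  shape <- dim(series$signal)[1:3]
  inmask <- which(mask)
  V <- length(inmask)
  S <- matrix(series$signal, prod(shape), nb)[inmask, , drop = FALSE]

  # initialise at the segmented least-squares estimate
  init <- fit_ivim_lsq(series, mask)
  g <- function(fld, fallback) {
    v <- fld[inmask]
    v[!is.finite(v)] <- fallback
    v
  }
  ds0 <- clip(g(init$d_slow, 1e-3), bounds$d_slow[1] * 1.01, bounds$d_slow[2] * 0.99)
  df0 <- clip(g(init$d_fast, 30e-3), bounds$d_fast[1] * 1.01, bounds$d_fast[2] * 0.99)
  fp0 <- clip(g(init$f_p, 0.2), 1e-3, 0.6 * 0.999)
  s0ref <- max(S[, which(b == 0)[1]], 1e-9)
  s00 <- clip(g(init$s0, s0ref), s0ref * 1e-4, s0ref * 10)
  df0 <- pmax(df0, ds0 * 1.2)

  # transformed state: u1 = log ds, u2 = log(df/ds), u3 = logit(fp/0.6),
  # u4 = log s0; flat priors within these bounds
  U <- cbind(log(ds0), log(df0 / ds0), stats::qlogis(fp0 / 0.6), log(s00))
  ub <- rbind(log(bounds$d_slow),
              c(log(1.05), log(bounds$d_fast[2] / bounds$d_slow[1])),
              c(-7, 7),
              log(s0ref) + c(-10, 3))

  back <- function(U) {
    ds <- exp(U[, 1]); df <- ds * exp(U[, 2])
    list(ds = ds, df = df, fp = 0.6 * stats::plogis(U[, 3]), s0 = exp(U[, 4]))
  }
  ssr_of <- function(U) {
    p <- back(U)
    M <- p$s0 * ivim_signal_matrix(p$ds, p$df, p$fp, b)
    rowSums((S - M)^2)
  }

  ssr <- ssr_of(U)
  sigma2 <- pmax(ssr / nb, 1e-12)
  prop_sd <- matrix(0.1, V, 4)
  acc_win <- matrix(0, V, 4)
  acc_post <- matrix(0, V, 4)

  n_keep <- config$n_iterations - config$n_burn_in
  thin <- max(1L, ceiling(n_keep / config$max_stored))
  kept <- seq(config$n_burn_in + thin, config$n_iterations, by = thin)
  K <- length(kept)
  store <- array(NA_real_, dim = c(V, 4, K))  # ds, df, fp, s0 natural scale
  sig_store <- matrix(NA_real_, V, K)
  ki <- 0L

  for (it in seq_len(config$n_iterations)) {
    for (k in 1:4) {
      Up <- U
      Up[, k] <- U[, k] + prop_sd[, k] * stats::rnorm(V)
      inb <- Up[, k] >= ub[k, 1] & Up[, k] <= ub[k, 2]
      if (k <= 2) {  # joint d_fast bound
        dfp <- exp(Up[, 1] + Up[, 2])
        inb <- inb & dfp >= bounds$d_fast[1] & dfp <= bounds$d_fast[2]
      }
      ssr_p <- ssr_of(Up)
      logacc <- (ssr - ssr_p) / (2 * sigma2)
      logacc[!inb] <- -Inf
      take <- log(stats::runif(V)) < logacc
      if (any(take)) {
        U[take, k] <- Up[take, k]
        ssr[take] <- ssr_p[take]
      }
      acc_win[, k] <- acc_win[, k] + take
      if (it > config$n_burn_in) acc_post[, k] <- acc_post[, k] + take
    }
    sigma2 <- pmax(1 / stats::rgamma(V, shape = config$prior_a + nb / 2,
                                     rate = config$prior_b + ssr / 2), 1e-14)
    if (it <= config$n_burn_in && it %% config$adapt_window == 0L) {
      rate <- acc_win / config$adapt_window
      prop_sd <- clip(prop_sd * exp(rate - 0.35), 1e-6, 5)
      acc_win[] <- 0
    }
    if (it > config$n_burn_in && (it - config$n_burn_in) %% thin == 0L) {
      ki <- ki + 1L
      p <- back(U)
      store[, 1, ki] <- p$ds; store[, 2, ki] <- p$df
      store[, 3, ki] <- p$fp; store[, 4, ki] <- p$s0
      sig_store[, ki] <- sigma2
    }
  }

  qfun <- function(j, probs) t(apply(store[, j, , drop = FALSE], 1,
                                     stats::quantile, probs = probs,
                                     names = FALSE))
  param_names <- c("d_slow", "d_fast", "f_p", "s0")
  summ <- list()
  point <- list()
  for (j in 1:4) {
    qs <- qfun(j, c(0.025, 0.5, 0.975))
    mn <- apply(store[, j, , drop = FALSE], 1, mean)
    summ[[param_names[j]]] <- data.frame(mean = mn, median = qs[, 2],
                                         lower = qs[, 1], upper = qs[, 3])
    point[[param_names[j]]] <-
      if (config$estimator == "median") qs[, 2] else mn
  }
  rate_post <- acc_post / (config$n_iterations - config$n_burn_in)
  # pinned: posterior median within 1% (relative) of a support bound
  near <- function(x, b) abs(x / b - 1) < 0.01
  pinned <- near(point$d_slow, bounds$d_slow[1]) |
    near(point$d_slow, bounds$d_slow[2]) |
    near(point$d_fast, bounds$d_fast[1]) |
    near(point$d_fast, bounds$d_fast[2]) |
    near(point$f_p, bounds$f_p[2])
  flagged <- apply(rate_post < 0.1 | rate_post > 0.6, 1, any) | pinned

  mk <- function(v) { a <- array(NA_real_, shape); a[inmask] <- v; a }
  maps <- ivim_maps(mk(point$d_slow), mk(point$d_fast), mk(point$f_p),
                    mk(point$s0), mask, n_failed = 0L, method = "bayes")
  posterior <- structure(list(summary = summ,
                              sigma2 = rowMeans(sig_store),
                              acceptance_rate = rate_post,
                              pinned = pinned,
                              flagged = flagged,
                              n_flagged = sum(flagged),
                              chain_length = config$n_iterations,
                              n_stored = K, thin = thin,
                              voxel_index = inmask),
                         class = "posterior_summary")
  list(maps = maps, posterior = posterior)
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("posterior_summary: %d voxels, chain %d (stored %d, thin %d), %d flagged\n",
              nrow(x$summary$d_slow), x$chain_length, x$n_stored, x$thin,
              x$n_flagged))
  invisible(x)
}

#' Global liver summary of an IVIM parameter map set
#'
#' Mean, median, SD (sample, n-1), min and max over in-mask voxels for each
#' parameter, in reporting units (1e-3 mm^2/s for diffusivities, percent
#' for the perfusion fraction). NaN voxels inside the mask are excluded and
#' counted.
#'
#' @param maps An `ivim_maps`.
#' @return A data.frame with one row per parameter.
#' @export
global_liver_summary <- function(maps) {
  if (!any(maps$mask)) stop("mask is empty")
  rows <- lapply(c("d_slow", "d_fast", "f_p"), function(p) {
    v <- maps[[p]][maps$mask]
    n_nan <- sum(!is.finite(v))
    v <- v[is.finite(v)]
    v <- si_to_report(v, if (p == "f_p") "fraction" else "diffusivity")
    data.frame(parameter = p,
               mean = mean(v), median = stats::median(v),
               sd = stats::sd(v), min = min(v), max = max(v),
               n = length(v), n_nan = n_nan,
               units = if (p == "f_p") "%" else "1e-3 mm2/s")
  })
  do.call(rbind, rows)
}
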