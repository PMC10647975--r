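# small in-code fixtures shared across test files

tiny_config <- function(seed = 1L, ...) {
  cohort_config(shape = c(16L, 16L, 3L), seed = seed, ...)
}

# dwi_series holding given per-voxel parameters in a minimal grid,
# optionally with per-excitation gaussian noise
series_from_params <- function(d_slow, d_fast, f_p, scheme = bvalue_scheme(),
                               noise_sd = 0, seed = 1L, s0 = 1) {
  nv <- length(d_slow)
  nx <- ceiling(sqrt(nv))
  shape <- c(nx, ceiling(nv / nx), 1L)
  mask <- array(FALSE, shape)
  mask[seq_len(nv)] <- TRUE
  b <- scheme$b_values
  S <- s0 * (f_p * exp(-outer(d_fast, b)) +
               (1 - f_p) * exp(-outer(d_slow, b)))
  set.seed(seed)
  sig <- array(0, c(shape, length(b)))
  for (j in seq_along(b)) {
    v <- numeric(prod(shape))
    if (noise_sd > 0) {
      acc <- 0
      for (a in seq_len(scheme$averages[j]))
        acc <- acc + S[, j] + stats::rnorm(nv, 0, noise_sd)
      v[seq_len(nv)] <- pmax(acc / scheme$averages[j], 0)
    } else {
      v[seq_len(nv)] <- S[, j]
    }
    sig[, , , j] <- v
  }
  dwi_series(sig, scheme, mask = mask)
}

# dce_series with every in-mask voxel sharing one retention function
dce_from_hef <- function(hef_values, times = default_dce_times(),
                         tau_fast = 60, tau_slow = 2e4, noise_sd = 0,
                         seed = 1L) {
  nv <- length(hef_values)
  nx <- ceiling(sqrt(nv))
  shape <- c(nx, ceiling(nv / nx), 1L)
  mask <- array(FALSE, shape)
  mask[seq_len(nv)] <- TRUE
  aif <- gamma_variate_aif(times)
  A <- build_convolution_matrix(aif, times)
  R <- outer(1 - hef_values, exp(-times / tau_fast)) +
    outer(hef_values, exp(-times / tau_slow))
  curves <- R %*% t(A)
  set.seed(seed)
  sig <- array(0, c(shape, length(times)))
  for (j in seq_along(times)) {
    v <- numeric(prod(shape))
    v[seq_len(nv)] <- curves[, j]
    if (noise_sd > 0) v[seq_len(nv)] <- v[seq_len(nv)] +
        stats::rnorm(nv, 0, noise_sd)
    sig[, , , j] <- v
  }
  dce_series(sig, times, aif, mask = mask)
}

# two-sided exact Mann-Whitney p by full enumeration over all group splits
enumerate_mw_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  pool <- c(a, b)
  u_obs <- sum(outer(a, b, `>`))
  splits <- combn(n, n1)
  us <- apply(splits, 2, function(idx)
    sum(outer(pool[idx], pool[-idx], `>`)))
  mu <- n1 * (n - n1) / 2
  p <- if (u_obs <= mu) 2 * mean(us <= u_obs) else 2 * mean(us >= u_obs)
  min(p, 1)
}

# max relative error of a fitted map against per-voxel truth
max_rel_err <- function(map, truth, mask) {
  max(abs(map[which(mask)] / truth - 1), na.rm = TRUE)
}
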