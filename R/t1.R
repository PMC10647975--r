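#' Dual-flip-angle SPGR acquisition container
#'
#' One 3D signal volume per flip angle, with repetition time and a
#' multiplicative B1 flip-angle-scaling map (nominal 1.0). Any scanner-
#' specific B1 encoding must be converted to this dimensionless factor
#' upstream.
#'
#' @param signals List of 3D arrays, one per flip angle.
#' @param flip_angles Nominal flip angles in degrees (>= 2 distinct).
#' @param tr Repetition time in ms (> 0).
#' @param b1_map Optional 3D positive array; defaults to homogeneous 1.
#' @param mask Optional binary 3D array.
#' @return An object of class `spgr_acquisition`.
#' @export
spgr_acquisition <- function(signals, flip_angles, tr, b1_map = NULL,
                             mask = NULL) {
  if (length(signals) != length(flip_angles))
    stop("one signal volume per flip angle is required")
  if (length(unique(flip_angles)) < 2L)
    stop("need at least 2 distinct flip angles")
  if (tr <= 0) stop("TR must be positive")
  shape <- dim(signals[[1]])
  if (is.null(b1_map)) b1_map <- array(1, dim = shape)
  if (any(b1_map <= 0)) stop("b1_map must be positive")
  structure(list(signals = signals, flip_angles = flip_angles, tr = tr,
                 b1_map = b1_map, mask = mask),
            class = "spgr_acquisition")
}

#' Spoiled gradient-echo steady-state signal
#'
#' `S = m0 sin(a) (1 - E1) / (1 - cos(a) E1)` with `E1 = exp(-tr/t1)` and
#' effective angle `a = alpha * b1`. This is the forward model underlying
#' variable-flip-angle T1 mapping.
#'
#' @param m0 Equilibrium magnetisation (signal units).
#' @param t1 Longitudinal relaxation time, ms (> 0).
#' @param tr Repetition time, ms (> 0).
#' @param alpha Nominal flip angle in degrees.
#' @param b1 Multiplicative flip-angle factor (default 1).
#' @return Signal in the units of `m0` (vectorised over any argument).
#' @export
spgr_signal <- function(m0, t1, tr, alpha, b1 = 1) {
  if (any(t1 <= 0) || any(tr <= 0)) stop("t1 and tr must be positive")
  a <- alpha * b1 * pi / 180
  if (any(a <= 0) || any(a >= pi)) stop("effective angle out of (0, 180) deg")
  e1 <- exp(-tr / t1)
  m0 * sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

#' T1 map container
#'
#' @param t1 3D array of T1 values, ms; NaN where undefined.
#' @param m0 3D array of fitted equilibrium magnetisation.
#' @param fit_quality 3D array of residual norms.
#' @param mask Binary 3D array.
#' @param n_failed Voxels where the fit failed (degenerate signals).
#' @param n_bounded Voxels whose solution ended on a fit bound.
#' @return An object of class `t1_map`.
#' @export
t1_map <- function(t1, m0, fit_quality, mask, n_failed = 0L, n_bounded = 0L) {
  structure(list(t1 = t1, m0 = m0, fit_quality = fit_quality, mask = mask,
                 n_failed = n_failed, n_bounded = n_bounded),
            class = "t1_map")
}

#' @export
print.t1_map <- function(x, ...) {
  v <- x$t1[x$mask]
  cat(sprintf("t1_map: %d mask voxels, median T1 %.0f ms, %d failed, %d bounded\n",
              sum(x$mask), stats::median(v, na.rm = TRUE), x$n_failed,
              x$n_bounded))
  invisible(x)
}

# fit bounds, ms
T1_FLOOR <- 50
T1_CEIL <- 5000

#' Dual-flip-angle T1 fit with B1 correction
#'
#' Estimates T1 and m0 per voxel by nonlinear least squares on the SPGR
#' signal model at B1-corrected effective angles, initialised from the
#' DESPOT1 linearisation (`S/sin(a)` vs `S/tan(a)` line, whose slope is
#' `exp(-tr/t1)`). The nonlinear refinement is a damped Gauss-Newton run
#' vectorised across voxels on `(log t1, log m0)`. Voxels with a
#' non-physical linear slope (outside (0,1)), equal signals at all angles
#' or non-positive signals are NaN and counted as failed; solutions pinned
#' at the T1 bounds [50, 5000] ms are counted as bounded.
#'
#' @param acq An [spgr_acquisition()].
#' @param mask Optional binary 3D array (defaults to the acquisition mask).
#' @return A [t1_map()].
#' @export
fit_t1_dfa <- function(acq, mask = NULL) {
  mask <- mask %||% acq$mask
  if (is.null(mask)) stop("a mask is required")
  if (!any(mask)) stop("mask is empty")
  shape <- dim(acq$signals[[1]])
  inmask <- which(mask)
  V <- length(inmask)
  nA <- length(acq$flip_angles)
  S <- vapply(acq$signals, function(s) s[inmask], numeric(V))  # V x nA
  b1 <- acq$b1_map[inmask]
  A <- outer(b1, acq$flip_angles * pi / 180)                   # effective rad

  # DESPOT1 line through the first and last angle
  y <- S / sin(A)
  x <- S / tan(A)
  slope <- (y[, nA] - y[, 1]) / (x[, nA] - x[, 1])
  ok <- is.finite(slope) & slope > 0 & slope < 1 &
    apply(S > 0, 1, all) & abs(x[, nA] - x[, 1]) > 1e-12
  t1 <- m0 <- fq <- rep(NA_real_, V)
  n_bounded <- 0L
  if (any(ok)) {
    t1_0 <- clip(-acq$tr / log(slope[ok]), T1_FLOOR, T1_CEIL)
    icpt <- y[ok, 1] - slope[ok] * x[ok, 1]
    m0_0 <- pmax(icpt / (1 - slope[ok]), 1e-9)
    th <- cbind(log(t1_0), log(m0_0))
    Sok <- S[ok, , drop = FALSE]
    Aok <- A[ok, , drop = FALSE]
    tr <- acq$tr
    model_ssr <- function(th) {
      e1 <- exp(-tr / exp(th[, 1]))
      M <- exp(th[, 2]) * sin(Aok) * (1 - e1) / (1 - cos(Aok) * e1)
      list(M = M, ssr = rowSums((Sok - M)^2))
    }
    cur <- model_ssr(th)
    lambda <- rep(1e-3, nrow(th))
    for (iter in 1:25) {
      t1v <- exp(th[, 1]); m0v <- exp(th[, 2])
      e1 <- exp(-tr / t1v)
      den <- 1 - cos(Aok) * e1
      M <- m0v * sin(Aok) * (1 - e1) / den
      # dM/dE1 and chain to log t1; dM/dlog m0 = M
      dM_dE <- m0v * sin(Aok) * (cos(Aok) - 1) / den^2
      dE_dlt1 <- e1 * (-tr / t1v) * (-1)   # d e1 / d log t1 = e1 * tr/t1
      J1 <- dM_dE * dE_dlt1
      r <- Sok - M
      g1 <- rowSums(J1 * r); g2 <- rowSums(M * r)
      h11 <- rowSums(J1^2); h22 <- rowSums(M^2); h12 <- rowSums(J1 * M)
      det <- (h11 * (1 + lambda)) * (h22 * (1 + lambda)) - h12^2
      det[abs(det) < 1e-30] <- 1e-30
      d1 <- (g1 * h22 * (1 + lambda) - g2 * h12) / det
      d2 <- (g2 * h11 * (1 + lambda) - g1 * h12) / det
      th_new <- th + cbind(d1, d2)
      th_new[, 1] <- clip(th_new[, 1], log(T1_FLOOR), log(T1_CEIL))
      new <- model_ssr(th_new)
      better <- new$ssr <= cur$ssr
      th[better, ] <- th_new[better, ]
      cur$ssr[better] <- new$ssr[better]
      lambda <- ifelse(better, lambda * 0.5, lambda * 4)
      step_max <- if (any(better))
        max(abs(cbind(d1, d2)[better, , drop = FALSE])) else 0
      if (step_max < 1e-10 && iter > 3) break
    }
    t1v <- exp(th[, 1])
    bounded <- t1v <= T1_FLOOR * 1.0001 | t1v >= T1_CEIL * 0.9999
    n_bounded <- sum(bounded)
    t1[ok] <- t1v
    m0[ok] <- exp(th[, 2])
    fq[ok] <- sqrt(cur$ssr)
  }
  mk <- function(v) { a <- array(NA_real_, shape); a[inmask] <- v; a }
  t1_map(mk(t1), mk(m0), mk(fq), mask, n_failed = sum(!ok),
         n_bounded = n_bounded)
}

#' Percent T1 reduction after contrast
#'
#' `100 * (T1_pre - T1_post) / T1_pre`, the voxelwise percent shortening of
#' T1 induced by hepatocyte gadoxetate uptake; higher values indicate
#' better-functioning tissue. NaN propagates.
#'
#' @param t1_pre,t1_post [t1_map()] objects or 3D arrays on the same grid.
#' @return 3D array of percent T1 reduction (class attribute
#'   `delta_t1_map` when inputs are maps).
#' @export
delta_t1_percent <- function(t1_pre, t1_post) {
  pre <- if (inherits(t1_pre, "t1_map")) t1_pre$t1 else t1_pre
  post <- if (inherits(t1_post, "t1_map")) t1_post$t1 else t1_post
  if (!all(dim(pre) == dim(post))) stop("T1 map grids do not match")
  if (any(pre <= 0, na.rm = TRUE)) stop("t1_pre must be positive where defined")
  100 * (pre - post) / pre
}
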