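#' Signed percent difference to a reference value
#'
#' `100 * (measured - reference) / reference`; the sign shows the direction
#' of the deviation. Used for phantom accuracy checks against certified
#' reference values.
#'
#' @param measured,reference Numeric (vectorised); `reference` must be
#'   non-zero.
#' @param absolute Return the absolute difference instead.
#' @return Percent difference(s).
#' @export
percent_difference <- function(measured, reference, absolute = FALSE) {
  if (any(reference == 0)) stop("reference must be non-zero")
  d <- 100 * (measured - reference) / reference
  if (absolute) abs(d) else d
}

#' Coefficient of variation
#'
#' `100 * SD / mean` with the sample SD (n - 1 denominator; group sizes in
#' repeatability studies are small).
#'
#' @param values Numeric vector of >= 2 values with non-zero mean.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("mean is zero")
  100 * stats::sd(values) / m
}

#' Intra- and inter-session coefficients of variation
#'
#' Intra-session CV is the CV of the repeats within each session (per
#' session and their mean); inter-session CV is the CV of the session
#' means. Both use the sample SD.
#'
#' @param values Numeric measurements.
#' @param sessions Session labels, same length.
#' @return List with `intra_session_cv` (mean over sessions),
#'   `per_session_cv`, and `inter_session_cv`, all in percent.
#' @export
session_cv <- function(values, sessions) {
  if (length(values) != length(sessions)) stop("lengths differ")
  groups <- split(values, sessions)
  if (any(lengths(groups) < 2L)) stop("each session needs >= 2 repeats")
  per <- vapply(groups, coefficient_of_variation, numeric(1))
  means <- vapply(groups, mean, numeric(1))
  list(intra_session_cv = mean(per),
       per_session_cv = per,
       inter_session_cv = if (length(means) >= 2L)
         coefficient_of_variation(means) else NA_real_)
}

#' Within-subject coefficient of variation for scan-rescan pairs
#'
#' Per subject, `100 * SD(scan, rescan) / mean(scan, rescan)` with the
#' sample SD; summarised by the mean and range across subjects.
#'
#' @param scan,rescan Paired per-subject measurements.
#' @return List with `per_subject` (percent), `mean`, `min`, `max`.
#' @export
within_subject_cv <- function(scan, rescan) {
  if (length(scan) != length(rescan)) stop("scan and rescan lengths differ")
  if (length(scan) < 1L) stop("need at least one subject")
  if (any(!is.finite(scan)) || any(!is.finite(rescan)))
    stop("missing scan or rescan value")
  per <- vapply(seq_along(scan), function(i) {
    coefficient_of_variation(c(scan[i], rescan[i]))
  }, numeric(1))
  list(per_subject = per, mean = mean(per), min = min(per), max = max(per))
}

#' Mann-Whitney U comparison of two groups
#'
#' Rank-based two-group comparison of global biomarker values. The exact
#' null distribution is used for small samples without ties
#' (`n_a + n_b <= 12`); otherwise the normal approximation with tie
#' correction and continuity correction. The reported U statistic counts
#' pairs where group A exceeds group B. Note: the conventional significance
#' level is 0.05, but stricter thresholds (e.g. 0.005) are sometimes
#' applied; `alpha` is configurable for that reason.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param alternative Passed to [stats::wilcox.test()]; default two-sided.
#' @param alpha Significance level for the flag, default 0.05.
#' @return An object of class `group_comparison`: descriptive statistics
#'   per group, `u_statistic`, `p_value`, `method`, `significant`.
#' @export
mann_whitney_u <- function(group_a, group_b, alternative = "two.sided",
                           alpha = 0.05) {
  if (length(group_a) < 1L || length(group_b) < 1L)
    stop("both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- !ties && (length(group_a) + length(group_b)) <= 12L
  wt <- suppressWarnings(stats::wilcox.test(group_a, group_b,
                                            alternative = alternative,
                                            exact = exact, correct = TRUE))
  desc <- function(v) c(n = length(v), median = stats::median(v),
                        min = min(v), max = max(v),
                        sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  structure(list(group_a = desc(group_a), group_b = desc(group_b),
                 u_statistic = unname(wt$statistic),
                 p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation",
                 alpha = alpha,
                 significant = wt$p.value < alpha,
                 alternative = alternative),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, p = %.4g (%s), %ssignificant at alpha = %g\n",
              x$u_statistic, x$p_value, x$method,
              if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' ROC analysis of a diagnostic score
#'
#' Rank-based AUC (ties counted one half), with the direction chosen
#' automatically so that AUC >= 0.5 and reported: `">"` means higher
#' scores indicate disease, `"<"` lower scores. The optimal cutoff
#' maximises the Youden index (sensitivity + specificity - 1); ties are
#' broken towards higher specificity. Sensitivity is the true-positive
#' fraction among diseased (label 1).
#'
#' @param scores Numeric scores.
#' @param labels Binary labels, healthy = 0 / disease = 1; both classes
#'   must be present.
#' @param direction `"auto"` (default), `">"` or `"<"`.
#' @return An object of class `roc_result` with `auc`, `direction`,
#'   `optimal_cutoff`, `sensitivity`, `specificity` and the full
#'   `cutpoints` table.
#' @export
roc_analysis <- function(scores, labels, direction = "auto") {
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  auc_gt <- auc_rank(scores, labels)   # AUC for 'higher score = disease'
  if (direction == "auto") direction <- if (auc_gt >= 0.5) ">" else "<"
  auc <- if (direction == ">") auc_gt else 1 - auc_gt
  # candidate cutoffs at midpoints between adjacent distinct scores,
  # plus sentinels
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, (su[-1] + su[-length(su)]) / 2, su[length(su)] + 1)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  if (direction == ">") {
    sens <- vapply(cand, function(ct) mean(pos > ct), numeric(1))
    spec <- vapply(cand, function(ct) mean(neg <= ct), numeric(1))
  } else {
    sens <- vapply(cand, function(ct) mean(pos < ct), numeric(1))
    spec <- vapply(cand, function(ct) mean(neg >= ct), numeric(1))
  }
  youden <- sens + spec - 1
  best <- which(youden >= max(youden) - 1e-12)
  best <- best[which.max(spec[best])]
  structure(list(auc = auc, direction = direction,
                 optimal_cutoff = cand[best],
                 sensitivity = sens[best], specificity = spec[best],
                 cutpoints = data.frame(cutoff = cand, sensitivity = sens,
                                        specificity = spec, youden = youden)),
            class = "roc_result")
}

# rank AUC: probability a random diseased score exceeds a random healthy
# score, ties counted half
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (direction %s), cutoff %.4g, sens %.3f, spec %.3f\n",
              x$auc, x$direction, x$optimal_cutoff, x$sensitivity,
              x$specificity))
  invisible(x)
}

#' Bootstrap validation of a ROC statistic
#'
#' Percentile confidence interval from stratified resampling (each class
#' resampled with replacement at its own size). Resamples that degenerate
#' to one class are redrawn and counted (impossible under stratification;
#' the guard is kept for non-stratified extensions).
#'
#' @param scores,labels As in [roc_analysis()].
#' @param statistic `"auc"` or `"cutoff"`.
#' @param n_samples Number of resamples, >= 100; default 1000.
#' @param level Confidence level in percent, in (50, 100); default 95.
#' @param seed Integer seed.
#' @return List with `estimate`, `lower`, `upper`, `level`, `n_samples`,
#'   `n_redrawn`.
#' @export
bootstrap_validate <- function(scores, labels, statistic = c("auc", "cutoff"),
                               n_samples = 1000L, level = 95, seed = 1L) {
  statistic <- match.arg(statistic)
  if (n_samples < 100L) stop("n_samples must be >= 100")
  if (level <= 50 || level >= 100) stop("level must be in (50, 100)")
  labels <- as.integer(labels)
  set.seed(seed)
  i1 <- which(labels == 1L); i0 <- which(labels == 0L)
  if (!length(i1) || !length(i0)) stop("both classes must be present")
  full <- roc_analysis(scores, labels)
  stat_of <- function(r) if (statistic == "auc") r$auc else r$optimal_cutoff
  vals <- numeric(n_samples)
  n_redrawn <- 0L
  for (s in seq_len(n_samples)) {
    repeat {
      idx <- c(sample(i1, length(i1), replace = TRUE),
               sample(i0, length(i0), replace = TRUE))
      if (length(unique(labels[idx])) == 2L) break
      n_redrawn <- n_redrawn + 1L
    }
    vals[s] <- stat_of(roc_analysis(scores[idx], labels[idx],
                                    direction = full$direction))
  }
  a <- (1 - level / 100) / 2
  ci <- unname(stats::quantile(vals, c(a, 1 - a)))
  list(estimate = stat_of(full), lower = ci[1], upper = ci[2],
       level = level, n_samples = n_samples, n_redrawn = n_redrawn)
}

# strength bands for |r|
correlation_strength <- function(r) {
  a <- abs(r)
  ifelse(a >= 0.5, "large",
         ifelse(a >= 0.3, "medium",
                ifelse(a >= 0.1, "small", "negligible")))
}

#' Voxelwise Pearson correlation over an ROI
#'
#' Pearson r between two parameter maps over paired ROI voxels, with the
#' p-value from [stats::cor.test()], a 95% CI via the Fisher transform and
#' a strength label (|r| 0.1-0.3 small, 0.3-0.5 medium, 0.5-1.0 large).
#' Voxels are treated as independent, as is conventional for ROI sizes well
#' above 100 voxels.
#'
#' @param map_a,map_b Numeric arrays (or vectors) of equal dimension.
#' @param roi Optional binary array selecting the ROI (>= 3 voxels).
#' @return List with `r`, `p_value`, `lower`, `upper`, `n`, `strength`.
#' @export
voxelwise_pearson <- function(map_a, map_b, roi = NULL) {
  if (!is.null(roi)) {
    a <- map_a[roi]; b <- map_b[roi]
  } else {
    a <- as.vector(map_a); b <- as.vector(map_b)
  }
  if (length(a) != length(b)) stop("maps differ in size")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 3L) stop("ROI must contain at least 3 finite voxel pairs")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("zero variance in one of the maps over the ROI")
  ct <- stats::cor.test(a, b)
  r <- unname(ct$estimate)
  z <- atanh(r); se <- 1 / sqrt(n - 3)
  list(r = r, p_value = ct$p.value,
       lower = tanh(z - stats::qnorm(0.975) * se),
       upper = tanh(z + stats::qnorm(0.975) * se),
       n = n, strength = correlation_strength(r))
}

#' Fisher-Z pooled correlation
#'
#' Averages correlation coefficients across subjects on the Fisher z scale
#' (`z = atanh(r)`) and back-transforms: `r_bar = tanh(mean(atanh(r)))`.
#'
#' @param r_values Correlations with |r| < 1.
#' @return List with `r_bar`, `z_bar`, `n`.
#' @export
fisher_z_average <- function(r_values) {
  if (any(abs(r_values) >= 1))
    stop("|r| = 1 gives an infinite Fisher z; remove degenerate correlations")
  z_bar <- mean(atanh(r_values))
  list(r_bar = tanh(z_bar), z_bar = z_bar, n = length(r_values))
}

#' Dice similarity between binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; used as registration quality control between
#' parametric-map masks. Two empty masks are defined to agree perfectly
#' (score 1).
#'
#' @param mask_a,mask_b Logical/binary arrays on the same grid.
#' @return Score in [0, 1].
#' @export
dice_similarity <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stop("mask grids do not match")
  a <- as.logical(mask_a); b <- as.logical(mask_b)
  denom <- sum(a) + sum(b)
  if (denom == 0) return(1)
  2 * sum(a & b) / denom
}

#' Kolmogorov-Smirnov normality diagnostic
#'
#' Reported diagnostic only (it gates nothing): KS test of the values
#' against a normal with their sample mean and SD.
#'
#' @param x Numeric vector.
#' @return List with `statistic`, `p_value`, `n`.
#' @export
normality_diagnostic <- function(x) {
  x <- x[is.finite(x)]
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(statistic = unname(kt$statistic), p_value = kt$p.value, n = length(x))
}
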