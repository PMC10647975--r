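#!/usr/bin/env Rscript
# Patient contrast-based function maps: B1-corrected dual-flip-angle T1
# pre/post gadoxetate, percent T1 reduction, and the TSVD-deconvolution
# hepatic extraction fraction map. Scores each map against ground truth.
#
# Input:  results/study/   Output: results/function_maps_summary.csv

library(hepamap)

seed <- 20260929L
cfg <- cohort_config(shape = c(32L, 32L, 6L), seed = seed)
study <- make_cohort(cfg)

rows <- list()
for (s in study$subjects) {
  if (is.null(s$dce)) next  # healthy volunteers: no contrast data
  t1_pre <- fit_t1_dfa(s$spgr_pre, s$mask)
  t1_post <- fit_t1_dfa(s$spgr_post, s$mask)
  dt1 <- delta_t1_percent(t1_pre, t1_post)
  hef <- hef_map(s$dce, s$mask)
  i <- which(s$mask)
  tr <- s$truth
  rows[[s$id]] <- data.frame(
    subject = s$id,
    t1_pre_median = median(t1_pre$t1[i], na.rm = TRUE),
    t1_pre_truth = median(tr$t1_pre[i]),
    t1_post_median = median(t1_post$t1[i], na.rm = TRUE),
    t1_post_truth = median(tr$t1_post[i]),
    delta_t1_median = median(dt1[i], na.rm = TRUE),
    hef_median = median(hef$hef[i], na.rm = TRUE),
    hef_truth = median(tr$hef[i]),
    hef_abs_err = abs(median(hef$hef[i], na.rm = TRUE) - median(tr$hef[i])))
}
df <- do.call(rbind, rows)
write.csv(df, "results/function_maps_summary.csv", row.names = FALSE)
print(df, row.names = FALSE, digits = 3)
cat(sprintf("\nmax |median HEF - truth| across patients: %.3f\n",
            max(df$hef_abs_err)))
cat("(dominated by the default-regularisation bias at high HEF; the\n")
cat(" recovery tolerance band is +-0.12 under noise)\n")
cat(sprintf("median T1 recovery error: pre %.1f ms, post %.1f ms\n",
            median(abs(df$t1_pre_median - df$t1_pre_truth)),
            median(abs(df$t1_post_median - df$t1_post_truth))))
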