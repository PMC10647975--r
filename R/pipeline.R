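#' Pipeline configuration
#'
#' Validated bundle of every stage's tunables. Unknown keys are rejected
#' (calling this constructor with an unrecognised argument fails), which is
#' also how YAML configs are validated.
#'
#' @param method IVIM fitter: `"bayes"` or `"lsq"`.
#' @param mcmc An [mcmc_config()] for the Bayesian fitter.
#' @param b_threshold Segmented-fit b threshold, s/mm^2.
#' @param median_filter Apply the slicewise 3x3 median filter first.
#' @param fit_inplane Optional `c(nx, ny)`: down-sample the signal to this
#'   in-plane grid for fitting and up-sample the maps back (the native-grid
#'   default skips resampling).
#' @param truncation_fraction TSVD singular-value cutoff fraction.
#' @param split_time HEF early/late window boundary, s.
#' @param alpha Significance level for group comparisons.
#' @param bootstrap_n,bootstrap_level ROC bootstrap settings.
#' @param dice_floor Minimum Dice between map masks for a subject to enter
#'   the voxelwise correlation stage.
#' @param correlation_slice Axial slice index for the single-slice
#'   correlation ROI (default: middle slice).
#' @param correlation_region Region label whose voxels form the ROI.
#' @param whole_volume_correlation Opt-in: correlate over the whole liver
#'   volume instead of the single-slice ROI.
#' @param stages Character subset of `c("ivim", "t1", "hef",
#'   "group_stats", "correlation")`.
#' @param seed Master seed for the stochastic stages.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(method = c("bayes", "lsq"),
                            mcmc = mcmc_config(),
                            b_threshold = 200,
                            median_filter = TRUE,
                            fit_inplane = NULL,
                            truncation_fraction = 0.15,
                            split_time = 300,
                            alpha = 0.05,
                            bootstrap_n = 1000L,
                            bootstrap_level = 95,
                            dice_floor = 0.8,
                            correlation_slice = NULL,
                            correlation_region = 1L,
                            whole_volume_correlation = FALSE,
                            stages = c("ivim", "t1", "hef", "group_stats",
                                       "correlation"),
                            seed = 1L) {
  method <- match.arg(method)
  bad <- setdiff(stages, c("ivim", "t1", "hef", "group_stats", "correlation"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  if (!"ivim" %in% stages) stop("the ivim stage is required")
  if (dice_floor < 0 || dice_floor > 1) stop("dice_floor must be in [0,1]")
  cfg <- list(method = method, mcmc = mcmc, b_threshold = b_threshold,
              median_filter = isTRUE(median_filter),
              fit_inplane = fit_inplane,
              truncation_fraction = truncation_fraction,
              split_time = split_time, alpha = alpha,
              bootstrap_n = as.integer(bootstrap_n),
              bootstrap_level = bootstrap_level,
              dice_floor = dice_floor,
              correlation_slice = correlation_slice,
              correlation_region = as.integer(correlation_region),
              whole_volume_correlation = isTRUE(whole_volume_correlation),
              stages = stages, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Keys map one-to-one onto [pipeline_config()] arguments; unknown keys
#' are rejected. An `mcmc` sub-map is passed to [mcmc_config()].
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$mcmc)) raw$mcmc <- do.call(mcmc_config, raw$mcmc)
  do.call(pipeline_config, raw)
}

config_hash <- function(config) {
  object_md5(unclass(config))
}

# maps for one subject; shared by run_study and run_pipeline
fit_subject <- function(subj, config) {
  dwi <- subj$dwi
  if (config$median_filter) dwi <- median_filter_slicewise(dwi)
  native <- dim(dwi$signal)[1:2]
  mask <- subj$mask
  if (!is.null(config$fit_inplane)) {
    sig <- resample_inplane(dwi$signal, config$fit_inplane, "down_for_fit")
    mlow <- resample_inplane(subj$mask + 0, config$fit_inplane,
                             "down_for_fit") > 0.5
    dwi <- dwi_series(pmax(sig, 0), dwi$scheme, dwi$voxel_size, mask = mlow)
    mask <- mlow
  }
  if (config$method == "bayes") {
    cfg <- config$mcmc
    cfg$seed <- derive_seed(config$seed, (subj$seed %||% 1L) %% 100000L)
    fit <- fit_ivim_bayes(dwi, mask, cfg)
    maps <- fit$maps
    posterior <- fit$posterior
  } else {
    maps <- fit_ivim_lsq(dwi, mask, config$b_threshold)
    posterior <- NULL
  }
  if (!is.null(config$fit_inplane)) {
    for (p in c("d_slow", "d_fast", "f_p", "s0"))
      maps[[p]] <- resample_inplane(maps[[p]], native, "up_for_maps")
    maps$mask <- subj$mask
  }
  list(maps = maps, posterior = posterior)
}

pair_label <- function(a, b) paste(a, b, sep = "-")

#' Run the full analysis over a study
#'
#' End-to-end driver: per subject, IVIM maps (Bayesian or segmented LSQ)
#' and their global liver summaries; for patients, B1-corrected T1 maps
#' pre/post contrast with percent T1 reduction and the TSVD HEF map; then
#' cohort statistics (Mann-Whitney comparisons, ROC with bootstrap CI per
#' IVIM parameter) and the single-slice voxelwise correlation table with
#' Fisher-Z pooling. A Dice QC score between the parametric-map masks is
#' computed per patient and subjects below `dice_floor` are excluded from
#' the correlation stage with a logged reason. The report carries a
#' provenance block (config hash, seed, package version) and reruns with
#' the same config and seed give an identical [report_digest()].
#'
#' @param study A `liver_study` from [make_cohort()] (or an equivalent list
#'   of subject bundles from [load_subject()]).
#' @param config A [pipeline_config()].
#' @return An object of class `study_report`.
#' @export
run_study <- function(study, config = pipeline_config()) {
  subjects <- study$subjects
  if (!length(subjects)) stop("study has no subjects")

  per_subject <- list()
  summaries <- list()
  correlations <- list()
  dice_rows <- list()
  excluded <- list()

  for (s in subjects) {
    fit <- fit_subject(s, config)
    maps <- fit$maps
    res <- list(id = s$id, cohort = s$cohort, ivim = maps,
                posterior = fit$posterior)
    gs <- global_liver_summary(maps)
    gs$subject <- s$id
    gs$cohort <- s$cohort
    summaries[[s$id]] <- gs

    if ("t1" %in% config$stages && !is.null(s$spgr_pre) &&
        !is.null(s$spgr_post)) {
      res$t1_pre <- fit_t1_dfa(s$spgr_pre, s$mask)
      res$t1_post <- fit_t1_dfa(s$spgr_post, s$mask)
      res$delta_t1 <- delta_t1_percent(res$t1_pre, res$t1_post)
    }
    if ("hef" %in% config$stages && !is.null(s$dce)) {
      res$hef <- hef_map(s$dce, s$mask, config$truncation_fraction,
                         config$split_time)
    }

    if ("correlation" %in% config$stages && !is.null(res$hef) &&
        !is.null(res$delta_t1)) {
      mask_ivim <- is.finite(maps$f_p) & maps$mask
      mask_hef <- is.finite(res$hef$hef) & maps$mask
      dice <- dice_similarity(mask_ivim, mask_hef)
      dice_rows[[s$id]] <- data.frame(subject = s$id, dice = dice)
      if (dice < config$dice_floor) {
        excluded[[s$id]] <- sprintf(
          "subject %s excluded from correlation: Dice %.3f below floor %.2f",
          s$id, dice, config$dice_floor)
      } else {
        fields <- list(HEF = res$hef$hef, T1post = res$t1_post$t1,
                       dT1 = res$delta_t1, D_slow = maps$d_slow,
                       D_fast = maps$d_fast, F_p = maps$f_p)
        if (config$whole_volume_correlation) {
          roi <- s$mask
        } else {
          z <- config$correlation_slice %||% ceiling(dim(s$mask)[3] / 2)
          roi <- array(FALSE, dim(s$mask))
          roi[, , z] <- s$truth$region_labels[, , z] == config$correlation_region
        }
        pairs <- list(c("HEF", "D_slow"), c("HEF", "D_fast"), c("HEF", "F_p"),
                      c("HEF", "T1post"), c("HEF", "dT1"),
                      c("D_slow", "T1post"), c("D_slow", "dT1"),
                      c("D_fast", "F_p"), c("D_fast", "T1post"),
                      c("D_fast", "dT1"), c("F_p", "T1post"), c("F_p", "dT1"))
        rows <- lapply(pairs, function(pr) {
          ct <- voxelwise_pearson(fields[[pr[1]]], fields[[pr[2]]], roi)
          data.frame(subject = s$id, pair = pair_label(pr[1], pr[2]),
                     r = ct$r, lower = ct$lower, upper = ct$upper,
                     p_value = ct$p_value, n = ct$n, strength = ct$strength)
        })
        correlations[[s$id]] <- do.call(rbind, rows)
      }
    }
    per_subject[[s$id]] <- res
  }

  subject_summary <- do.call(rbind, summaries)
  rownames(subject_summary) <- NULL

  group_comparison <- NULL
  roc <- NULL
  if ("group_stats" %in% config$stages) {
    cohorts <- vapply(subjects, `[[`, "", "cohort")
    if (length(unique(cohorts)) == 2L) {
      gc_rows <- list(); roc_rows <- list()
      for (p in c("d_slow", "f_p", "d_fast")) {
        vals <- subject_summary[subject_summary$parameter == p, ]
        g <- vals$mean[match(names(subjects), vals$subject)]
        healthy <- g[cohorts == "healthy"]
        patient <- g[cohorts == "patient"]
        mw <- mann_whitney_u(healthy, patient, alpha = config$alpha)
        gc_rows[[p]] <- data.frame(
          parameter = p,
          healthy_median = mw$group_a["median"], healthy_sd = mw$group_a["sd"],
          patient_median = mw$group_b["median"], patient_sd = mw$group_b["sd"],
          u_statistic = mw$u_statistic, p_value = mw$p_value,
          method = mw$method, significant = mw$significant)
        labels <- as.integer(cohorts == "patient")
        rr <- roc_analysis(g, labels)
        bs <- bootstrap_validate(g, labels, "auc", config$bootstrap_n,
                                 config$bootstrap_level,
                                 seed = derive_seed(config$seed, 777L))
        roc_rows[[p]] <- data.frame(
          parameter = p, auc = rr$auc, direction = rr$direction,
          optimal_cutoff = rr$optimal_cutoff, sensitivity = rr$sensitivity,
          specificity = rr$specificity, auc_lower = bs$lower,
          auc_upper = bs$upper, level = bs$level, n_boot = bs$n_samples)
      }
      group_comparison <- do.call(rbind, gc_rows)
      roc <- do.call(rbind, roc_rows)
      rownames(group_comparison) <- rownames(roc) <- NULL
    }
  }

  correlation_table <- if (length(correlations))
    do.call(rbind, c(correlations, list(make.row.names = FALSE))) else NULL
  pooled <- NULL
  if (!is.null(correlation_table)) {
    pooled <- do.call(rbind, lapply(split(correlation_table,
                                          correlation_table$pair),
                                    function(df) {
      fz <- fisher_z_average(df$r)
      data.frame(pair = df$pair[1], z_bar = fz$z_bar, r_bar = fz$r_bar,
                 min_r = min(df$r), max_r = max(df$r), n_subjects = nrow(df),
                 strength = correlation_strength(fz$r_bar))
    }))
    rownames(pooled) <- NULL
  }

  structure(list(
    subject_summary = subject_summary,
    group_comparison = group_comparison,
    roc = roc,
    correlations = correlation_table,
    pooled_correlations = pooled,
    dice_qc = if (length(dice_rows)) do.call(rbind, dice_rows) else NULL,
    excluded = unname(unlist(excluded)),
    per_subject = per_subject,
    provenance = list(config_hash = config_hash(config),
                      seed = config$seed,
                      method = config$method,
                      package_version =
                        as.character(utils::packageVersion("hepamap")))),
    class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report\n")
  cat(sprintf("  subjects: %d  (method %s, config %s)\n",
              length(x$per_subject), x$provenance$method,
              substr(x$provenance$config_hash, 1, 8)))
  if (!is.null(x$group_comparison)) {
    cat("  group comparison (global means):\n")
    print(x$group_comparison[, c("parameter", "p_value", "significant")],
          row.names = FALSE)
  }
  if (!is.null(x$roc)) {
    cat("  ROC AUC:\n")
    print(x$roc[, c("parameter", "auc", "optimal_cutoff")], row.names = FALSE)
  }
  if (length(x$excluded)) cat("  exclusions:", length(x$excluded), "\n")
  invisible(x)
}

#' Run the pipeline from an on-disk study layout
#'
#' Loads each subject from the layout (inputs are never modified), runs
#' [run_study()], and optionally writes the derived maps and result tables
#' under `<root>/derived/` with provenance (stage, config hash, seed) in
#' every NIfTI header and CSV comment line.
#'
#' @param layout A [study_layout()].
#' @param config A [pipeline_config()].
#' @param write_outputs Write derived maps/tables to disk.
#' @return A `study_report`.
#' @export
run_pipeline <- function(layout, config = pipeline_config(),
                         write_outputs = FALSE) {
  truth_path <- file.path(layout$root, "truth.csv")
  truth <- if (file.exists(truth_path)) utils::read.csv(truth_path) else NULL
  subjects <- lapply(layout$manifest$subject, function(id) {
    s <- load_subject(layout, id)
    # region labels are needed for the single-slice correlation ROI; for
    # on-disk studies the mask itself is the fallback ROI source
    s$truth <- list(region_labels = array(1L, dim(s$mask)) * (s$mask + 0L))
    s
  })
  names(subjects) <- layout$manifest$subject
  report <- run_study(list(subjects = subjects), config)
  if (write_outputs) {
    outdir <- file.path(layout$root, "derived")
    dir.create(outdir, showWarnings = FALSE)
    hash <- substr(report$provenance$config_hash, 1, 8)
    tag <- function(stage) sprintf("%s cfg=%s seed=%d", stage, hash,
                                   config$seed)
    for (id in names(report$per_subject)) {
      ps <- report$per_subject[[id]]
      sd <- file.path(outdir, id)
      dir.create(sd, showWarnings = FALSE)
      write_volume(si_to_report(ps$ivim$d_slow, "diffusivity"),
                   file.path(sd, "d_slow.nii.gz"), descrip = tag("ivim"))
      write_volume(si_to_report(ps$ivim$d_fast, "diffusivity"),
                   file.path(sd, "d_fast.nii.gz"), descrip = tag("ivim"))
      write_volume(si_to_report(ps$ivim$f_p, "fraction"),
                   file.path(sd, "f_p.nii.gz"), descrip = tag("ivim"))
      if (!is.null(ps$t1_pre)) {
        write_volume(ps$t1_pre$t1, file.path(sd, "t1_pre.nii.gz"),
                     descrip = tag("t1"))
        write_volume(ps$t1_post$t1, file.path(sd, "t1_post.nii.gz"),
                     descrip = tag("t1"))
        write_volume(ps$delta_t1, file.path(sd, "delta_t1_pct.nii.gz"),
                     descrip = tag("t1"))
      }
      if (!is.null(ps$hef))
        write_volume(ps$hef$hef, file.path(sd, "hef.nii.gz"),
                     descrip = tag("hef"))
    }
    write_report_csv <- function(df, name, stage) {
      if (is.null(df)) return()
      p <- file.path(outdir, name)
      con <- file(p, "w")
      writeLines(sprintf("# stage=%s cfg=%s seed=%d", stage, hash,
                         config$seed), con)
      utils::write.csv(df, con, row.names = FALSE)
      close(con)
    }
    write_report_csv(report$subject_summary, "subject_summary.csv", "summary")
    write_report_csv(report$group_comparison, "group_comparison.csv", "stats")
    write_report_csv(report$roc, "roc.csv", "stats")
    write_report_csv(report$correlations, "correlations.csv", "correlation")
    write_report_csv(report$pooled_correlations, "pooled_correlations.csv",
                     "correlation")
  }
  report
}

#' Deterministic digest of a study report
#'
#' MD5 of the report's numeric tables serialised to canonical JSON;
#' identical configs and seeds reproduce it bit-for-bit.
#'
#' @param report A `study_report`.
#' @return 32-character hex digest.
#' @export
report_digest <- function(report) {
  object_md5(list(summary = report$subject_summary,
                  comparison = report$group_comparison,
                  roc = report$roc,
                  correlations = report$correlations,
                  pooled = report$pooled_correlations,
                  provenance = report$provenance))
}
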