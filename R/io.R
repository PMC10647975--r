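#' Read a NIfTI volume
#'
#' Thin wrapper over RNifti preserving the raw array and voxel geometry.
#' Arrays are returned with R's native 1-based, column-major (x fastest)
#' indexing; the 4th axis, when present, is the b/t axis.
#'
#' @param path NIfTI-1/2 file (.nii or .nii.gz).
#' @return Numeric array with attribute `voxel_size` (mm).
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  attr(arr, "voxel_size") <- RNifti::pixdim(img)[seq_len(min(3, length(dim(img))))]
  arr
}

#' Write a NIfTI volume
#'
#' @param x 3D or 4D numeric array.
#' @param path Output path (.nii or .nii.gz).
#' @param voxel_size Voxel dimensions in mm (defaults to the array's
#'   `voxel_size` attribute, else 1 mm isotropic).
#' @param descrip Optional short provenance string stored in the NIfTI
#'   header description field (producing stage, config hash, seed).
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, voxel_size = NULL, descrip = NULL) {
  nd <- length(dim(x))
  if (!nd %in% c(3L, 4L)) stop("x must be a 3D or 4D array")
  vs <- voxel_size %||% attr(x, "voxel_size") %||% rep(1, 3)
  img <- RNifti::asNifti(x)
  RNifti::pixdim(img) <- c(vs, rep(1, nd - 3))
  if (!is.null(descrip)) img$descrip <- substr(descrip, 1, 79)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read / write a b-value sidecar
#'
#' Plain-text b-values (s/mm^2). Written one value per line; the reader
#' also accepts the single-line whitespace-separated dialect.
#'
#' @param path Text file.
#' @return Numeric vector of b-values.
#' @export
read_bvals <- function(path) {
  as.numeric(scan(path, what = numeric(), quiet = TRUE))
}

#' @rdname read_bvals
#' @param b_values Numeric vector to write.
#' @export
write_bvals <- function(b_values, path) {
  writeLines(format(b_values, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read / write a DCE time-stamp sidecar (seconds, one per line)
#' @param path Text file.
#' @return Numeric vector of times.
#' @export
read_times <- function(path) as.numeric(scan(path, what = numeric(), quiet = TRUE))

#' @rdname read_times
#' @param times Numeric vector to write.
#' @export
write_times <- function(times, path) {
  writeLines(format(times, trim = TRUE, scientific = FALSE), path)
  invisible(path)
}

#' Read / write an input-function CSV (`time,value`)
#' @param path CSV file with columns `time` and `value`.
#' @return Data frame with `time` and `value`.
#' @export
read_aif <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("time", "value") %in% names(df)))
    stop("AIF CSV must have 'time' and 'value' columns")
  df
}

#' @rdname read_aif
#' @param times,values Vectors to write.
#' @export
write_aif <- function(times, values, path) {
  utils::write.csv(data.frame(time = times, value = values), path,
                   row.names = FALSE)
  invisible(path)
}

#' Load a DWI series from NIfTI + b-value sidecar
#'
#' @param dwi_path 4D NIfTI file.
#' @param bval_path b-value sidecar.
#' @param averages Optional per-b excitation counts (defaults to 1).
#' @param mask_path Optional mask NIfTI.
#' @return A [dwi_series()].
#' @export
read_dwi <- function(dwi_path, bval_path, averages = NULL, mask_path = NULL) {
  arr <- read_volume(dwi_path)
  b <- read_bvals(bval_path)
  if (length(dim(arr)) != 4L) stop("DWI volume must be 4D")
  if (dim(arr)[4] != length(b))
    stop(sprintf("bval sidecar has %d entries but the volume has %d b-frames",
                 length(b), dim(arr)[4]))
  scheme <- bvalue_scheme(b, averages %||% rep(1L, length(b)))
  mask <- if (!is.null(mask_path)) read_volume(mask_path) > 0.5 else NULL
  dwi_series(arr, scheme, voxel_size = attr(arr, "voxel_size"), mask = mask)
}

#' Write a synthetic study to a per-subject directory layout
#'
#' Per subject: `dwi.nii.gz` + `dwi.bval`, `mask.nii.gz` and, for patients,
#' per-angle SPGR volumes (`spgr_<phase>_fa<angle>.nii.gz`), `b1.nii.gz`,
#' `dce.nii.gz` + `dce.times` + `aif.csv`. A `manifest.csv` (subject id,
#' cohort, seed) and a ground-truth table (`truth.csv`: subject, cohort,
#' region, parameter, value — region medians) are written at the root.
#'
#' @param study A `liver_study` from [make_cohort()].
#' @param dir Output directory (created if needed).
#' @return A `study_layout` (see [read_study()]), invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  truth_rows <- list()
  for (s in study$subjects) {
    sd <- file.path(dir, s$id)
    dir.create(sd, showWarnings = FALSE)
    write_volume(s$dwi$signal, file.path(sd, "dwi.nii.gz"),
                 voxel_size = s$dwi$voxel_size)
    write_bvals(s$dwi$scheme$b_values, file.path(sd, "dwi.bval"))
    writeLines(format(s$dwi$scheme$averages), file.path(sd, "dwi.averages"))
    write_volume(s$mask + 0, file.path(sd, "mask.nii.gz"))
    if (!is.null(s$spgr_pre)) {
      yaml::write_yaml(list(tr = s$spgr_pre$tr,
                            flip_angles = s$spgr_pre$flip_angles),
                       file.path(sd, "acq.yaml"))
      for (phase in c("pre", "post")) {
        acq <- s[[paste0("spgr_", phase)]]
        if (is.null(acq)) next
        for (k in seq_along(acq$flip_angles)) {
          write_volume(acq$signals[[k]],
                       file.path(sd, sprintf("spgr_%s_fa%02d.nii.gz", phase,
                                             acq$flip_angles[k])))
        }
      }
      write_volume(s$spgr_pre$b1_map, file.path(sd, "b1.nii.gz"))
    }
    if (!is.null(s$dce)) {
      write_volume(s$dce$signal, file.path(sd, "dce.nii.gz"))
      write_times(s$dce$times, file.path(sd, "dce.times"))
      write_aif(s$dce$times, s$dce$aif, file.path(sd, "aif.csv"))
    }
    rows[[s$id]] <- data.frame(subject = s$id, cohort = s$cohort,
                               seed = s$seed)
    tr <- s$truth
    for (p in c("d_slow", "d_fast", "f_p", "t1_pre", "t1_post", "hef")) {
      for (k in sort(unique(tr$region_labels[tr$region_labels > 0]))) {
        sel <- tr$region_labels == k
        truth_rows[[length(truth_rows) + 1L]] <-
          data.frame(subject = s$id, cohort = s$cohort, region = k,
                     parameter = p,
                     value = stats::median(tr[[p]][sel]))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  utils::write.csv(do.call(rbind, truth_rows), file.path(dir, "truth.csv"),
                   row.names = FALSE)
  invisible(study_layout(dir))
}

#' Study directory layout
#'
#' Indexes a study directory written by [write_study()] (or following the
#' same conventions). Stage outputs are kept under `<root>/derived/` and
#' never overwrite inputs.
#'
#' @param dir Study root containing `manifest.csv`.
#' @return An object of class `study_layout` with the manifest and root.
#' @export
study_layout <- function(dir) {
  mf <- file.path(dir, "manifest.csv")
  if (!file.exists(mf)) stop("no manifest.csv under ", dir)
  manifest <- utils::read.csv(mf)
  structure(list(root = dir, manifest = manifest), class = "study_layout")
}

#' @rdname study_layout
#' @export
read_study <- function(dir) study_layout(dir)

subject_file <- function(layout, id, name, required = TRUE) {
  p <- file.path(layout$root, id, name)
  if (!file.exists(p)) {
    if (required) stop(sprintf("missing input %s for subject %s", name, id))
    return(NULL)
  }
  p
}

#' Load one subject's data bundle from a study layout
#'
#' @param layout A `study_layout`.
#' @param id Subject id from the manifest.
#' @param averages Optional per-b excitation counts for the DWI scheme.
#' @return List with `id`, `cohort`, `dwi`, `mask` and, when present on
#'   disk, `spgr_pre`, `spgr_post`, `dce`.
#' @export
load_subject <- function(layout, id, averages = NULL) {
  row <- layout$manifest[layout$manifest$subject == id, ]
  if (nrow(row) != 1L) stop("unknown subject id: ", id)
  mask <- read_volume(subject_file(layout, id, "mask.nii.gz")) > 0.5
  avg_path <- subject_file(layout, id, "dwi.averages", required = FALSE)
  if (is.null(averages) && !is.null(avg_path))
    averages <- as.integer(scan(avg_path, quiet = TRUE))
  dwi <- read_dwi(subject_file(layout, id, "dwi.nii.gz"),
                  subject_file(layout, id, "dwi.bval"),
                  averages = averages)
  dwi$mask <- mask
  out <- list(id = id, cohort = row$cohort, seed = row$seed, dwi = dwi,
              mask = mask)
  b1p <- subject_file(layout, id, "b1.nii.gz", required = FALSE)
  if (!is.null(b1p)) {
    b1 <- read_volume(b1p)
    acq <- yaml::read_yaml(subject_file(layout, id, "acq.yaml"))
    for (phase in c("pre", "post")) {
      files <- list.files(file.path(layout$root, id),
                          pattern = sprintf("^spgr_%s_fa\\d+\\.nii\\.gz$", phase))
      if (!length(files)) next
      angles <- as.numeric(sub(sprintf("spgr_%s_fa(\\d+)\\.nii\\.gz", phase),
                               "\\1", files))
      ord <- order(angles)
      sigs <- lapply(files[ord], function(f)
        read_volume(file.path(layout$root, id, f)))
      out[[paste0("spgr_", phase)]] <-
        spgr_acquisition(sigs, angles[ord], tr = acq$tr, b1_map = b1,
                         mask = mask)
    }
  }
  dcep <- subject_file(layout, id, "dce.nii.gz", required = FALSE)
  if (!is.null(dcep)) {
    times <- read_times(subject_file(layout, id, "dce.times"))
    aif <- read_aif(subject_file(layout, id, "aif.csv"))
    out$dce <- dce_series(read_volume(dcep), times, aif$value, mask = mask)
  }
  out
}
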