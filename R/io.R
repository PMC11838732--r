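# On-disk interchange: NIfTI volumes with a JSON sidecar per study, cohort
# metadata CSV, run manifests, and the canonical-orientation (LPS) loader
# with optional in-plane resampling and slice coarsening.

#' Write a study to disk
#'
#' One `.nii.gz` per sequence plus a `study.json` sidecar holding names,
#' labels, findings, acuity, age, referrals, per-sequence geometry and any
#' subgroup metadata.
#'
#' @param study an [mri_study()].
#' @param report the paired `report_record`.
#' @param dir output directory (created if needed).
#' @param meta optional subgroup metadata list.
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, report, dir, meta = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seq_info <- lapply(seq_along(study$sequences), function(j) {
    s <- study$sequences[[j]]
    file <- sprintf("seq%02d.nii.gz", j)
    img <- RNifti::asNifti(s$voxels, pixdim = s$spacing)
    RNifti::writeNifti(img, file.path(dir, file))
    list(file = file, name = s$sequence_name, plane = s$plane,
         orientation = s$orientation, spacing = s$spacing)
  })
  sidecar <- list(study_name = study$study_name,
                  patient_id = study$patient_id,
                  abnormal = study$abnormal,
                  labels = as.list(report$labels),
                  findings = report$findings,
                  acuity = report$acuity,
                  age = report$age,
                  referrals = as.list(report$referrals),
                  sequences = seq_info,
                  meta = meta)
  jsonlite::write_json(sidecar, file.path(dir, "study.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Reorient a voxel array to LPS
#'
#' Orientation codes name the anatomical direction of increasing index per
#' stored axis (x: L/R, y: P/A, z: S/I); axes whose letter disagrees with
#' LPS are index-flipped.
#'
#' @param voxels 3D array.
#' @param orientation 3-letter code (e.g. `"RAS"`).
#' @return the reoriented array.
#' @export
reorient_to_lps <- function(voxels, orientation) {
  if (!orientation %in% ORIENTATIONS)
    stop("unknown orientation code: ", orientation)
  letters3 <- strsplit(orientation, "")[[1L]]
  target <- c("L", "P", "S")
  for (a in 1:3) {
    if (letters3[a] != target[a]) {
      idx <- rev(seq_len(dim(voxels)[a]))
      voxels <- switch(a, voxels[idx, , , drop = FALSE],
                       voxels[, idx, , drop = FALSE],
                       voxels[, , idx, drop = FALSE])
    }
  }
  voxels
}

# bilinear resize of a matrix
bilinear_resize <- function(m, out_r, out_c) {
  src <- function(n_out, n_in) {
    x <- ((seq_len(n_out)) - 0.5) * n_in / n_out + 0.5
    pmin(pmax(x, 1), n_in)
  }
  xi <- src(out_r, nrow(m)); yi <- src(out_c, ncol(m))
  x0 <- floor(xi); x1 <- pmin(x0 + 1, nrow(m)); wx <- xi - x0
  y0 <- floor(yi); y1 <- pmin(y0 + 1, ncol(m)); wy <- yi - y0
  rowi <- m[x0, , drop = FALSE] * (1 - wx) + m[x1, , drop = FALSE] * wx
  t(t(rowi[, y0, drop = FALSE]) * (1 - wy) + t(rowi[, y1, drop = FALSE]) * wy)
}

# in-plane (first two axes) resample + slice coarsening by mean aggregation
normalize_geometry <- function(voxels, spacing, target_inplane = NULL,
                               min_slice_mm = NULL) {
  d <- dim(voxels)
  if (!is.null(target_inplane) && any(d[1:2] != target_inplane)) {
    out <- array(0, c(target_inplane, target_inplane, d[3L]))
    for (k in seq_len(d[3L]))
      out[, , k] <- bilinear_resize(voxels[, , k], target_inplane, target_inplane)
    spacing[1:2] <- spacing[1:2] * d[1:2] / target_inplane
    voxels <- out
    d <- dim(voxels)
  }
  if (!is.null(min_slice_mm) && spacing[3L] < min_slice_mm) {
    f <- ceiling(min_slice_mm / spacing[3L])
    nz <- d[3L] %/% f
    if (nz >= 1L) {
      out <- array(0, c(d[1:2], nz))
      for (k in seq_len(nz))
        out[, , k] <- apply(voxels[, , ((k - 1L) * f + 1L):(k * f), drop = FALSE],
                            c(1L, 2L), mean)
      voxels <- out
      spacing[3L] <- spacing[3L] * f
    }
  }
  list(voxels = voxels, spacing = spacing)
}

#' Read a study from disk
#'
#' Loads the sidecar and the per-sequence NIfTI volumes, reorients every
#' volume to LPS, and optionally resamples in-plane to a square grid and
#' coarsens slice spacing to at least `min_slice_mm` (mean aggregation).
#'
#' @param dir study directory written by [write_study()].
#' @param target_inplane in-plane grid size (e.g. 256), or `NULL` to keep
#'   the native grid.
#' @param min_slice_mm minimum slice spacing in mm, or `NULL`.
#' @param training when `TRUE`, studies with fewer than 2 sequences raise a
#'   warning (single-sequence studies are allowed at inference).
#' @return list with `study`, `report` and `meta`.
#' @export
read_study <- function(dir, target_inplane = NULL, min_slice_mm = NULL,
                       training = TRUE) {
  sc_path <- file.path(dir, "study.json")
  if (!file.exists(sc_path)) stop("missing sidecar: ", sc_path)
  sc <- jsonlite::read_json(sc_path, simplifyVector = TRUE)
  if (training && length(sc$sequences$file) < 2L)
    warning("study has fewer than 2 sequences")
  seqs <- lapply(seq_len(nrow(sc$sequences)), function(j) {
    info <- sc$sequences[j, ]
    vox <- array(as.numeric(RNifti::readNifti(file.path(dir, info$file))),
                 dim(RNifti::readNifti(file.path(dir, info$file))))
    vox <- reorient_to_lps(vox, info$orientation)
    g <- normalize_geometry(vox, unlist(info$spacing), target_inplane,
                            min_slice_mm)
    mri_volume(g$voxels, spacing = g$spacing, plane = info$plane,
               orientation = "LPS", sequence_name = info$name)
  })
  labels <- unlist(sc$labels)
  report <- report_record(findings = as.character(unlist(sc$findings)),
                          labels = labels, acuity = sc$acuity, age = sc$age,
                          referrals = unlist(sc$referrals))
  list(study = mri_study(sc$study_name, seqs, sc$patient_id, sc$abnormal),
       report = report, meta = sc$meta)
}

#' Write cohort subgroup metadata as CSV
#'
#' Numeric columns are written with 9 significant digits.
#'
#' @param cohort output of [generate_cohort()] (or a metadata data.frame).
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_cohort_csv <- function(cohort, file) {
  df <- if (is.data.frame(cohort)) cohort else cohort_metadata(cohort)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 9))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' Write a run manifest
#'
#' Records the package version, configuration, seeds and input file hashes
#' so any artifact can be reproduced from its manifest.
#'
#' @param path output JSON path.
#' @param config named list of configuration values.
#' @param seeds named list of per-stage seeds.
#' @param inputs character vector of input file paths (md5-hashed).
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, config = list(), seeds = list(),
                           inputs = character()) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else NULL
  jsonlite::write_json(
    list(package = "radclip",
         version = as.character(utils::packageVersion("radclip")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = config, seeds = seeds, input_hashes = hashes),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
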