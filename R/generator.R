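# Synthetic phantom-study generator.
#
# Produces multi-sequence 3D "head" phantoms with geometric lesions tied to
# diagnosis classes, templated itemized findings, acuity/referral/age targets
# and per-patient subgroup metadata. Ground truth (lesion voxel masks, planted
# turnaround-time odds) is retained so token attribution and fairness audits
# can be validated end to end.

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

PLANES <- c("axial", "coronal", "sagittal")
ORIENTATIONS <- c("LPS", "LPI", "LAS", "LAI", "RPS", "RPI", "RAS", "RAI")

#' Default diagnosis label catalog
#'
#' Each class plants a distinct geometric signature in the phantom:
#' a bright sphere (tumor), a bright ring with hypointense core (abscess),
#' paired ellipsoid ventricle enlargement (ventriculomegaly) and a bright
#' wedge (infarct). `visible` lists the sequence contrast families in which
#' the lesion appears; `acuity` and `referral` are the default transfer-task
#' mappings shipped with the package (both editable).
#'
#' @return a list describing the classes, their lesion geometry, visibility,
#'   acuity level and referral service.
#' @export
default_label_catalog <- function() {
  list(
    classes = c("tumor", "abscess", "ventriculomegaly", "infarct"),
    shape = c(tumor = "sphere", abscess = "ring",
              ventriculomegaly = "paired_ellipsoid", infarct = "wedge"),
    visible = list(tumor = c("T1", "T2"), abscess = c("T1", "DWI"),
                   ventriculomegaly = c("T1", "T2", "DWI"),
                   infarct = c("T2", "DWI")),
    acuity = c(tumor = "high", abscess = "medium",
               ventriculomegaly = "medium", infarct = "high"),
    referrals = c("neurosurgery", "neurology"),
    referral = c(tumor = "neurosurgery", abscess = "neurosurgery",
                 ventriculomegaly = "neurosurgery", infarct = "neurology")
  )
}

ACUITY_LEVELS <- c("normal", "medium", "high")

#' Construct an MRI volume object
#'
#' @param voxels 3D numeric array of intensities.
#' @param spacing voxel spacing in mm (length 3).
#' @param plane acquisition plane: `"axial"`, `"coronal"` or `"sagittal"`.
#' @param orientation 3-letter anatomical orientation code (e.g. `"LPS"`).
#' @param sequence_name free-text sequence name (e.g. `"AX_T2_FLAIR"`).
#' @return an object of class `mri_volume`.
#' @export
mri_volume <- function(voxels, spacing = c(1, 1, 1), plane = "axial",
                       orientation = "LPS", sequence_name = "AX_T1") {
  stopifnot(length(dim(voxels)) == 3L, all(dim(voxels) >= 1L),
            all(is.finite(voxels)), length(spacing) == 3L)
  plane <- match.arg(plane, PLANES)
  if (!orientation %in% ORIENTATIONS)
    stop("unknown orientation code: ", orientation)
  structure(list(voxels = voxels, spacing = as.numeric(spacing),
                 plane = plane, orientation = orientation,
                 sequence_name = sequence_name),
            class = "mri_volume")
}

#' Construct an MRI study object
#'
#' @param study_name free-text study name.
#' @param sequences list of [mri_volume()] objects (length >= 1).
#' @param patient_id opaque patient identifier shared by all sequences.
#' @param abnormal logical; whether any diagnosis label is positive.
#' @param lesion_masks optional ground-truth masks: per class, a list of
#'   logical arrays (or `NULL`) aligned with `sequences`.
#' @return an object of class `mri_study`.
#' @export
mri_study <- function(study_name, sequences, patient_id, abnormal = FALSE,
                      lesion_masks = NULL) {
  stopifnot(length(sequences) >= 1L,
            all(vapply(sequences, inherits, TRUE, "mri_volume")))
  structure(list(study_name = study_name, sequences = sequences,
                 patient_id = patient_id, abnormal = abnormal,
                 lesion_masks = lesion_masks),
            class = "mri_study")
}

#' @export
print.mri_study <- function(x, ...) {
  cat("<mri_study>", x$study_name, "| patient", x$patient_id,
      "|", length(x$sequences), "sequences |",
      if (x$abnormal) "abnormal" else "normal", "\n")
  for (s in x$sequences)
    cat("  ", s$sequence_name, paste(dim(s$voxels), collapse = "x"),
        s$plane, s$orientation, "\n")
  invisible(x)
}

report_record <- function(findings, labels, acuity, age, referrals) {
  stopifnot((sum(labels) == 0L) == (length(findings) == 0L),
            acuity %in% ACUITY_LEVELS)
  if (sum(labels) == 0L && acuity != "normal")
    stop("all-zero labels require normal acuity")
  structure(list(findings = findings, labels = labels, acuity = acuity,
                 age = age, referrals = referrals),
            class = "report_record")
}

#' Render a report record as itemized text
#'
#' Findings are rendered as a numbered list, one line per finding; a normal
#' study renders as the empty string.
#'
#' @param report a `report_record`.
#' @return a single string.
#' @export
report_text <- function(report) {
  if (length(report$findings) == 0L) return("")
  paste(sprintf("%d . %s", seq_along(report$findings), report$findings),
        collapse = " \n ")
}

# sequence name construction and contrast-family lookup -----------------------

plane_prefix <- c(axial = "AX", coronal = "COR", sagittal = "SAG")
FAMILY_VARIANTS <- list(T1 = c("T1", "T1_POST"),
                        T2 = c("T2", "T2_FLAIR"),
                        DWI = "DWI")

make_sequence_name <- function(plane, family) {
  variant <- sample(FAMILY_VARIANTS[[family]], 1L)
  paste(plane_prefix[[plane]], variant, sep = "_")
}

#' Contrast family of a sequence name
#' @param name sequence name string.
#' @return `"T1"`, `"T2"` or `"DWI"` (defaults to `"T1"` when unrecognized).
#' @export
sequence_family <- function(name) {
  n <- toupper(name)
  if (grepl("DWI", n)) "DWI" else if (grepl("T2|FLAIR", n)) "T2" else "T1"
}

# tissue intensities by contrast family: brain parenchyma, CSF/ventricle
FAMILY_INTENSITY <- list(T1 = c(brain = 0.60, csf = 0.15),
                         T2 = c(brain = 0.45, csf = 0.90),
                         DWI = c(brain = 0.40, csf = 0.25))

# normalized [0,1]^3 coordinate arrays for a volume of dims d
norm_coords <- function(d) {
  list(x = (slice.index(array(0, d), 1L) - 0.5) / d[1L],
       y = (slice.index(array(0, d), 2L) - 0.5) / d[2L],
       z = (slice.index(array(0, d), 3L) - 0.5) / d[3L])
}

# base head phantom in canonical (x, y, z) axial frame; returns intensities
# and the brain/ventricle masks used for lesion placement
head_phantom <- function(d, family, vent_scale = 1) {
  cc <- norm_coords(d)
  ii <- FAMILY_INTENSITY[[family]]
  brain <- ((cc$x - 0.5) / 0.40)^2 + ((cc$y - 0.5) / 0.44)^2 +
    ((cc$z - 0.5) / 0.46)^2 <= 1
  vox <- array(0, d)
  vox[brain] <- ii[["brain"]]
  vent <- array(FALSE, d)
  for (sgn in c(-1, 1)) {
    cx <- 0.5 + sgn * 0.10
    e <- ((cc$x - cx) / (0.055 * vent_scale))^2 +
      ((cc$y - 0.48) / (0.16 * vent_scale))^2 +
      ((cc$z - 0.55) / (0.10 * vent_scale))^2 <= 1
    vent <- vent | e
  }
  vent <- vent & brain
  vox[vent] <- ii[["csf"]]
  list(vox = vox, brain = brain, vent = vent, coords = cc)
}

# lesion geometries; each returns a logical mask in the canonical frame
lesion_mask_geom <- function(shape, cc, brain, center, size) {
  r2 <- ((cc$x - center[1]) / size)^2 + ((cc$y - center[2]) / size)^2 +
    ((cc$z - center[3]) / (1.4 * size))^2
  m <- switch(shape,
    sphere = r2 <= 1,
    ring = r2 <= 1 & r2 >= 0.35,
    wedge = {
      ang <- atan2(cc$y - 0.5, cc$x - 0.5)
      a0 <- atan2(center[2] - 0.5, center[1] - 0.5)
      dd <- abs(((ang - a0 + pi) %% (2 * pi)) - pi)
      rad <- sqrt((cc$x - 0.5)^2 + (cc$y - 0.5)^2)
      dd <= 0.55 & rad >= 0.12 & rad <= 0.42 & abs(cc$z - center[3]) <= size
    },
    stop("unknown lesion shape: ", shape))
  m & brain
}

# axis permutation taking a canonical axial array to the acquisition plane
plane_perm <- function(plane) {
  switch(plane, axial = c(1L, 2L, 3L), coronal = c(1L, 3L, 2L),
         sagittal = c(3L, 1L, 2L))
}

rician_noise <- function(vox, snr) {
  sigma <- if (is.finite(snr) && snr > 0) max(vox) / snr else 0
  if (sigma == 0) return(vox)
  n1 <- array(stats::rnorm(length(vox), sd = sigma), dim(vox))
  n2 <- array(stats::rnorm(length(vox), sd = sigma), dim(vox))
  sqrt((vox + n1)^2 + n2^2)
}

region_descriptor <- function(center) {
  side <- if (center[1] < 0.5) "left" else "right"
  lobe <- if (center[2] < 0.38) "frontal" else if (center[2] < 0.62)
    "parietal" else "occipital"
  paste(side, lobe, "region")
}

generator_preset <- function(size_preset) {
  switch(size_preset,
    desk = list(shapes = list(c(32L, 32L, 8L), c(40L, 40L, 8L), c(32L, 32L, 12L)),
                n_seq_range = c(2L, 4L), spacing = c(4, 4, 5), snr = 100),
    full = list(shapes = list(c(128L, 128L, 24L), c(160L, 160L, 24L),
                               c(128L, 128L, 32L)),
                 n_seq_range = c(2L, 8L), spacing = c(1.5, 1.5, 5), snr = 100),
    stop("unknown size preset: ", size_preset))
}

#' Generate one phantom MRI study with its report
#'
#' Builds a head phantom (ellipsoid "brain" with paired dark/bright
#' "ventricles" whose size grows linearly with age — the atrophy signal),
#' plants one geometric lesion per requested class in the contrast families
#' where the class is visible, adds magnitude (Rician-approximating) noise,
#' and writes one templated itemized finding per class.
#'
#' @param seed integer seed; the study is a deterministic function of it.
#' @param lesion_classes character vector of classes from the catalog
#'   (empty for a normal study).
#' @param size_preset `"desk"` (small volumes) or `"full"`.
#' @param catalog label catalog, see [default_label_catalog()].
#' @param snr signal-to-noise ratio of the magnitude noise (peak / sigma).
#' @return a list with elements `study` ([mri_study()], with ground-truth
#'   `lesion_masks`) and `report` (a `report_record`).
#' @export
generate_study <- function(seed, lesion_classes = character(),
                           size_preset = c("desk", "full"),
                           catalog = default_label_catalog(), snr = NULL) {
  size_preset <- match.arg(size_preset)
  lesion_classes <- as.character(lesion_classes)
  unknown <- setdiff(lesion_classes, catalog$classes)
  if (length(unknown) > 0L)
    stop("unknown lesion class: ", paste(unknown, collapse = ", "))
  if (length(catalog$classes) < 2L)
    stop("label catalog must have at least 2 classes")
  pg <- generator_preset(size_preset)
  if (is.null(snr)) snr <- pg$snr

  with_seed(seed, {
    m <- sample(pg$n_seq_range[1L]:pg$n_seq_range[2L], 1L)
    fams <- sample(c("T1", "T2", "DWI"), m, replace = TRUE)
    # guarantee every planted class is visible in at least one sequence
    for (cl in lesion_classes) {
      vis <- catalog$visible[[cl]]
      if (!any(fams %in% vis)) fams[sample.int(m, 1L)] <- sample(vis, 1L)
    }
    planes <- sample(PLANES, m, replace = TRUE)
    orients <- sample(ORIENTATIONS, m, replace = TRUE)
    shapes <- pg$shapes[sample.int(length(pg$shapes), m, replace = TRUE)]

    age <- stats::runif(1, 5, 90)
    atrophy <- pmin(pmax(0.004 * age + stats::rnorm(1, 0, 0.03), 0), 0.4)
    vent_scale <- 1 + atrophy
    if ("ventriculomegaly" %in% lesion_classes) vent_scale <- vent_scale * 2.2

    # one lesion placement per class, shared across sequences
    placements <- list()
    for (cl in lesion_classes) {
      placements[[cl]] <- list(
        center = c(stats::runif(1, 0.28, 0.72), stats::runif(1, 0.28, 0.72),
                   stats::runif(1, 0.35, 0.65)),
        size = stats::runif(1, 0.18, 0.28))
    }

    sequences <- vector("list", m)
    masks <- lapply(lesion_classes, function(cl) vector("list", m))
    names(masks) <- lesion_classes
    for (j in seq_len(m)) {
      d <- shapes[[j]]
      ph <- head_phantom(d, fams[j], vent_scale)
      vox <- ph$vox
      for (cl in lesion_classes) {
        if (!fams[j] %in% catalog$visible[[cl]]) next
        shp <- catalog$shape[[cl]]
        if (shp == "paired_ellipsoid") {
          mask <- ph$vent
        } else {
          pl <- placements[[cl]]
          mask <- lesion_mask_geom(shp, ph$coords, ph$brain, pl$center, pl$size)
          # class- and contrast-family-specific lesion intensity profiles
          if (shp == "sphere") {            # tumor: solid, brightest on T2
            vox[mask] <- if (fams[j] == "T2") 1.3 else 0.85
          } else if (shp == "ring") {       # abscess: rim on T1, core on DWI
            core <- lesion_mask_geom("sphere", ph$coords, ph$brain,
                                     pl$center, 0.55 * pl$size)
            if (fams[j] == "DWI") {
              vox[mask] <- 0.5
              vox[core] <- 1.2              # restricted diffusion in the core
            } else {
              vox[mask] <- 1.05
              vox[core] <- 0.15             # hypointense core
            }
          } else if (shp == "wedge") {      # infarct: strongest on DWI
            vox[mask] <- if (fams[j] == "DWI") 0.95 else 0.7
          }
        }
        masks[[cl]][[j]] <- mask
      }
      vox <- rician_noise(vox, snr)
      perm <- plane_perm(planes[j])
      vox <- aperm(vox, perm)
      for (cl in lesion_classes)
        if (!is.null(masks[[cl]][[j]]))
          masks[[cl]][[j]] <- aperm(masks[[cl]][[j]], perm)
      sequences[[j]] <- mri_volume(vox, spacing = pg$spacing[plane_perm(planes[j])],
                                   plane = planes[j], orientation = orients[j],
                                   sequence_name = make_sequence_name(planes[j], fams[j]))
    }

    labels <- stats::setNames(as.integer(catalog$classes %in% lesion_classes),
                              catalog$classes)
    findings <- character(0)
    for (cl in lesion_classes) {
      reg <- if (catalog$shape[[cl]] == "paired_ellipsoid") "lateral ventricles"
             else region_descriptor(placements[[cl]]$center)
      findings <- c(findings, paste(cl, "in", reg))
    }
    acuity <- if (length(lesion_classes) == 0L) "normal" else
      ACUITY_LEVELS[max(match(catalog$acuity[lesion_classes], ACUITY_LEVELS))]
    referrals <- stats::setNames(integer(length(catalog$referrals)),
                                 catalog$referrals)
    for (cl in lesion_classes) referrals[catalog$referral[[cl]]] <- 1L

    study <- mri_study(
      study_name = sample(c("MRI BRAIN WITHOUT CONTRAST",
                            "MRI BRAIN WITH AND WITHOUT CONTRAST"), 1L),
      sequences = sequences,
      patient_id = sprintf("P%08d", seed %% 99999999L),
      abnormal = length(lesion_classes) > 0L,
      lesion_masks = masks)
    report <- report_record(findings, labels, acuity, age, referrals)
    list(study = study, report = report)
  })
}

# subgroup metadata ------------------------------------------------------------

SUBGROUP_LEVELS <- list(
  region = c("urban", "suburban", "rural"),
  schedule = c("weekday", "weekend"),
  sex = c("female", "male"),
  age_band = c("0-18", "19-45", "46-70", "71+"),
  insurer = c("public", "private"),
  scanner = c("scanner_A", "scanner_B", "scanner_C"))

age_band_of <- function(age) {
  SUBGROUP_LEVELS$age_band[findInterval(age, c(0, 19, 46, 71))]
}

#' Generate a cohort of phantom studies with subgroup metadata
#'
#' Diagnosis classes are planted independently per study at the requested
#' prevalences. Turnaround time is drawn through a dichotomized "late report"
#' indicator (> `late_threshold` days) whose odds are multiplied per matching
#' `bias_spec` attribute level, so planted odds ratios are recoverable by
#' [odds_ratio_fisher()].
#'
#' @param n number of studies (>= 1).
#' @param class_prevalences named numeric vector of per-class prevalences in
#'   \[0,1\] (names from the catalog; unnamed values recycle over the catalog).
#' @param bias_spec named list: attribute -> named vector of odds multipliers
#'   for the late-report indicator (e.g. `list(region = c(rural = 4))`).
#' @param seed integer seed.
#' @param size_preset `"desk"` or `"full"`.
#' @param catalog label catalog.
#' @param base_late_prob baseline probability of a late report.
#' @param late_threshold days; the dichotomization point for "late".
#' @return list of entries, each with `study`, `report` and `meta`
#'   (attributes + `turnaround_days`).
#' @export
generate_cohort <- function(n, class_prevalences = 0.25, bias_spec = list(),
                            seed = 1L, size_preset = c("desk", "full"),
                            catalog = default_label_catalog(),
                            base_late_prob = 0.25, late_threshold = 7) {
  if (n < 1L) stop("n must be >= 1")
  size_preset <- match.arg(size_preset)
  prev <- class_prevalences
  if (is.null(names(prev)))
    prev <- stats::setNames(rep_len(prev, length(catalog$classes)), catalog$classes)
  if (any(prev < 0 | prev > 1)) stop("prevalences must be in [0,1]")
  for (attr in names(bias_spec)) {
    if (!attr %in% names(SUBGROUP_LEVELS)) stop("unknown attribute: ", attr)
    bad <- setdiff(names(bias_spec[[attr]]), SUBGROUP_LEVELS[[attr]])
    if (length(bad)) stop("unknown level for ", attr, ": ", bad[1])
  }
  with_seed(seed, {
    study_seeds <- sample.int(2^30, n)
    entries <- vector("list", n)
    for (i in seq_len(n)) {
      planted <- names(prev)[stats::runif(length(prev)) < prev]
      sr <- generate_study(study_seeds[i], planted, size_preset, catalog)
      attrs <- lapply(SUBGROUP_LEVELS, function(lv) sample(lv, 1L))
      attrs$age_band <- age_band_of(sr$report$age)
      odds <- base_late_prob / (1 - base_late_prob)
      for (attr in names(bias_spec)) {
        mult <- bias_spec[[attr]]
        lev <- attrs[[attr]]
        if (lev %in% names(mult)) odds <- odds * mult[[lev]]
      }
      p_late <- odds / (1 + odds)
      late <- stats::runif(1) < p_late
      turnaround <- if (late) late_threshold + stats::rexp(1, 1 / 3)
                    else stats::runif(1, 0.1, late_threshold)
      entries[[i]] <- list(study = sr$study, report = sr$report,
                           meta = c(attrs, list(turnaround_days = turnaround)))
    }
    entries
  })
}

#' Subgroup metadata table of a cohort
#'
#' @param cohort output of [generate_cohort()].
#' @return a data.frame with one row per study: patient id, abnormal flag,
#'   labels, acuity, age, subgroup attributes and turnaround days.
#' @export
cohort_metadata <- function(cohort) {
  do.call(rbind, lapply(cohort, function(e) {
    data.frame(patient_id = e$study$patient_id,
               abnormal = e$study$abnormal,
               t(e$report$labels),
               acuity = e$report$acuity,
               age = e$report$age,
               region = e$meta$region, schedule = e$meta$schedule,
               sex = e$meta$sex, age_band = e$meta$age_band,
               insurer = e$meta$insurer, scanner = e$meta$scanner,
               turnaround_days = e$meta$turnaround_days,
               stringsAsFactors = FALSE)
  }))
}
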