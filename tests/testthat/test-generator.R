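# Phantom generator: determinism, label/lesion/finding consistency, cohort
# prevalence bounds, and recoverability of planted turnaround-time bias.

test_that("normal studies satisfy the all-zero invariant chain", {
  sr <- generate_study(1, character())
  expect_false(sr$study$abnormal)
  expect_true(all(sr$report$labels == 0))
  expect_identical(sr$report$acuity, "normal")
  expect_length(sr$report$findings, 0)
  expect_identical(report_text(sr$report), "")
})

test_that("a planted tumor yields one finding and a recorded lesion mask", {
  sr <- generate_study(2, "tumor")
  expect_true(sr$study$abnormal)
  expect_identical(unname(sr$report$labels["tumor"]), 1L)
  expect_length(sr$report$findings, 1)
  expect_match(sr$report$findings[1], "^tumor in ")
  masks <- sr$study$lesion_masks$tumor
  expect_true(any(vapply(masks, function(m) !is.null(m) && any(m), TRUE)))
  # the mask is visible only in T1/T2 family sequences
  fams <- vapply(sr$study$sequences, function(s) sequence_family(s$sequence_name), "")
  for (j in seq_along(masks))
    if (!is.null(masks[[j]])) expect_true(fams[j] %in% c("T1", "T2"))
})

test_that("generation is bitwise deterministic given the seed", {
  a <- generate_study(2, "tumor")
  b <- generate_study(2, "tumor")
  expect_identical(a, b)
  expect_identical(generate_cohort(3, 0.5, seed = 9),
                   generate_cohort(3, 0.5, seed = 9))
})

test_that("unknown lesion classes and bad cohort arguments error", {
  expect_error(generate_study(1, "gliosis"), "unknown lesion class")
  expect_error(generate_cohort(0), "n must be")
  expect_error(generate_cohort(2, 1.5), "prevalences")
  expect_error(generate_cohort(2, 0.5, bias_spec = list(region = c(mars = 2))),
               "unknown level")
})

test_that("label <-> lesion <-> finding consistency holds across a cohort", {
  cohort <- fix_cohort()
  for (e in cohort) {
    pos <- names(e$report$labels)[e$report$labels == 1]
    expect_setequal(names(e$study$lesion_masks), pos)
    expect_length(e$report$findings, length(pos))
    for (cl in pos) expect_true(any(grepl(paste0("^", cl, " in "),
                                          e$report$findings)))
    expect_identical(e$study$abnormal, length(pos) > 0)
  }
})

test_that("empirical prevalence stays within 3 binomial SD of target", {
  cohort <- generate_cohort(200, c(tumor = 0.5, abscess = 0, ventriculomegaly = 0,
                                   infarct = 0), seed = 7)
  npos <- sum(vapply(cohort, function(e) e$report$labels[["tumor"]], 1L))
  expect_within(npos, 200 * 0.5 - 3 * sqrt(200 * 0.25),
                200 * 0.5 + 3 * sqrt(200 * 0.25))
})

test_that("sequence counts and heterogeneous shapes are as configured", {
  cohort <- fix_cohort()
  m <- vapply(cohort, function(e) length(e$study$sequences), 1L)
  expect_true(all(m >= 2 & m <= 4))
  shp <- unique(unlist(lapply(cohort, function(e)
    lapply(e$study$sequences, function(s) paste(sort(dim(s$voxels)), collapse = "x")))))
  expect_gt(length(shp), 1)
})

test_that("acuity follows the configurable mapping with max severity", {
  catalog <- default_label_catalog()
  sr <- generate_study(5, c("tumor", "abscess"))
  expect_identical(sr$report$acuity, "high")  # tumor outranks abscess
  sr2 <- generate_study(6, "abscess")
  expect_identical(sr2$report$acuity, "medium")
  expect_identical(unname(sr2$report$referrals["neurosurgery"]), 1L)
})

test_that("a planted x4 turnaround odds ratio is recovered within its CI", {
  cohort <- generate_cohort(400, 0.2, bias_spec = list(region = c(rural = 4)),
                            seed = 31)
  meta <- cohort_metadata(cohort)
  late <- meta$turnaround_days > 7
  rural <- meta$region == "rural"
  res <- odds_ratio_fisher(c(sum(late & rural), sum(!late & rural)),
                           c(sum(late & !rural), sum(!late & !rural)))
  expect_within(4, res$ci[1], res$ci[2])
  expect_gt(res$or, 1.8)
})

test_that("without planted bias, odds-ratio CIs cover 1 across levels", {
  cohort <- generate_cohort(300, 0.2, seed = 17)
  meta <- cohort_metadata(cohort)
  covered <- 0L; total <- 0L
  for (attr in c("region", "schedule", "sex", "insurer", "scanner")) {
    res <- audit_turnaround_bias(meta, attr)
    total <- total + nrow(res)
    covered <- covered + sum(res$ci_lo <= 1 & res$ci_hi >= 1)
  }
  expect_gte(covered / total, 18 / 20)
})

test_that("age drives the ventricular atrophy signal monotonically", {
  # regenerate the same seed twice with different forced ages via the cohort
  ages <- c(); vent_frac <- c()
  for (s in 1:12) {
    sr <- generate_study(100 + s, character())
    t2 <- which(vapply(sr$study$sequences, function(x)
      sequence_family(x$sequence_name) == "T2", TRUE))
    if (length(t2) == 0) next
    v <- sr$study$sequences[[t2[1]]]$voxels
    ages <- c(ages, sr$report$age)
    vent_frac <- c(vent_frac, mean(v > 0.8))  # bright CSF fraction on T2
  }
  expect_gt(cor(ages, vent_frac), 0.3)
})
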