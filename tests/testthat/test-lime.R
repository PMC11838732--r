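# LIME: mask sampling statistics, exact recovery for mask-affine models,
# ranking invariances, and overlap-accuracy arithmetic.

test_that("mask sampling honors keep_prob, non-emptiness and determinism", {
  m <- sample_masks(10, 50, keep_prob = 1, seed = 1)
  expect_true(all(m == 1))
  m2 <- sample_masks(10, 3000, keep_prob = 0.5, seed = 2)
  expect_true(all(rowSums(m2) >= 1))
  expect_true(all(m2[1, ] == 1))  # all-ones mask included once
  mean_bits <- mean(rowSums(m2))
  sd3 <- 3 * sqrt(10 * 0.25 / 3000)
  expect_within(mean_bits, 5 - sd3 - 0.1, 5 + sd3 + 0.1)
  expect_identical(m2, sample_masks(10, 3000, keep_prob = 0.5, seed = 2))
})

test_that("an affine-in-mask model is recovered exactly", {
  set.seed(3)
  for (trial in 1:10) {
    n_tok <- sample(5:12, 1)
    a <- rnorm(1); b <- rnorm(n_tok)
    masks <- sample_masks(n_tok, 200, 0.5, seed = trial)
    logits <- as.vector(a + masks %*% b)
    ex <- lime_fit(masks, logits)
    expect_lt(max(abs(ex$weights - b)), 1e-6)
    expect_lt(abs(ex$intercept - a), 1e-6)
    # ranking invariant to a constant offset of the model output
    ex2 <- lime_fit(masks, logits + 100)
    expect_identical(ex$ranking, ex2$ranking)
  }
})

test_that("a token the model ignores gets negligible weight", {
  set.seed(4)
  b <- c(2, 0, -1.5, 0.8, 0)
  masks <- sample_masks(5, 300, 0.5, seed = 9)
  logits <- as.vector(masks %*% b) + rnorm(300, sd = 1e-4)
  ex <- lime_fit(masks, logits)
  expect_lt(abs(ex$weights[2]), 0.01 * max(abs(ex$weights)))
  expect_lt(abs(ex$weights[5]), 0.01 * max(abs(ex$weights)))
})

test_that("degenerate designs are rejected", {
  masks <- matrix(1L, 50, 4)
  expect_error(lime_fit(masks, rnorm(50)), "degenerate")
})

test_that("ranking ties break by lexicographic grid coordinate", {
  masks <- sample_masks(4, 200, 0.5, seed = 5)
  logits <- as.vector(masks %*% c(1, 1, 2, 0))
  gc <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L), c(2L, 0L, 0L))
  ex <- lime_fit(masks, logits, grid_coords = gc)
  expect_equal(ex$ranking[1], 3)           # unique max
  expect_equal(ex$ranking[2:3], c(2, 1))   # tie: (0,1,0) before (1,0,0)
})

test_that("overlap accuracy matches its closed-form random baseline", {
  expect_equal(topk_overlap_accuracy(
    list(structure(list(weights = c(3, 1), ranking = c(1L, 2L),
                        grid_coords = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))),
                   class = "lime_explanation")),
    list(rbind(c(0L, 0L, 0L))), k = 1), 1.0)
  # random rankings, lesion 10% of tokens, k = 3: about 1 - 0.9^3
  set.seed(6)
  n_tok <- 30
  les <- rbind(c(0L, 0L, 0L), c(1L, 0L, 0L), c(2L, 0L, 0L))
  gcs <- cbind(0:(n_tok - 1L), 0L, 0L)
  acc <- mean(replicate(400, {
    rk <- sample(n_tok)
    topk_overlap_accuracy(list(structure(list(weights = rnorm(n_tok),
                                              ranking = rk, grid_coords = gcs),
                                         class = "lime_explanation")),
                          list(les), k = 3)
  }))
  expect_equal(acc, 1 - (27 / 30) * (26 / 29) * (25 / 28), tolerance = 0.08)
  # k = n_tokens always hits a non-empty lesion set
  expect_equal(topk_overlap_accuracy(
    list(structure(list(weights = rnorm(n_tok), ranking = sample(n_tok),
                        grid_coords = gcs), class = "lime_explanation")),
    list(les), k = n_tok), 1.0)
  expect_warning(topk_overlap_accuracy(
    list(structure(list(weights = 1:2, ranking = 1:2,
                        grid_coords = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))),
                   class = "lime_explanation"),
         structure(list(weights = 1:2, ranking = 1:2,
                        grid_coords = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))),
                   class = "lime_explanation")),
    list(matrix(integer(0), 0, 3), rbind(c(0L, 0L, 0L))), k = 1), "excluded")
})

test_that("heat volumes paint each patch with its token weight", {
  cfg <- desk_tokenizer_config()
  ex <- structure(list(weights = c(2, -1),
                       ranking = c(1L, 2L),
                       grid_coords = rbind(c(0L, 0L, 0L), c(1L, 0L, 0L))),
                  class = "lime_explanation")
  h <- lime_heat_volume(ex, c(12L, 8L, 4L), cfg)
  expect_equal(h[1, 1, 1], 2)
  expect_equal(h[9, 1, 1], -1)
  expect_equal(h[12, 8, 4], -1)  # truncated boundary patch
  f <- tempfile(fileext = ".nii.gz")
  lime_heat_volume(ex, c(12L, 8L, 4L), cfg, file = f)
  expect_equal(array(as.numeric(RNifti::readNifti(f)), c(12, 8, 4)), h,
               tolerance = 1e-6)
  unlink(f)
})

test_that("explanations through the encoder are seed-reproducible", {
  model <- fix_model()
  cohort <- fix_cohort()
  idx <- which(vapply(cohort, function(e) e$report$labels[["tumor"]] == 1, TRUE))[1]
  ts <- fix_tokenized()[[idx]]
  sq_idx <- which(vapply(ts$sequences, function(s) length(s$tokens) >= 2, TRUE))[1]
  # an untrained head suffices for the reproducibility contract
  emb <- encode_study_embedding(model, ts)
  fit <- train_head(matrix(rnorm(20 * length(emb)), 20),
                    rbinom(20, 1, 0.5) * 0 + c(rep(0, 10), rep(1, 10)),
                    head_config("probe", length(emb)), seed = 2, epochs = 3)
  fit$positive_weights <- c(tumor = 1)
  ex1 <- lime_explain(model, fit, ts, sq_idx, "tumor", n_samples = 40, seed = 8)
  ex2 <- lime_explain(model, fit, ts, sq_idx, "tumor", n_samples = 40, seed = 8)
  expect_identical(ex1, ex2)
  expect_length(ex1$weights, length(ts$sequences[[sq_idx]]$tokens))
  expect_setequal(ex1$ranking, seq_along(ex1$weights))
})
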