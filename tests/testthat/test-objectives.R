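# Training objectives: CLIP loss against closed-form softmax cross-entropy,
# the patient-discrimination loss against an independently coded brute-force
# oracle, the combined loss, augmentation contracts and the upsampler.

# independent brute-force evaluation of the discrimination objective:
# cosine logits / tau_p, optional -10 self-logits, row softmax, -log of the
# same-study probability mass, weighted 1/(k * n_i)
patdis_oracle <- function(U, groups, tau_p, pseudocode = TRUE) {
  Un <- U / sqrt(rowSums(U^2))
  L <- (Un %*% t(Un)) / tau_p
  if (pseudocode) diag(L) <- -10
  total <- 0
  k <- length(unique(groups))
  for (i in seq_len(nrow(U))) {
    p <- exp(L[i, ] - max(L[i, ]))
    p <- p / sum(p)
    total <- total + (-log(sum(p[groups == groups[i]]))) /
      (k * sum(groups == groups[i]))
  }
  total
}

test_that("clip loss matches the hand-computed 2x2 softmax cross-entropy", {
  v <- rbind(c(1, 0), c(0, 1))
  tau <- 0.07
  s <- exp(tau) * (v %*% t(v))
  ce_row <- function(M) mean(vapply(1:2, function(i)
    log(sum(exp(M[i, ]))) - M[i, i], 1))
  expect_equal(clip_loss(v, v, tau), ce_row(s) + ce_row(t(s)), tolerance = 1e-9)
  # k = 1 is forced to zero; identical pair order permutations are symmetric
  expect_equal(clip_loss(matrix(c(1, 2), 1), matrix(c(1, 1), 1)), 0)
  set.seed(3)
  a <- matrix(rnorm(12), 4, 3); b <- matrix(rnorm(12), 4, 3)
  p <- sample(4)
  expect_equal(clip_loss(a, b), clip_loss(a[p, ], b[p, ]), tolerance = 1e-12)
  expect_gte(clip_loss(a, b), 0)
  expect_error(clip_loss(rbind(c(0, 0)), rbind(c(1, 0))), "zero-norm")
})

test_that("discrimination loss matches the brute-force oracle on small batches", {
  set.seed(11)
  for (trial in 1:25) {
    k <- sample(2:4, 1)
    ni <- sample(1:3, k, replace = TRUE)
    groups <- rep(seq_len(k), ni)
    U <- matrix(rnorm(length(groups) * 5), ncol = 5)
    for (conv in c("pseudocode", "equation")) {
      got <- patient_discrimination_loss(U, groups, tau_p = 0.1,
                                         convention = conv)
      expect_equal(got, patdis_oracle(U, groups, 0.1, conv == "pseudocode"),
                   tolerance = 1e-10)
    }
  }
})

test_that("discrimination loss on the structured 2x2 case and its limits", {
  # two studies x two sequences: identical within, orthogonal across
  U <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  g <- c(1, 1, 2, 2)
  expect_equal(patient_discrimination_loss(U, g, tau_p = 0.1),
               patdis_oracle(U, g, 0.1), tolerance = 1e-8)
  # all identical: same-study mass is about the in-study fraction of the batch
  Uc <- matrix(1, 6, 3) + matrix(rnorm(18, sd = 1e-9), 6, 3)
  gc <- c(1, 1, 1, 2, 2, 2)
  expect_equal(patient_discrimination_loss(Uc, gc, tau_p = 0.1),
               patdis_oracle(Uc, gc, 0.1), tolerance = 1e-8)
  # raising within-study similarity lowers the loss when every cross-study
  # similarity is pinned at zero (partner rotated in an orthogonal plane)
  pd_theta <- function(theta) patient_discrimination_loss(
    rbind(c(1, 0, 0), c(cos(theta), sin(theta), 0), c(0, 0, 1), c(0, 0, -1)),
    c(1, 1, 2, 2), tau_p = 0.1)
  expect_lt(pd_theta(0.2), pd_theta(1.0))
  expect_error(patient_discrimination_loss(U, rep(1, 4)), ">= 2 studies")
})

test_that("combined loss is clip + lambda * patdis, with gradient linearity", {
  expect_equal(combined_loss(1, 2, 0.03), 1.06)
  expect_equal(combined_loss(5, 7, 0), 5)
  ag <- asNamespace("radclip")
  p <- ag$ag_param(matrix(2, 1, 1))
  la <- ag$ag_square(p)           # d/dp = 2p = 4
  lb <- ag$ag_scale(p, 3)         # d/dp = 3
  ag$ag_backward(combined_loss(la, lb, 0.5))
  expect_equal(p$grad[1], 4 + 0.5 * 3)
})

test_that("augmentation respects its contracts", {
  ts <- fix_tokenized()[[which(vapply(fix_cohort(), function(e)
    sum(e$report$labels) >= 2, TRUE))[1]]]
  e <- fix_cohort()[[which(vapply(fix_cohort(), function(e)
    sum(e$report$labels) >= 2, TRUE))[1]]]
  # all probabilities zero: identity
  p0 <- augment_policy(0, 0, 0, 0, 0)
  out <- augment_pair(ts, e$report, p0, seed = 4)
  expect_identical(out$study, ts)
  expect_identical(out$report, e$report)
  # shuffle-only preserves the findings multiset and the labels
  ps <- augment_policy(1, 0, 0, 0, 0)
  out2 <- augment_pair(ts, e$report, ps, seed = 5)
  expect_setequal(out2$report$findings, e$report$findings)
  expect_identical(out2$report$labels, e$report$labels)
  # sequence drop probability 1 leaves exactly the minimum of one sequence
  pd <- augment_policy(0, 0, 0, 1, 0)
  out3 <- augment_pair(ts, e$report, pd, seed = 6)
  expect_length(out3$study$sequences, 1)
  # token drop never empties a sequence
  pt <- augment_policy(0, 1, 0, 0, 0)
  out4 <- augment_pair(ts, e$report, pt, seed = 7)
  for (sq in out4$study$sequences) expect_gte(length(sq$tokens), 1)
  # unk-name replacement hits every sequence at probability 1
  pu <- augment_policy(0, 0, 1, 0, 0)
  out5 <- augment_pair(ts, e$report, pu, seed = 8)
  expect_true(all(vapply(out5$study$sequences, function(s) s$name, "") == "unk"))
})

test_that("the abnormal upsampler multiplies abnormal studies by the factor", {
  flags <- c(rep(FALSE, 10), rep(TRUE, 10))
  stream <- abnormal_upsampler(flags, factor = 4, seed = 1)
  expect_length(stream, 10 + 4 * 10)
  counts <- table(stream)
  expect_true(all(counts[as.character(1:10)] == 1))    # normal census conserved
  expect_true(all(counts[as.character(11:20)] == 4))
  expect_length(abnormal_upsampler(flags, factor = 1, seed = 2), 20)
  expect_warning(abnormal_upsampler(rep(FALSE, 5), factor = 4, seed = 3),
                 "identity")
})

test_that("upsampled abnormal fraction matches its expectation", {
  flags <- c(rep(FALSE, 30), rep(TRUE, 10))
  fr <- vapply(1:100, function(s)
    mean(abnormal_upsampler(flags, 4, s) > 30), 1)
  expect_equal(mean(fr), 40 / 70, tolerance = 1e-12)  # deterministic census
})
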