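# Fairness audit: TPR counting, disparity identity and bounds, bootstrap
# calibration and power, Fisher/odds-ratio oracles, and the superiority
# sample-size formula.

mk_table <- function(n, tpr_pos = 0.8, seed = 1) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  y_hat <- ifelse(y == 1, rbinom(n, 1, tpr_pos), rbinom(n, 1, 0.1))
  data.frame(y = y, y_hat = y_hat)
}

test_that("TPR is the exact count ratio and errors without positives", {
  tab <- data.frame(y = c(1, 1, 1, 1, 0), y_hat = c(1, 1, 1, 0, 1))
  expect_equal(tpr(tab), 0.75)
  expect_equal(tpr(data.frame(y = 1, y_hat = 1)), 1.0)
  expect_error(tpr(data.frame(y = 0, y_hat = 0)), "TPR undefined")
  set.seed(2)
  tab2 <- mk_table(200)
  oracle <- sum(tab2$y == 1 & tab2$y_hat == 1) / sum(tab2$y == 1)
  expect_equal(tpr(tab2), oracle)
})

test_that("disparity is zero for the whole population and stays in [-1, 1]", {
  tab <- mk_table(300)
  expect_equal(tpr_disparity(tab, seq_len(nrow(tab)))$disparity, 0)
  set.seed(3)
  for (trial in 1:200) {
    t2 <- mk_table(40, tpr_pos = runif(1, 0.2, 1), seed = trial)
    g <- sample(40, 15)
    if (!any(t2$y[g] == 1)) next
    d <- tpr_disparity(t2, g)$disparity
    expect_within(d, -1, 1)
  }
  tab3 <- data.frame(y = c(1, 1, 1, 1, 1, 1, 1, 1),
                     y_hat = c(1, 1, 1, 0, 0, 1, 1, 1))
  g <- 1:5  # group TPR 0.6 vs population 0.75
  expect_equal(tpr_disparity(tab3, g)$disparity, 0.6 - 0.75)
})

test_that("null bootstrap rarely flags an unbiased random subgroup", {
  # health-system regime: draws much smaller than the subgroup, so the
  # bootstrap spread dominates the subgroup's own sampling noise
  flagged <- 0L
  for (s in 1:20) {
    tab <- mk_table(8000, seed = 100 + s)
    set.seed(1000 + s)
    g <- sample(8000, 2500)
    res <- bootstrap_disparity_test(tab, g, n_per_draw = 200, iterations = 20,
                                    seed = s)
    if (res$p_value <= 0.05) flagged <- flagged + 1L
  }
  expect_lte(flagged, 2L)
})

test_that("a strongly disadvantaged subgroup is detected with power", {
  detected <- 0L
  for (s in 1:20) {
    set.seed(500 + s)
    n <- 500
    g <- seq_len(150)
    y <- rbinom(n, 1, 0.4)
    grp <- seq_len(n) %in% g
    y_hat <- ifelse(y == 1, rbinom(n, 1, ifelse(grp, 0.3, 0.9)),
                    rbinom(n, 1, 0.1))
    tab <- data.frame(y = y, y_hat = y_hat)
    res <- bootstrap_disparity_test(tab, g, n_per_draw = 100, iterations = 20,
                                    seed = s)
    if (res$p_value < 0.05) detected <- detected + 1L
    expect_lt(res$disparity, 0)
  }
  expect_gte(detected, 18L)
})

test_that("the point disparity lies within the bootstrap spread", {
  covered <- 0L
  for (s in 1:10) {
    tab <- mk_table(300, seed = 50 + s)
    g <- sample(300, 100)
    res <- bootstrap_disparity_test(tab, g, n_per_draw = 150, iterations = 20,
                                    seed = s)
    dr <- res$draws[, "group"] - res$draws[, "population"]
    if (res$disparity >= min(dr) && res$disparity <= max(dr))
      covered <- covered + 1L
  }
  expect_gte(covered, 9L)
})

test_that("odds ratios and Fisher p-values match exact oracles", {
  expect_equal(odds_ratio_fisher(c(10, 10), c(10, 10))$or, 1)
  res <- odds_ratio_fisher(c(20, 10), c(10, 20))
  expect_equal(res$or, 4)
  expect_equal(res$p, fisher.test(matrix(c(20, 10, 10, 20), 2, byrow = TRUE))$p.value)
  # hypergeometric enumeration oracle for small tables
  set.seed(9)
  for (trial in 1:20) {
    a <- sample(0:15, 1); b <- sample(1:15, 1)
    c_ <- sample(1:15, 1); d <- sample(0:15, 1)
    if ((a + b) == 0 || (c_ + d) == 0) next
    m <- matrix(c(a, b, c_, d), 2, byrow = TRUE)
    # two-sided exact conditional p: sum of hypergeometric probabilities
    # not exceeding that of the observed table
    k1 <- a + b; k0 <- c_ + d; mpos <- a + c_
    xs <- max(0, mpos - k0):min(k1, mpos)
    ph <- dhyper(xs, k1, k0, mpos)
    p_or <- sum(ph[ph <= dhyper(a, k1, k0, mpos) * (1 + 1e-7)])
    expect_equal(odds_ratio_fisher(c(a, b), c(c_, d))$p, p_or, tolerance = 1e-6)
  }
  expect_true(odds_ratio_fisher(c(0, 10), c(5, 5))$corrected)
  expect_error(odds_ratio_fisher(c(-1, 2), c(1, 1)), "negative")
})

test_that("the superiority sample-size formula reproduces its oracle", {
  # z-quantile hand computation
  n_oracle <- function(p1, p2, margin, alpha, power) {
    z <- qnorm(1 - alpha) + qnorm(power)
    per <- ceiling(z^2 * (p1 * (1 - p1) + p2 * (1 - p2)) / (p2 - p1 - margin)^2)
    2 * per
  }
  expect_equal(superiority_sample_size(0.78, 0.78, 0.02, 0.01, 0.90),
               n_oracle(0.78, 0.78, 0.02, 0.01, 0.90))
  # doubling the margin shrinks the total about fourfold
  n1 <- superiority_sample_size(0.78, 0.78, 0.02, 0.01, 0.90)
  n2 <- superiority_sample_size(0.78, 0.78, 0.04, 0.01, 0.90)
  expect_equal(n1 / n2, 4, tolerance = 0.01)
  # monotonicity: decreasing in margin, increasing in power
  expect_gt(superiority_sample_size(0.7, 0.7, 0.01, 0.05, 0.8),
            superiority_sample_size(0.7, 0.7, 0.03, 0.05, 0.8))
  expect_gt(superiority_sample_size(0.7, 0.7, 0.02, 0.05, 0.95),
            superiority_sample_size(0.7, 0.7, 0.02, 0.05, 0.8))
  expect_error(superiority_sample_size(0, 0.5, 0.1), "proportions")
  expect_error(superiority_sample_size(0.5, 0.5, -0.1), "margin")
})

test_that("the turnaround audit applies family-wise correction", {
  cohort <- generate_cohort(150, 0.2, seed = 77)
  meta <- cohort_metadata(cohort)
  res <- audit_turnaround_bias(meta, "region")
  expect_equal(nrow(res), 2)
  expect_true(all(res$p_adj >= res$p))
})
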