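# Evaluation metrics: retrieval accuracy, grouped retrieval, multi-label
# AUROC, neighbor-based normalized positive rate (NPR), and priority-score
# correlation.

#' Top-k retrieval accuracy
#'
#' Fraction of rows of a study-by-report similarity matrix whose matched
#' (diagonal) entry ranks among the k largest; ties break toward the lowest
#' column index. Monotone non-decreasing in k.
#'
#' @param sim N x N similarity matrix, row i / column i the matched pair.
#' @param k number of retrieval candidates (k <= N).
#' @return accuracy in \[0,1\].
#' @export
topk_retrieval <- function(sim, k = 1L) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  stopifnot(k >= 1L, k <= n, ncol(sim) == n)
  hits <- vapply(seq_len(n), function(i) {
    i %in% order(-sim[i, ])[seq_len(k)]
  }, TRUE)
  mean(hits)
}

#' Grouped Top-1 retrieval
#'
#' Randomly partitions the N matched pairs into disjoint groups of
#' `group_size`, computes Top-1 retrieval within each group's submatrix and
#' averages across groups. Remainder items (N mod group_size) are dropped.
#'
#' @param sim N x N similarity matrix (N >= group_size).
#' @param group_size items per group.
#' @param seed integer seed for the random grouping.
#' @return mean within-group Top-1 accuracy.
#' @export
grouped_retrieval <- function(sim, group_size = 100L, seed = 1L) {
  sim <- as.matrix(sim)
  n <- nrow(sim)
  if (n < group_size) stop("need at least one full group of ", group_size)
  n_groups <- n %/% group_size
  dropped <- n - n_groups * group_size
  if (dropped > 0L)
    message(dropped, " items dropped (incomplete final group)")
  with_seed(seed, {
    perm <- sample.int(n)
    accs <- vapply(seq_len(n_groups), function(g) {
      idx <- perm[((g - 1L) * group_size + 1L):(g * group_size)]
      topk_retrieval(sim[idx, idx, drop = FALSE], 1L)
    }, 1)
    mean(accs)
  })
}

#' Per-label and mean AUROC for multi-label scores
#'
#' Rank-based (Mann-Whitney) AUROC with midranks for ties. Labels observed
#' in only one class are reported as `NA` and excluded from the mean with a
#' warning.
#'
#' @param scores n x L numeric score matrix.
#' @param labels n x L binary label matrix.
#' @return list with `per_label` (named numeric vector) and `mean`.
#' @export
multilabel_auroc <- function(scores, labels) {
  scores <- as.matrix(scores); labels <- as.matrix(labels)
  stopifnot(identical(dim(scores), dim(labels)))
  per <- vapply(seq_len(ncol(scores)), function(j) {
    y <- labels[, j]
    n1 <- sum(y == 1); n0 <- sum(y == 0)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(scores[, j])
    (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 1)
  names(per) <- colnames(scores)
  if (anyNA(per))
    warning("labels with a single observed class excluded from the mean")
  list(per_label = per, mean = mean(per, na.rm = TRUE))
}

#' Normalized positive rate of nearest neighbors
#'
#' For each query embedding, the positive-label rate among its k nearest
#' reference neighbors (cosine similarity) divided by the reference base
#' rate. The expected value under random labeling is 1. Returned are the
#' mean over all queries and the mean over positive queries only. When the
#' queries are the reference set itself (`self_exclude = TRUE`), each
#' query's own row is removed from its neighbor list.
#'
#' @param embeddings_query q x d matrix.
#' @param embeddings_reference n x d matrix.
#' @param labels_reference binary vector of length n.
#' @param query_labels binary vector of length q (used only to split out the
#'   positive-query mean).
#' @param k neighbors per query.
#' @param self_exclude drop neighbor i for query i (requires aligned sets).
#' @return list with `mean_all`, `mean_positive` and per-query `npr`.
#' @export
npr <- function(embeddings_query, embeddings_reference, labels_reference,
                query_labels = NULL, k = 20L, self_exclude = FALSE) {
  q <- as.matrix(embeddings_query)
  r <- as.matrix(embeddings_reference)
  base <- mean(labels_reference)
  if (base == 0) stop("reference base rate is zero for this label")
  qn <- q / sqrt(rowSums(q^2))
  rn <- r / sqrt(rowSums(r^2))
  sims <- qn %*% t(rn)
  vals <- vapply(seq_len(nrow(q)), function(i) {
    s <- sims[i, ]
    if (self_exclude) s[i] <- -Inf
    nb <- order(-s)[seq_len(k)]
    mean(labels_reference[nb]) / base
  }, 1)
  list(mean_all = mean(vals),
       mean_positive = if (!is.null(query_labels) && any(query_labels == 1))
         mean(vals[query_labels == 1]) else NA_real_,
       npr = vals)
}

#' Correlation between predicted priority scores and ordinal truth
#'
#' Pearson correlation (per the prospective evaluation protocol) of the
#' normalized priority score in \[0,1\] against the three-tier ordinal truth
#' coded 0/1/2, with a Fisher-z 95% confidence interval. Spearman rank
#' correlation is available behind `method`.
#'
#' @param priority_score numeric vector in \[0,1\].
#' @param priority_truth integer vector in `{0,1,2}`.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param conf_level confidence level of the Fisher-z interval.
#' @return list with `r`, `ci` (length 2) and `n`.
#' @export
priority_correlation <- function(priority_score, priority_truth,
                                 method = c("pearson", "spearman"),
                                 conf_level = 0.95) {
  method <- match.arg(method)
  n <- length(priority_score)
  if (n < 3L) stop("need at least 3 observations")
  if (stats::sd(priority_score) == 0 || stats::sd(priority_truth) == 0)
    stop("constant input: correlation undefined")
  r <- stats::cor(priority_score, priority_truth, method = method)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  zc <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(r = r, ci = tanh(c(z - zc * se, z + zc * se)), n = n)
}

#' Priority score from acuity class probabilities
#'
#' The softmax-expected ordinal class index rescaled to \[0,1\].
#'
#' @param probs n x 3 matrix of class probabilities (normal, medium, high).
#' @return numeric vector in \[0,1\].
#' @export
priority_score <- function(probs) {
  probs <- as.matrix(probs)
  stopifnot(ncol(probs) == 3L)
  as.vector(probs %*% c(0, 1, 2)) / 2
}
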