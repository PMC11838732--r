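# Transfer heads on frozen study embeddings: multi-label diagnosis and
# referral (positive-weighted BCE), acuity (categorical cross-entropy), age
# (L2 regression), and the generic cross-validated linear-probe protocol.

#' Positive weights for multi-label binary cross-entropy
#'
#' For each label column, the exact ratio of negative to positive counts on
#' the training split.
#'
#' @param labels n x L binary matrix.
#' @return numeric vector of length L.
#' @export
compute_positive_weights <- function(labels) {
  labels <- as.matrix(labels)
  pos <- colSums(labels == 1)
  neg <- colSums(labels == 0)
  if (any(pos == 0)) {
    bad <- colnames(labels)[pos == 0]
    if (is.null(bad)) bad <- which(pos == 0)
    stop("label with zero positives: ", paste(bad, collapse = ", "))
  }
  stats::setNames(neg / pos, colnames(labels))
}

#' Positive-weighted multi-label binary cross-entropy
#'
#' `-(1/L) * sum_i [ p_i y_i log(yhat_i) + (1 - y_i) log(1 - yhat_i) ]`,
#' averaged over rows when matrices are passed. Probabilities at exactly 0
#' or 1 are clamped to `[1e-7, 1 - 1e-7]` with a warning.
#'
#' @param y_hat predicted probabilities (vector or n x L matrix).
#' @param y binary targets, same shape.
#' @param p positive weights of length L (see [compute_positive_weights()]).
#' @return a number.
#' @export
multilabel_bce <- function(y_hat, y, p) {
  y_hat <- as_mat(y_hat); y <- as_mat(y)
  stopifnot(identical(dim(y_hat), dim(y)), length(p) == ncol(y))
  if (any(y_hat <= 0 | y_hat >= 1)) {
    warning("probabilities clamped to [1e-7, 1 - 1e-7]")
    y_hat <- pmin(pmax(y_hat, 1e-7), 1 - 1e-7)
  }
  pw <- matrix(p, nrow(y), ncol(y), byrow = TRUE)
  -mean(rowMeans(pw * y * log(y_hat) + (1 - y) * log(1 - y_hat)))
}

# tape version on logits (stable)
bce_logits_node <- function(logits, y, p) {
  pw <- matrix(p, nrow(y), ncol(y), byrow = TRUE)
  pos <- ag_mul(ag_softplus(ag_scale(logits, -1)), ag_const(pw * y))
  neg <- ag_mul(ag_softplus(logits), ag_const(1 - y))
  ag_mean(ag_add(pos, neg))
}

#' Transfer head configuration
#'
#' Diagnosis, referral and acuity heads are 3-layer MLPs; the linear-probe
#' head is a 2-layer MLP with a single logit. Hidden width defaults to
#' `max(out_dim, in_dim / 4)`.
#'
#' @param task one of `"diagnosis"`, `"referral"`, `"acuity"`, `"age"`,
#'   `"probe"`.
#' @param in_dim embedding dimension.
#' @param out_dim output dimension (L labels, R referrals, 3 acuity classes,
#'   1 for age and probe).
#' @param hidden hidden width (default rule above).
#' @return a `head_config` list.
#' @export
head_config <- function(task = c("diagnosis", "referral", "acuity", "age",
                                 "probe"),
                        in_dim, out_dim = NULL, hidden = NULL) {
  task <- match.arg(task)
  if (is.null(out_dim))
    out_dim <- switch(task, acuity = 3L, age = 1L, probe = 1L,
                      stop("out_dim required for task ", task))
  if (task == "acuity" && out_dim != 3L) stop("acuity head outputs 3 classes")
  layers <- if (task == "probe") 2L else 3L
  # width floor keeps tiny embeddings trainable
  if (is.null(hidden)) hidden <- max(out_dim, ceiling(in_dim / 4), 16L)
  dims <- c(in_dim, rep(hidden, layers - 1L), out_dim)
  structure(list(task = task, in_dim = in_dim, out_dim = out_dim,
                 layers = layers, dims = dims),
            class = "head_config")
}

head_targets_check <- function(config, targets) {
  targets <- as.matrix(targets)
  ok <- switch(config$task,
    diagnosis = , referral = ncol(targets) == config$out_dim &&
      all(targets %in% c(0, 1)),
    acuity = ncol(targets) == 1L && all(targets %in% 0:2),
    age = ncol(targets) == 1L,
    probe = ncol(targets) == 1L && all(targets %in% c(0, 1)))
  if (!ok) stop("targets do not match task ", config$task)
  targets
}

#' Train a transfer head on frozen embeddings
#'
#' Full-batch Adam on the task-appropriate loss: positive-weighted BCE for
#' diagnosis/referral, categorical cross-entropy for acuity, L2 for age,
#' plain BCE for the probe. The backbone embeddings are inputs and never
#' touched. Returns the checkpoint with the best validation metric
#' (mean AUROC, accuracy, negative MAE or AUROC by task; ties go to the
#' earliest epoch).
#'
#' @param embeddings n x d matrix of frozen study features.
#' @param targets task targets (n x L binary, or a vector: acuity classes
#'   0..2, ages, or binary probe labels).
#' @param config a [head_config()].
#' @param seed integer seed.
#' @param train_idx,val_idx row split; defaults to an 80/20 random split.
#' @param epochs,lr optimizer settings.
#' @return list with `head` (at the best checkpoint), `trace`
#'   (per-epoch validation metric), `best_epoch` and `positive_weights`
#'   (diagnosis/referral only).
#' @export
train_head <- function(embeddings, targets, config, seed = 1L,
                       train_idx = NULL, val_idx = NULL, epochs = 150L,
                       lr = 5e-3) {
  X <- as.matrix(embeddings)
  stopifnot(ncol(X) == config$in_dim)
  targets <- head_targets_check(config, targets)
  # standardize features (training-split statistics)
  with_seed(seed, {
    n <- nrow(X)
    if (is.null(train_idx)) {
      val_idx <- sample.int(n, max(1L, round(0.2 * n)))
      train_idx <- setdiff(seq_len(n), val_idx)
    }
    mu <- colMeans(X[train_idx, , drop = FALSE])
    sg <- apply(X[train_idx, , drop = FALSE], 2L, stats::sd)
    sg[sg < 1e-8] <- 1
    X <- sweep(sweep(X, 2L, mu), 2L, sg, "/")
    y_center <- 0; y_scale <- 1
    if (config$task == "age") {
      y_center <- mean(targets[train_idx, 1L])
      y_scale <- max(stats::sd(targets[train_idx, 1L]), 1e-8)
      targets <- (targets - y_center) / y_scale
    }
    head <- nn_mlp(config$dims)
    params <- nn_params(head)
    opt <- adam_new(params, lr = lr)
    pw <- NULL
    if (config$task %in% c("diagnosis", "referral"))
      pw <- compute_positive_weights(targets[train_idx, , drop = FALSE])
    if (config$task == "probe")
      pw <- 1
    ytr <- targets[train_idx, , drop = FALSE]
    Xtr <- ag_const(X[train_idx, , drop = FALSE])
    val_metric <- function() {
      pr <- predict_head(head, X[val_idx, , drop = FALSE], config)
      yv <- targets[val_idx, , drop = FALSE]
      switch(config$task,
        diagnosis = , referral = multilabel_auroc(pr, yv)$mean,
        probe = multilabel_auroc(pr, yv)$mean,
        acuity = mean(max.col(pr, ties.method = "first") - 1L == yv[, 1L]),
        age = -mean(abs(pr - yv[, 1L])))
    }
    trace <- numeric(epochs)
    best <- -Inf; best_epoch <- 0L; best_vals <- NULL
    for (ep in seq_len(epochs)) {
      logits <- nn_mlp_fwd(head, Xtr)
      loss <- switch(config$task,
        diagnosis = , referral = , probe = bce_logits_node(logits, ytr, pw),
        acuity = ag_cross_entropy_rows(logits, ytr[, 1L] + 1L),
        age = ag_mean(ag_square(ag_sub(logits, ag_const(ytr)))))
      ag_backward(loss)
      adam_step(opt, clip = Inf)
      m <- val_metric()
      trace[ep] <- m
      if (m > best) {  # strict: ties keep the earliest epoch
        best <- m; best_epoch <- ep
        best_vals <- lapply(params, function(p) p$value)
      }
    }
    for (i in seq_along(params)) params[[i]]$value <- best_vals[[i]]
    list(head = head, config = config, trace = trace,
         best_epoch = best_epoch, positive_weights = pw,
         center = mu, scale = sg, y_center = y_center, y_scale = y_scale)
  })
}

#' Predict with a trained head
#'
#' @param head MLP from [train_head()] (or its `$head`).
#' @param embeddings n x d matrix.
#' @param config the matching [head_config()].
#' @return probabilities (diagnosis/referral/probe: n x L; acuity: n x 3
#'   softmax) or numeric predictions (age).
#' @export
predict_head <- function(head, embeddings, config) {
  X <- as.matrix(embeddings)
  y_center <- 0; y_scale <- 1
  if (!is.null(head$head)) {
    config <- head$config
    if (!is.null(head$center))
      X <- sweep(sweep(X, 2L, head$center), 2L, head$scale, "/")
    if (config$task == "age") { y_center <- head$y_center; y_scale <- head$y_scale }
    head <- head$head
  }
  logits <- ag_no_grad(nn_mlp_fwd(head, ag_const(X)))$value
  switch(config$task,
    diagnosis = , referral = , probe = 1 / (1 + exp(-logits)),
    acuity = {
      e <- exp(logits - apply(logits, 1L, max))
      e / rowSums(e)
    },
    age = as.vector(logits) * y_scale + y_center)
}

#' Cross-validated linear probe
#'
#' Stratified `folds`-way cross-validation of a 2-layer single-logit probe
#' trained with binary cross-entropy on frozen embeddings; reports the mean
#' and standard deviation of the per-fold validation AUROC.
#'
#' @param embeddings n x d matrix.
#' @param binary_target binary vector of length n (both classes present).
#' @param folds number of folds.
#' @param seed integer seed.
#' @param epochs,lr probe optimizer settings.
#' @return list with `mean`, `sd` and `fold_auroc`.
#' @export
linear_probe_cv <- function(embeddings, binary_target, folds = 5L, seed = 1L,
                            epochs = 120L, lr = 5e-3) {
  X <- as.matrix(embeddings)
  y <- as.integer(binary_target)
  if (length(unique(y)) < 2L) stop("single-class target")
  if (nrow(X) < folds) stop("fewer rows than folds")
  with_seed(seed, {
    fold_of <- integer(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_of[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    aucs <- vapply(seq_len(folds), function(f) {
      tr <- which(fold_of != f); te <- which(fold_of == f)
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L)
        stop("fold without both classes; reduce folds")
      cfg <- head_config("probe", in_dim = ncol(X))
      fit <- train_head(X, y, cfg, seed = sample.int(2^30, 1L),
                        train_idx = tr, val_idx = te, epochs = epochs,
                        lr = lr)
      pr <- predict_head(fit, X[te, , drop = FALSE], cfg)
      multilabel_auroc(pr, matrix(y[te]))$mean
    }, 1)
    list(mean = mean(aucs), sd = stats::sd(aucs), fold_auroc = aucs)
  })
}
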