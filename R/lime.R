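# LIME token attribution: Bernoulli masks over one sequence's volume tokens,
# model evaluation on each masked token subset, and a locality-weighted
# least-squares surrogate whose coefficients rank token importance.

#' Sample Bernoulli token masks
#'
#' i.i.d. Bernoulli(keep_prob) bits per token; all-zero draws are resampled
#' and the all-ones mask is always included once (first row).
#'
#' @param n_tokens number of tokens (>= 1).
#' @param n_samples number of masks.
#' @param keep_prob probability of keeping a token, in (0, 1].
#' @param seed integer seed.
#' @return binary matrix (n_samples x n_tokens); 1 = token kept.
#' @export
sample_masks <- function(n_tokens, n_samples = 3000L, keep_prob = 0.5,
                         seed = 1L) {
  stopifnot(n_tokens >= 1L, keep_prob > 0, keep_prob <= 1)
  with_seed(seed, {
    m <- matrix(as.integer(stats::runif(n_samples * n_tokens) < keep_prob),
                n_samples, n_tokens)
    for (i in seq_len(n_samples)) {
      while (sum(m[i, ]) == 0L)
        m[i, ] <- as.integer(stats::runif(n_tokens) < keep_prob)
    }
    m[1L, ] <- 1L
    m
  })
}

# locality kernel: exponential in the cosine distance between a mask and the
# all-ones mask; cos(m, 1) = sqrt(mean(m))
lime_kernel <- function(masks, sigma = 0.25) {
  s <- sqrt(rowMeans(masks))
  exp(-(1 - s)^2 / sigma^2)
}

#' Fit a LIME surrogate from masks and model outputs
#'
#' Locality-weighted (ridge-optional) least squares from mask bits to the
#' model's target logit. For any model affine in the mask the coefficients
#' are recovered exactly. The ranking is invariant to constant offsets of
#' the model output; ties break by the token's grid coordinate
#' (lexicographic, lowest first).
#'
#' @param masks binary matrix from [sample_masks()].
#' @param logits numeric vector of model outputs, one per mask row.
#' @param grid_coords optional integer matrix (n_tokens x 3) used for tie
#'   breaking in the ranking.
#' @param sigma locality kernel width.
#' @param ridge ridge penalty (0 = plain weighted least squares).
#' @return a `lime_explanation`: `weights`, `intercept`, `ranking` (token
#'   indices, most important first) and `grid_coords`.
#' @export
lime_fit <- function(masks, logits, grid_coords = NULL, sigma = 0.25,
                     ridge = 0) {
  masks <- as.matrix(masks)
  n_tok <- ncol(masks)
  if (nrow(unique(masks)) < 2L)
    stop("degenerate design: all masks identical")
  Z <- cbind(1, masks)
  w <- lime_kernel(masks, sigma)
  A <- crossprod(Z * w, Z) + diag(ridge, n_tok + 1L)
  b <- crossprod(Z * w, logits)
  coefs <- tryCatch(solve(A, b), error = function(e)
    solve(A + diag(1e-8, n_tok + 1L), b))
  wts <- as.vector(coefs[-1L])
  if (is.null(grid_coords)) grid_coords <- matrix(0L, n_tok, 3L)
  # order on rounded weights so numerically tied tokens fall through to the
  # lexicographic grid-coordinate tie break
  ranking <- order(-signif(wts, 10), grid_coords[, 1L], grid_coords[, 2L],
                   grid_coords[, 3L])
  structure(list(weights = wts, intercept = coefs[1L], ranking = ranking,
                 grid_coords = grid_coords),
            class = "lime_explanation")
}

#' Explain one diagnosis logit of one sequence
#'
#' Perturbs a single sequence of a study by token removal (removed tokens
#' are dropped from the transformer input), evaluates the target label's
#' logit through the frozen encoder and a trained diagnosis head for every
#' mask, and fits the locality-weighted surrogate.
#'
#' @param model a `clip_model`.
#' @param head_fit a trained diagnosis head from [train_head()].
#' @param study a `tokenized_study`.
#' @param sequence_index which sequence to perturb (the only one used).
#' @param target_label label name or column index of the head output.
#' @param n_samples number of masks.
#' @param keep_prob Bernoulli keep probability.
#' @param seed integer seed; explanations are reproducible given the seed.
#' @param sigma,ridge surrogate options, see [lime_fit()].
#' @return a `lime_explanation` (see [lime_fit()]).
#' @export
lime_explain <- function(model, head_fit, study, sequence_index, target_label,
                         n_samples = 300L, keep_prob = 0.5, seed = 1L,
                         sigma = 0.25, ridge = 0) {
  sq <- study$sequences[[sequence_index]]
  n_tok <- length(sq$tokens)
  if (n_tok < 2L) stop("sequence must have at least 2 tokens")
  lab <- if (is.character(target_label))
    match(target_label, names(head_fit$positive_weights)) else target_label
  if (is.na(lab)) stop("unknown target label: ", target_label)
  masks <- sample_masks(n_tok, n_samples, keep_prob, seed)
  single <- study
  logits <- vapply(seq_len(nrow(masks)), function(i) {
    sq2 <- sq
    sq2$tokens <- sq$tokens[masks[i, ] == 1L]
    single$sequences <- list(sq2)
    emb <- encode_study_embedding(model, single)
    lg <- ag_no_grad(nn_mlp_fwd(head_fit$head,
                                ag_const(matrix(emb, 1L))))$value
    lg[1L, lab]
  }, 1)
  gc_mat <- t(vapply(sq$tokens, function(tk) tk$grid_coord, integer(3L)))
  lime_fit(masks, logits, grid_coords = gc_mat, sigma = sigma, ridge = ridge)
}

#' Top-k overlap accuracy against ground-truth lesion token sets
#'
#' Fraction of cases in which at least one of the k highest-ranked tokens
#' lies inside the lesion's token set; cases with an empty lesion set are
#' excluded with a warning.
#'
#' @param explanations list of `lime_explanation`s.
#' @param lesion_token_sets list of integer matrices (cells x 3, 0-based
#'   grid coordinates), aligned with `explanations`.
#' @param k number of top tokens considered.
#' @return overlap accuracy in \[0,1\].
#' @export
topk_overlap_accuracy <- function(explanations, lesion_token_sets, k = 3L) {
  stopifnot(length(explanations) == length(lesion_token_sets))
  hits <- logical(0)
  skipped <- 0L
  for (i in seq_along(explanations)) {
    les <- lesion_token_sets[[i]]
    if (is.null(les) || nrow(les) == 0L) { skipped <- skipped + 1L; next }
    ex <- explanations[[i]]
    top <- ex$grid_coords[ex$ranking[seq_len(min(k, length(ex$ranking)))], ,
                          drop = FALSE]
    les_key <- apply(les, 1L, paste, collapse = ",")
    top_key <- apply(top, 1L, paste, collapse = ",")
    hits <- c(hits, any(top_key %in% les_key))
  }
  if (skipped > 0L) warning(skipped, " case(s) with empty lesion set excluded")
  if (length(hits) == 0L) stop("no cases with a non-empty lesion set")
  mean(hits)
}

#' Render an explanation as a heat volume aligned to its source sequence
#'
#' Every voxel of a token's patch receives that token's surrogate weight,
#' giving an overlay volume for viewers; optionally written as NIfTI.
#'
#' @param explanation a `lime_explanation`.
#' @param volume_dim dimensions of the source volume.
#' @param config the [tokenizer_config()] used to tokenize it.
#' @param file optional `.nii.gz` output path.
#' @return the heat volume (3D array), invisibly when written to file.
#' @export
lime_heat_volume <- function(explanation, volume_dim, config, file = NULL) {
  heat <- array(0, volume_dim)
  ps <- config$patch_shape
  for (i in seq_along(explanation$weights)) {
    g <- explanation$grid_coords[i, ]
    xr <- (g[1] * ps[1] + 1):min((g[1] + 1) * ps[1], volume_dim[1])
    yr <- (g[2] * ps[2] + 1):min((g[2] + 1) * ps[2], volume_dim[2])
    zr <- (g[3] * ps[3] + 1):min((g[3] + 1) * ps[3], volume_dim[3])
    heat[xr, yr, zr] <- explanation$weights[i]
  }
  if (!is.null(file)) {
    RNifti::writeNifti(RNifti::asNifti(heat), file)
    return(invisible(heat))
  }
  heat
}

#' Lesion token cells of a study's sequence
#'
#' Maps the stored ground-truth lesion voxel mask of `class` in sequence
#' `sequence_index` onto the tokenizer grid.
#'
#' @param study an [mri_study()] with `lesion_masks`.
#' @param class diagnosis class name.
#' @param sequence_index sequence number.
#' @param config a [tokenizer_config()].
#' @return integer matrix (cells x 3) of 0-based grid coordinates (0 rows
#'   when the lesion is absent from that sequence).
#' @export
lesion_token_cells <- function(study, class, sequence_index, config) {
  mk <- study$lesion_masks[[class]]
  if (is.null(mk) || is.null(mk[[sequence_index]]))
    return(matrix(integer(0), 0L, 3L))
  mask_token_cells(mk[[sequence_index]], config)
}
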