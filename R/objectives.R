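# Joint training objective: symmetric CLIP alignment between study and
# report projections plus a patient sequence-discrimination loss over the
# per-sequence representations, combined as L = L_clip + lambda * L_patdis.
# Also the training-time augmentation policy and the abnormal upsampler.

maybe_value <- function(node, as_number) {
  if (as_number) node$value[1L] else node
}

#' Symmetric CLIP contrastive loss
#'
#' Cosine-similarity logits between k matched study/report projections are
#' scaled by `exp(tau)`; the loss is the mean cross-entropy toward the
#' diagonal computed in both retrieval directions and summed. Zero for a
#' single pair; always non-negative.
#'
#' @param v_m k x d study projections (matrix or tape node).
#' @param v_r k x d report projections, row-aligned with `v_m`.
#' @param tau temperature; the logit scale is `exp(tau)`. A number or a
#'   trainable node.
#' @return a number when both inputs are plain matrices, otherwise a tape
#'   node.
#' @export
clip_loss <- function(v_m, v_r, tau = 0.07) {
  raw <- !is_node(v_m) && !is_node(v_r) && !is_node(tau)
  vm <- if (is_node(v_m)) v_m else ag_const(as_mat(v_m))
  vr <- if (is_node(v_r)) v_r else ag_const(as_mat(v_r))
  if (nrow(vm$value) != nrow(vr$value)) stop("row count mismatch")
  if (any(rowSums(vm$value^2) == 0) || any(rowSums(vr$value^2) == 0))
    stop("zero-norm embedding row: cosine similarity undefined")
  k <- nrow(vm$value)
  scale <- if (is_node(tau)) ag_exp(tau) else exp(tau)
  logits <- ag_mul(ag_matmul(ag_l2normalize_rows(vm),
                             ag_t(ag_l2normalize_rows(vr))), scale)
  targets <- seq_len(k)
  loss <- ag_add(ag_cross_entropy_rows(logits, targets),
                 ag_cross_entropy_rows(ag_t(logits), targets))
  maybe_value(loss, raw)
}

#' Patient sequence-discrimination loss
#'
#' Pulls together the projected representations of sequences belonging to
#' the same study. Cosine logits between all sequence pairs are divided by
#' `tau_p`; following the pseudocode convention the self-logit is set to -10
#' and self pairs stay inside the positive mask; each row contributes
#' `-log` of its same-study softmax mass, weighted by 1 / (k * n_i) for
#' study i with n_i sequences over k studies. `convention = "equation"`
#' keeps the untouched self-similarity logits instead.
#'
#' @param seq_embs n x d matrix (or node) of sequence representations,
#'   stacked across the batch.
#' @param study_index integer vector of length n mapping rows to studies.
#' @param projection optional 2-layer MLP ([nn_mlp()]-style list) applied
#'   before the cosine logits.
#' @param tau_p temperature (number or trainable node).
#' @param convention `"pseudocode"` (default) or `"equation"`.
#' @return a number for plain inputs, otherwise a tape node.
#' @export
patient_discrimination_loss <- function(seq_embs, study_index,
                                        projection = NULL, tau_p = 0.1,
                                        convention = c("pseudocode", "equation")) {
  convention <- match.arg(convention)
  raw <- !is_node(seq_embs) && !is_node(tau_p)
  x <- if (is_node(seq_embs)) seq_embs else ag_const(as_mat(seq_embs))
  n <- nrow(x$value)
  if (length(study_index) != n) stop("study_index length mismatch")
  k <- length(unique(study_index))
  if (k < 2L) stop("patient discrimination requires >= 2 studies in the batch")
  u <- if (is.null(projection)) x else nn_mlp_fwd(projection, x)
  un <- ag_l2normalize_rows(u)
  inv_tau <- if (is_node(tau_p)) ag_reciprocal(tau_p) else 1 / tau_p
  logits <- ag_mul(ag_matmul(un, ag_t(un)), inv_tau)
  if (convention == "pseudocode") {
    off <- 1 - diag(n)
    logits <- ag_add(ag_mul(logits, ag_const(off)), ag_const(-10 * diag(n)))
  }
  q <- ag_softmax_rows(logits)
  mask <- outer(study_index, study_index, "==") * 1
  agg <- ag_matmul(ag_mul(q, ag_const(mask)), ag_const(matrix(1, n, 1L)))
  n_i <- as.vector(table(study_index)[as.character(study_index)])
  w <- matrix(1 / (k * n_i), n, 1L)
  loss <- ag_scale(ag_sum(ag_mul(ag_log(agg), ag_const(w))), -1)
  maybe_value(loss, raw)
}

#' Combined training loss
#'
#' @param clip CLIP loss (number or node).
#' @param patdis patient-discrimination loss (number or node).
#' @param lambda weight of the discrimination term (default 0.03).
#' @return `clip + lambda * patdis`, same type as the inputs.
#' @export
combined_loss <- function(clip, patdis, lambda = 0.03) {
  if (!is_node(clip) && !is_node(patdis)) return(clip + lambda * patdis)
  ag_add(if (is_node(clip)) clip else ag_const(clip),
         ag_scale(if (is_node(patdis)) patdis else ag_const(patdis), lambda))
}

#' Training-time augmentation policy
#'
#' @param shuffle_findings probability of permuting the report's findings.
#' @param token_drop per-token drop probability (at least one token per
#'   sequence always survives).
#' @param unk_name per-sequence probability of replacing the name with
#'   `"unk"`.
#' @param seq_drop per-sequence drop probability (at least one sequence
#'   always survives).
#' @param threshold_jitter relative jitter of the background filter
#'   threshold; the effective threshold is multiplied by
#'   `U(1 - j, 1 + j)`. Tokens are precomputed, so only raising the
#'   threshold has an effect.
#' @param base_threshold the tokenizer threshold the tokens were filtered at.
#' @return an `augment_policy` list.
#' @export
augment_policy <- function(shuffle_findings = 0.5, token_drop = 0.1,
                           unk_name = 0.1, seq_drop = 0.1,
                           threshold_jitter = 0.5, base_threshold = 0.05) {
  p <- list(shuffle_findings = shuffle_findings, token_drop = token_drop,
            unk_name = unk_name, seq_drop = seq_drop,
            threshold_jitter = threshold_jitter,
            base_threshold = base_threshold)
  stopifnot(all(unlist(p[1:4]) >= 0), all(unlist(p[1:4]) <= 1))
  structure(p, class = "augment_policy")
}

#' Augment one study/report training pair
#'
#' Applies, each with its own probability: finding-order shuffling, visual
#' token dropping, sequence-name replacement with "unk", background filter
#' threshold jitter and whole-sequence dropping. Labels are never changed
#' and at least one sequence (with at least one token) always survives.
#'
#' @param study a `tokenized_study`.
#' @param report a `report_record`.
#' @param policy an [augment_policy()].
#' @param seed integer seed.
#' @return list with augmented `study` and `report`.
#' @export
augment_pair <- function(study, report, policy = augment_policy(), seed = 1L) {
  with_seed(seed, {
    if (length(report$findings) > 1L &&
        stats::runif(1) < policy$shuffle_findings) {
      report$findings <- sample(report$findings)
    }
    m <- length(study$sequences)
    keep <- stats::runif(m) >= policy$seq_drop
    if (!any(keep)) keep[sample.int(m, 1L)] <- TRUE
    study$sequences <- study$sequences[keep]
    thr <- policy$base_threshold *
      stats::runif(1, 1 - policy$threshold_jitter, 1 + policy$threshold_jitter)
    study$sequences <- lapply(study$sequences, function(sq) {
      if (stats::runif(1) < policy$unk_name) sq$name <- "unk"
      nt <- length(sq$tokens)
      if (nt > 0L) {
        keep_tok <- stats::runif(nt) >= policy$token_drop
        fr <- vapply(sq$tokens, function(tk)
          if (is.null(tk$fg_frac)) 1 else tk$fg_frac, 1)
        keep_tok <- keep_tok & fr >= thr
        if (!any(keep_tok)) keep_tok[which.max(fr)] <- TRUE
        if (!all(keep_tok)) {
          gd <- attr(sq$tokens, "grid_dim")
          sq$tokens <- sq$tokens[keep_tok]
          attr(sq$tokens, "grid_dim") <- gd
        }
      }
      sq
    })
    list(study = study, report = report)
  })
}

#' Epoch sampling stream with abnormal upsampling
#'
#' Abnormal studies appear `factor` times each, normal studies once each;
#' the stream is shuffled. The normal census is conserved.
#'
#' @param cohort list of entries carrying an abnormal flag (either
#'   `$abnormal` or `$study$abnormal`), or a logical vector.
#' @param factor upsampling multiplicity for abnormal studies.
#' @param seed integer seed.
#' @return integer vector of indices into `cohort`.
#' @export
abnormal_upsampler <- function(cohort, factor = 4L, seed = 1L) {
  flags <- if (is.logical(cohort)) cohort else
    vapply(cohort, function(e) {
      if (!is.null(e$abnormal)) e$abnormal else e$study$abnormal
    }, TRUE)
  if (!any(flags)) {
    warning("no abnormal studies: identity sampling")
    factor <- 1L
  }
  idx <- c(which(!flags), rep(which(flags), factor))
  with_seed(seed, idx[sample.int(length(idx))])
}
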