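# The full vision-language model: tokenizer output -> hierarchical encoder,
# report language model as the text tower, name encoders, learnable
# temperatures, and the joint CLIP + patient-discrimination training loop.

#' Assemble a vision-language model
#'
#' @param encoder_cfg an [encoder_config()].
#' @param report_state pre-trained report encoder from
#'   [pretrain_report_lm()].
#' @param seq_name_state,study_name_state [name_encoder()] states; created
#'   fresh (with `out_dim = encoder_cfg$name_dim`) when `NULL`. The study
#'   name encoder shares the architecture but is not pre-trained.
#' @param seed integer seed for weight initialization.
#' @return a `clip_model` list: hierarchical encoder, text towers and the
#'   learnable temperatures `tau` (init 0.07) and `tau_p` (init 0.1).
#' @export
clip_model_new <- function(encoder_cfg, report_state,
                           seq_name_state = NULL, study_name_state = NULL,
                           seed = 1L) {
  if (is.null(seq_name_state))
    seq_name_state <- name_encoder(dim = 32L, layers = 2L, heads = 2L,
                                   out_dim = encoder_cfg$name_dim,
                                   seed = seed + 11L)
  if (is.null(study_name_state))
    study_name_state <- name_encoder(dim = 32L, layers = 2L, heads = 2L,
                                     out_dim = encoder_cfg$name_dim,
                                     seed = seed + 23L)
  stopifnot(seq_name_state$out_dim == encoder_cfg$name_dim,
            study_name_state$out_dim == encoder_cfg$name_dim)
  hv <- hvit_new(encoder_cfg, seed = seed)
  hv <- hvit_bind_text(hv, report_state$dim, seed = seed + 37L)
  structure(list(config = encoder_cfg, hvit = hv, report = report_state,
                 seq_name = seq_name_state, study_name = study_name_state,
                 tau = ag_param(matrix(0.07, 1L, 1L)),
                 tau_p = ag_param(matrix(0.1, 1L, 1L))),
            class = "clip_model")
}

clip_trainable_params <- function(model, train_text = TRUE) {
  ps <- c(nn_params(model$hvit[setdiff(names(model$hvit), "config")]),
          list(model$tau, model$tau_p))
  if (train_text) {
    ps <- c(ps,
            nn_params(model$report[c("tok_emb", "pos_emb", "trunk", "lm_head")]),
            nn_params(model$seq_name[c("chr_emb", "pos_emb", "trunk", "out")]),
            nn_params(model$study_name[c("chr_emb", "pos_emb", "trunk", "out")]))
  }
  ps
}

# tape forward over a batch of (tokenized_study, report text) pairs;
# name encodings are computed once per unique name within the batch
clip_batch_nodes <- function(model, studies, texts, need_reps = TRUE) {
  name_cache <- new.env(parent = emptyenv())
  enc_name <- function(name, which) {
    key <- paste0(which, ":", toupper(name))
    nd <- name_cache[[key]]
    if (is.null(nd)) {
      st <- if (which == "s") model$seq_name else model$study_name
      nd <- encode_name_node(st, name)
      name_cache[[key]] <- nd
    }
    nd
  }
  k <- length(studies)
  # flatten all sequences, bucketed by token count so each bucket runs as one
  # block-masked transformer call
  seq_entries <- list()
  owner <- integer(0)
  for (i in seq_len(k)) {
    ts <- studies[[i]]
    found <- FALSE
    for (sq in ts$sequences) {
      if (length(sq$tokens) == 0L) next
      found <- TRUE
      seq_entries[[length(seq_entries) + 1L]] <-
        list(tokens = sq$tokens, name_node = enc_name(sq$name, "s"))
      owner <- c(owner, i)
    }
    if (!found)
      stop("study ", ts$patient_id, ": every sequence was fully filtered")
  }
  counts <- vapply(seq_entries, function(s) length(s$tokens), 1L)
  rep_rows <- vector("list", length(seq_entries))
  for (ct in unique(counts)) {
    sel <- which(counts == ct)
    grp <- vit_seq_forward_batch(model$hvit, seq_entries[sel])
    for (j in seq_along(sel)) rep_rows[[sel[j]]] <- ag_rows(grp, j)
  }
  # studies bucketed by surviving sequence count for the study transformer
  st_entries <- lapply(seq_len(k), function(i)
    list(rep_rows = rep_rows[owner == i],
         name_node = enc_name(studies[[i]]$study_name, "t")))
  m_of <- vapply(st_entries, function(s) length(s$rep_rows), 1L)
  v_rows <- vector("list", k)
  for (m in unique(m_of)) {
    sel <- which(m_of == m)
    grp <- vit_st_forward_batch(model$hvit, st_entries[sel])
    for (j in seq_along(sel)) v_rows[[sel[j]]] <- ag_rows(grp, j)
  }
  reps <- if (need_reps) rep_rows else NULL
  study_index <- owner
  # identical texts (e.g. empty normal reports) are encoded once
  utx <- unique(texts)
  u_rows <- lapply(utx, function(tx)
    encode_report_node(model$report, report_ids(tx, model$report$vocab)))
  v_study <- ag_rbind(v_rows)
  r_report <- ag_rows(ag_rbind(u_rows), match(texts, utx))
  list(v_m = nn_linear_fwd(model$hvit$clip_proj_m, v_study),
       v_r = nn_linear_fwd(model$hvit$clip_proj_r, r_report),
       v_study = v_study,
       reps = if (need_reps) ag_rbind(reps) else NULL,
       study_index = study_index)
}

#' Encode a tokenized study to its frozen feature vector
#'
#' The study-level representation used for transfer learning (length
#' `study_dim`), computed without building a gradient tape.
#'
#' @param model a `clip_model`.
#' @param ts a `tokenized_study`.
#' @return numeric vector.
#' @export
encode_study_embedding <- function(model, ts) {
  ag_no_grad({
    rs <- list()
    for (sq in ts$sequences) {
      if (length(sq$tokens) == 0L) next
      nv <- encode_name_node(model$seq_name, sq$name)
      rs[[length(rs) + 1L]] <- encode_sequence_node(model$hvit, sq$tokens, nv)
    }
    if (length(rs) == 0L) stop("study has no surviving tokens")
    v <- vit_st_forward(model$hvit, rs,
                        encode_name_node(model$study_name, ts$study_name))
    as.vector(v$value)
  })
}

#' Cosine similarity matrix between studies and report texts
#'
#' Row i / column j is the CLIP-space cosine similarity between study i and
#' text j; the diagonal holds the matched pairs.
#'
#' @param model a `clip_model`.
#' @param studies list of `tokenized_study` objects.
#' @param texts character vector of report texts, aligned with `studies`.
#' @return an N x N numeric matrix.
#' @export
clip_similarity_matrix <- function(model, studies, texts) {
  ag_no_grad({
    nodes <- clip_batch_nodes(model, studies, texts, need_reps = FALSE)
    vm <- nodes$v_m$value
    vr <- nodes$v_r$value
    vm <- vm / sqrt(rowSums(vm^2))
    vr <- vr / sqrt(rowSums(vr^2))
    vm %*% t(vr)
  })
}

#' Train the vision-language model
#'
#' Optimizes the symmetric CLIP loss plus `lambda_patdis` times the patient
#' sequence-discrimination loss over minibatches of study/report pairs, with
#' abnormal studies upsampled in each epoch stream and the augmentation
#' policy applied per draw. Volume tokens are precomputed and frozen; the
#' hierarchical encoder, text towers and temperatures are trainable.
#' Retrieval accuracy on a held-out split is logged per epoch.
#'
#' @param pairs list of entries, each with `study` (a `tokenized_study`) and
#'   `report` (a `report_record`).
#' @param model a [clip_model_new()].
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param batch_size contrastive batch size.
#' @param lr Adam learning rate.
#' @param lambda_patdis weight of the discrimination loss (0.03 default).
#' @param use_patdis include the patient-discrimination term.
#' @param upsample_factor abnormal upsampling multiplicity.
#' @param policy an [augment_policy()] (or `NULL` for no augmentation).
#' @param val_fraction held-out fraction for the retrieval trace.
#' @param val_idx optional explicit validation indices (overrides
#'   `val_fraction`).
#' @param temp_lr_mult learning-rate multiplier for the two temperatures.
#' @param weight_decay decoupled weight decay of the optimizer.
#' @param verbose print per-epoch progress.
#' @return list with `model` (trained in place), `trace` (per-epoch loss and
#'   validation Top-1/Top-5 retrieval) and `val_idx`.
#' @export
train_clip <- function(pairs, model, epochs = 10L, seed = 1L, batch_size = 32L,
                       lr = 2e-3, lambda_patdis = 0.03, use_patdis = TRUE,
                       upsample_factor = 4L, policy = augment_policy(),
                       val_fraction = 0.2, val_idx = NULL,
                       temp_lr_mult = 25, weight_decay = 0.01,
                       verbose = FALSE) {
  if (length(pairs) < 2L) stop("need at least 2 study-report pairs")
  with_seed(seed, {
    n <- length(pairs)
    if (is.null(val_idx))
      val_idx <- sample.int(n, max(2L, round(val_fraction * n)))
    train_idx <- setdiff(seq_len(n), val_idx)
    params <- clip_trainable_params(model)
    # the printed logit scale exp(tau) starts near 1, so the temperatures
    # get a larger step size to let the scale adapt within a short schedule
    mult <- vapply(params, function(p)
      if (identical(p, model$tau) || identical(p, model$tau_p)) temp_lr_mult
      else 1, 1)
    opt <- adam_new(params, lr = lr, lr_mult = mult,
                    weight_decay = weight_decay)
    # cosine learning-rate schedule with a short linear warmup
    est_steps <- max(1L, epochs * ceiling(2.5 * length(train_idx) / batch_size))
    step_no <- 0L
    lr_at <- function(s) {
      lr * min(1, s / 10) *
        (0.1 + 0.9 * 0.5 * (1 + cos(pi * min(1, s / est_steps))))
    }
    trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_top1 = numeric(0), val_top5 = numeric(0))
    val_studies <- lapply(pairs[val_idx], function(e) e$study)
    val_texts <- vapply(pairs[val_idx], function(e) report_text(e$report), "")
    for (ep in seq_len(epochs)) {
      stream <- abnormal_upsampler(lapply(pairs[train_idx], function(e) e$study),
                                   factor = upsample_factor,
                                   seed = sample.int(2^30, 1L))
      stream <- train_idx[stream]
      losses <- c()
      for (st in seq(1L, length(stream), by = batch_size)) {
        idx <- stream[st:min(st + batch_size - 1L, length(stream))]
        if (length(idx) < 2L) next
        entries <- lapply(idx, function(i) {
          e <- pairs[[i]]
          if (is.null(policy)) list(study = e$study, report = e$report)
          else augment_pair(e$study, e$report, policy, sample.int(2^30, 1L))
        })
        studies <- lapply(entries, function(e) e$study)
        texts <- vapply(entries, function(e) report_text(e$report), "")
        nodes <- clip_batch_nodes(model, studies, texts,
                                  need_reps = use_patdis)
        lc <- clip_loss(nodes$v_m, nodes$v_r, model$tau)
        loss <- if (use_patdis) {
          lp <- patient_discrimination_loss(nodes$reps, nodes$study_index,
                                            projection = model$hvit$patdis_mlp,
                                            tau_p = model$tau_p)
          combined_loss(lc, lp, lambda_patdis)
        } else lc
        ag_backward(loss)
        step_no <- step_no + 1L
        opt$lr <- lr_at(step_no)
        adam_step(opt)
        # keep the logit scale exp(tau) within [exp(0.07), 100]: unbounded
        # downward drift parks the softmax at its uniform fixed point before
        # alignment can take hold
        model$tau$value[1L] <- min(max(model$tau$value[1L], 0.07), log(100))
        model$tau_p$value[1L] <- min(max(model$tau_p$value[1L], 0.01), 10)
        losses <- c(losses, loss$value[1L])
      }
      sim <- clip_similarity_matrix(model, val_studies, val_texts)
      t1 <- topk_retrieval(sim, 1L)
      t5 <- topk_retrieval(sim, min(5L, nrow(sim)))
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = mean(losses),
                                       val_top1 = t1, val_top5 = t5))
      if (verbose)
        message(sprintf("epoch %d loss %.4f top1 %.3f top5 %.3f",
                        ep, mean(losses), t1, t5))
    }
    list(model = model, trace = trace, val_idx = val_idx)
  })
}
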