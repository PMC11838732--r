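# Text encoders: a decoder-only autoregressive language model over itemized
# report text (the CLIP text tower, pre-trained with next-word prediction)
# and character-level transformer encoders for sequence and study names.

# ---- word-level report tokenization -----------------------------------------

report_tokenize <- function(text) {
  text <- tolower(text)
  toks <- unlist(strsplit(gsub("([[:punct:]])", " \\1 ", text), "[[:space:]]+"))
  toks[nzchar(toks)]
}

#' Build a word vocabulary from a report corpus
#'
#' Reserved symbols: `<bos>`, `<eos>`, `<unk>` and `<empty>` (the encoding
#' of an empty report — normal studies exist).
#'
#' @param corpus character vector of report texts.
#' @return character vector, the vocabulary (reserved symbols first).
#' @export
build_report_vocab <- function(corpus) {
  words <- sort(unique(unlist(lapply(corpus, report_tokenize))))
  c("<bos>", "<eos>", "<unk>", "<empty>", words)
}

report_ids <- function(text, vocab) {
  toks <- report_tokenize(text)
  if (length(toks) == 0L) toks <- "<empty>"
  ids <- match(toks, vocab)
  ids[is.na(ids)] <- match("<unk>", vocab)
  c(match("<bos>", vocab), ids, match("<eos>", vocab))
}

# ---- report language model ---------------------------------------------------

report_lm_new <- function(vocab, dim = 64L, layers = 2L, heads = 2L,
                          max_len = 64L) {
  list(vocab = vocab, dim = dim, max_len = max_len,
       tok_emb = ag_param(ag_init(length(vocab), dim)),
       pos_emb = ag_param(ag_init(max_len, dim)),
       trunk = nn_transformer(layers, dim, heads),
       lm_head = nn_linear(dim, length(vocab)))
}

report_lm_hidden <- function(state, ids) {
  n <- length(ids)
  if (n > state$max_len) {
    ids <- ids[seq_len(state$max_len)]
    n <- state$max_len
  }
  x <- ag_add(ag_rows(state$tok_emb, ids), ag_rows(state$pos_emb, seq_len(n)))
  nn_transformer_fwd(state$trunk, x, mask = nn_causal_mask(n))
}

# mean next-token negative log-likelihood of one id sequence
report_lm_nll <- function(state, ids) {
  n <- length(ids)
  h <- report_lm_hidden(state, ids)
  logits <- nn_linear_fwd(state$lm_head, ag_rows(h, seq_len(n - 1L)))
  ag_cross_entropy_rows(logits, ids[2:n])
}

#' Pre-train the report language model
#'
#' Autoregressive next-word prediction over the report corpus; returns the
#' trained encoder state and the per-epoch validation perplexity trace
#' (perplexity = exp(mean token NLL), bounded below by 1).
#'
#' @param corpus character vector of report texts (non-empty).
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param dim,layers,heads model dimensions.
#' @param lr Adam learning rate.
#' @param val_fraction held-out fraction for the perplexity trace.
#' @param vocab optional fixed vocabulary (built from `corpus` otherwise).
#' @return list with `state` (report encoder) and `trace` (epoch,
#'   validation perplexity).
#' @export
pretrain_report_lm <- function(corpus, epochs = 10L, seed = 1L, dim = 64L,
                               layers = 2L, heads = 2L, lr = 3e-3,
                               val_fraction = 0.15, vocab = NULL) {
  if (length(corpus) == 0L) stop("empty corpus")
  if (is.null(vocab)) vocab <- build_report_vocab(corpus)
  with_seed(seed, {
    state <- report_lm_new(vocab, dim = dim, layers = layers, heads = heads)
    n <- length(corpus)
    val_idx <- if (n >= 5L) sample.int(n, max(1L, round(val_fraction * n))) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)
    if (length(train_idx) == 0L) train_idx <- seq_len(n)
    params <- nn_params(state[c("tok_emb", "pos_emb", "trunk", "lm_head")])
    opt <- adam_new(params, lr = lr)
    # templated corpora repeat texts heavily: train on unique texts weighted
    # by their multiplicity
    utr <- table(corpus[train_idx])
    utexts <- names(utr)
    uw <- as.numeric(utr) / sum(utr)
    uids <- lapply(utexts, report_ids, vocab = vocab)
    vids <- lapply(corpus[val_idx], report_ids, vocab = vocab)
    val_ppl <- function() {
      if (length(vids) == 0L) return(NA_real_)
      tot <- 0; ntok <- 0
      for (ids in vids) {
        tot <- tot + ag_no_grad(report_lm_nll(state, ids))$value[1L] * (length(ids) - 1L)
        ntok <- ntok + length(ids) - 1L
      }
      exp(tot / ntok)
    }
    trace <- data.frame(epoch = integer(0), val_perplexity = numeric(0))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(uids))
      for (i in ord) {
        loss <- ag_scale(report_lm_nll(state, uids[[i]]),
                         uw[i] * length(uids))
        ag_backward(loss)
        adam_step(opt)
      }
      trace <- rbind(trace, data.frame(epoch = ep, val_perplexity = val_ppl()))
    }
    list(state = state, trace = trace)
  })
}

# last-position hidden state as the report embedding (tape-aware)
encode_report_node <- function(state, ids) {
  h <- report_lm_hidden(state, ids)
  ag_rows(h, min(length(ids), state$max_len))
}

#' Encode a report text to a fixed-length vector
#'
#' The embedding is the final-position hidden state of the autoregressive
#' model after the end token; an empty text is encoded through the reserved
#' empty-report symbol. Deterministic given the weights.
#'
#' @param text report text (may be empty).
#' @param state trained report encoder state from [pretrain_report_lm()].
#' @return numeric vector of length `state$dim`.
#' @export
encode_report <- function(text, state) {
  ids <- report_ids(text, state$vocab)
  as.vector(ag_no_grad(encode_report_node(state, ids))$value)
}

# ---- character-level name encoders ------------------------------------------

NAME_CHARSET <- c(LETTERS, 0:9, "_", " ", "-", ".", "<unk>")

name_ids <- function(name) {
  ch <- strsplit(toupper(name), "")[[1L]]
  if (length(ch) == 0L) ch <- " "
  ids <- match(ch, NAME_CHARSET)
  ids[is.na(ids)] <- length(NAME_CHARSET)
  ids
}

#' Initialize a character-level name encoder
#'
#' A bidirectional character transformer (3 layers at full scale); names
#' are case-folded and unknown characters map to a reserved symbol. The
#' embedding is the mean-pooled final layer projected to `out_dim`.
#'
#' @param dim internal width.
#' @param layers transformer layers.
#' @param heads attention heads.
#' @param out_dim output embedding dimension.
#' @param max_len maximum name length in characters.
#' @param seed integer seed.
#' @return a `name_encoder` state list.
#' @export
name_encoder <- function(dim = 32L, layers = 3L, heads = 2L, out_dim = 32L,
                         max_len = 48L, seed = 1L) {
  with_seed(seed, {
    list(dim = dim, out_dim = out_dim, max_len = max_len,
         chr_emb = ag_param(ag_init(length(NAME_CHARSET), dim)),
         pos_emb = ag_param(ag_init(max_len, dim)),
         trunk = nn_transformer(layers, dim, heads),
         out = nn_linear(dim, out_dim))
  })
}

encode_name_node <- function(state, name) {
  ids <- name_ids(name)
  if (length(ids) > state$max_len) ids <- ids[seq_len(state$max_len)]
  x <- ag_add(ag_rows(state$chr_emb, ids),
              ag_rows(state$pos_emb, seq_along(ids)))
  h <- nn_transformer_fwd(state$trunk, x)
  nn_linear_fwd(state$out, ag_mean_rows(h))
}

#' Encode a sequence name
#' @param name free-text sequence name.
#' @param state a [name_encoder()].
#' @return numeric vector of length `state$out_dim`.
#' @export
encode_sequence_name <- function(name, state) {
  as.vector(ag_no_grad(encode_name_node(state, name))$value)
}

#' Encode a study name
#'
#' Same architecture as the sequence name encoder but typically left
#' unpretrained.
#'
#' @inheritParams encode_sequence_name
#' @return numeric vector of length `state$out_dim`.
#' @export
encode_study_name <- function(name, state) encode_sequence_name(name, state)

#' Pre-train the sequence name encoder
#'
#' Contrastive (CLIP-style) alignment between name embeddings and the
#' mean-pooled latent embeddings of the paired sequence's visual tokens, so
#' that names of the same modality family land close in cosine space.
#'
#' @param pairs list of elements with `name` (string) and `visual` (numeric
#'   vector: mean-pooled token embedding of that sequence).
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param state optional initialized [name_encoder()].
#' @param batch_size contrastive batch size.
#' @param lr Adam learning rate.
#' @return the trained `name_encoder` state.
#' @export
pretrain_sequence_name_encoder <- function(pairs, epochs = 10L, seed = 1L,
                                           state = NULL, batch_size = 16L,
                                           lr = 3e-3) {
  nm <- vapply(pairs, function(p) toupper(p$name), "")
  if (length(unique(nm)) < 2L)
    stop("contrastive pre-training requires >= 2 distinct names")
  vdim <- length(pairs[[1L]]$visual)
  with_seed(seed, {
    if (is.null(state)) state <- name_encoder(seed = seed)
    vproj <- nn_linear(vdim, state$out_dim)
    tau <- ag_param(matrix(0.07, 1L, 1L))
    params <- c(nn_params(state[c("chr_emb", "pos_emb", "trunk", "out")]),
                nn_params(vproj), list(tau))
    opt <- adam_new(params, lr = lr)
    V <- t(vapply(pairs, function(p) p$visual, numeric(vdim)))
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(pairs))
      for (st in seq(1L, length(ord), by = batch_size)) {
        idx <- ord[st:min(st + batch_size - 1L, length(ord))]
        if (length(idx) < 2L) next
        nvec <- ag_rbind(lapply(idx, function(i)
          encode_name_node(state, pairs[[i]]$name)))
        vvec <- nn_linear_fwd(vproj, ag_const(V[idx, , drop = FALSE]))
        loss <- clip_loss(nvec, vvec, tau)
        ag_backward(loss)
        adam_step(opt)
      }
    }
    state
  })
}
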