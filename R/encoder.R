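# Two-level hierarchical vision transformer.
#
# The sequence transformer attends over a sequence's volume tokens together
# with learned register tokens and the encoded sequence name; its register
# outputs are concatenated and projected to the sequence representation r_i.
# The study transformer attends over the (projected) sequence
# representations, its own registers and the encoded study name; its register
# outputs, each projected back to the representation width, concatenate into
# the study vector. Positional information enters only through explicit
# features (3D sinusoids + plane one-hot), so both levels are
# permutation-invariant over their inputs.

#' Hierarchical encoder configuration
#'
#' @param token_embed_dim flat latent length of one volume token.
#' @param name_dim output dimension of the name encoders.
#' @param seq_dim,seq_layers,seq_heads sequence transformer width/depth/heads.
#' @param seq_registers number of sequence-level register tokens.
#' @param rep_dim length of the sequence representation r_i.
#' @param st_dim,st_layers,st_heads study transformer width/depth/heads.
#' @param st_registers number of study-level register tokens.
#' @param clip_proj_dim output dimension of the CLIP projections.
#' @param patdis_dim patient-discrimination embedding dimension.
#' @param mlp_ratio transformer MLP expansion.
#' @return an `encoder_config` list; `study_dim = st_registers * rep_dim`.
#' @export
encoder_config <- function(token_embed_dim = 16L, name_dim = 32L,
                           seq_dim = 48L, seq_layers = 2L, seq_heads = 2L,
                           seq_registers = 4L, rep_dim = 48L,
                           st_dim = 48L, st_layers = 2L, st_heads = 2L,
                           st_registers = 2L, clip_proj_dim = 32L,
                           patdis_dim = 32L, mlp_ratio = 4) {
  stopifnot(seq_registers >= 1L, st_registers >= 1L)
  structure(list(token_embed_dim = as.integer(token_embed_dim),
                 name_dim = as.integer(name_dim),
                 seq_dim = as.integer(seq_dim), seq_layers = as.integer(seq_layers),
                 seq_heads = as.integer(seq_heads),
                 seq_registers = as.integer(seq_registers),
                 rep_dim = as.integer(rep_dim),
                 st_dim = as.integer(st_dim), st_layers = as.integer(st_layers),
                 st_heads = as.integer(st_heads),
                 st_registers = as.integer(st_registers),
                 clip_proj_dim = as.integer(clip_proj_dim),
                 patdis_dim = as.integer(patdis_dim),
                 mlp_ratio = mlp_ratio,
                 pos_dim = 33L,
                 study_dim = as.integer(st_registers) * as.integer(rep_dim)),
            class = "encoder_config")
}

#' Full-scale encoder configuration
#'
#' 15-layer/16-head (64-dim heads) sequence transformer with 20 registers and
#' a 1024-dim sequence representation; 4-layer/8-head study transformer with
#' 10 registers, giving a 10240-dim study vector; 128-dim CLIP projections.
#' The study transformer's native width (8 x 64 = 512) is bridged to the
#' 1024-wide representations by input and output projections.
#'
#' @export
full_scale_encoder_config <- function() {
  encoder_config(token_embed_dim = 256L, name_dim = 64L,
                 seq_dim = 1024L, seq_layers = 15L, seq_heads = 16L,
                 seq_registers = 20L, rep_dim = 1024L,
                 st_dim = 512L, st_layers = 4L, st_heads = 8L,
                 st_registers = 10L, clip_proj_dim = 128L,
                 patdis_dim = 128L)
}

#' Desk-scale encoder configuration
#' @export
desk_encoder_config <- function() encoder_config()

#' Sinusoidal + plane positional feature of a volume token
#'
#' 30 dimensions of sinusoids (10 per axis, 5 geometric frequency pairs over
#' the 0-based token grid coordinate) concatenated with a 3-dim one-hot for
#' the acquisition plane.
#'
#' @param grid_coord 0-based integer 3-vector.
#' @param plane `"axial"`, `"coronal"` or `"sagittal"`.
#' @return numeric vector of length 33, sinusoid values in \[-1, 1\].
#' @export
positional_feature <- function(grid_coord, plane) {
  freqs <- 100^(-(0:4) / 4)
  sinus <- unlist(lapply(1:3, function(a) {
    t <- grid_coord[a]
    as.vector(rbind(sin(t * freqs), cos(t * freqs)))
  }))
  onehot <- as.numeric(PLANES == plane)
  if (sum(onehot) != 1) stop("unknown plane: ", plane)
  c(sinus, onehot)
}

#' Initialize the hierarchical encoder
#'
#' @param config an [encoder_config()].
#' @param seed integer seed.
#' @return an `hvit` model list of parameter nodes. Weight sharing holds by
#'   construction: the one sequence transformer serves every sequence.
#' @export
hvit_new <- function(config, seed = 1L) {
  with_seed(seed, {
    list(config = config,
         seq_registers = ag_param(ag_init(config$seq_registers, config$seq_dim)),
         seq_name_proj = nn_linear(config$name_dim, config$seq_dim),
         tok_proj = nn_linear(config$token_embed_dim + config$pos_dim,
                              config$seq_dim),
         vit_seq = nn_transformer(config$seq_layers, config$seq_dim,
                                  config$seq_heads, config$mlp_ratio),
         rep_proj = nn_linear(config$seq_registers * config$seq_dim,
                              config$rep_dim),
         st_registers = ag_param(ag_init(config$st_registers, config$st_dim)),
         st_name_proj = nn_linear(config$name_dim, config$st_dim),
         seq_rep_proj = nn_linear(config$rep_dim, config$st_dim),
         vit_st = nn_transformer(config$st_layers, config$st_dim,
                                 config$st_heads, config$mlp_ratio),
         st_out_proj = nn_linear(config$st_dim, config$rep_dim),
         clip_proj_m = nn_linear(config$study_dim, config$clip_proj_dim),
         clip_proj_r = nn_linear(config$name_dim, config$clip_proj_dim),
         patdis_mlp = nn_mlp(c(config$rep_dim, config$rep_dim,
                               config$patdis_dim)))
  })
}

# set the text-side CLIP projection input width once the report dim is known
hvit_bind_text <- function(model, report_dim, seed = 1L) {
  with_seed(seed, {
    model$clip_proj_r <- nn_linear(report_dim, model$config$clip_proj_dim)
  })
  model
}

token_feature_matrix <- function(tokens, config) {
  t(vapply(tokens, function(tk) {
    emb <- tk$embedding
    if (length(emb) != config$token_embed_dim)
      stop("token embedding length ", length(emb),
           " does not match configured ", config$token_embed_dim)
    c(emb, positional_feature(tk$grid_coord, tk$plane))
  }, numeric(config$token_embed_dim + config$pos_dim)))
}

#' Build the sequence transformer input
#'
#' Ordered concatenation `[registers | encoded name | token features]`, where
#' each token feature is its latent embedding joined with its positional
#' feature, projected to the transformer width. The returned attention mask
#' marks real positions (no padding is introduced here).
#'
#' @param model an [hvit_new()] model.
#' @param tokens non-empty list of `latent_token`s.
#' @param name_vec encoded sequence name (vector or tape node).
#' @return list with `input` (tape node, `(registers + 1 + n) x seq_dim`),
#'   `n_tokens` and `attention_mask`.
#' @export
build_sequence_input <- function(model, tokens, name_vec) {
  if (length(tokens) == 0L)
    stop("sequence fully background-filtered: no tokens to encode")
  cfg <- model$config
  feats <- token_feature_matrix(tokens, cfg)
  tokrows <- nn_linear_fwd(model$tok_proj, ag_const(feats))
  namerow <- nn_linear_fwd(model$seq_name_proj,
                           if (is_node(name_vec)) name_vec else
                             ag_const(matrix(name_vec, 1L)))
  input <- ag_rbind(list(model$seq_registers, namerow, tokrows))
  list(input = input, n_tokens = length(tokens),
       attention_mask = rep(1L, cfg$seq_registers + 1L + length(tokens)))
}

#' Sequence transformer forward pass
#'
#' @param model an [hvit_new()] model.
#' @param input output of [build_sequence_input()] (or its `input` node).
#' @return list with `r` (1 x rep_dim tape node, the sequence
#'   representation) and `registers` (register output rows).
#' @export
vit_seq_forward <- function(model, input) {
  x <- if (is.list(input) && !is_node(input)) input$input else input
  out <- nn_transformer_fwd(model$vit_seq, x)
  nreg <- model$config$seq_registers
  flat <- ag_flatten_rows(out, seq_len(nreg))
  if (any(!is.finite(flat$value))) stop("non-finite activations in vit_seq")
  list(r = nn_linear_fwd(model$rep_proj, flat),
       registers = ag_rows(out, seq_len(nreg)))
}

# convenience: tokens + name vector -> r_i node
encode_sequence_node <- function(model, tokens, name_vec) {
  vit_seq_forward(model, build_sequence_input(model, tokens, name_vec))$r
}

# additive block-diagonal mask: position i attends only within its block
block_diag_mask <- function(G, L) {
  m <- matrix(-Inf, G * L, G * L)
  for (g in seq_len(G)) {
    idx <- ((g - 1L) * L + 1L):(g * L)
    m[idx, idx] <- 0
  }
  m
}

# Batched sequence-transformer forward: every sequence in `seqs` (elements:
# list(tokens, name_node)) must yield the same input length; the stacked
# blocks attend independently under a block-diagonal mask. Returns a
# G x rep_dim node of sequence representations.
vit_seq_forward_batch <- function(model, seqs) {
  cfg <- model$config
  G <- length(seqs)
  n_tok <- length(seqs[[1L]]$tokens)
  L <- cfg$seq_registers + 1L + n_tok
  feats <- do.call(rbind, lapply(seqs, function(s)
    token_feature_matrix(s$tokens, cfg)))
  tokrows <- nn_linear_fwd(model$tok_proj, ag_const(feats))
  names_mat <- nn_linear_fwd(model$seq_name_proj,
                             ag_rbind(lapply(seqs, function(s) s$name_node)))
  pieces <- vector("list", 3L * G)
  for (g in seq_len(G)) {
    pieces[[3L * g - 2L]] <- model$seq_registers
    pieces[[3L * g - 1L]] <- ag_rows(names_mat, g)
    pieces[[3L * g]] <- ag_rows(tokrows, ((g - 1L) * n_tok + 1L):(g * n_tok))
  }
  x <- ag_rbind(pieces)
  out <- nn_transformer_fwd(model$vit_seq, x,
                            mask = if (G > 1L) block_diag_mask(G, L) else NULL)
  flat <- ag_rbind(lapply(seq_len(G), function(g)
    ag_flatten_rows(out, ((g - 1L) * L + 1L):((g - 1L) * L + cfg$seq_registers))))
  nn_linear_fwd(model$rep_proj, flat)
}

# Batched study-transformer forward over studies with equal sequence count m.
# `studies` elements: list(rep_rows = 1-row rep nodes (length m),
# name_node). Returns a k x study_dim node.
vit_st_forward_batch <- function(model, studies) {
  cfg <- model$config
  k <- length(studies)
  m <- length(studies[[1L]]$rep_rows)
  L <- cfg$st_registers + 1L + m
  reps <- nn_linear_fwd(model$seq_rep_proj,
                        ag_rbind(unlist(lapply(studies, function(s) s$rep_rows),
                                        recursive = FALSE)))
  names_mat <- nn_linear_fwd(model$st_name_proj,
                             ag_rbind(lapply(studies, function(s) s$name_node)))
  pieces <- vector("list", 3L * k)
  for (g in seq_len(k)) {
    pieces[[3L * g - 2L]] <- model$st_registers
    pieces[[3L * g - 1L]] <- ag_rows(names_mat, g)
    pieces[[3L * g]] <- ag_rows(reps, ((g - 1L) * m + 1L):(g * m))
  }
  x <- ag_rbind(pieces)
  out <- nn_transformer_fwd(model$vit_st, x,
                            mask = if (k > 1L) block_diag_mask(k, L) else NULL)
  regs <- nn_linear_fwd(model$st_out_proj, out)
  ag_rbind(lapply(seq_len(k), function(g)
    ag_flatten_rows(regs, ((g - 1L) * L + 1L):((g - 1L) * L + cfg$st_registers))))
}

#' Study transformer forward pass
#'
#' Input is `[study registers | encoded study name | projected sequence
#' representations]`; the study vector concatenates the register outputs
#' (each projected to the representation width). No positional encoding is
#' attached to sequences, so the output is invariant to their order.
#'
#' @param model an [hvit_new()] model.
#' @param seq_reps list of sequence representation nodes (1 x rep_dim each)
#'   or a single k x rep_dim matrix/node, k >= 1.
#' @param study_name_vec encoded study name (vector or node).
#' @return 1 x study_dim tape node.
#' @export
vit_st_forward <- function(model, seq_reps, study_name_vec) {
  cfg <- model$config
  if (is.list(seq_reps) && !is_node(seq_reps)) {
    if (length(seq_reps) == 0L) stop("study has no sequence representations")
    seq_reps <- ag_rbind(seq_reps)
  } else if (!is_node(seq_reps)) seq_reps <- ag_const(as_mat(seq_reps))
  namerow <- nn_linear_fwd(model$st_name_proj,
                           if (is_node(study_name_vec)) study_name_vec else
                             ag_const(matrix(study_name_vec, 1L)))
  x <- ag_rbind(list(model$st_registers, namerow,
                     nn_linear_fwd(model$seq_rep_proj, seq_reps)))
  out <- nn_transformer_fwd(model$vit_st, x)
  regs <- nn_linear_fwd(model$st_out_proj,
                        ag_rows(out, seq_len(cfg$st_registers)))
  ag_flatten_rows(regs, seq_len(cfg$st_registers))
}

#' Project study and report embeddings into the shared CLIP space
#'
#' @param model an [hvit_new()] model (after text binding).
#' @param v_study study vector (node or numeric, length study_dim).
#' @param r_report report embedding (node or numeric).
#' @return list of nodes `v_m` and `v_r`, both 1 x clip_proj_dim.
#' @export
project_for_clip <- function(model, v_study, r_report) {
  vs <- if (is_node(v_study)) v_study else ag_const(matrix(v_study, 1L))
  vr <- if (is_node(r_report)) r_report else ag_const(matrix(r_report, 1L))
  list(v_m = nn_linear_fwd(model$clip_proj_m, vs),
       v_r = nn_linear_fwd(model$clip_proj_r, vr))
}
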