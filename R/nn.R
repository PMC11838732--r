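# Neural building blocks: linear layers, layer norm, multi-head attention and
# pre-norm transformer blocks, all expressed through the autograd ops.
# Constructors return plain lists of parameter nodes; forward functions take
# the layer list plus an input node.

# fan-in scaled Gaussian init
nn_linear <- function(d_in, d_out, sd = 1 / sqrt(d_in)) {
  list(W = ag_param(ag_init(d_in, d_out, sd)),
       b = ag_param(matrix(0, 1L, d_out)))
}

nn_linear_fwd <- function(l, x) ag_linear_op(wrap(x), l$W, l$b)

nn_layernorm <- function(d) {
  list(gamma = ag_param(matrix(1, 1L, d)),
       beta = ag_param(matrix(0, 1L, d)))
}

nn_layernorm_fwd <- function(l, x) ag_layernorm(x, l$gamma, l$beta)

# Multi-head self-attention with a fused QKV projection;
# model width = heads * head_dim.
nn_mha <- function(d, heads) {
  stopifnot(d %% heads == 0L)
  list(heads = heads, head_dim = d %/% heads,
       Wqkv = nn_linear(d, 3L * d), Wo = nn_linear(d, d))
}

# mask: optional additive n x n matrix (e.g. -Inf for causal masking)
nn_mha_fwd <- function(m, x, mask = NULL) {
  qkv <- nn_linear_fwd(m$Wqkv, x)
  nn_linear_fwd(m$Wo, ag_attention(qkv, m$heads, mask = mask))
}

nn_block <- function(d, heads, mlp_ratio = 4) {
  dh <- round(d * mlp_ratio)
  list(ln1 = nn_layernorm(d), attn = nn_mha(d, heads),
       ln2 = nn_layernorm(d),
       fc1 = nn_linear(d, dh), fc2 = nn_linear(dh, d))
}

nn_block_fwd <- function(b, x, mask = NULL) {
  x <- ag_add(x, nn_mha_fwd(b$attn, nn_layernorm_fwd(b$ln1, x), mask = mask))
  h <- ag_relu(nn_linear_fwd(b$fc1, nn_layernorm_fwd(b$ln2, x)))
  ag_add(x, nn_linear_fwd(b$fc2, h))
}

# Pre-norm transformer stack with a final layer norm.
nn_transformer <- function(layers, d, heads, mlp_ratio = 4) {
  list(d = d,
       blocks = lapply(seq_len(layers), function(i) nn_block(d, heads, mlp_ratio)),
       ln_f = nn_layernorm(d))
}

nn_transformer_fwd <- function(tr, x, mask = NULL) {
  for (b in tr$blocks) x <- nn_block_fwd(b, x, mask = mask)
  nn_layernorm_fwd(tr$ln_f, x)
}

# Small MLP with ReLU activations; `dims` includes input and output widths.
nn_mlp <- function(dims) {
  list(layers = lapply(seq_len(length(dims) - 1L),
                       function(i) nn_linear(dims[i], dims[i + 1L])))
}

nn_mlp_fwd <- function(m, x) {
  nl <- length(m$layers)
  for (i in seq_len(nl)) {
    x <- nn_linear_fwd(m$layers[[i]], x)
    if (i < nl) x <- ag_relu(x)
  }
  x
}

# Recursively collect every parameter node inside a nested layer list.
nn_params <- function(obj) {
  out <- list()
  walk <- function(o) {
    if (is_node(o)) {
      if (o$param) out[[length(out) + 1L]] <<- o
    } else if (is.list(o)) {
      for (el in o) walk(el)
    }
  }
  walk(obj)
  out
}

nn_n_params <- function(obj) {
  sum(vapply(nn_params(obj), function(p) length(p$value), 1))
}

# Causal (autoregressive) additive mask for an n-position sequence.
nn_causal_mask <- function(n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- -Inf
  m
}
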