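# Tape-based reverse-mode automatic differentiation on dense matrices.
#
# Every neural component in the package (VQ codec, transformers, MLP heads)
# is expressed through the `ag_*` operations below. A node is an environment
# holding a value (always a base matrix), its parent nodes and a backward
# closure. Tracked nodes are appended to a global tape in creation order,
# which is already a topological order, so ag_backward() is a single reverse
# sweep with no graph search. Constants do not extend the tape, and forward
# passes under ag_no_grad() record nothing.

.ag <- new.env(parent = emptyenv())
.ag$grad_enabled <- TRUE
.ag$last <- NULL  # tail of the linked tape

#' Evaluate an expression without recording gradients
#'
#' Forward passes run inside `ag_no_grad()` build no backward graph, which
#' makes inference and metric evaluation cheap.
#'
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
ag_no_grad <- function(expr) {
  old <- .ag$grad_enabled
  .ag$grad_enabled <- FALSE
  on.exit(.ag$grad_enabled <- old)
  expr
}

ag_tape_clear <- function() {
  # unlink so stale nodes become collectable
  n <- .ag$last
  .ag$last <- NULL
  while (!is.null(n)) {
    p <- n$prev
    n$prev <- NULL
    n <- p
  }
  invisible(NULL)
}

# Tracked nodes join a linked tape in creation order (a topological order of
# the graph), so appending is O(1) and backward is a single reverse walk.
ag_node <- function(value, parents = NULL, bw = NULL) {
  track <- FALSE
  if (.ag$grad_enabled && !is.null(parents)) {
    for (p in parents) if (p$track) { track <- TRUE; break }
  }
  n <- new.env(parent = emptyenv())
  n$value <- value
  n$grad <- NULL
  n$param <- FALSE
  if (track) {
    n$parents <- parents
    n$bw <- bw
    n$track <- TRUE
    n$prev <- .ag$last
    .ag$last <- n
  } else {
    n$track <- FALSE
  }
  class(n) <- "ag_node"
  n
}

as_mat <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1L)
}

#' @keywords internal
ag_const <- function(x) ag_node(as_mat(x))

#' Create a trainable parameter node
#' @param x numeric matrix or vector of initial values.
#' @keywords internal
ag_param <- function(x) {
  n <- ag_node(as_mat(x))
  n$track <- TRUE
  n$param <- TRUE
  n
}

is_node <- function(x) is.environment(x) && inherits(x, "ag_node")
wrap <- function(x) if (is.environment(x)) x else ag_const(x)

ag_value <- function(x) x$value

# fast row-wise max via max.col (C level)
row_max <- function(x) x[cbind(seq_len(nrow(x)), max.col(x, ties.method = "first"))]

# broadcast a 1-row matrix over the rows of an n x d matrix
bcast <- function(v, nr) rep(as.vector(v), each = nr)

# ---- core ops ---------------------------------------------------------------

ag_matmul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  v <- a$value %*% b$value
  ag_node(v, list(a, b), function(g, n) {
    list(tcrossprod(g, n$parents[[2]]$value),
         crossprod(n$parents[[1]]$value, g))
  })
}

# fused affine map x %*% W + b (b broadcast over rows)
ag_linear_op <- function(x, W, b) {
  x <- wrap(x)
  v <- x$value %*% W$value
  v <- v + bcast(b$value, nrow(v))
  ag_node(v, list(x, W, b), function(g, n) {
    list(tcrossprod(g, n$parents[[2]]$value),
         crossprod(n$parents[[1]]$value, g),
         matrix(colSums(g), 1L))
  })
}

# addition with broadcasting of a 1-row matrix or a 1x1 scalar on either side
ag_add <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  av <- a$value; bv <- b$value
  v <- if (identical(dim(av), dim(bv))) av + bv
       else if (nrow(bv) == 1L && ncol(bv) == ncol(av)) av + bcast(bv, nrow(av))
       else if (length(bv) == 1L) av + bv[1L]
       else if (nrow(av) == 1L && ncol(av) == ncol(bv)) bv + bcast(av, nrow(bv))
       else if (length(av) == 1L) bv + av[1L]
       else stop("ag_add: incompatible shapes")
  reduce_to <- function(g, tv) {
    if (identical(dim(g), dim(tv))) g
    else if (length(tv) == 1L) matrix(sum(g), 1L, 1L)
    else matrix(colSums(g), 1L)
  }
  ag_node(v, list(a, b), function(g, n) {
    list(reduce_to(g, n$parents[[1]]$value), reduce_to(g, n$parents[[2]]$value))
  })
}

ag_sub <- function(a, b) ag_add(a, ag_scale(b, -1))

ag_scale <- function(a, k) {
  a <- wrap(a)
  ag_node(a$value * k, list(a), function(g, n) list(g * k))
}

ag_mul <- function(a, b) {
  a <- wrap(a); b <- wrap(b)
  av <- a$value; bv <- b$value
  brow_b <- nrow(bv) == 1L && ncol(bv) == ncol(av) && nrow(av) > 1L &&
    length(bv) > 1L
  brow_a <- nrow(av) == 1L && ncol(av) == ncol(bv) && nrow(bv) > 1L &&
    length(av) > 1L
  v <- if (identical(dim(av), dim(bv))) av * bv
       else if (length(bv) == 1L) av * bv[1L]
       else if (length(av) == 1L) bv * av[1L]
       else if (brow_b) av * bcast(bv, nrow(av))
       else if (brow_a) bv * bcast(av, nrow(bv))
       else stop("ag_mul: incompatible shapes")
  ag_node(v, list(a, b), function(g, n) {
    av <- n$parents[[1]]$value; bv <- n$parents[[2]]$value
    ga <- if (length(bv) == 1L) g * bv[1L]
          else if (brow_b) g * bcast(bv, nrow(g))
          else if (brow_a) matrix(colSums(g * bv), 1L)
          else g * bv
    gb <- if (length(av) == 1L) g * av[1L]
          else if (brow_a) g * bcast(av, nrow(g))
          else if (brow_b) matrix(colSums(g * av), 1L)
          else g * av
    if (length(av) == 1L && length(bv) > 1L) ga <- matrix(sum(g * bv), 1L, 1L)
    if (length(bv) == 1L && length(av) > 1L) gb <- matrix(sum(g * av), 1L, 1L)
    list(ga, gb)
  })
}

ag_t <- function(a) {
  a <- wrap(a)
  ag_node(t(a$value), list(a), function(g, n) list(t(g)))
}

ag_relu <- function(a) {
  a <- wrap(a)
  v <- a$value
  v[v < 0] <- 0
  ag_node(v, list(a), function(g, n) list(g * (n$parents[[1]]$value > 0)))
}

# tanh-approximation GELU; the derivative factor is cached at forward time
ag_gelu <- function(a) {
  a <- wrap(a)
  x <- a$value
  c0 <- sqrt(2 / pi)
  inner <- c0 * (x + 0.044715 * x^3)
  th <- tanh(inner)
  v <- 0.5 * x * (1 + th)
  n <- ag_node(v, list(a), function(g, n) list(g * n$dact))
  if (n$track)
    n$dact <- 0.5 * (1 + th) + 0.5 * x * (1 - th^2) * c0 * (1 + 3 * 0.044715 * x^2)
  n
}

ag_tanh <- function(a) {
  a <- wrap(a)
  v <- tanh(a$value)
  ag_node(v, list(a), function(g, n) list(g * (1 - n$value^2)))
}

ag_exp <- function(a) {
  a <- wrap(a)
  v <- exp(a$value)
  ag_node(v, list(a), function(g, n) list(g * n$value))
}

ag_log <- function(a) {
  a <- wrap(a)
  ag_node(log(a$value), list(a), function(g, n) list(g / n$parents[[1]]$value))
}

ag_square <- function(a) {
  a <- wrap(a)
  ag_node(a$value^2, list(a), function(g, n) list(2 * g * n$parents[[1]]$value))
}

ag_abs <- function(a) {
  a <- wrap(a)
  ag_node(abs(a$value), list(a), function(g, n) list(g * sign(n$parents[[1]]$value)))
}

# numerically stable log(1 + exp(x))
ag_softplus <- function(a) {
  a <- wrap(a)
  x <- a$value
  v <- pmax(x, 0) + log1p(exp(-abs(x)))
  ag_node(v, list(a), function(g, n) {
    list(g / (1 + exp(-n$parents[[1]]$value)))
  })
}

ag_reciprocal <- function(a) {
  a <- wrap(a)
  v <- 1 / a$value
  ag_node(v, list(a), function(g, n) list(-g * n$value^2))
}

ag_sigmoid <- function(a) {
  a <- wrap(a)
  v <- 1 / (1 + exp(-a$value))
  ag_node(v, list(a), function(g, n) list(g * n$value * (1 - n$value)))
}

ag_sum <- function(a) {
  a <- wrap(a)
  ag_node(matrix(sum(a$value), 1L, 1L), list(a), function(g, n) {
    v <- n$parents[[1]]$value
    list(matrix(g[1L], nrow(v), ncol(v)))
  })
}

ag_mean <- function(a) {
  a <- wrap(a)
  k <- length(a$value)
  ag_node(matrix(mean(a$value), 1L, 1L), list(a), function(g, n) {
    v <- n$parents[[1]]$value
    list(matrix(g[1L] / k, nrow(v), ncol(v)))
  })
}

# column means over rows -> 1 x d
ag_mean_rows <- function(a) {
  a <- wrap(a)
  nr <- nrow(a$value)
  ag_node(matrix(colMeans(a$value), 1L), list(a), function(g, n) {
    list(matrix(bcast(g / nr, nr), nrow = nr))
  })
}

# gather rows (embedding lookup); backward scatter-adds
ag_rows <- function(a, idx) {
  a <- wrap(a)
  ag_node(a$value[idx, , drop = FALSE], list(a), function(g, n) {
    v <- n$parents[[1]]$value
    out <- matrix(0, nrow(v), ncol(v))
    for (r in seq_along(idx)) out[idx[r], ] <- out[idx[r], ] + g[r, ]
    list(out)
  })
}

# gather rows and flatten them (row-major) into a single row vector
ag_flatten_rows <- function(a, idx) {
  a <- wrap(a)
  nc <- ncol(a$value)
  v <- matrix(t(a$value[idx, , drop = FALSE]), 1L)
  ag_node(v, list(a), function(g, n) {
    pv <- n$parents[[1]]$value
    out <- matrix(0, nrow(pv), nc)
    out[idx, ] <- matrix(g, ncol = nc, byrow = TRUE)
    list(out)
  })
}

# column slice
ag_cols <- function(a, idx) {
  a <- wrap(a)
  ag_node(a$value[, idx, drop = FALSE], list(a), function(g, n) {
    v <- n$parents[[1]]$value
    out <- matrix(0, nrow(v), ncol(v))
    out[, idx] <- g
    list(out)
  })
}

ag_rbind <- function(nodes) {
  nodes <- lapply(nodes, wrap)
  rows <- vapply(nodes, function(n) nrow(n$value), 1L)
  ag_node(do.call(rbind, lapply(nodes, ag_value)), nodes, function(g, n) {
    ends <- cumsum(rows)
    starts <- c(1L, ends[-length(ends)] + 1L)
    lapply(seq_along(rows), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ag_cbind <- function(nodes) {
  nodes <- lapply(nodes, wrap)
  cols <- vapply(nodes, function(n) ncol(n$value), 1L)
  ag_node(do.call(cbind, lapply(nodes, ag_value)), nodes, function(g, n) {
    ends <- cumsum(cols)
    starts <- c(1L, ends[-length(ends)] + 1L)
    lapply(seq_along(cols), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

ag_stopgrad <- function(a) {
  a <- wrap(a)
  ag_node(a$value)
}

# row-wise softmax of (scale * x + mask); softmax values cached for backward
ag_softmax_rows <- function(a, mask = NULL, scale = 1) {
  a <- wrap(a)
  x <- a$value * scale
  if (!is.null(mask)) x <- x + mask
  e <- exp(x - row_max(x))
  s <- e / rowSums(e)
  ag_node(s, list(a), function(g, n) {
    s <- n$value
    list(scale * s * (g - rowSums(g * s)))
  })
}

# mean cross-entropy of row logits against integer targets (fused, stable)
ag_cross_entropy_rows <- function(logits, targets) {
  logits <- wrap(logits)
  x <- logits$value
  m <- row_max(x)
  e <- exp(x - m)
  p <- e / rowSums(e)
  nr <- nrow(x)
  hit <- cbind(seq_len(nr), targets)
  nll <- (m + log(rowSums(e))) - x[hit]
  n <- ag_node(matrix(mean(nll), 1L, 1L), list(logits), function(g, n) {
    p <- n$p
    p[n$hit] <- p[n$hit] - 1
    list(g[1L] * p / nrow(p))
  })
  if (n$track) { n$p <- p; n$hit <- hit }
  n
}

# row-wise L2 normalization (fused for speed and stability)
ag_l2normalize_rows <- function(a, eps = 1e-12) {
  a <- wrap(a)
  x <- a$value
  r <- sqrt(rowSums(x^2)) + eps
  y <- x / r
  n <- ag_node(y, list(a), function(g, n) {
    y <- n$value
    list((g - y * rowSums(g * y)) / n$r)
  })
  if (n$track) n$r <- r
  n
}

ag_layernorm <- function(a, gamma, beta, eps = 1e-5) {
  a <- wrap(a)
  x <- a$value
  xc <- x - rowMeans(x)
  inv <- 1 / sqrt(rowMeans(xc^2) + eps)
  xhat <- xc * inv
  nr <- nrow(x)
  v <- xhat * bcast(gamma$value, nr) + bcast(beta$value, nr)
  n <- ag_node(v, list(a, gamma, beta), function(g, n) {
    xhat <- n$xhat
    gxhat <- g * bcast(n$parents[[2]]$value, nrow(g))
    gx <- n$inv * (gxhat - rowMeans(gxhat) - xhat * rowMeans(gxhat * xhat))
    list(gx, matrix(colSums(g * xhat), 1L), matrix(colSums(g), 1L))
  })
  if (n$track) { n$xhat <- xhat; n$inv <- inv }
  n
}

# Blockwise linear map: a strided 3D convolution whose kernel equals its
# stride visits each voxel block exactly once, so it is a linear map applied
# independently per block. `idx` (n_blocks x block_features) holds the input
# feature columns of each block; output columns of block k are contiguous.
ag_block_linear <- function(x, W, b, idx) {
  x <- wrap(x)
  xv <- x$value
  nb <- nrow(idx)
  co <- ncol(W$value)
  v <- matrix(0, nrow(xv), nb * co)
  for (k in seq_len(nb)) {
    v[, ((k - 1L) * co + 1L):(k * co)] <-
      xv[, idx[k, ], drop = FALSE] %*% W$value
  }
  v <- v + bcast(rep(as.vector(b$value), nb), nrow(v))
  ag_node(v, list(x, W, b), function(g, n) {
    xv <- n$parents[[1]]$value
    Wv <- n$parents[[2]]$value
    gx <- matrix(0, nrow(xv), ncol(xv))
    gW <- matrix(0, nrow(Wv), ncol(Wv))
    gb <- matrix(0, 1L, co)
    for (k in seq_len(nb)) {
      gk <- g[, ((k - 1L) * co + 1L):(k * co), drop = FALSE]
      cols <- idx[k, ]
      gx[, cols] <- gx[, cols] + tcrossprod(gk, Wv)
      gW <- gW + crossprod(xv[, cols, drop = FALSE], gk)
      gb <- gb + colSums(gk)
    }
    list(gx, gW, gb)
  })
}

# Scatter columns of x into a V-wide matrix at positions `spatial_idx`
# (a permutation when length(spatial_idx) == V).
ag_assign_cols <- function(x, spatial_idx, V) {
  x <- wrap(x)
  v <- matrix(0, nrow(x$value), V)
  v[, spatial_idx] <- x$value
  ag_node(v, list(x), function(g, n) list(g[, spatial_idx, drop = FALSE]))
}

# Fused multi-head self-attention core. Input is the concatenated QKV
# activation (n x 3d); output is the concatenated head outputs (n x d).
# Forward caches the per-head attention matrices for the hand-written
# backward pass.
ag_attention <- function(qkv, heads, mask = NULL) {
  qkv <- wrap(qkv)
  x <- qkv$value
  n <- nrow(x)
  d <- ncol(x) %/% 3L
  hd <- d %/% heads
  sc <- 1 / sqrt(hd)
  atts <- vector("list", heads)
  out <- matrix(0, n, d)
  for (h in seq_len(heads)) {
    off <- (h - 1L) * hd
    q <- x[, (off + 1L):(off + hd), drop = FALSE]
    k <- x[, (d + off + 1L):(d + off + hd), drop = FALSE]
    v <- x[, (2L * d + off + 1L):(2L * d + off + hd), drop = FALSE]
    s <- tcrossprod(q, k) * sc
    if (!is.null(mask)) s <- s + mask
    e <- exp(s - row_max(s))
    a <- e / rowSums(e)
    atts[[h]] <- a
    out[, (off + 1L):(off + hd)] <- a %*% v
  }
  node <- ag_node(out, list(qkv), function(g, n) {
    x <- n$parents[[1]]$value
    gx <- matrix(0, nrow(x), ncol(x))
    for (h in seq_len(heads)) {
      off <- (h - 1L) * hd
      q <- x[, (off + 1L):(off + hd), drop = FALSE]
      k <- x[, (d + off + 1L):(d + off + hd), drop = FALSE]
      v <- x[, (2L * d + off + 1L):(2L * d + off + hd), drop = FALSE]
      a <- n$atts[[h]]
      go <- g[, (off + 1L):(off + hd), drop = FALSE]
      ga <- tcrossprod(go, v)
      gs <- a * (ga - rowSums(ga * a))           # softmax backward
      gx[, (off + 1L):(off + hd)] <- (gs %*% k) * sc
      gx[, (d + off + 1L):(d + off + hd)] <- crossprod(gs, q) * sc
      gx[, (2L * d + off + 1L):(2L * d + off + hd)] <- crossprod(a, go)
    }
    list(gx)
  })
  if (node$track) node$atts <- atts
  node
}

# ---- backward pass ----------------------------------------------------------

#' Backpropagate from a scalar loss node
#'
#' Sweeps the tape in reverse creation order, accumulating gradients into
#' the `$grad` field of every reachable tracked node (parameters keep theirs
#' until the optimizer consumes them). The tape is cleared afterwards.
#'
#' @param loss an `ag_node` holding a 1x1 value.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(length(loss$value) == 1L)
  if (!loss$track) return(invisible(NULL))
  loss$grad <- matrix(1, 1L, 1L)
  n <- .ag$last
  while (!is.null(n)) {
    if (!is.null(n$grad) && !is.null(n$bw)) {
      pg <- n$bw(n$grad, n)
      parents <- n$parents
      for (j in seq_along(parents)) {
        p <- parents[[j]]
        if (!p$track) next
        g <- pg[[j]]
        if (is.null(g)) next
        p$grad <- if (is.null(p$grad)) g else p$grad + g
      }
      if (!n$param) n$grad <- NULL  # free intermediate gradients
    }
    n <- n$prev
  }
  ag_tape_clear()
  invisible(NULL)
}

# ---- optimizer --------------------------------------------------------------

#' Adam optimizer with decoupled weight decay
#'
#' @param params flat list of parameter nodes.
#' @param lr learning rate.
#' @param betas first/second moment decay rates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled L2 decay applied to the weights directly.
#' @param lr_mult optional per-parameter learning-rate multipliers.
#' @return optimizer state (environment).
#' @keywords internal
adam_new <- function(params, lr = 1e-3, betas = c(0.9, 0.999), eps = 1e-8,
                     weight_decay = 0, lr_mult = NULL) {
  st <- new.env(parent = emptyenv())
  st$params <- params
  st$lr <- lr
  st$b1 <- betas[1]; st$b2 <- betas[2]
  st$eps <- eps
  st$wd <- weight_decay
  st$t <- 0L
  st$mult <- if (is.null(lr_mult)) rep(1, length(params)) else lr_mult
  st$m <- lapply(params, function(p) array(0, dim(p$value)))
  st$v <- lapply(params, function(p) array(0, dim(p$value)))
  st
}

#' Take one optimizer step and zero the gradients
#' @param st state from [adam_new()].
#' @param clip global gradient-norm clip (Inf to disable).
#' @keywords internal
adam_step <- function(st, clip = 1.0) {
  st$t <- st$t + 1L
  if (is.finite(clip)) {
    tot <- 0
    for (p in st$params) if (!is.null(p$grad)) tot <- tot + sum(p$grad^2)
    nrm <- sqrt(tot)
    scale <- if (nrm > clip) clip / nrm else 1
  } else scale <- 1
  bc1 <- 1 - st$b1^st$t
  bc2 <- 1 - st$b2^st$t
  for (i in seq_along(st$params)) {
    p <- st$params[[i]]
    if (is.null(p$grad)) next
    g <- p$grad * scale
    st$m[[i]] <- st$b1 * st$m[[i]] + (1 - st$b1) * g
    st$v[[i]] <- st$b2 * st$v[[i]] + (1 - st$b2) * g^2
    mhat <- st$m[[i]] / bc1
    vhat <- st$v[[i]] / bc2
    upd <- (st$lr * st$mult[i]) * mhat / (sqrt(vhat) + st$eps)
    if (st$wd > 0) upd <- upd + st$lr * st$wd * p$value
    p$value <- p$value - upd
    p$grad <- NULL
  }
  invisible(NULL)
}

ag_zero_grads <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(NULL)
}

# Gaussian init helper used by all model constructors
ag_init <- function(nr, nc, sd = 0.02) {
  matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
}
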