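# Volume tokenizer: patch extraction, background filtering, axis-permutation
# augmentation, and a vector-quantized autoencoder (VQ-VAE) codec whose
# encoder/decoder are strided 3D convolutions with kernel = stride, trained
# with an L1 reconstruction objective plus codebook and commitment terms
# under a straight-through gradient estimator.

#' Tokenizer configuration
#'
#' @param patch_shape integer 3-vector, voxels per patch.
#' @param latent_grid integer 3-vector, latent positions per patch after
#'   downsampling; `patch_shape` must be divisible by the per-axis factors.
#' @param latent_channels feature dimensions per latent position; the
#'   codebook lives in this space (quantization is per latent position).
#' @param codebook_size number of codebook vectors (>= 2).
#' @param background_threshold minimum fraction of foreground voxels for a
#'   patch to survive [intensity_filter()].
#' @param hidden_channels channels of the intermediate convolution stage.
#' @return a `tokenizer_config` list; `compression_ratio(config)` gives
#'   input voxels per latent scalar.
#' @export
tokenizer_config <- function(patch_shape = c(8L, 8L, 4L),
                             latent_grid = c(2L, 2L, 2L),
                             latent_channels = 2L,
                             codebook_size = 256L,
                             background_threshold = 0.05,
                             hidden_channels = 16L) {
  patch_shape <- as.integer(patch_shape)
  latent_grid <- as.integer(latent_grid)
  if (any(patch_shape %% latent_grid != 0L))
    stop("patch_shape must be divisible by latent_grid")
  factors <- patch_shape %/% latent_grid
  if (!all(factors %in% c(1L, 2L, 4L)))
    stop("per-axis downsampling factors must be 1, 2 or 4")
  if (codebook_size < 2L) stop("codebook_size must be >= 2")
  if (background_threshold < 0 || background_threshold > 1)
    stop("background_threshold must be in [0,1]")
  structure(list(patch_shape = patch_shape, latent_grid = latent_grid,
                 latent_channels = as.integer(latent_channels),
                 codebook_size = as.integer(codebook_size),
                 background_threshold = background_threshold,
                 hidden_channels = as.integer(hidden_channels),
                 factors = factors),
            class = "tokenizer_config")
}

#' Full-scale tokenizer configuration (32x32x4 patches, codebook 8192)
#' @export
full_scale_tokenizer_config <- function() {
  tokenizer_config(patch_shape = c(32L, 32L, 4L), latent_grid = c(8L, 8L, 2L),
                   latent_channels = 2L, codebook_size = 8192L,
                   background_threshold = 0.05, hidden_channels = 32L)
}

#' Desk-scale tokenizer configuration (8x8x4 patches)
#' @export
desk_tokenizer_config <- function() tokenizer_config()

#' Compression ratio of a tokenizer configuration
#'
#' Input voxels per patch divided by latent scalars per patch (16 at full
#' scale).
#'
#' @param config a [tokenizer_config()].
#' @return a number.
#' @export
compression_ratio <- function(config) {
  prod(config$patch_shape) / (prod(config$latent_grid) * config$latent_channels)
}

# ---- patching ----------------------------------------------------------------

#' Split a volume into zero-padded patches
#'
#' Tiles the volume with `ceiling(dim / patch)` patches per axis; boundary
#' patches are zero-padded. Patching is a partition: every voxel belongs to
#' exactly one patch and grid coordinates (0-based) are bijective with
#' patches.
#'
#' @param volume an [mri_volume()] or a 3D array.
#' @param config a [tokenizer_config()].
#' @return list of patches, each with `voxels` (array of `patch_shape`),
#'   `grid_coord` (0-based integer 3-vector), `plane` and `orientation`.
#' @export
patch_volume <- function(volume, config) {
  if (inherits(volume, "mri_volume")) {
    vox <- volume$voxels; plane <- volume$plane; orientation <- volume$orientation
  } else {
    vox <- volume; plane <- "axial"; orientation <- "LPS"
  }
  d <- dim(vox)
  ps <- config$patch_shape
  ng <- as.integer(ceiling(d / ps))
  patches <- vector("list", prod(ng))
  i <- 0L
  for (gz in 0:(ng[3L] - 1L)) for (gy in 0:(ng[2L] - 1L)) for (gx in 0:(ng[1L] - 1L)) {
    p <- array(0, ps)
    xr <- (gx * ps[1L] + 1L):min((gx + 1L) * ps[1L], d[1L])
    yr <- (gy * ps[2L] + 1L):min((gy + 1L) * ps[2L], d[2L])
    zr <- (gz * ps[3L] + 1L):min((gz + 1L) * ps[3L], d[3L])
    p[seq_along(xr), seq_along(yr), seq_along(zr)] <- vox[xr, yr, zr]
    i <- i + 1L
    patches[[i]] <- list(voxels = p, grid_coord = c(gx, gy, gz),
                         plane = plane, orientation = orientation)
  }
  attr(patches, "volume_dim") <- d
  attr(patches, "grid_dim") <- ng
  patches
}

#' Reassemble a volume from its patches
#'
#' Inverse of [patch_volume()]; padding voxels are dropped.
#'
#' @param patches output of [patch_volume()].
#' @param volume_dim original volume dimensions (defaults to the attribute
#'   stored by [patch_volume()]).
#' @param config the [tokenizer_config()] used for patching.
#' @return a 3D array.
#' @export
unpatch_volume <- function(patches, config, volume_dim = attr(patches, "volume_dim")) {
  ps <- config$patch_shape
  out <- array(0, volume_dim)
  for (p in patches) {
    g <- p$grid_coord
    xr <- (g[1L] * ps[1L] + 1L):min((g[1L] + 1L) * ps[1L], volume_dim[1L])
    yr <- (g[2L] * ps[2L] + 1L):min((g[2L] + 1L) * ps[2L], volume_dim[2L])
    zr <- (g[3L] * ps[3L] + 1L):min((g[3L] + 1L) * ps[3L], volume_dim[3L])
    out[xr, yr, zr] <- p$voxels[seq_along(xr), seq_along(yr), seq_along(zr)]
  }
  out
}

#' Remove background patches by intensity
#'
#' A voxel is background when its intensity falls below `background_level`
#' (default: 5% of the maximum intensity over all patches). A patch is kept
#' when its fraction of foreground voxels is at least `threshold`; order is
#' preserved and an empty result is allowed.
#'
#' @param patches list of patches from [patch_volume()].
#' @param threshold foreground fraction cutoff in \[0,1\].
#' @param background_level absolute intensity below which a voxel counts as
#'   background; computed from the data when `NULL`.
#' @return the retained subset of `patches`.
#' @export
intensity_filter <- function(patches, threshold = 0.05, background_level = NULL) {
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0,1]")
  if (length(patches) == 0L) return(patches)
  if (is.null(background_level)) {
    mx <- max(vapply(patches, function(p) max(p$voxels), 1))
    background_level <- 0.05 * mx
  }
  keep <- vapply(patches, function(p) {
    mean(p$voxels >= background_level) >= threshold
  }, TRUE)
  out <- patches[keep]
  attr(out, "volume_dim") <- attr(patches, "volume_dim")
  attr(out, "grid_dim") <- attr(patches, "grid_dim")
  out
}

#' Randomly permute the image axes of a batch of patches
#'
#' Training-time augmentation: patches are bucketed by shape, one of the six
#' axis orders is drawn uniformly per bucket, and every patch in the bucket
#' is transposed accordingly. The voxel multiset of each patch is unchanged.
#'
#' @param batch list of patches.
#' @param seed integer seed.
#' @return the permuted batch (same order).
#' @export
random_axis_permutation <- function(batch, seed) {
  if (length(batch) == 0L) return(batch)
  perms <- list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  shapes <- vapply(batch, function(p) paste(dim(p$voxels), collapse = "x"), "")
  with_seed(seed, {
    out <- batch
    for (s in unique(shapes)) {
      members <- which(shapes == s)
      dims <- dim(batch[[members[1L]]]$voxels)
      if (any(vapply(members, function(i)
        !identical(dim(batch[[i]]$voxels), dims), TRUE)))
        stop("internal error: mixed shapes within a permutation bucket")
      perm <- perms[[sample.int(6L, 1L)]]
      for (i in members) out[[i]]$voxels <- aperm(out[[i]]$voxels, perm)
    }
    out
  })
}

# ---- VQ codec ----------------------------------------------------------------

# feature-column index matrix for blockwise convolution: rows enumerate the
# blocks of a `dims` grid (column-major), entries are input feature columns
# ((position-1)*ch + channel, channel fastest within a voxel)
block_index_matrix <- function(dims, k, ch) {
  nd <- dims %/% k
  nb <- prod(nd)
  bs <- prod(k) * ch
  idx <- matrix(0L, nb, bs)
  bi <- 0L
  for (bz in 0:(nd[3L] - 1L)) for (by in 0:(nd[2L] - 1L)) for (bx in 0:(nd[1L] - 1L)) {
    bi <- bi + 1L
    j <- 0L
    for (oz in 0:(k[3L] - 1L)) for (oy in 0:(k[2L] - 1L)) for (ox in 0:(k[1L] - 1L)) {
      px <- bx * k[1L] + ox; py <- by * k[2L] + oy; pz <- bz * k[3L] + oz
      pos <- px + dims[1L] * (py + dims[2L] * pz)  # 0-based column-major
      for (c in seq_len(ch)) {
        j <- j + 1L
        idx[bi, j] <- pos * ch + c
      }
    }
  }
  idx
}

# split a per-axis downsampling factor into two convolution stages
stage_kernels <- function(factors) {
  k1 <- ifelse(factors >= 2L, 2L, 1L)
  k2 <- factors %/% k1
  list(k1 = as.integer(k1), k2 = as.integer(k2))
}

#' Initialize a VQ-VAE codec
#'
#' Two strided convolution blocks (kernel = stride) on each side, ReLU
#' between stages; the codebook is initialized from encoder outputs on a
#' sample of the data during [train_vqvae()].
#'
#' @param config a [tokenizer_config()].
#' @param seed integer seed for weight initialization.
#' @return a `vq_codec` list holding parameter nodes and an index cache.
#' @export
vq_codec <- function(config, seed = 1L) {
  ch <- config$hidden_channels
  lc <- config$latent_channels
  sk <- stage_kernels(config$factors)
  b1 <- prod(sk$k1); b2 <- prod(sk$k2)
  with_seed(seed, {
    codec <- list(
      config = config, k1 = sk$k1, k2 = sk$k2,
      enc1 = list(W = ag_param(ag_init(b1, ch, sd = 0.3)),
                  b = ag_param(matrix(0, 1L, ch))),
      enc2 = list(W = ag_param(ag_init(b2 * ch, lc, sd = 0.1)),
                  b = ag_param(matrix(0, 1L, lc))),
      dec1 = list(W = ag_param(ag_init(lc, b2 * ch, sd = 0.1)),
                  b = ag_param(matrix(0, 1L, b2 * ch))),
      dec2 = list(W = ag_param(ag_init(ch, b1, sd = 0.3)),
                  b = ag_param(matrix(0, 1L, b1))),
      codebook = ag_param(ag_init(config$codebook_size, lc, sd = 0.05)),
      idx_cache = new.env(parent = emptyenv()))
    codec
  })
}

codec_indices <- function(codec, dims) {
  key <- paste(dims, collapse = "x")
  cached <- codec$idx_cache[[key]]
  if (!is.null(cached)) return(cached)
  ch <- codec$config$hidden_channels
  lc <- codec$config$latent_channels
  d1 <- dims %/% codec$k1
  d2 <- d1 %/% codec$k2
  if (any(dims %% codec$k1 != 0L) || any(d1 %% codec$k2 != 0L))
    stop("input dims ", key, " not divisible by codec strides")
  res <- list(
    d1 = d1, d2 = d2,
    enc1 = block_index_matrix(dims, codec$k1, 1L),
    enc2 = block_index_matrix(d1, codec$k2, ch),
    dec1_in = block_index_matrix(d2, c(1L, 1L, 1L), lc),
    dec1_out = as.vector(t(block_index_matrix(d1, codec$k2, ch))),
    dec2_in = block_index_matrix(d1, c(1L, 1L, 1L), ch),
    dec2_out = as.vector(t(block_index_matrix(dims, codec$k1, 1L))))
  codec$idx_cache[[key]] <- res
  res
}

# encoder forward on a batch node X (B x prod(dims)); returns z_e node
# (B x n_latent_positions * latent_channels, channel fastest)
codec_encode_node <- function(codec, X, dims) {
  ix <- codec_indices(codec, dims)
  h <- ag_relu(ag_block_linear(X, codec$enc1$W, codec$enc1$b, ix$enc1))
  ag_block_linear(h, codec$enc2$W, codec$enc2$b, ix$enc2)
}

codec_decode_node <- function(codec, Z, dims) {
  ix <- codec_indices(codec, dims)
  ch <- codec$config$hidden_channels
  h <- ag_block_linear(Z, codec$dec1$W, codec$dec1$b, ix$dec1_in)
  h <- ag_relu(ag_assign_cols(h, ix$dec1_out, prod(ix$d1) * ch))
  out <- ag_block_linear(h, codec$dec2$W, codec$dec2$b, ix$dec2_in)
  ag_assign_cols(out, ix$dec2_out, prod(dims))
}

#' Encode a patch to its continuous latent
#'
#' @param codec a trained or initialized [vq_codec()].
#' @param patch a patch from [patch_volume()] or a 3D array.
#' @return matrix (n latent positions x latent_channels) of `z_e`.
#' @export
codec_encode <- function(codec, patch) {
  vox <- if (is.list(patch)) patch$voxels else patch
  if (any(!is.finite(vox))) stop("non-finite voxels in patch")
  X <- matrix(as.vector(vox), 1L)
  z <- ag_no_grad(codec_encode_node(codec, ag_const(X), dim(vox)))$value
  lc <- codec$config$latent_channels
  matrix(z, ncol = lc, byrow = TRUE)
}

#' Quantize latents against a codebook
#'
#' Each latent position (row of `z_e`) is snapped to its nearest codebook
#' vector in Euclidean norm, ties broken toward the lowest index.
#'
#' @param z_e matrix (n positions x code dim).
#' @param codebook matrix (codebook size x code dim).
#' @return list with `z_q` (same shape as `z_e`) and integer `code_indices`
#'   (1-based).
#' @export
quantize <- function(z_e, codebook) {
  if (is_node(codebook)) codebook <- codebook$value
  z_e <- as_mat(z_e)
  if (any(!is.finite(z_e))) stop("non-finite latents")
  if (nrow(codebook) < 1L) stop("empty codebook")
  score <- z_e %*% t(codebook)
  score <- sweep(score, 2L, 0.5 * rowSums(codebook^2))
  idx <- max.col(score, ties.method = "first")
  list(z_q = codebook[idx, , drop = FALSE], code_indices = idx)
}

#' Decode a quantized latent back to a patch
#'
#' @param codec a [vq_codec()].
#' @param z_q matrix (n positions x latent_channels).
#' @param dims output patch dimensions.
#' @return 3D array of `dims`.
#' @export
codec_decode <- function(codec, z_q, dims = codec$config$patch_shape) {
  Z <- matrix(as.vector(t(z_q)), 1L)
  out <- ag_no_grad(codec_decode_node(codec, ag_const(Z), as.integer(dims)))$value
  array(out, dims)
}

#' Encode a patch into a latent token
#'
#' @param codec a [vq_codec()].
#' @param patch a patch from [patch_volume()].
#' @return a `latent_token`: `embedding` (flat quantized latent, position
#'   major with channels fastest), `code_indices`, and the patch
#'   `grid_coord`/`plane`/`orientation`.
#' @export
encode_patch <- function(codec, patch) {
  ze <- codec_encode(codec, patch)
  q <- quantize(ze, codec$codebook)
  structure(list(embedding = as.vector(t(q$z_q)),
                 code_indices = q$code_indices,
                 grid_coord = patch$grid_coord,
                 plane = patch$plane, orientation = patch$orientation),
            class = "latent_token")
}

# rows (b,p) with position fastest; channel columns
ze_positions <- function(zeB, lc) {
  B <- nrow(zeB)
  npos <- ncol(zeB) %/% lc
  arr <- array(t(zeB), c(lc, npos, B))
  t(matrix(arr, lc, npos * B))
}

positions_to_batch <- function(Zp, B, lc) {
  npos <- nrow(Zp) %/% B
  arr <- array(t(Zp), c(lc, npos, B))
  t(matrix(arr, lc * npos, B))
}

#' Train the VQ-VAE codec
#'
#' Minimizes mean L1 reconstruction error plus the vector-quantization
#' objective (codebook term and commitment term, weight 0.25) with
#' straight-through gradients. The codebook is initialized from encoder
#' outputs on a data sample. Axis-permutation augmentation is applied per
#' batch when `permute_augment` is `TRUE`.
#'
#' @param patches list of patches (all the same shape, e.g. after
#'   [patch_volume()] + [intensity_filter()]).
#' @param config a [tokenizer_config()].
#' @param epochs training epochs.
#' @param seed integer seed.
#' @param lr Adam learning rate.
#' @param batch_size minibatch size.
#' @param val_fraction held-out fraction for the validation trace.
#' @param permute_augment apply random axis permutations during training.
#' @param commitment_weight weight of the commitment term.
#' @return list with `codec` and `trace` (per-epoch train/validation L1).
#' @export
train_vqvae <- function(patches, config, epochs = 20L, seed = 1L, lr = 3e-3,
                        batch_size = 32L, val_fraction = 0.15,
                        permute_augment = TRUE, commitment_weight = 0.25) {
  if (length(patches) < 1L) stop("empty patch dataset")
  codec <- vq_codec(config, seed = seed)
  lc <- config$latent_channels
  n <- length(patches)
  with_seed(seed + 1L, {
    val_idx <- if (n >= 8L) sample.int(n, max(1L, round(val_fraction * n))) else integer(0)
    train_idx <- setdiff(seq_len(n), val_idx)

    # data-dependent codebook init: k-means over encoder outputs allocates
    # centers to rare but coherent latent clusters (e.g. bright lesions)
    samp <- train_idx[sample.int(length(train_idx), min(256L, length(train_idx)))]
    zs <- do.call(rbind, lapply(samp, function(i) codec_encode(codec, patches[[i]])))
    if (nrow(zs) > config$codebook_size) {
      km <- tryCatch(stats::kmeans(zs, centers = config$codebook_size,
                                   nstart = 3L, iter.max = 30L),
                     error = function(e) NULL)
      codec$codebook$value <- if (!is.null(km)) unname(km$centers) else
        zs[sample.int(nrow(zs), config$codebook_size), , drop = FALSE]
    } else {
      pick <- sample.int(nrow(zs), config$codebook_size, replace = TRUE)
      codec$codebook$value <- zs[pick, , drop = FALSE] +
        matrix(stats::rnorm(config$codebook_size * lc, sd = 0.01),
               config$codebook_size, lc)
    }

    params <- nn_params(codec[c("enc1", "enc2", "dec1", "dec2", "codebook")])
    opt <- adam_new(params, lr = lr)
    trace <- data.frame(epoch = integer(0), train_l1 = numeric(0),
                        val_l1 = numeric(0))
    batch_l1 <- function(idx, augment) {
      pb <- patches[idx]
      if (augment) pb <- random_axis_permutation(pb, sample.int(2^30, 1L))
      dims <- dim(pb[[1L]]$voxels)
      X <- t(vapply(pb, function(p) as.vector(p$voxels), numeric(prod(dims))))
      ze <- codec_encode_node(codec, ag_const(X), dims)
      Zp <- ze_positions(ze$value, lc)
      q <- quantize(Zp, codec$codebook$value)
      zqB <- positions_to_batch(q$z_q, nrow(X), lc)
      zq_st <- ag_add(ze, ag_const(zqB - ze$value))  # straight-through
      recon <- codec_decode_node(codec, zq_st, dims)
      l1 <- ag_mean(ag_abs(ag_sub(recon, ag_const(X))))
      e_sel <- ag_rows(codec$codebook, q$code_indices)
      cb_loss <- ag_mean(ag_square(ag_sub(e_sel, ag_const(Zp))))
      commit <- ag_mean(ag_square(ag_sub(ze, ag_const(zqB))))
      loss <- ag_add(l1, ag_add(cb_loss, ag_scale(commit, commitment_weight)))
      list(loss = loss, l1 = l1$value[1L], codes = q$code_indices,
           Zp = Zp, zq_pos = q$z_q)
    }
    usage <- integer(config$codebook_size)
    worst <- NULL  # (latent, error) pool for dead-code revival
    for (ep in seq_len(epochs)) {
      ord <- train_idx[sample.int(length(train_idx))]
      # bucket by shape so each minibatch is stackable
      shp <- vapply(ord, function(i) paste(dim(patches[[i]]$voxels), collapse = "x"), "")
      l1s <- c()
      usage[] <- 0L
      worst_z <- NULL; worst_e <- -Inf
      for (s in unique(shp)) {
        idxs <- ord[shp == s]
        starts <- seq(1L, length(idxs), by = batch_size)
        for (st in starts) {
          idx <- idxs[st:min(st + batch_size - 1L, length(idxs))]
          res <- batch_l1(idx, augment = permute_augment)
          ag_backward(res$loss)
          adam_step(opt)
          l1s <- c(l1s, res$l1)
          tb <- tabulate(res$codes, config$codebook_size)
          usage <- usage + tb
          qe <- rowSums((res$Zp - res$zq_pos)^2)
          top <- order(-qe)[seq_len(min(config$codebook_size, length(qe)))]
          if (max(qe) > worst_e) { worst_e <- max(qe); worst_z <- res$Zp[top, , drop = FALSE] }
        }
      }
      # dead-code revival: starved codes move to the latents the codebook
      # currently represents worst, preventing collapse onto dense regions
      dead <- which(usage <= 0.01 * sum(usage) / config$codebook_size)
      if (length(dead) > 0L && !is.null(worst_z)) {
        take <- min(length(dead), nrow(worst_z))
        codec$codebook$value[dead[seq_len(take)], ] <-
          worst_z[seq_len(take), , drop = FALSE]
      }
      val_l1 <- NA_real_
      if (length(val_idx) > 0L) {
        val_l1 <- ag_no_grad(batch_l1(val_idx, augment = FALSE))$l1
      }
      trace <- rbind(trace, data.frame(epoch = ep, train_l1 = mean(l1s),
                                       val_l1 = val_l1))
    }
    list(codec = codec, trace = trace)
  })
}

#' Reconstruction L1 of a codec on a set of patches
#' @param codec a [vq_codec()].
#' @param patches list of same-shape patches.
#' @return mean absolute reconstruction error.
#' @export
codec_reconstruction_l1 <- function(codec, patches) {
  dims <- dim(patches[[1L]]$voxels)
  X <- t(vapply(patches, function(p) as.vector(p$voxels), numeric(prod(dims))))
  lc <- codec$config$latent_channels
  ag_no_grad({
    ze <- codec_encode_node(codec, ag_const(X), dims)
    Zp <- ze_positions(ze$value, lc)
    q <- quantize(Zp, codec$codebook$value)
    zqB <- positions_to_batch(q$z_q, nrow(X), lc)
    recon <- codec_decode_node(codec, ag_const(zqB), dims)
    mean(abs(recon$value - X))
  })
}

#' Tokenize one volume
#'
#' Patches the volume, removes background patches, and encodes each retained
#' patch to a quantized latent token.
#'
#' @param codec a trained [vq_codec()].
#' @param volume an [mri_volume()].
#' @param config tokenizer configuration (defaults to the codec's).
#' @param threshold background filter threshold (defaults to the config's).
#' @return list of `latent_token`s; attribute `grid_dim` holds the token
#'   grid dimensions.
#' @export
tokenize_volume <- function(codec, volume, config = codec$config,
                            threshold = config$background_threshold) {
  patches <- patch_volume(volume, config)
  mx <- max(vapply(patches, function(p) max(p$voxels), 1))
  fracs <- vapply(patches, function(p) mean(p$voxels >= 0.05 * mx), 1)
  kept_idx <- which(fracs >= threshold)
  kept <- patches[kept_idx]
  if (length(kept) == 0L) {
    out <- list()
    attr(out, "grid_dim") <- attr(patches, "grid_dim")
    return(out)
  }
  dims <- dim(kept[[1L]]$voxels)
  X <- t(vapply(kept, function(p) as.vector(p$voxels), numeric(prod(dims))))
  lc <- codec$config$latent_channels
  zeB <- ag_no_grad(codec_encode_node(codec, ag_const(X), dims))$value
  Zp <- ze_positions(zeB, lc)
  q <- quantize(Zp, codec$codebook$value)
  npos <- ncol(zeB) %/% lc
  out <- lapply(seq_along(kept), function(i) {
    rows <- ((i - 1L) * npos + 1L):(i * npos)
    structure(list(embedding = as.vector(t(q$z_q[rows, , drop = FALSE])),
                   code_indices = q$code_indices[rows],
                   grid_coord = kept[[i]]$grid_coord,
                   plane = kept[[i]]$plane, orientation = kept[[i]]$orientation,
                   fg_frac = fracs[kept_idx[i]]),
              class = "latent_token")
  })
  attr(out, "grid_dim") <- attr(patches, "grid_dim")
  out
}

#' Tokenize every sequence of a study
#'
#' @param codec a trained [vq_codec()].
#' @param study an [mri_study()].
#' @param config,threshold see [tokenize_volume()].
#' @return a `tokenized_study`: study name, patient id, abnormal flag and a
#'   list of per-sequence elements, each with the sequence `name`, its
#'   `tokens` and the token `grid_dim`.
#' @export
tokenize_study <- function(codec, study, config = codec$config,
                           threshold = config$background_threshold) {
  seqs <- lapply(study$sequences, function(s) {
    toks <- tokenize_volume(codec, s, config, threshold)
    list(name = s$sequence_name, tokens = toks,
         grid_dim = attr(toks, "grid_dim"))
  })
  structure(list(study_name = study$study_name,
                 patient_id = study$patient_id,
                 abnormal = study$abnormal,
                 sequences = seqs),
            class = "tokenized_study")
}

#' Token-grid cells overlapped by a voxel mask
#'
#' Maps a ground-truth lesion voxel mask onto the tokenizer's patch grid.
#'
#' @param mask logical 3D array.
#' @param config a [tokenizer_config()].
#' @return integer matrix (n cells x 3) of 0-based grid coordinates.
#' @export
mask_token_cells <- function(mask, config) {
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0L)
    return(matrix(integer(0), 0L, 3L))
  g <- unique((w - 1L) %/% matrix(config$patch_shape, nrow(w), 3L, byrow = TRUE))
  storage.mode(g) <- "integer"
  unname(g)
}
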