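# Volume tokenizer: exact tiling and reassembly, background filtering against
# a per-voxel counting oracle, axis-permutation statistics, quantizer-oracle
# equivalence, compression identities and VQ-VAE training behavior.

test_that("patch counts follow the ceiling rule and pad with zeros", {
  cfg <- tokenizer_config(patch_shape = c(32L, 32L, 4L),
                          latent_grid = c(8L, 8L, 2L))
  p <- patch_volume(array(1, c(64, 64, 8)), cfg)
  expect_length(p, 8)
  p2 <- patch_volume(array(1, c(33, 32, 4)), cfg)
  expect_length(p2, 2)
  expect_equal(sum(p2[[2]]$voxels != 0), 32 * 4)  # 31 padded columns
  coords <- t(vapply(p, function(q) q$grid_coord, integer(3)))
  expect_equal(nrow(unique(coords)), length(p))  # grid coords bijective
})

test_that("unpatching reconstructs random volumes exactly", {
  cfg <- desk_tokenizer_config()
  set.seed(5)
  for (i in 1:20) {
    d <- c(sample(5:40, 2), sample(3:12, 1))
    v <- array(runif(prod(d)), d)
    expect_identical(unpatch_volume(patch_volume(v, cfg), cfg), v)
  }
})

test_that("intensity filter matches a per-voxel counting oracle", {
  cfg <- desk_tokenizer_config()
  sr <- generate_study(3, "tumor")
  vol <- sr$study$sequences[[1]]
  patches <- patch_volume(vol, cfg)
  kept <- intensity_filter(patches, 0.05)
  lvl <- 0.05 * max(vapply(patches, function(p) max(p$voxels), 1))
  oracle <- vapply(patches, function(p) mean(p$voxels >= lvl) >= 0.05, TRUE)
  expect_length(kept, sum(oracle))
  expect_gt(length(kept), 0)
  expect_lt(length(kept), length(patches))  # background exists and is removed
  # threshold 0 keeps everything; an all-zero patch is dropped at 0.05
  expect_length(intensity_filter(patches, 0), length(patches))
  zero <- list(list(voxels = array(0, cfg$patch_shape), grid_coord = c(0L, 0L, 0L)))
  expect_length(intensity_filter(c(zero, patches[1]), 0.05), 1)
})

test_that("axis permutation preserves voxel multisets and is uniform", {
  cfg <- desk_tokenizer_config()
  p <- patch_volume(array(runif(8 * 8 * 4), c(8, 8, 4)), cfg)
  out <- random_axis_permutation(p, seed = 2)
  for (i in seq_along(p))
    expect_equal(sort(as.vector(out[[i]]$voxels)), sort(as.vector(p[[i]]$voxels)))
  # frequency of the 6 axis orders over 600 draws: 1/6 +- 3 SD
  one <- list(list(voxels = array(seq_len(24), c(2, 3, 4)), grid_coord = c(0L, 0L, 0L)))
  seen <- vapply(1:600, function(s)
    paste(dim(random_axis_permutation(one, s)[[1]]$voxels), collapse = "x"), "")
  freq <- table(seen) / 600
  expect_length(freq, 6)
  sd3 <- 3 * sqrt((1 / 6) * (5 / 6) / 600)
  expect_true(all(abs(freq - 1 / 6) < sd3))
})

test_that("identity permutation draw returns the input unchanged", {
  one <- list(list(voxels = array(seq_len(24), c(2, 3, 4)), grid_coord = c(0L, 0L, 0L)))
  hit <- FALSE
  for (s in 1:50) {
    out <- random_axis_permutation(one, s)
    if (identical(out[[1]]$voxels, one[[1]]$voxels)) { hit <- TRUE; break }
  }
  expect_true(hit)
})

test_that("quantizer equals exhaustive nearest-neighbor search with low ties", {
  set.seed(8)
  for (trial in 1:100) {
    cb <- matrix(rnorm(32), 16, 2)
    ze <- matrix(rnorm(20), 10, 2)
    q <- quantize(ze, cb)
    oracle <- apply(ze, 1, function(z) {
      d <- colSums((t(cb) - z)^2)
      which(d == min(d))[1]  # lowest index on ties
    })
    expect_identical(q$code_indices, unname(oracle))
    expect_identical(q$z_q, cb[oracle, , drop = FALSE])
  }
  # single-entry codebook forces index 1
  q1 <- quantize(matrix(rnorm(6), 3, 2), matrix(c(0, 0), 1, 2))
  expect_identical(q1$code_indices, rep(1L, 3))
})

test_that("full-scale configuration compresses 16x with 256-long latents", {
  cfg <- full_scale_tokenizer_config()
  expect_equal(compression_ratio(cfg), 16)
  expect_equal(prod(cfg$latent_grid) * cfg$latent_channels, 256)
  expect_equal(cfg$codebook_size, 8192L)
  codec <- vq_codec(cfg, seed = 1)
  tok <- encode_patch(codec, list(voxels = array(runif(32 * 32 * 4), c(32, 32, 4)),
                                  grid_coord = c(0L, 0L, 0L),
                                  plane = "axial", orientation = "LPS"))
  expect_length(tok$embedding, 256)
  expect_true(all(tok$code_indices >= 1 & tok$code_indices <= 8192))
})

test_that("invalid configurations are rejected", {
  expect_error(tokenizer_config(patch_shape = c(9, 8, 4)), "divisible")
  expect_error(tokenizer_config(codebook_size = 1), "codebook_size")
  expect_error(intensity_filter(list(list(voxels = array(1, c(2, 2, 2)))), -0.1),
               "threshold")
  expect_error(quantize(matrix(Inf, 1, 2), matrix(0, 4, 2)), "non-finite")
})

test_that("VQ-VAE training reduces reconstruction error", {
  codec <- fix_codec()
  cohort <- fix_cohort()
  cfg <- codec$config
  trace <- fixture("codec_trace", function() NULL)
  # retrain a tiny codec to inspect its trace
  pats <- intensity_filter(patch_volume(cohort[[1]]$study$sequences[[1]], cfg),
                           cfg$background_threshold)
  fit <- train_vqvae(pats, cfg, epochs = 6, seed = 2)
  expect_lt(tail(fit$trace$train_l1, 1), fit$trace$train_l1[1])
  expect_true(all(is.finite(fit$trace$val_l1)))
})

test_that("a constant-valued dataset is reconstructed almost exactly", {
  cfg <- desk_tokenizer_config()
  pats <- lapply(1:24, function(i)
    list(voxels = array(0.7, cfg$patch_shape), grid_coord = c(0L, 0L, 0L),
         plane = "axial", orientation = "LPS"))
  fit <- train_vqvae(pats, cfg, epochs = 80, seed = 3, batch_size = 8L,
                     permute_augment = FALSE)
  expect_lt(codec_reconstruction_l1(fit$codec, pats), 0.05)
})

test_that("the trained codec uses more than one code (no collapse)", {
  codec <- fix_codec()
  toks <- fix_tokenized()
  codes <- unlist(lapply(toks[1:5], function(ts)
    lapply(ts$sequences, function(sq)
      lapply(sq$tokens, function(tk) tk$code_indices))))
  expect_gt(length(unique(codes)), 1)
})

test_that("axis-permuted held-out patches reconstruct within 20% of unpermuted", {
  codec <- fix_codec()
  cohort <- fix_cohort()
  cfg <- codec$config
  pats <- intensity_filter(patch_volume(cohort[[9]]$study$sequences[[1]], cfg),
                           cfg$background_threshold)
  l1 <- codec_reconstruction_l1(codec, pats)
  perm <- lapply(pats, function(p) { p$voxels <- aperm(p$voxels, c(3, 1, 2)); p })
  l1p <- codec_reconstruction_l1(codec, perm)
  expect_lt(abs(l1p - l1) / l1, 0.2)
})

test_that("lesion masks map onto token-grid cells for overlap scoring", {
  cfg <- desk_tokenizer_config()
  sr <- generate_study(12, "tumor")
  masks <- sr$study$lesion_masks$tumor
  j <- which(!vapply(masks, is.null, TRUE))[1]
  cells <- mask_token_cells(masks[[j]], cfg)
  expect_gt(nrow(cells), 0)
  grid <- ceiling(dim(masks[[j]]) / cfg$patch_shape)
  expect_true(all(cells >= 0))
  expect_true(all(t(t(cells) < grid)))
  # brute-force voxel check: every masked voxel falls in a listed cell
  w <- which(masks[[j]], arr.ind = TRUE)
  key <- unique(paste((w[, 1] - 1) %/% cfg$patch_shape[1],
                      (w[, 2] - 1) %/% cfg$patch_shape[2],
                      (w[, 3] - 1) %/% cfg$patch_shape[3]))
  expect_setequal(key, paste(cells[, 1], cells[, 2], cells[, 3]))
})
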