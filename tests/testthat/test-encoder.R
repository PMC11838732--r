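# Hierarchical encoder: shape contracts at desk and full scale, input
# construction, permutation invariances, and weight sharing.

mk_tokens <- function(n, cfg, seed = 1) {
  radclip:::with_seed(seed, lapply(seq_len(n), function(i) {
    structure(list(embedding = rnorm(cfg$token_embed_dim),
                   code_indices = 1L,
                   grid_coord = c((i - 1L) %% 4L, (i - 1L) %/% 4L, 0L),
                   plane = "axial", orientation = "LPS", fg_frac = 1),
              class = "latent_token")
  }))
}

test_that("positional features are bounded sinusoids plus a plane one-hot", {
  pf <- positional_feature(c(0L, 0L, 0L), "axial")
  expect_length(pf, 33)
  expect_true(all(abs(pf[1:30]) <= 1))
  expect_equal(sum(pf[31:33]), 1)
  # tokens differing only in the first axis differ only in its 10 bands
  a <- positional_feature(c(0L, 2L, 1L), "coronal")
  b <- positional_feature(c(1L, 2L, 1L), "coronal")
  expect_true(any(a[1:10] != b[1:10]))
  expect_identical(a[11:33], b[11:33])
  expect_error(positional_feature(c(0L, 0L, 0L), "oblique"), "unknown plane")
})

test_that("sequence input is [registers | name | tokens] with matching length", {
  model <- fix_model()
  cfg <- model$config
  toks <- mk_tokens(7, cfg)
  nv <- rnorm(cfg$name_dim)
  built <- build_sequence_input(model$hvit, toks, nv)
  expect_equal(nrow(built$input$value), cfg$seq_registers + 1 + 7)
  expect_equal(built$n_tokens, 7)
  expect_length(built$attention_mask, cfg$seq_registers + 1 + 7)
  expect_error(build_sequence_input(model$hvit, list(), nv),
               "background-filtered")
})

test_that("desk-scale forward passes satisfy the configured shapes", {
  model <- fix_model()
  cfg <- model$config
  toks <- mk_tokens(9, cfg)
  nv <- rnorm(cfg$name_dim)
  out <- radclip:::ag_no_grad(
    vit_seq_forward(model$hvit, build_sequence_input(model$hvit, toks, nv)))
  expect_equal(dim(out$r$value), c(1L, cfg$rep_dim))
  expect_equal(nrow(out$registers$value), cfg$seq_registers)
  v <- radclip:::ag_no_grad(
    vit_st_forward(model$hvit, list(out$r), rnorm(cfg$name_dim)))
  expect_equal(ncol(v$value), cfg$study_dim)  # single-sequence study works
  pr <- radclip:::ag_no_grad(
    project_for_clip(model$hvit, as.vector(v$value),
                     rnorm(fix_report_lm()$dim)))
  expect_equal(ncol(pr$v_m$value), cfg$clip_proj_dim)
})

test_that("full-scale output dimensions are 1024, 10240 and 128", {
  cfg <- full_scale_encoder_config()
  expect_equal(cfg$rep_dim, 1024L)
  expect_equal(cfg$study_dim, 10240L)
  expect_equal(cfg$clip_proj_dim, 128L)
  hv <- hvit_new(cfg, seed = 2)
  toks <- mk_tokens(6, cfg)
  nv <- rnorm(cfg$name_dim)
  out <- radclip:::ag_no_grad(
    vit_seq_forward(hv, build_sequence_input(hv, toks, nv)))
  expect_equal(ncol(out$r$value), 1024L)
  v <- radclip:::ag_no_grad(vit_st_forward(hv, list(out$r, out$r),
                                           rnorm(cfg$name_dim)))
  expect_equal(ncol(v$value), 10240L)
  # parameter count lands within an order of magnitude of the printed total
  np <- radclip:::nn_n_params(hv[c("seq_registers", "vit_seq", "rep_proj",
                                   "st_registers", "vit_st", "st_out_proj",
                                   "seq_rep_proj")])
  expect_within(np / 1e6, 10, 500)
})

test_that("token order and sequence order permutations leave outputs unchanged", {
  model <- fix_model()
  cfg <- model$config
  toks <- mk_tokens(8, cfg, seed = 3)
  nv <- rnorm(cfg$name_dim)
  r1 <- radclip:::ag_no_grad(
    vit_seq_forward(model$hvit, build_sequence_input(model$hvit, toks, nv)))$r$value
  perm <- sample(8)
  r2 <- radclip:::ag_no_grad(
    vit_seq_forward(model$hvit,
                    build_sequence_input(model$hvit, toks[perm], nv)))$r$value
  expect_equal(r1, r2, tolerance = 1e-8)
  reps <- lapply(1:3, function(i) matrix(rnorm(cfg$rep_dim), 1))
  snv <- rnorm(cfg$name_dim)
  v1 <- radclip:::ag_no_grad(vit_st_forward(model$hvit, reps, snv))$value
  v2 <- radclip:::ag_no_grad(vit_st_forward(model$hvit, reps[c(3, 1, 2)], snv))$value
  expect_equal(v1, v2, tolerance = 1e-8)
})

test_that("different sequences map to different representations at init", {
  model <- fix_model()
  cfg <- model$config
  nv <- rnorm(cfg$name_dim)
  r1 <- radclip:::ag_no_grad(vit_seq_forward(
    model$hvit, build_sequence_input(model$hvit, mk_tokens(8, cfg, 4), nv)))$r$value
  r2 <- radclip:::ag_no_grad(vit_seq_forward(
    model$hvit, build_sequence_input(model$hvit, mk_tokens(8, cfg, 5), nv)))$r$value
  expect_gt(max(abs(r1 - r2)), 1e-6)
})

test_that("one sequence-transformer parameter set serves every sequence", {
  model <- fix_model()
  # the forward path closes over the same parameter environments regardless
  # of which sequence is encoded: object identity, not equality
  W1 <- model$hvit$vit_seq$blocks[[1]]$attn$Wqkv$W
  ts <- fix_tokenized()[[1]]
  expect_true(is.environment(W1))
  expect_identical(W1, model$hvit$vit_seq$blocks[[1]]$attn$Wqkv$W)
  n_before <- length(radclip:::nn_params(model$hvit$vit_seq))
  emb1 <- encode_study_embedding(model, ts)
  expect_length(radclip:::nn_params(model$hvit$vit_seq), n_before)
  expect_length(emb1, model$config$study_dim)
})

test_that("token embeddings of the wrong width are rejected", {
  model <- fix_model()
  bad <- mk_tokens(3, model$config)
  bad[[2]]$embedding <- rnorm(5)
  expect_error(build_sequence_input(model$hvit, bad, rnorm(model$config$name_dim)),
               "does not match")
})
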