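# Shared fixtures, built once per test run and cached in an environment.
# Everything is generated in code; no data files.

.fix <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

# small cohort of phantom studies with all four classes represented
fix_cohort <- function() fixture("cohort", function() {
  radclip::generate_cohort(24, 0.3, seed = 421)
})

# a trained desk-scale codec over patches drawn from the fixture cohort
fix_codec <- function() fixture("codec", function() {
  cohort <- fix_cohort()
  cfg <- radclip::desk_tokenizer_config()
  pats <- list()
  for (e in cohort[1:8]) for (s in e$study$sequences)
    pats <- c(pats, radclip::intensity_filter(radclip::patch_volume(s, cfg),
                                              cfg$background_threshold))
  set.seed(7)
  pats <- pats[sample(length(pats), min(400, length(pats)))]
  radclip::train_vqvae(pats, cfg, epochs = 25, seed = 11)$codec
})

fix_tokenized <- function() fixture("tokenized", function() {
  codec <- fix_codec()
  lapply(fix_cohort(), function(e) radclip::tokenize_study(codec, e$study))
})

fix_report_lm <- function() fixture("report_lm", function() {
  texts <- vapply(fix_cohort(), function(e) radclip::report_text(e$report), "")
  radclip::pretrain_report_lm(texts, epochs = 3, seed = 5)$state
})

# an untrained desk model bound to the fixture text encoder
fix_model <- function() fixture("model", function() {
  radclip::clip_model_new(radclip::desk_encoder_config(), fix_report_lm(),
                          seed = 3)
})

expect_within <- function(x, lo, hi) {
  expect_gte(x, lo)
  expect_lte(x, hi)
}

# The full end-to-end desk pipeline at its study conditions: a 200-study
# cohort with the four default classes, tokenizer + report LM + name-encoder
# pretraining, then joint CLIP + patient-discrimination training. Built once
# and shared by the end-to-end and explainability acceptance checks.
fix_desk_run <- function() fixture("desk_run", function() {
  seed <- 2024L
  cohort <- radclip::generate_cohort(200, 0.2, seed = seed)
  cfg <- radclip::desk_tokenizer_config()
  pats <- list()
  for (e in cohort[1:25]) for (s in e$study$sequences)
    pats <- c(pats, radclip::intensity_filter(radclip::patch_volume(s, cfg),
                                              cfg$background_threshold))
  pats <- radclip:::with_seed(seed + 1L,
    pats[sample(length(pats), min(600, length(pats)))])
  vq <- radclip::train_vqvae(pats, cfg, epochs = 10, seed = seed)
  toks <- lapply(cohort, function(e) radclip::tokenize_study(vq$codec, e$study))
  texts <- vapply(cohort, function(e) radclip::report_text(e$report), "")
  lmfit <- radclip::pretrain_report_lm(texts, epochs = 4, seed = seed)
  np <- list()
  for (ts in toks[1:60]) for (sq in ts$sequences) if (length(sq$tokens) > 0)
    np[[length(np) + 1L]] <- list(name = sq$name,
      visual = colMeans(t(sapply(sq$tokens, function(tk) tk$embedding))))
  snenc <- radclip::pretrain_sequence_name_encoder(np, epochs = 6, seed = seed,
    state = radclip::name_encoder(dim = 32L, layers = 2L, heads = 2L,
                                  out_dim = 32L, seed = seed + 100L))
  pairs <- lapply(seq_along(cohort), function(i)
    list(study = toks[[i]], report = cohort[[i]]$report))
  model <- radclip::clip_model_new(radclip::desk_encoder_config(), lmfit$state,
                                   seq_name_state = snenc, seed = seed)
  fit <- radclip::train_clip(pairs, model, epochs = 30, seed = seed,
                             batch_size = 32, lr = 2e-3,
                             policy = radclip::augment_policy(0.5, 0.3, 0.2, 0.2))
  emb <- t(sapply(pairs, function(e)
    radclip::encode_study_embedding(model, e$study)))
  labs <- t(sapply(cohort, function(e) e$report$labels))
  list(cohort = cohort, codec = vq$codec, pairs = pairs, model = model,
       trace = fit$trace, val_idx = fit$val_idx, emb = emb, labs = labs)
})
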