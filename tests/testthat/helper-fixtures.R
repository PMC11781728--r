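# Shared fixtures: random small models/sequences, and memoized trained
# models under the planted-signal study conditions (shared across the
# end-to-end tests so each model is trained once per session).

random_tagged_sequence <- function(n = 8, vocab_n = 20, with_pads = TRUE,
                                   C = 4) {
  n_real <- if (with_pads) sample(2:n, 1) else n
  types <- sample(entity_types(), n_real, replace = TRUE,
                  prob = c(0.55, 0.2, 0.15, 0.1))
  types[1] <- "OTHERS"
  tagged_sequence(
    tokens = c("[CLS]", sprintf("t%d", seq_len(n_real - 1))),
    token_ids = c(2L, sample(4:(vocab_n - 1), n_real - 1, replace = TRUE)),
    entity_types = types,
    segment_ids = sample(0:1, n_real, replace = TRUE),
    pad_flags = rep(FALSE, n_real),
    label = sample(0:(C - 1), 1)
  ) |>
    pad_and_truncate(n)
}

random_small_model <- function(n = 8, H = 2, d = 8, L = 2, vocab_n = 20,
                               seed = NULL, ...) {
  cfg <- model_config(L = L, H = H, d = d, C = 4, n_max = n,
                      vocab_size = vocab_n, entity_layers = seq_len(L),
                      dropout = 0, attn_dropout = 0, ...)
  params <- init_params(cfg, seed = if (is.null(seed)) sample.int(1e6, 1) else seed,
                        sigma = 0.3, sigma_entity = 0.3)
  list(config = cfg, params = params)
}

# ---- planted-signal study conditions -------------------------------------
# 2,500 training + 500 held-out records at full ambiguity (rho = 1), the
# 2-layer/4-head/64-dim profile, 6 training epochs. Models are cached per
# (seed, variant) for the session.

.fit_cache <- new.env(parent = emptyenv())

planted_conditions <- function(seed) {
  key <- paste0("corpus", seed)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  cfg <- generator_config(n_samples = 3000L, ambiguity_rate = 1, seed = seed)
  recs <- generate_corpus(cfg)
  vocab <- corpus_vocabulary(recs)
  out <- list(records = recs, vocab = vocab,
              train = recs[1:2400], dev = recs[2401:2500],
              test = recs[2501:3000])
  .fit_cache[[key]] <- out
  out
}

planted_model_config <- function(vocab, variant) {
  base <- small_config(vocab_size = vocab_size(vocab))
  switch(variant,
         full = base,
         blind = model_config(L = 2, H = 4, d = 64, C = 4, n_max = 128,
                              vocab_size = vocab_size(vocab),
                              entity_layers = integer(0),
                              use_entity_embedding = FALSE),
         ablation_variants(base, variant)[[1]])
}

planted_fit <- function(seed, variant) {
  key <- paste0("fit", seed, "_", variant)
  if (!is.null(.fit_cache[[key]])) return(.fit_cache[[key]])
  cond <- planted_conditions(seed)
  fit <- train(cond$train, cond$dev, vocab = cond$vocab,
               config = planted_model_config(cond$vocab, variant),
               tconf = train_config(epochs = 6L, seed = seed),
               max_len = 64L)
  .fit_cache[[key]] <- fit
  fit
}

planted_test_f1 <- function(seed, variant) {
  cond <- planted_conditions(seed)
  evaluate_model(planted_fit(seed, variant), cond$test)$macro_f1
}
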