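# Small fast corpora keep these runs to a few seconds: 1-layer, 16-dim
# models on a couple of hundred short records.

tiny_conditions <- function(n = 220, seed = 3, rho = 0) {
  cfg <- generator_config(n_samples = n, ambiguity_rate = rho,
                          qa_pairs_range = c(2, 3), tokens_per_answer = c(4, 6),
                          seed = seed)
  recs <- generate_corpus(cfg)
  list(records = recs, vocab = corpus_vocabulary(recs))
}

tiny_model <- function(vocab, entity_layers = 1L, ...) {
  model_config(L = 1, H = 2, d = 16, C = 4, n_max = 48,
               vocab_size = vocab_size(vocab), entity_layers = entity_layers,
               ...)
}

test_that("training is deterministic given the seed and learns the
           planted corpus", {
  cond <- tiny_conditions()
  tr <- cond$records[1:160]; dev <- cond$records[161:200]
  tc <- train_config(epochs = 5, batch_size = 8, seed = 0)
  fit1 <- train(tr, dev, vocab = cond$vocab, config = tiny_model(cond$vocab),
                tconf = tc, max_len = 40)
  fit2 <- train(tr, dev, vocab = cond$vocab, config = tiny_model(cond$vocab),
                tconf = tc, max_len = 40)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)
  # loss decreases over training on the planted corpus
  expect_lt(fit1$history$train_loss[5], fit1$history$train_loss[1])
  # checkpoint bookkeeping: best epoch is the argmax of the dev series
  expect_identical(fit1$best_epoch, which.max(fit1$history$dev_macro_f1))
  # a different seed gives a different trajectory
  fit3 <- train(tr, dev, vocab = cond$vocab, config = tiny_model(cond$vocab),
                tconf = train_config(epochs = 5, batch_size = 8, seed = 1),
                max_len = 40)
  expect_false(identical(fit1$history, fit3$history))
})

test_that("predict returns probabilities that sum to 1 and argmax classes", {
  cond <- tiny_conditions(n = 120, seed = 4)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 0)
  fit <- train(cond$records[1:80], cond$records[81:100], vocab = cond$vocab,
               config = tiny_model(cond$vocab), tconf = tc, max_len = 40)
  te <- cond$records[101:120]
  probs <- predict(fit, te, type = "prob")
  expect_identical(dim(probs), c(20L, 4L))
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-10)
  cls <- predict(fit, te)
  expect_identical(cls, max.col(probs) - 1L)
  rep <- evaluate_model(fit, te)
  expect_s3_class(rep, "metrics_report")
  expect_identical(rep$n, 20L)
})

test_that("nested cross-validation trains 15 runs per rate and aggregates
           fold means", {
  cond <- tiny_conditions(n = 90, seed = 5)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 0, lr_grid = 5e-4)
  res <- run_nested_cv(cond$records, config = tiny_model(cond$vocab),
                       tconf = tc, vocab = cond$vocab)
  expect_length(res$fold_metrics, 5L)
  expect_length(res$plan$triples, 15L)
  expect_equal(res$aggregate[["accuracy"]],
               mean(vapply(res$fold_metrics, `[[`, 0, "accuracy")),
               tolerance = 1e-12)
  expect_equal(res$aggregate[["macro_f1"]],
               mean(vapply(res$fold_metrics, `[[`, 0, "macro_f1")),
               tolerance = 1e-12)
  expect_true(all(res$selected_lr %in% tc$lr_grid))
  # the plan is reproducible from the same seed irrespective of when built
  plan2 <- nested_cv_splits(vapply(cond$records, `[[`, 0L, "label"), seed = 0)
  expect_identical(res$plan$outer_fold, plan2$outer_fold)
})

test_that("the ablation grid trains the named variants with the declared
           switches", {
  cond <- tiny_conditions(n = 120, seed = 6)
  split <- list(train = 1:80, dev = 81:100, test = 101:120)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 0)
  res <- ablation_grid(cond$records, split, config = tiny_model(cond$vocab),
                       tconf = tc,
                       variants = c("baseline", "embedding_only",
                                    "attention_only", "full", "wo_disease"),
                       vocab = cond$vocab)
  expect_identical(nrow(res$table), 5L)
  expect_identical(res$table$variant,
                   c("baseline", "embedding_only", "attention_only", "full",
                     "wo_disease"))
  cfgs <- lapply(res$fits, `[[`, "config")
  expect_false(cfgs$baseline$use_entity_embedding)
  expect_length(cfgs$baseline$entity_layers, 0L)
  expect_true(cfgs$embedding_only$use_entity_embedding)
  expect_length(cfgs$embedding_only$entity_layers, 0L)
  expect_false(cfgs$attention_only$use_entity_embedding)
  expect_gt(length(cfgs$attention_only$entity_layers), 0L)
  expect_setequal(cfgs$wo_disease$enabled_entity_types,
                  c("SYMPTOM", "LOCATION"))
})

test_that("the ablation baseline equals a separately built vanilla run", {
  cond <- tiny_conditions(n = 100, seed = 7)
  split <- list(train = 1:70, dev = 71:85, test = 86:100)
  tc <- train_config(epochs = 2, batch_size = 8, seed = 0)
  res <- ablation_grid(cond$records, split, config = tiny_model(cond$vocab),
                       tconf = tc, variants = "baseline", vocab = cond$vocab)
  direct <- train(cond$records[split$train], cond$records[split$dev],
                  vocab = cond$vocab,
                  config = tiny_model(cond$vocab, entity_layers = integer(0),
                                      use_entity_embedding = FALSE),
                  tconf = tc)
  expect_identical(res$fits$baseline$params, direct$params)
  expect_identical(res$fits$baseline$history, direct$history)
})

test_that("knockout variants collapse the removed type in the input codes", {
  cond <- tiny_conditions(n = 10, seed = 8)
  base <- tiny_model(cond$vocab)
  ko <- ablation_variants(base, "wo_disease")[[1]]
  seqs <- assemble_corpus(cond$records, cond$vocab, 40)
  te_full <- entattn:::tensorize(seqs, base)
  te_ko <- entattn:::tensorize(seqs, ko)
  dis <- 3L
  expect_false(any(te_ko$ent == dis))
  expect_identical(te_ko$ent[te_full$ent != dis], te_full$ent[te_full$ent != dis])
})
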