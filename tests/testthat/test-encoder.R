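test_that("encoder layer composes its sub-operations (compositional oracle)", {
  set.seed(51)
  for (rep in 1:10) {
    m <- random_small_model(n = 8, d = 8, H = 2, L = 1, vocab_n = 16)
    s <- random_tagged_sequence(n = 8, vocab_n = 16)
    masks <- list(M_glob = build_global_mask(s$pad_flags),
                  M_local = build_local_mask(s$entity_types, s$pad_flags))
    h <- embed(s, m$params, m$config)
    lp <- entattn:::layer_params(m$params, 1)
    got <- encoder_layer_forward(h, masks, lp, m$config)
    a <- oracle_mhsa(h, masks$M_glob, masks$M_local, lp, 2, TRUE)
    h1 <- oracle_layer_norm(h + a, lp$ln1_g, lp$ln1_b)
    want <- oracle_layer_norm(h1 + oracle_ffn(h1, lp), lp$ln2_g, lp$ln2_b)
    expect_lt(max(abs(got - want)), 1e-6)
    # deterministic in eval mode
    expect_identical(got, encoder_layer_forward(h, masks, lp, m$config))
  }
})

test_that("zeroed sublayers pass row-normalized input through unchanged", {
  m <- random_small_model(n = 5, d = 8, H = 2, L = 1, vocab_n = 16, seed = 8)
  s <- random_tagged_sequence(n = 5, vocab_n = 16)
  lp <- entattn:::layer_params(m$params, 1)
  for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
               "W1", "b1", "W2", "b2")) lp[[nm]][] <- 0
  masks <- list(M_glob = build_global_mask(s$pad_flags),
                M_local = build_local_mask(s$entity_types, s$pad_flags))
  # rows already mean 0 / variance 1 are fixed points of layer normalization
  h <- matrix(rnorm(40), 5, 8)
  h <- t(apply(h, 1, function(r) (r - mean(r)) / sqrt(mean((r - mean(r))^2))))
  out <- encoder_layer_forward(h, masks, lp, m$config)
  expect_equal(out, h, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("a one-layer encoder equals a single layer call on the embedding", {
  m <- random_small_model(n = 8, d = 8, H = 2, L = 1, vocab_n = 16, seed = 12)
  s <- random_tagged_sequence(n = 8, vocab_n = 16)
  masks <- list(M_glob = build_global_mask(s$pad_flags),
                M_local = build_local_mask(s$entity_types, s$pad_flags))
  fw <- encoder_forward(s, m$params, m$config)
  h <- embed(s, m$params, m$config)
  one <- encoder_layer_forward(h, masks, entattn:::layer_params(m$params, 1),
                               m$config)
  expect_equal(fw$hidden, one, tolerance = 1e-12)
  expect_equal(fw$h_cls, one[1, ], tolerance = 1e-12)
})

test_that("appending extra pads leaves h_cls unchanged (pad invariance)", {
  set.seed(61)
  for (rep in 1:10) {
    m <- random_small_model(n = 12, d = 8, H = 2, L = 2, vocab_n = 16)
    s <- random_tagged_sequence(n = 8, vocab_n = 16)
    s_more <- pad_and_truncate(s, 12)
    a <- encoder_forward(s, m$params, m$config)$h_cls
    b <- encoder_forward(s_more, m$params, m$config)$h_cls
    expect_lt(max(abs(a - b)), 1e-5)
  }
})

test_that("no entity layers + zero entity table reproduces an independent
           vanilla transformer classifier", {
  set.seed(71)
  for (rep in 1:8) {
    vocab_n <- 16
    cfg <- model_config(L = 2, H = 2, d = 8, C = 4, n_max = 10,
                        vocab_size = vocab_n, entity_layers = integer(0),
                        dropout = 0, attn_dropout = 0)
    params <- init_params(cfg, seed = rep, sigma = 0.3)
    params$ent_emb[] <- 0
    s <- random_tagged_sequence(n = 10, vocab_n = vocab_n)
    fw <- encoder_forward(s, params, cfg)
    got <- classify(fw$h_cls, params$cls_W, params$cls_b)
    want <- oracle_vanilla_classifier(s, params, cfg)
    expect_lt(max(abs(got - want)), 1e-5)
  }
})

test_that("the C++ fast path agrees with the R operations", {
  set.seed(81)
  for (rep in 1:6) {
    m <- random_small_model(n = 10, d = 8, H = 2, L = 2, vocab_n = 16)
    seqs <- lapply(1:4, function(i) random_tagged_sequence(n = 10, vocab_n = 16))
    te <- entattn:::tensorize(seqs, m$config)
    probs <- entattn:::cpp_forward(te$tok, te$ent, te$seg, te$pad, m$params,
                                   entattn:::cfg_for_cpp(m$config))
    for (i in seq_along(seqs)) {
      fw <- encoder_forward(seqs[[i]], m$params, m$config)
      expect_lt(max(abs(probs[i, ] -
                          classify(fw$h_cls, m$params$cls_W, m$params$cls_b))),
                1e-10)
    }
  }
})

test_that("analytic gradients match central finite differences", {
  m <- random_small_model(n = 8, d = 8, H = 2, L = 2, vocab_n = 16, seed = 33)
  seqs <- lapply(1:3, function(i) random_tagged_sequence(n = 8, vocab_n = 16))
  te <- entattn:::tensorize(seqs, m$config)
  ccfg <- entattn:::cfg_for_cpp(m$config)
  lg <- entattn:::cpp_loss_grad(te$tok, te$ent, te$seg, te$pad, te$labels,
                                m$params, ccfg)
  eps <- 1e-5
  set.seed(34)
  for (nm in c("tok_emb", "ent_emb", "emb_ln_g", "layer1.Wq", "layer1.Wg",
               "layer1.bg", "layer2.W1", "layer2.ln2_b", "cls_W",
               "layer1.Wo", "layer2.Wv", "pos_emb", "seg_emb", "layer2.bk")) {
    for (j in sample(length(m$params[[nm]]), min(4, length(m$params[[nm]])))) {
      p2 <- m$params
      p2[[nm]][j] <- p2[[nm]][j] + eps
      lp <- entattn:::cpp_loss_grad(te$tok, te$ent, te$seg, te$pad, te$labels,
                                    p2, ccfg)$loss
      p2[[nm]][j] <- p2[[nm]][j] - 2 * eps
      lm <- entattn:::cpp_loss_grad(te$tok, te$ent, te$seg, te$pad, te$labels,
                                    p2, ccfg)$loss
      expect_equal(lg$grads[[nm]][j], (lp - lm) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})

test_that("fully-masked local rows give finite gradients on an all-OTHERS
           batch (no NaN through the empty local path)", {
  m <- random_small_model(n = 8, d = 8, H = 2, L = 2, vocab_n = 16, seed = 44)
  seqs <- lapply(1:3, function(i) {
    s <- random_tagged_sequence(n = 8, vocab_n = 16)
    s$entity_types[] <- "OTHERS"
    s
  })
  te <- entattn:::tensorize(seqs, m$config)
  lg <- entattn:::cpp_loss_grad(te$tok, te$ent, te$seg, te$pad, te$labels,
                                m$params, entattn:::cfg_for_cpp(m$config))
  expect_true(is.finite(lg$loss))
  for (g in lg$grads) expect_true(all(is.finite(g)))
  # and the local-path projections receive exactly zero gradient via V
  # (the local matrices are identically zero so only the global path drives Wv)
  expect_true(all(is.finite(lg$grads[["layer1.Wg"]])))
})

test_that("checkpoints round-trip bit-exactly for eval outputs", {
  m <- random_small_model(n = 8, d = 8, H = 2, L = 2, vocab_n = 16, seed = 55)
  s <- random_tagged_sequence(n = 8, vocab_n = 16)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m$config, m$params, path, meta = list(note = "test"))
  ck <- load_checkpoint(path)
  expect_identical(ck$params, m$params)
  a <- encoder_forward(s, m$params, m$config)$h_cls
  b <- encoder_forward(s, ck$params, ck$config)$h_cls
  expect_identical(a, b)
  expect_identical(ck$meta$note, "test")
})
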