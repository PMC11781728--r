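test_that("global mask zeroes exactly the non-pad block", {
  expect_identical(build_global_mask(c(FALSE, FALSE, FALSE)), matrix(0, 3, 3))
  m <- build_global_mask(c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(m[1:2, 1:2], matrix(0, 2, 2))
  expect_true(all(m[3:4, ] == -Inf) && all(m[, 3:4] == -Inf))
  expect_true(all(build_global_mask(c(TRUE, TRUE)) == -Inf))
})

test_that("local mask admits only enabled medical entity pairs", {
  types <- c("OTHERS", "SYMPTOM", "LOCATION", "OTHERS")
  m <- build_local_mask(types, rep(FALSE, 4))
  expect_identical(which(m == 0), c(6L, 7L, 10L, 11L))  # (2,2),(3,2),(2,3),(3,3)
  expect_true(all(build_local_mask(rep("OTHERS", 3), rep(FALSE, 3)) == -Inf))
  # knockout: disease no longer counts as medically relevant
  m2 <- build_local_mask(c("SYMPTOM", "LOCATION", "DISEASE"), rep(FALSE, 3),
                         enabled_types = c("SYMPTOM", "LOCATION"))
  expect_identical(m2[1:2, 1:2], matrix(0, 2, 2))
  expect_true(all(m2[3, ] == -Inf) && all(m2[, 3] == -Inf))
  # entities on pad positions never unlock attention
  m3 <- build_local_mask(c("SYMPTOM", "SYMPTOM"), c(FALSE, TRUE))
  expect_identical(m3[1, 1], 0)
  expect_true(all(m3[2, ] == -Inf) && all(m3[, 2] == -Inf))
})

test_that("local mask zeros nest inside global mask zeros", {
  set.seed(31)
  for (rep in 1:50) {
    n <- sample(2:10, 1)
    n_real <- sample(1:n, 1)
    pads <- c(rep(FALSE, n_real), rep(TRUE, n - n_real))
    types <- c(sample(entity_types(), n_real, replace = TRUE),
               rep("OTHERS", n - n_real))
    Mg <- build_global_mask(pads)
    Ml <- build_local_mask(types, pads)
    expect_true(all(Mg[Ml == 0] == 0))
  }
})

test_that("masked softmax is exp-normalize over support, zeros elsewhere", {
  # closed form: row [0, ln 3] -> [0.25, 0.75]
  s <- matrix(c(0, log(3), 0, 0), 2, 2, byrow = TRUE)
  out <- masked_softmax(s, matrix(0, 2, 2))
  expect_equal(out[1, ], c(0.25, 0.75), tolerance = 1e-12)
  # fully masked row convention
  m <- matrix(c(0, 0, -Inf, -Inf), 2, 2, byrow = TRUE)
  out <- masked_softmax(matrix(rnorm(4), 2, 2), m)
  expect_identical(out[2, ], c(0, 0))
  expect_true(all(is.finite(out)))
  # random instances vs oracle
  set.seed(7)
  for (rep in 1:60) {
    n <- 6
    sc <- matrix(rnorm(n * n, sd = 3), n, n)
    mask <- matrix(ifelse(runif(n * n) < 0.4, -Inf, 0), n, n)
    got <- masked_softmax(sc, mask)
    expect_lt(max(abs(got - oracle_softmax(sc, mask))), 1e-10)
    rs <- rowSums(got)
    expect_true(all(abs(rs - 1) < 1e-12 | rs == 0))
  }
})

test_that("gate is the sigmoid of an affine map, one scalar per token", {
  h <- matrix(rnorm(12), 3, 4)
  expect_equal(compute_gate(h, matrix(0, 4, 1), 0), rep(0.5, 3))
  expect_equal(compute_gate(h, matrix(0, 4, 1), log(3)), rep(0.75, 3),
               tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:20) {
    h <- matrix(rnorm(40), 5, 8)
    W <- matrix(rnorm(8), 8, 1); b <- rnorm(1)
    want <- vapply(1:5, function(i) 1 / (1 + exp(-(sum(h[i, ] * W) + b))), 0)
    expect_lt(max(abs(compute_gate(h, W, b) - want)), 1e-12)
  }
})

test_that("gated head obeys its two gate limits and matches the naive loop", {
  set.seed(17)
  for (rep in 1:20) {
    n <- 8; dk <- 4; d <- 8
    h <- matrix(rnorm(n * d), n, d)
    hp <- list(Wq = matrix(rnorm(d * dk), d, dk), bq = matrix(rnorm(dk), 1),
               Wk = matrix(rnorm(d * dk), d, dk), bk = matrix(rnorm(dk), 1),
               Wv = matrix(rnorm(d * dk), d, dk), bv = matrix(rnorm(dk), 1))
    pads <- c(rep(FALSE, 6), TRUE, TRUE)
    types <- c("OTHERS", "SYMPTOM", "LOCATION", "DISEASE", "OTHERS", "SYMPTOM",
               "OTHERS", "OTHERS")
    masks <- list(M_glob = build_global_mask(pads),
                  M_local = build_local_mask(types, pads))
    g <- runif(n)
    expect_lt(max(abs(entity_aware_head(h, masks, hp, g) -
                        oracle_gated_head(h, masks$M_glob, masks$M_local, hp, g))),
              1e-6)
    # gate limits
    tr <- entity_aware_head(h, masks, hp, rep(1, n), return_trace = TRUE)
    expect_equal(tr$O_k, tr$S_local %*%
                   (sweep(h %*% hp$Wv, 2, as.numeric(hp$bv), "+")),
                 tolerance = 1e-10, ignore_attr = TRUE)
    tr0 <- entity_aware_head(h, masks, hp, rep(0, n), return_trace = TRUE)
    expect_equal(tr0$O_k, tr0$S_glob %*%
                   (sweep(h %*% hp$Wv, 2, as.numeric(hp$bv), "+")),
                 tolerance = 1e-10, ignore_attr = TRUE)
  }
})

test_that("fused attention rows are convex combinations: sum to 1 on local
           support, to 1 - g on empty local support", {
  set.seed(23)
  for (rep in 1:25) {
    m <- random_small_model(n = 8, d = 8, H = 2, L = 1, vocab_n = 16)
    s <- random_tagged_sequence(n = 8, vocab_n = 16)
    masks <- list(M_glob = build_global_mask(s$pad_flags),
                  M_local = build_local_mask(s$entity_types, s$pad_flags))
    h <- embed(s, m$params, m$config)
    res <- mhsa_forward(h, masks, entattn:::layer_params(m$params, 1), H = 2,
                        return_trace = TRUE)
    g <- res$trace$gate
    elig <- s$entity_types %in% medical_entity_types() & !s$pad_flags
    for (hd in 1:2) {
      fused <- res$trace$heads[[hd]]$fused
      for (i in which(!s$pad_flags)) {
        if (elig[i]) expect_equal(sum(fused[i, ]), 1, tolerance = 1e-6)
        else expect_equal(sum(fused[i, ]), 1 - g[i], tolerance = 1e-6)
      }
    }
  }
})

test_that("multi-head attention matches the naive reference, both modes", {
  set.seed(29)
  for (rep in 1:15) {
    m <- random_small_model(n = 8, d = 16, H = 2, L = 1, vocab_n = 16)
    s <- random_tagged_sequence(n = 8, vocab_n = 16)
    masks <- list(M_glob = build_global_mask(s$pad_flags),
                  M_local = build_local_mask(s$entity_types, s$pad_flags))
    h <- embed(s, m$params, m$config)
    lp <- entattn:::layer_params(m$params, 1)
    for (ea in c(TRUE, FALSE)) {
      got <- mhsa_forward(h, masks, lp, H = 2, entity_aware = ea)
      want <- oracle_mhsa(h, masks$M_glob, masks$M_local, lp, 2, ea)
      expect_lt(max(abs(got - want)), 1e-6)
    }
  }
})

test_that("single-head identity projection returns the head output", {
  m <- random_small_model(n = 6, d = 8, H = 1, L = 1, vocab_n = 16, seed = 2)
  s <- random_tagged_sequence(n = 6, vocab_n = 16)
  masks <- list(M_glob = build_global_mask(s$pad_flags),
                M_local = build_local_mask(s$entity_types, s$pad_flags))
  h <- embed(s, m$params, m$config)
  lp <- entattn:::layer_params(m$params, 1)
  lp$Wo <- diag(8); lp$bo <- matrix(0, 1, 8)
  g <- compute_gate(h, lp$Wg, lp$bg)
  O1 <- entity_aware_head(h, masks, entattn:::head_slice(lp, 1, 8), g)
  expect_equal(mhsa_forward(h, masks, lp, H = 1), O1, tolerance = 1e-12)
})

test_that("all-OTHERS sequences zero the local path so output is the
           (1 - g)-scaled global attention", {
  m <- random_small_model(n = 6, d = 8, H = 2, L = 1, vocab_n = 16, seed = 4)
  s <- random_tagged_sequence(n = 6, vocab_n = 16)
  s$entity_types[] <- "OTHERS"
  masks <- list(M_glob = build_global_mask(s$pad_flags),
                M_local = build_local_mask(s$entity_types, s$pad_flags))
  h <- embed(s, m$params, m$config)
  lp <- entattn:::layer_params(m$params, 1)
  res <- mhsa_forward(h, masks, lp, H = 2, return_trace = TRUE)
  for (hd in 1:2) {
    expect_true(all(res$trace$heads[[hd]]$S_local == 0))
  }
  expect_lt(max(abs(res$out - oracle_mhsa(h, masks$M_glob, masks$M_local,
                                          lp, 2, TRUE))), 1e-6)
})

test_that("feed-forward network computes the exact-GELU two-layer map", {
  lp <- list(W1 = matrix(rnorm(8 * 32), 8, 32), b1 = matrix(0, 1, 32),
             W2 = matrix(rnorm(32 * 8), 32, 8), b2 = matrix(0, 1, 8))
  expect_identical(ffn_forward(matrix(0, 3, 8), lp), matrix(0, 3, 8))
  # GELU(x) -> x for large x: scalar path with unit weights
  lp1 <- list(W1 = matrix(1, 1, 1), b1 = matrix(0, 1, 1),
              W2 = matrix(1, 1, 1), b2 = matrix(0, 1, 1))
  expect_equal(ffn_forward(matrix(10, 1, 1), lp1)[1, 1], 10, tolerance = 1e-3)
  set.seed(37)
  for (rep in 1:10) {
    x <- matrix(rnorm(4 * 8), 4, 8)
    lp$b1 <- matrix(rnorm(32), 1); lp$b2 <- matrix(rnorm(8), 1)
    expect_lt(max(abs(ffn_forward(x, lp) - oracle_ffn(x, lp))), 1e-6)
  }
})

test_that("classifier head is softmax over the affine map of h_cls", {
  expect_equal(classify(rnorm(8), matrix(0, 8, 4), rep(0, 4)), rep(0.25, 4))
  expect_equal(classify(rnorm(8), matrix(0, 8, 4), c(0, log(3), 0, 0)),
               c(1, 3, 1, 1) / 6, tolerance = 1e-12)
  set.seed(41)
  for (rep in 1:20) {
    h <- rnorm(8); W <- matrix(rnorm(32), 8, 4); b <- rnorm(4)
    z <- as.numeric(h %*% W) + b
    want <- exp(z) / sum(exp(z))
    p <- classify(h, W, b)
    expect_lt(max(abs(p - want)), 1e-12)
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
})
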