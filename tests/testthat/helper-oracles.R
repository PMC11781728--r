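# Independent reference implementations used as oracles. Everything here
# is written naively (explicit loops, textbook formulas) and shares no code
# with the package internals.

# exp-normalize over the unmasked support, row by row
oracle_softmax <- function(scores, mask) {
  n <- nrow(scores)
  out <- matrix(0, n, ncol(scores))
  for (i in seq_len(n)) {
    sup <- which(is.finite(mask[i, ]))
    if (length(sup) == 0) next
    e <- exp(scores[i, sup] - max(scores[i, sup]))
    out[i, sup] <- e / sum(e)
  }
  out
}

# naive single-head gated attention: explicit loops over query rows
oracle_gated_head <- function(hidden, M_glob, M_local, hp, gate) {
  n <- nrow(hidden)
  Q <- hidden %*% hp$Wq; K <- hidden %*% hp$Wk; V <- hidden %*% hp$Wv
  for (i in seq_len(n)) {
    Q[i, ] <- Q[i, ] + as.numeric(hp$bq)
    K[i, ] <- K[i, ] + as.numeric(hp$bk)
    V[i, ] <- V[i, ] + as.numeric(hp$bv)
  }
  dk <- ncol(Q)
  scores <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    scores[i, j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
  }
  Sg <- oracle_softmax(scores, M_glob)
  Sl <- oracle_softmax(scores, M_local)
  O <- matrix(0, n, dk)
  for (i in seq_len(n)) {
    row <- gate[i] * Sl[i, ] + (1 - gate[i]) * Sg[i, ]
    for (c in seq_len(dk)) O[i, c] <- sum(row * V[, c])
  }
  O
}

# naive multi-head attention block (entity-aware or plain)
oracle_mhsa <- function(hidden, M_glob, M_local, lp, H, entity_aware) {
  d <- ncol(hidden); dk <- d / H
  gate <- if (entity_aware) {
    as.numeric(1 / (1 + exp(-(hidden %*% lp$Wg + as.numeric(lp$bg)))))
  } else rep(0, nrow(hidden))
  concat <- NULL
  for (h in seq_len(H)) {
    idx <- ((h - 1) * dk + 1):(h * dk)
    hp <- list(Wq = lp$Wq[, idx, drop = FALSE], bq = lp$bq[, idx, drop = FALSE],
               Wk = lp$Wk[, idx, drop = FALSE], bk = lp$bk[, idx, drop = FALSE],
               Wv = lp$Wv[, idx, drop = FALSE], bv = lp$bv[, idx, drop = FALSE])
    Ml <- if (entity_aware) M_local else M_glob
    gt <- if (entity_aware) gate else rep(0, nrow(hidden))
    concat <- cbind(concat, oracle_gated_head(hidden, M_glob, Ml, hp, gt))
  }
  out <- concat %*% lp$Wo
  for (i in seq_len(nrow(out))) out[i, ] <- out[i, ] + as.numeric(lp$bo)
  out
}

oracle_layer_norm <- function(x, g, b, eps = 1e-12) {
  out <- x
  for (i in seq_len(nrow(x))) {
    mu <- mean(x[i, ])
    v <- mean((x[i, ] - mu)^2)
    out[i, ] <- (x[i, ] - mu) / sqrt(v + eps) * as.numeric(g) + as.numeric(b)
  }
  out
}

oracle_gelu <- function(x) x * 0.5 * (1 + erf_(x / sqrt(2)))
erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

oracle_ffn <- function(x, lp) {
  z <- x %*% lp$W1
  for (i in seq_len(nrow(z))) z[i, ] <- z[i, ] + as.numeric(lp$b1)
  a <- oracle_gelu(z)
  out <- a %*% lp$W2
  for (i in seq_len(nrow(out))) out[i, ] <- out[i, ] + as.numeric(lp$b2)
  out
}

# an independently coded standard (pad-masked) transformer classifier:
# embeddings without the entity table, plain masked attention in every
# layer, post-LN residuals, softmax head
oracle_vanilla_classifier <- function(seq, params, config) {
  n <- length(seq$token_ids)
  keep <- !seq$pad_flags
  M <- matrix(-Inf, n, n)
  M[keep, keep] <- 0
  e <- matrix(0, n, config$d)
  for (i in seq_len(n)) {
    e[i, ] <- params$tok_emb[seq$token_ids[i] + 1, ] +
      params$pos_emb[i, ] + params$seg_emb[seq$segment_ids[i] + 1, ]
  }
  h <- oracle_layer_norm(e, params$emb_ln_g, params$emb_ln_b)
  for (l in seq_len(config$L)) {
    lp <- list()
    for (nm in c("Wq", "bq", "Wk", "bk", "Wv", "bv", "Wo", "bo",
                 "ln1_g", "ln1_b", "W1", "b1", "W2", "b2", "ln2_g", "ln2_b")) {
      lp[[nm]] <- params[[paste0("layer", l, ".", nm)]]
    }
    a <- oracle_mhsa(h, M, NULL, lp, config$H, entity_aware = FALSE)
    h1 <- oracle_layer_norm(h + a, lp$ln1_g, lp$ln1_b)
    f <- oracle_ffn(h1, lp)
    h <- oracle_layer_norm(h1 + f, lp$ln2_g, lp$ln2_b)
  }
  z <- as.numeric(h[1, ] %*% params$cls_W) + as.numeric(params$cls_b)
  exp(z - max(z)) / sum(exp(z - max(z)))
}

# textbook per-class metrics computed with explicit loops
oracle_metrics <- function(cm) {
  C <- nrow(cm)
  prec <- rec <- f1 <- numeric(C)
  for (k in seq_len(C)) {
    tp <- cm[k, k]
    fp <- sum(cm[, k]) - tp
    fn <- sum(cm[k, ]) - tp
    prec[k] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k] <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1[k] <- if (prec[k] + rec[k] > 0) 2 * prec[k] * rec[k] / (prec[k] + rec[k]) else 0
  }
  list(accuracy = sum(diag(cm)) / sum(cm),
       precision = prec, recall = rec, f1 = f1,
       macro_precision = mean(prec), macro_recall = mean(rec),
       macro_f1 = mean(f1))
}

# binary MCC straight from the printed formula
oracle_mcc_binary <- function(tp, fn, fp, tn) {
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# multiclass MCC from the one-hot covariance definition: expand the
# confusion matrix to label vectors and correlate indicator matrices
oracle_mcc_multi <- function(cm) {
  C <- nrow(cm)
  y <- p <- integer(0)
  for (i in seq_len(C)) for (j in seq_len(C)) {
    y <- c(y, rep(i, cm[i, j])); p <- c(p, rep(j, cm[i, j]))
  }
  n <- length(y)
  if (n == 0) return(0)
  X <- matrix(0, n, C); Y <- matrix(0, n, C)
  X[cbind(seq_len(n), y)] <- 1; Y[cbind(seq_len(n), p)] <- 1
  covv <- function(A, B) {
    s <- 0
    for (k in seq_len(C)) s <- s + sum((A[, k] - mean(A[, k])) * (B[, k] - mean(B[, k])))
    s
  }
  den <- sqrt(covv(X, X)) * sqrt(covv(Y, Y))
  if (den == 0) return(0)
  covv(X, Y) / den
}

# exhaustive-span dictionary matcher: enumerates all candidate spans and
# resolves overlaps left-to-right preferring longer spans
oracle_span_tagger <- function(tokens, lexicon) {
  abbr <- c(SYMPTOM = "SYM", LOCATION = "LOC", DISEASE = "DIS")
  n <- length(tokens)
  spans <- list()
  for (e in lexicon$entries) {
    k <- length(e$tokens)
    if (k > n) next
    for (i in seq_len(n - k + 1)) {
      if (all(tokens[i:(i + k - 1)] == e$tokens)) {
        spans[[length(spans) + 1]] <- list(start = i, len = k, type = e$type)
      }
    }
  }
  tags <- rep("O", n)
  used <- rep(FALSE, n)
  if (length(spans) > 0) {
    ord <- order(vapply(spans, `[[`, 0, "start"),
                 -vapply(spans, `[[`, 0, "len"))
    for (s in spans[ord]) {
      pos <- s$start:(s$start + s$len - 1)
      if (any(used[pos])) next
      used[pos] <- TRUE
      tags[pos] <- c(paste0("B-", abbr[[s$type]]),
                     rep(paste0("I-", abbr[[s$type]]), s$len - 1))
    }
  }
  tags
}
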