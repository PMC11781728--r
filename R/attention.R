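# Gated entity-aware multi-head self-attention, feed-forward network,
# and the classification head. Hidden states are rows (n x d).

sigmoid <- function(x) 1 / (1 + exp(-x))

# exact (erf-form) GELU; erf(x) = 2*pnorm(x*sqrt(2)) - 1
gelu <- function(x) x * stats::pnorm(x)

#' Compute the per-token attention gate
#'
#' One sigmoid scalar per token, `g = sigmoid(h W_g + b_g)`, computed from
#' the layer's input hidden states and shared across all heads of the
#' layer. The gate convexly combines the entity-restricted (local) and
#' pad-masked (global) attention matrices.
#'
#' @param hidden n x d matrix of the layer's input hidden states.
#' @param W_g d x 1 gate weight.
#' @param b_g Scalar gate bias (or 1 x 1 matrix).
#' @return Numeric n-vector with entries in (0, 1).
#' @export
compute_gate <- function(hidden, W_g, b_g) {
  as.numeric(sigmoid(hidden %*% W_g + as.numeric(b_g)))
}

#' Single-head gated entity-aware attention
#'
#' Computes, for one head, the two masked attention matrices
#' `S_glob = softmax(Q K'/sqrt(d_k) + M_glob)` and
#' `S_local = softmax(Q K'/sqrt(d_k) + M_local)`, fuses them row-wise with
#' the gate, `g S_local + (1 - g) S_glob`, and applies the result to the
#' values.
#'
#' @param hidden n x d_in matrix of the layer's input hidden states.
#' @param masks List with `M_glob` and `M_local` additive masks.
#' @param head_params List with `Wq`, `Wk`, `Wv` (d_in x d_k) and `bq`,
#'   `bk`, `bv` (length-d_k) for this head.
#' @param gate Numeric n-vector from [compute_gate()].
#' @param return_trace Logical; also return `S_glob`, `S_local` and the
#'   fused matrix.
#' @return n x d_k output matrix, or a list when `return_trace = TRUE`.
#' @export
entity_aware_head <- function(hidden, masks, head_params, gate,
                              return_trace = FALSE) {
  Q <- hidden %*% head_params$Wq
  K <- hidden %*% head_params$Wk
  V <- hidden %*% head_params$Wv
  if (!is.null(head_params$bq)) Q <- sweep(Q, 2L, as.numeric(head_params$bq), `+`)
  if (!is.null(head_params$bk)) K <- sweep(K, 2L, as.numeric(head_params$bk), `+`)
  if (!is.null(head_params$bv)) V <- sweep(V, 2L, as.numeric(head_params$bv), `+`)
  d_k <- ncol(Q)
  scores <- tcrossprod(Q, K) / sqrt(d_k)
  S_glob <- masked_softmax(scores, masks$M_glob)
  S_local <- masked_softmax(scores, masks$M_local)
  fused <- gate * S_local + (1 - gate) * S_glob
  O_k <- fused %*% V
  if (return_trace) list(O_k = O_k, S_glob = S_glob, S_local = S_local,
                         fused = fused, gate = gate)
  else O_k
}

# slice one head's projections out of full d x d layer parameters
head_slice <- function(lp, h, d_k) {
  idx <- ((h - 1L) * d_k + 1L):(h * d_k)
  list(Wq = lp$Wq[, idx, drop = FALSE], bq = lp$bq[, idx, drop = FALSE],
       Wk = lp$Wk[, idx, drop = FALSE], bk = lp$bk[, idx, drop = FALSE],
       Wv = lp$Wv[, idx, drop = FALSE], bv = lp$bv[, idx, drop = FALSE])
}

#' Multi-head self-attention forward pass
#'
#' Runs all heads, concatenates their outputs and applies the output
#' projection `O = [O_1; ...; O_H] W_o + b_o`. With `entity_aware = FALSE`
#' every head uses the global (pad) mask only and the gate is not
#' evaluated — this is standard masked multi-head self-attention.
#'
#' @param hidden n x d matrix of the layer's input hidden states.
#' @param masks List with `M_glob` and `M_local`.
#' @param lp Layer parameter list (see [init_params()] layout).
#' @param H Number of heads.
#' @param entity_aware Logical; use gated entity-aware attention.
#' @param return_trace Logical; also return per-head matrices and the gate.
#' @return n x d output matrix, or a list when `return_trace = TRUE`.
#' @export
mhsa_forward <- function(hidden, masks, lp, H, entity_aware = TRUE,
                         return_trace = FALSE) {
  d <- ncol(hidden)
  stopifnot(d %% H == 0L)
  d_k <- d %/% H
  gate <- if (entity_aware) compute_gate(hidden, lp$Wg, lp$bg) else rep(0, nrow(hidden))
  trace <- if (return_trace) list(gate = gate, heads = vector("list", H)) else NULL
  O <- matrix(0, nrow(hidden), d)
  for (h in seq_len(H)) {
    hp <- head_slice(lp, h, d_k)
    if (entity_aware) {
      res <- entity_aware_head(hidden, masks, hp, gate, return_trace = return_trace)
    } else {
      Q <- sweep(hidden %*% hp$Wq, 2L, as.numeric(hp$bq), `+`)
      K <- sweep(hidden %*% hp$Wk, 2L, as.numeric(hp$bk), `+`)
      V <- sweep(hidden %*% hp$Wv, 2L, as.numeric(hp$bv), `+`)
      S <- masked_softmax(tcrossprod(Q, K) / sqrt(d_k), masks$M_glob)
      res <- if (return_trace) list(O_k = S %*% V, S_glob = S, S_local = NULL,
                                    fused = S) else S %*% V
    }
    O_k <- if (return_trace) res$O_k else res
    O[, ((h - 1L) * d_k + 1L):(h * d_k)] <- O_k
    if (return_trace) trace$heads[[h]] <- res
  }
  out <- sweep(O %*% lp$Wo, 2L, as.numeric(lp$bo), `+`)
  if (return_trace) list(out = out, trace = trace) else out
}

#' Position-wise feed-forward network
#'
#' `FFN(x) = GELU(x W_1 + b_1) W_2 + b_2` with the exact (erf-form) GELU;
#' `W_1` expands the hidden size four-fold and `W_2` projects back.
#'
#' @param x n x d input matrix.
#' @param lp Layer parameters (uses `W1`, `b1`, `W2`, `b2`).
#' @return n x d output matrix.
#' @export
ffn_forward <- function(x, lp) {
  h <- gelu(sweep(x %*% lp$W1, 2L, as.numeric(lp$b1), `+`))
  sweep(h %*% lp$W2, 2L, as.numeric(lp$b2), `+`)
}

#' Single encoder layer forward pass
#'
#' Post-LN residual ordering (original BERT):
#' `h' = LN(h + MHSA(h))`, `out = LN(h' + FFN(h'))`. Dropout is applied to
#' the two sublayer outputs only in training mode.
#'
#' @inheritParams mhsa_forward
#' @param config A [model_config()].
#' @param train_mode Logical; apply dropout.
#' @return n x d matrix, or a list when `return_trace = TRUE`.
#' @export
encoder_layer_forward <- function(hidden, masks, lp, config,
                                  entity_aware = TRUE, train_mode = FALSE,
                                  return_trace = FALSE) {
  att <- mhsa_forward(hidden, masks, lp, config$H, entity_aware,
                      return_trace = return_trace)
  a <- if (return_trace) att$out else att
  if (train_mode && config$dropout > 0) a <- dropout_mat(a, config$dropout)
  h1 <- layer_norm(hidden + a, lp$ln1_g, lp$ln1_b)
  f <- ffn_forward(h1, lp)
  if (train_mode && config$dropout > 0) f <- dropout_mat(f, config$dropout)
  out <- layer_norm(h1 + f, lp$ln2_g, lp$ln2_b)
  if (return_trace) list(out = out, trace = att$trace) else out
}

#' Full encoder forward pass
#'
#' Embeds a tagged sequence and runs it through all `L` encoder layers;
#' layer `l` uses gated entity-aware attention iff `l` is listed in
#' `config$entity_layers`. The class representation `h_cls` is row 1
#' (the `[CLS]` position) of the final hidden states.
#'
#' @param seq A [tagged_sequence()].
#' @param params Parameter list from [init_params()].
#' @param config A [model_config()].
#' @param train_mode Logical; apply dropout.
#' @param record_trace Logical; record per-layer attention matrices and
#'   gate vectors (the basis of [gate_summary()] / [attention_summary()]).
#' @return List with `hidden` (n x d final states), `h_cls` (d-vector) and,
#'   when recording, `trace` (per-layer list).
#' @export
encoder_forward <- function(seq, params, config, train_mode = FALSE,
                            record_trace = FALSE) {
  masks <- list(
    M_glob = build_global_mask(seq$pad_flags),
    M_local = build_local_mask(seq$entity_types, seq$pad_flags,
                               config$enabled_entity_types))
  h <- embed(seq, params, config, train_mode)
  trace <- if (record_trace) vector("list", config$L) else NULL
  for (l in seq_len(config$L)) {
    res <- encoder_layer_forward(h, masks, layer_params(params, l), config,
                                 entity_aware = l %in% config$entity_layers,
                                 train_mode = train_mode,
                                 return_trace = record_trace)
    if (record_trace) { h <- res$out; trace[[l]] <- res$trace } else h <- res
  }
  out <- list(hidden = h, h_cls = h[1L, ])
  if (record_trace) out$trace <- trace
  out
}

#' Classification head
#'
#' `p = softmax(h_cls W_p + b_p)`: class probabilities from the final
#' `[CLS]` hidden state.
#'
#' @param h_cls Numeric d-vector.
#' @param cls_W d x C weight matrix.
#' @param cls_b Length-C bias.
#' @return Probability vector of length C (sums to 1).
#' @export
classify <- function(h_cls, cls_W, cls_b) {
  z <- as.numeric(h_cls %*% cls_W) + as.numeric(cls_b)
  e <- exp(z - max(z))
  e / sum(e)
}
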