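# Embedding block: token + position + segment + entity lookups, summed,
# then layer normalization (and dropout in training mode).

# row-wise layer normalization; gain/shift are 1 x d matrices
layer_norm <- function(x, gain, shift, eps = 1e-12) {
  mu <- rowMeans(x)
  xc <- x - mu
  sd <- sqrt(rowMeans(xc^2) + eps)
  sweep(xc / sd, 2L, as.numeric(gain), `*`) +
    matrix(as.numeric(shift), nrow(x), ncol(x), byrow = TRUE)
}

#' Embed a tagged sequence
#'
#' Maps each position to the sum of its token, position, segment and
#' entity-type embedding vectors, followed by layer normalization; dropout
#' is applied only in training mode, so eval-mode calls are deterministic.
#' With `use_entity_embedding = FALSE` (or an all-zero entity table) this is
#' exactly the standard three-term transformer embedding block.
#'
#' @param seq A [tagged_sequence()].
#' @param params Parameter list from [init_params()].
#' @param config A [model_config()].
#' @param train_mode Logical; apply dropout.
#' @return n x d numeric matrix of initial hidden states.
#' @export
embed <- function(seq, params, config, train_mode = FALSE) {
  n <- length(seq$token_ids)
  if (any(seq$token_ids >= config$vocab_size)) stop("token id out of range")
  if (n > config$n_max) stop("sequence longer than n_max")
  e <- params$tok_emb[seq$token_ids + 1L, , drop = FALSE] +
    params$pos_emb[seq_len(n), , drop = FALSE] +
    params$seg_emb[seq$segment_ids + 1L, , drop = FALSE]
  if (config$use_entity_embedding) {
    codes <- effective_entity_codes(seq$entity_types, config)
    e <- e + params$ent_emb[codes + 1L, , drop = FALSE]
  }
  h <- layer_norm(e, params$emb_ln_g, params$emb_ln_b)
  if (train_mode && config$dropout > 0) h <- dropout_mat(h, config$dropout)
  h
}

# inverted dropout
dropout_mat <- function(x, rate) {
  keep <- matrix(stats::runif(length(x)) >= rate, nrow(x), ncol(x))
  x * keep / (1 - rate)
}
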