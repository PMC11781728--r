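# Parameter initialization and checkpointing.
#
# Parameters live in a flat named list of matrices (biases as 1-row
# matrices) so the same object passes unchanged to the C++ training core.
# Canonical names:
#   tok_emb (V x d), pos_emb (n_max x d), seg_emb (2 x d), ent_emb (4 x d),
#   emb_ln_g, emb_ln_b (1 x d),
#   layer<l>.{Wq,Wk,Wv (d x d), bq,bk,bv (1 x d), Wg (d x 1), bg (1 x 1),
#             Wo (d x d), bo (1 x d), ln1_g, ln1_b (1 x d),
#             W1 (d x 4d), b1 (1 x 4d), W2 (4d x d), b2 (1 x d),
#             ln2_g, ln2_b (1 x d)},
#   cls_W (d x C), cls_b (1 x C)
# Head h of a d x d projection occupies columns (h-1)*d_k + 1 .. h*d_k.

#' Initialize model parameters
#'
#' Weights are drawn N(0, 0.02^2) (the standard BERT initialization scale),
#' biases and normalization shifts start at 0, normalization gains at 1.
#' The `OTHERS` row of the entity embedding table starts at zero and the
#' three medical-entity rows at N(0, sigma_entity^2), keeping the
#' sparse-entity limit close to vanilla behaviour.
#'
#' @param config A [model_config()].
#' @param seed Integer seed; initialization is fully deterministic given it.
#' @param sigma Initialization scale for weights.
#' @param sigma_entity Initialization scale for the medical entity rows.
#' @return Named list of parameter matrices.
#' @export
init_params <- function(config, seed = 0L, sigma = 0.02, sigma_entity = 0.02) {
  stopifnot(inherits(config, "model_config"))
  set.seed(as.integer(seed))
  d <- config$d
  rnd <- function(nr, nc, s = sigma) matrix(stats::rnorm(nr * nc, 0, s), nr, nc)
  zeros <- function(nr, nc) matrix(0, nr, nc)
  ones <- function(nc) matrix(1, 1L, nc)
  p <- list(
    tok_emb = rnd(config$vocab_size, d),
    pos_emb = rnd(config$n_max, d),
    seg_emb = rnd(2L, d),
    ent_emb = rbind(zeros(1L, d), rnd(3L, d, sigma_entity)),
    emb_ln_g = ones(d), emb_ln_b = zeros(1L, d))
  for (l in seq_len(config$L)) {
    lp <- list(Wq = rnd(d, d), bq = zeros(1L, d),
               Wk = rnd(d, d), bk = zeros(1L, d),
               Wv = rnd(d, d), bv = zeros(1L, d),
               Wg = rnd(d, 1L), bg = zeros(1L, 1L),
               Wo = rnd(d, d), bo = zeros(1L, d),
               ln1_g = ones(d), ln1_b = zeros(1L, d),
               W1 = rnd(d, 4L * d), b1 = zeros(1L, 4L * d),
               W2 = rnd(4L * d, d), b2 = zeros(1L, d),
               ln2_g = ones(d), ln2_b = zeros(1L, d))
    names(lp) <- paste0("layer", l, ".", names(lp))
    p <- c(p, lp)
  }
  p$cls_W <- rnd(d, config$C)
  p$cls_b <- zeros(1L, config$C)
  p
}

# view of one layer's parameters without the name prefix
layer_params <- function(params, l) {
  pre <- paste0("layer", l, ".")
  keep <- startsWith(names(params), pre)
  lp <- params[keep]
  names(lp) <- substring(names(lp), nchar(pre) + 1L)
  lp
}

#' Save and load model checkpoints
#'
#' A checkpoint is a single RDS archive holding the model configuration and
#' the named parameter tensors (plus any metadata supplied). Eval-mode
#' outputs after a save/load round trip are bit-exact.
#'
#' @param config A [model_config()].
#' @param params Named parameter list as from [init_params()].
#' @param path File path.
#' @param meta Optional list of run metadata to store alongside.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(config, params, meta)`.
#' @export
save_checkpoint <- function(config, params, path, meta = NULL) {
  saveRDS(list(config = config, params = params, meta = meta), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$config, "model_config"), is.list(ck$params))
  ck
}
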