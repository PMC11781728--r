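# Training: tensorization, the AdamW loop (C++ core), prediction and
# evaluation.

#' Training configuration
#'
#' Defaults follow the reference schedule: batch size 4, 30 epochs, AdamW
#' (decoupled weight decay 1e-2), linear learning-rate schedule with a 0.1
#' warm-up ratio, learning rate selected among {5e-4, 5e-6} when grid
#' selection is used. The per-epoch checkpoint is kept at the maximum
#' validation macro F1.
#'
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param lr Learning rate used by [train()] directly.
#' @param lr_grid Learning-rate grid searched by [run_nested_cv()].
#' @param weight_decay Decoupled weight decay (not applied to biases or
#'   normalization parameters).
#' @param warmup_ratio Fraction of total steps spent in linear warm-up.
#' @param seed Integer seed controlling initialization, batching and
#'   dropout.
#' @param device Only `"cpu"` is supported.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 4L, epochs = 30L, lr = 5e-4,
                         lr_grid = c(5e-4, 5e-6), weight_decay = 1e-2,
                         warmup_ratio = 0.1, seed = 0L, device = "cpu") {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0, weight_decay >= 0,
            warmup_ratio >= 0, warmup_ratio < 1, identical(device, "cpu"))
  structure(list(batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), lr = lr, lr_grid = lr_grid,
                 weight_decay = weight_decay, warmup_ratio = warmup_ratio,
                 seed = as.integer(seed), device = device),
            class = "train_config")
}

# pack tagged sequences into 0-based integer matrices for the C++ core;
# entity codes are the *effective* codes (knockouts collapsed to OTHERS)
tensorize <- function(seqs, config) {
  n <- max(vapply(seqs, function(s) length(s$token_ids), 0L))
  N <- length(seqs)
  tok <- ent <- seg <- pad <- matrix(0L, N, n)
  labels <- integer(N)
  for (r in seq_len(N)) {
    s <- seqs[[r]]
    m <- length(s$token_ids)
    if (m < n) {  # right-pad to the common length
      s <- pad_and_truncate(s, n)
      m <- n
    }
    tok[r, ] <- s$token_ids
    ent[r, ] <- effective_entity_codes(s$entity_types, config)
    seg[r, ] <- s$segment_ids
    pad[r, ] <- as.integer(s$pad_flags)
    labels[r] <- s$label
  }
  list(tok = tok, ent = ent, seg = seg, pad = pad, labels = labels, n = n)
}

cfg_for_cpp <- function(config) {
  list(L = config$L, H = config$H, d = config$d, C = config$C,
       use_entity_embedding = config$use_entity_embedding,
       entity_aware = as.integer(seq_len(config$L) %in% config$entity_layers),
       dropout = config$dropout, attn_dropout = config$attn_dropout)
}

no_decay_flags <- function(params) {
  nm <- names(params)
  grepl("(^|\\.)b[a-z0-9]*$|ln|emb_ln", nm) & !grepl("Wg|W1|W2|Wo|Wq|Wk|Wv|cls_W|_emb", nm)
}

#' Train a classifier
#'
#' Minimizes cross-entropy on the softmax classifier output with AdamW and
#' a linear warm-up/decay schedule; after every epoch the model is scored
#' on the dev set by macro F1 and the best-scoring epoch's weights are the
#' returned model. Fully deterministic given `tconf$seed`.
#'
#' @param records Training corpus records.
#' @param dev_records Development records for model selection.
#' @param vocab A [build_vocabulary()]; built from `records` if `NULL`.
#' @param config A [model_config()]; a [small_config()] is built if `NULL`.
#' @param tconf A [train_config()].
#' @param max_len Model input length; defaults to `config$n_max`.
#' @return An object of class `entattn_fit`: list with `params` (weights of
#'   the best epoch), `final_params`, `config`, `vocab`, `tconf`, `history`
#'   (per-epoch train loss and dev macro F1) and `best_epoch`.
#' @export
train <- function(records, dev_records, vocab = NULL, config = NULL,
                  tconf = train_config(), max_len = NULL) {
  if (length(records) == 0L || length(dev_records) == 0L) stop("empty data")
  if (is.null(vocab)) vocab <- corpus_vocabulary(records)
  if (is.null(config)) config <- small_config(vocab_size = vocab_size(vocab))
  if (is.null(max_len)) max_len <- config$n_max
  tr <- tensorize(assemble_corpus(records, vocab, max_len), config)
  dv <- tensorize(assemble_corpus(dev_records, vocab, max_len), config)
  set.seed(tconf$seed)
  params <- init_params(config, seed = tconf$seed)
  tc <- unclass(tconf)
  tc$no_decay <- no_decay_flags(params)
  res <- cpp_train(tr$tok, tr$ent, tr$seg, tr$pad, tr$labels,
                   dv$tok, dv$ent, dv$seg, dv$pad, dv$labels,
                   params, cfg_for_cpp(config), tc)
  structure(list(params = res$params, final_params = res$final_params,
                 config = config, vocab = vocab, tconf = tconf,
                 history = data.frame(epoch = seq_along(res$train_loss),
                                      train_loss = res$train_loss,
                                      dev_macro_f1 = res$dev_macro_f1),
                 best_epoch = res$best_epoch,
                 max_len = max_len),
            class = "entattn_fit")
}

#' @export
print.entattn_fit <- function(x, ...) {
  cat("<entattn_fit> ", x$config$L, "-layer model, best epoch ", x$best_epoch,
      " (dev macro F1 ", sprintf("%.4f", max(x$history$dev_macro_f1)), ")\n",
      sep = "")
  invisible(x)
}

#' Predict classes or probabilities
#'
#' @param object An [train()] fit.
#' @param records Corpus records to score.
#' @param type `"class"` for 0-based predicted labels, `"prob"` for the
#'   N x C probability matrix.
#' @param ... Unused.
#' @return Integer vector or numeric matrix.
#' @export
predict.entattn_fit <- function(object, records, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  te <- tensorize(assemble_corpus(records, object$vocab, object$max_len),
                  object$config)
  probs <- cpp_forward(te$tok, te$ent, te$seg, te$pad, object$params,
                       cfg_for_cpp(object$config))
  if (type == "prob") probs else max.col(probs) - 1L
}

#' Evaluate a fitted model on a test corpus
#'
#' @param fit An [train()] fit.
#' @param records Test corpus records.
#' @return A [classification_metrics()] report.
#' @export
evaluate_model <- function(fit, records) {
  y <- vapply(records, function(r) r$label, 0L)
  p <- predict(fit, records)
  classification_metrics(confusion_matrix(y, p, fit$config$C))
}
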