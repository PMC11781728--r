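# Nested cross-validation driver and the ablation grid.

#' Run nested cross-validation
#'
#' For each outer fold, every learning rate in `tconf$lr_grid` is trained
#' on each inner train/dev split (so `outer * inner` runs per setting); the
#' rate with the best mean inner dev macro F1 is selected. By default the
#' best inner model under the selected rate is evaluated directly on the
#' outer test fold (retrain-free selection); with `retrain = TRUE` a fresh
#' model is trained on the full outer-training set instead, using the best
#' inner split's dev set for epoch selection.
#'
#' @param records Corpus records.
#' @param config A [model_config()]; built from the corpus if `NULL`.
#' @param tconf A [train_config()].
#' @param plan A [nested_cv_splits()] plan; built from the labels with
#'   `tconf$seed` if `NULL`.
#' @param retrain Logical; retrain on the outer-training set after rate
#'   selection.
#' @param vocab Optional [build_vocabulary()].
#' @param verbose Print per-fold progress.
#' @return An object of class `nested_cv_result`: list with `fold_metrics`
#'   (per outer fold [classification_metrics()]), `selected_lr`,
#'   `aggregate` (unweighted means of accuracy, macro P/R/F1, MCC over the
#'   outer folds), `plan`.
#' @export
run_nested_cv <- function(records, config = NULL, tconf = train_config(),
                          plan = NULL, retrain = FALSE, vocab = NULL,
                          verbose = FALSE) {
  labels <- vapply(records, function(r) r$label, 0L)
  if (is.null(plan)) plan <- nested_cv_splits(labels, seed = tconf$seed)
  if (is.null(vocab)) vocab <- corpus_vocabulary(records)
  if (is.null(config)) config <- small_config(vocab_size = vocab_size(vocab))
  fold_metrics <- vector("list", plan$outer)
  selected_lr <- numeric(plan$outer)
  for (o in seq_len(plan$outer)) {
    triples <- Filter(function(t) t$outer == o, plan$triples)
    best <- list(lr = NA_real_, mean_f1 = -Inf, fits = NULL)
    for (lr in tconf$lr_grid) {
      tc <- tconf; tc$lr <- lr
      fits <- lapply(triples, function(tri) {
        train(records[tri$train], records[tri$dev], vocab = vocab,
              config = config, tconf = tc)
      })
      f1s <- vapply(fits, function(f) max(f$history$dev_macro_f1), 0)
      if (verbose) {
        message(sprintf("outer %d lr %g: mean inner dev F1 %.4f", o, lr, mean(f1s)))
      }
      if (mean(f1s) > best$mean_f1) best <- list(lr = lr, mean_f1 = mean(f1s),
                                                 fits = fits, f1s = f1s)
    }
    selected_lr[o] <- best$lr
    test_idx <- triples[[1L]]$test
    if (retrain) {
      tc <- tconf; tc$lr <- best$lr
      dev_idx <- triples[[which.max(best$f1s)]]$dev
      tr_idx <- setdiff(which(plan$outer_fold != o), dev_idx)
      final_fit <- train(records[tr_idx], records[dev_idx], vocab = vocab,
                         config = config, tconf = tc)
    } else {
      final_fit <- best$fits[[which.max(best$f1s)]]
    }
    fold_metrics[[o]] <- evaluate_model(final_fit, records[test_idx])
  }
  agg <- sapply(c("accuracy", "macro_precision", "macro_recall", "macro_f1", "mcc"),
                function(k) mean(vapply(fold_metrics, function(m) m[[k]], 0)))
  structure(list(fold_metrics = fold_metrics, selected_lr = selected_lr,
                 aggregate = agg, plan = plan),
            class = "nested_cv_result")
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat("<nested_cv_result> ", length(x$fold_metrics), " outer folds\n", sep = "")
  print(round(x$aggregate, 4))
  invisible(x)
}

#' Named model variants for the ablation grid
#'
#' Derives a [model_config()] for each named variant from a base
#' configuration: component switches (`baseline` = no entity features,
#' `embedding_only`, `attention_only`, `full`), per-entity-type knockouts
#' (`wo_symptom`, `wo_location`, `wo_disease` — the removed type collapses
#' to `OTHERS` in both the embedding lookup and the local mask), and
#' layer-placement variants (`layers_bottom`, `layers_middle`,
#' `layers_top`, `layers_stride`, `layers_all`).
#'
#' @param config Base [model_config()].
#' @param variants Character vector of variant names (defaults to the
#'   component and knockout variants).
#' @return Named list of `model_config` objects.
#' @export
ablation_variants <- function(config,
                              variants = c("baseline", "embedding_only",
                                           "attention_only", "full",
                                           "wo_symptom", "wo_location",
                                           "wo_disease")) {
  third <- function(part) {
    k <- max(1L, config$L %/% 3L)
    switch(part,
           bottom = seq_len(k),
           middle = seq_len(k) + (config$L - k) %/% 2L,
           top = config$L - k + seq_len(k))
  }
  mk <- function(...) {
    over <- list(...)
    args <- list(L = config$L, H = config$H, d = config$d, C = config$C,
                 n_max = config$n_max, vocab_size = config$vocab_size,
                 entity_layers = config$entity_layers,
                 use_entity_embedding = config$use_entity_embedding,
                 enabled_entity_types = config$enabled_entity_types,
                 dropout = config$dropout, attn_dropout = config$attn_dropout)
    args[names(over)] <- over
    do.call(model_config, args)
  }
  defs <- list(
    baseline = mk(use_entity_embedding = FALSE, entity_layers = integer(0)),
    embedding_only = mk(use_entity_embedding = TRUE, entity_layers = integer(0)),
    attention_only = mk(use_entity_embedding = FALSE),
    full = mk(),
    wo_symptom = mk(enabled_entity_types = setdiff(medical_entity_types(), "SYMPTOM")),
    wo_location = mk(enabled_entity_types = setdiff(medical_entity_types(), "LOCATION")),
    wo_disease = mk(enabled_entity_types = setdiff(medical_entity_types(), "DISEASE")),
    layers_bottom = mk(entity_layers = third("bottom")),
    layers_middle = mk(entity_layers = third("middle")),
    layers_top = mk(entity_layers = third("top")),
    layers_stride = mk(entity_layers = unique(pmax(1L, seq_len(3L) * (config$L %/% 3L)))),
    layers_all = mk(entity_layers = seq_len(config$L)))
  unknown <- setdiff(variants, names(defs))
  if (length(unknown) > 0L) stop("unknown variant(s): ", paste(unknown, collapse = ", "))
  defs[variants]
}

#' Run an ablation grid
#'
#' Trains and evaluates each requested model variant on a fixed
#' train/dev/test split, all from the same seed, and collects one metrics
#' row per variant.
#'
#' @param records Corpus records.
#' @param split List with integer index vectors `train`, `dev`, `test`.
#' @param config Base [model_config()].
#' @param tconf A [train_config()].
#' @param variants Character vector of variant names
#'   (see [ablation_variants()]).
#' @param vocab Optional [build_vocabulary()].
#' @return List with `table` (data frame: variant, accuracy, macro P/R/F1,
#'   MCC) and `fits` (named list of fitted models).
#' @export
ablation_grid <- function(records, split, config = NULL,
                          tconf = train_config(),
                          variants = c("baseline", "embedding_only",
                                       "attention_only", "full",
                                       "wo_symptom", "wo_location",
                                       "wo_disease"),
                          vocab = NULL) {
  if (is.null(vocab)) vocab <- corpus_vocabulary(records)
  if (is.null(config)) config <- small_config(vocab_size = vocab_size(vocab))
  defs <- ablation_variants(config, variants)
  fits <- list(); rows <- list()
  for (v in names(defs)) {
    fit <- train(records[split$train], records[split$dev], vocab = vocab,
                 config = defs[[v]], tconf = tconf)
    rep <- evaluate_model(fit, records[split$test])
    fits[[v]] <- fit
    rows[[v]] <- cbind(data.frame(variant = v), metrics_to_csv_row(rep))
  }
  list(table = do.call(rbind, c(rows, make.row.names = FALSE)), fits = fits)
}
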