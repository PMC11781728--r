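# Nested cross-validation plans: stratified outer test folds, inner
# train/dev folds within each outer-training set.

# stratified k-fold assignment over labels; deterministic given the RNG state
stratified_folds <- function(labels, k, stratify = TRUE) {
  n <- length(labels)
  fold <- integer(n)
  if (stratify) {
    offset <- 0L  # rotate fold numbering across classes to balance totals
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
      offset <- offset + length(idx)
    }
  } else {
    fold[sample.int(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Build a nested cross-validation plan
#'
#' Splits the data into `outer` stratified test folds; within each
#' outer-training set, `inner` stratified folds define train/dev splits for
#' model selection. The plan enumerates all `outer * inner` train/dev/test
#' triples (15 under the 5x3 default), so every configuration is trained
#' that many times per setting.
#'
#' @param labels Integer vector of 0-based class labels (used for
#'   stratification and to size the folds).
#' @param outer,inner Fold counts (default 5 and 3).
#' @param seed Integer seed; the plan is deterministic given it.
#' @param stratify Logical; stratify folds by class label.
#' @return An object of class `cv_plan`: list with `outer_fold` (length-n
#'   assignment), `inner_folds` (per outer fold, assignment over that
#'   fold's training indices), and `triples` (list of
#'   `list(outer, inner, train, dev, test)` index sets).
#' @export
nested_cv_splits <- function(labels, outer = 5L, inner = 3L, seed = 0L,
                             stratify = TRUE) {
  outer <- as.integer(outer); inner <- as.integer(inner)
  n <- length(labels)
  if (n < outer * inner) stop("too few items for ", outer, "x", inner, " nested CV")
  set.seed(as.integer(seed))
  outer_fold <- stratified_folds(labels, outer, stratify)
  inner_folds <- vector("list", outer)
  triples <- list()
  for (o in seq_len(outer)) {
    test_idx <- which(outer_fold == o)
    train_pool <- which(outer_fold != o)
    inner_assign <- stratified_folds(labels[train_pool], inner, stratify)
    inner_folds[[o]] <- stats::setNames(inner_assign, train_pool)
    for (j in seq_len(inner)) {
      dev_idx <- train_pool[inner_assign == j]
      tr_idx <- train_pool[inner_assign != j]
      triples[[length(triples) + 1L]] <-
        list(outer = o, inner = j, train = tr_idx, dev = dev_idx, test = test_idx)
    }
  }
  structure(list(outer_fold = outer_fold, inner_folds = inner_folds,
                 triples = triples, outer = outer, inner = inner,
                 seed = as.integer(seed), stratify = stratify),
            class = "cv_plan")
}

#' @export
print.cv_plan <- function(x, ...) {
  cat("<cv_plan> ", x$outer, " outer x ", x$inner, " inner folds over ",
      length(x$outer_fold), " items (", length(x$triples),
      " train/dev/test triples), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
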