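# Tagged model-input sequences: [CLS] QA1 [SEP] QA2 [SEP] ... with
# per-token entity types, segment ids and pad flags.

#' Construct a tagged sequence
#'
#' The unit of model input: parallel per-token vectors of tokens, token ids,
#' entity types, segment ids and pad flags, plus a 0-based class label.
#' Position 1 holds `[CLS]` and every question-answer (QA) unit is terminated
#' by `[SEP]`. Padding is always a suffix and carries entity type `OTHERS`
#' and segment id 0.
#'
#' @param tokens Character vector.
#' @param token_ids Integer vector of 0-based vocabulary ids.
#' @param entity_types Character vector of entity types (see [entity_types()]).
#' @param segment_ids Integer vector of 0/1 segment ids.
#' @param pad_flags Logical vector, `TRUE` for `[PAD]` positions.
#' @param label 0-based class index.
#' @return An object of class `tagged_sequence`.
#' @export
tagged_sequence <- function(tokens, token_ids, entity_types, segment_ids,
                            pad_flags, label) {
  seq <- structure(
    list(tokens = as.character(tokens),
         token_ids = as.integer(token_ids),
         entity_types = as.character(entity_types),
         segment_ids = as.integer(segment_ids),
         pad_flags = as.logical(pad_flags),
         label = as.integer(label)),
    class = "tagged_sequence")
  validate_tagged_sequence(seq)
  seq
}

#' Validate tagged-sequence invariants
#'
#' Checks equal field lengths, the leading `[CLS]`, suffix-only padding, and
#' that pad positions carry entity type `OTHERS` and segment id 0. Called by
#' the constructor; exported so that property tests and downstream code can
#' re-check sequences produced elsewhere.
#'
#' @param seq A `tagged_sequence`.
#' @return `seq`, invisibly; errors on violation.
#' @export
validate_tagged_sequence <- function(seq) {
  n <- length(seq$tokens)
  lens <- c(length(seq$token_ids), length(seq$entity_types),
            length(seq$segment_ids), length(seq$pad_flags))
  if (any(lens != n)) stop("per-token fields have unequal lengths")
  if (n < 1L) stop("empty sequence")
  if (seq$tokens[[1L]] != "[CLS]") stop("sequence must start with [CLS]")
  if (!all(seq$entity_types %in% entity_types())) stop("invalid entity type")
  if (!all(seq$segment_ids %in% c(0L, 1L))) stop("segment ids must be 0/1")
  if (any(seq$token_ids < 0L)) stop("negative token id")
  p <- seq$pad_flags
  if (any(p)) {
    first <- which(p)[1L]
    if (!all(p[first:n])) stop("padding must be a suffix")
    if (!all(seq$entity_types[p] == "OTHERS")) stop("pad positions must be OTHERS")
    if (!all(seq$segment_ids[p] == 0L)) stop("pad positions must have segment id 0")
  }
  if (is.na(seq$label) || seq$label < 0L) stop("label must be a non-negative class index")
  invisible(seq)
}

#' @export
print.tagged_sequence <- function(x, ...) {
  n <- length(x$tokens)
  np <- sum(x$pad_flags)
  cat("<tagged_sequence> length ", n, " (", np, " pad), label ", x$label, "\n", sep = "")
  show <- min(n, 12L)
  cat(" ", paste0(x$tokens[seq_len(show)],
                  ifelse(x$entity_types[seq_len(show)] == "OTHERS", "",
                         paste0("/", x$entity_types[seq_len(show)])),
                  collapse = " "),
      if (n > show) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Assemble QA units into a model input sequence
#'
#' Concatenates question-answer units into the standard transformer layout
#' `[CLS] QA1 [SEP] QA2 [SEP] ... QAn [SEP]`. Special tokens carry entity
#' type `OTHERS` (so they never unlock entity-restricted attention). Segment
#' ids alternate 0/1 per QA unit starting at 0, with `[CLS]` on segment 0
#' and each `[SEP]` taking its unit's segment.
#'
#' @param qa_pairs List of units, each a list with `tokens` (character) and
#'   `bio_tags` (character, same length).
#' @param vocab A [build_vocabulary()] object; unknown tokens map to `[UNK]`.
#' @param label 0-based class index.
#' @return A [tagged_sequence()].
#' @examples
#' v <- build_vocabulary(c("a", "b"))
#' assemble_input(list(list(tokens = c("a", "b"), bio_tags = c("B-SYM", "O"))), v, 0)
#' @export
assemble_input <- function(qa_pairs, vocab, label) {
  if (length(qa_pairs) == 0L) stop("at least one QA unit is required")
  toks <- "[CLS]"; types <- "OTHERS"; segs <- 0L
  for (u in seq_along(qa_pairs)) {
    unit <- qa_pairs[[u]]
    if (length(unit$tokens) != length(unit$bio_tags)) {
      stop("unit ", u, ": tokens and bio_tags lengths differ")
    }
    seg <- (u - 1L) %% 2L
    toks <- c(toks, unit$tokens, "[SEP]")
    types <- c(types, bio_to_entity_types(unit$bio_tags), "OTHERS")
    segs <- c(segs, rep(seg, length(unit$tokens) + 1L))
  }
  tagged_sequence(tokens = toks,
                  token_ids = token_to_id(vocab, toks),
                  entity_types = types,
                  segment_ids = segs,
                  pad_flags = rep(FALSE, length(toks)),
                  label = label)
}

#' Pad or truncate a sequence to a fixed length
#'
#' Padding appends `[PAD]` tokens (pad flag set, entity type `OTHERS`,
#' segment 0). Truncation keeps the prefix but always retains a terminal
#' `[SEP]` so the QA structure stays well-formed.
#'
#' @param seq A [tagged_sequence()].
#' @param max_len Target length, at least 2.
#' @param vocab Vocabulary used to look up the `[PAD]`/`[SEP]` ids; defaults
#'   to the reserved ids of [build_vocabulary()].
#' @return A `tagged_sequence` of length exactly `max_len`.
#' @export
pad_and_truncate <- function(seq, max_len, vocab = build_vocabulary()) {
  stopifnot(inherits(seq, "tagged_sequence"), max_len >= 2L)
  n <- length(seq$tokens)
  if (n > max_len) {
    keep <- max_len - 1L
    seq <- tagged_sequence(
      tokens = c(seq$tokens[seq_len(keep)], "[SEP]"),
      token_ids = c(seq$token_ids[seq_len(keep)], token_to_id(vocab, "[SEP]")),
      entity_types = c(seq$entity_types[seq_len(keep)], "OTHERS"),
      segment_ids = c(seq$segment_ids[seq_len(keep)], seq$segment_ids[[keep]]),
      pad_flags = rep(FALSE, max_len),
      label = seq$label)
  } else if (n < max_len) {
    k <- max_len - n
    seq <- tagged_sequence(
      tokens = c(seq$tokens, rep("[PAD]", k)),
      token_ids = c(seq$token_ids, rep(token_to_id(vocab, "[PAD]"), k)),
      entity_types = c(seq$entity_types, rep("OTHERS", k)),
      segment_ids = c(seq$segment_ids, rep(0L, k)),
      pad_flags = c(seq$pad_flags, rep(TRUE, k)),
      label = seq$label)
  }
  seq
}
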