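# Whitespace-token vocabulary with the four reserved special tokens.

#' Build a vocabulary over a token list
#'
#' The package works with whitespace tokens and a corpus-built vocabulary so
#' that the model is fully self-contained (the attention mechanism itself is
#' tokenizer-agnostic). Ids are 0-based; the reserved ids 0..3 are
#' `[PAD]`, `[UNK]`, `[CLS]`, `[SEP]`.
#'
#' @param tokens Character vector of corpus tokens (duplicates allowed).
#' @return An object of class `vocabulary`: a named integer vector mapping
#'   token to id.
#' @examples
#' v <- build_vocabulary(c("fever", "nausea", "fever"))
#' token_to_id(v, c("fever", "zzz"))  # unknown tokens fall back to [UNK]
#' @export
build_vocabulary <- function(tokens = character(0)) {
  specials <- c("[PAD]", "[UNK]", "[CLS]", "[SEP]")
  toks <- setdiff(unique(as.character(tokens)), specials)
  ids <- seq_len(length(specials) + length(toks)) - 1L
  names(ids) <- c(specials, toks)
  structure(ids, class = "vocabulary")
}

#' @rdname build_vocabulary
#' @param vocab A `vocabulary`.
#' @param x Character vector of tokens (for `token_to_id`) or integer ids
#'   (for `id_to_token`).
#' @export
token_to_id <- function(vocab, x) {
  stopifnot(inherits(vocab, "vocabulary"))
  out <- unname(vocab[x])
  out[is.na(out)] <- vocab[["[UNK]"]]
  as.integer(out)
}

#' @rdname build_vocabulary
#' @export
id_to_token <- function(vocab, x) {
  stopifnot(inherits(vocab, "vocabulary"))
  nm <- names(vocab)[match(as.integer(x), unname(vocab))]
  nm[is.na(nm)] <- "[UNK]"
  nm
}

#' @rdname build_vocabulary
#' @export
vocab_size <- function(vocab) length(vocab)

#' @export
print.vocabulary <- function(x, ...) {
  cat("<vocabulary> ", length(x), " tokens (ids 0..", length(x) - 1L, ")\n", sep = "")
  invisible(x)
}
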