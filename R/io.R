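# Corpus I/O: CoNLL-style token/tag files and JSON-lines.
#
# A corpus record is a list with
#   units: list of QA units, each list(tokens =, bio_tags =)
#   label: 0-based class index
# Both formats round-trip tokens, tags, labels and the QA-unit structure.

new_record <- function(units, label) {
  structure(list(units = units, label = as.integer(label)), class = "corpus_record")
}

#' Read and write CoNLL-style corpora
#'
#' The on-disk format is two whitespace-separated columns (token, BIO tag),
#' one token per line. Each record starts with a `# label=<k>` comment line,
#' QA units within a record are separated by `# qa` comment lines, and
#' records are separated by blank lines.
#'
#' @param path File path.
#' @param records List of corpus records (each `list(units, label)`, where
#'   `units` is a list of `list(tokens, bio_tags)`).
#' @return `read_conll` returns the list of records; `write_conll` returns
#'   `path` invisibly.
#' @export
read_conll <- function(path) {
  lines <- readLines(path)
  records <- list()
  cur_units <- NULL; cur_label <- NULL
  toks <- character(0); tags <- character(0)
  flush_unit <- function() {
    if (length(toks) > 0L) {
      cur_units[[length(cur_units) + 1L]] <<- list(tokens = toks, bio_tags = tags)
      toks <<- character(0); tags <<- character(0)
    }
  }
  flush_record <- function() {
    flush_unit()
    if (!is.null(cur_label)) {
      if (length(cur_units) == 0L) stop("record with label but no tokens")
      records[[length(records) + 1L]] <<- new_record(cur_units, cur_label)
    } else if (length(cur_units) > 0L) {
      stop("record without a '# label=' header")
    }
    cur_units <<- NULL; cur_label <<- NULL
  }
  cur_units <- list()
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (line == "") {
      flush_record(); cur_units <- list()
    } else if (startsWith(line, "# label=")) {
      cur_label <- as.integer(sub("^# label=", "", line))
      if (is.na(cur_label)) stop("line ", i, ": unparseable label header")
    } else if (line == "# qa") {
      flush_unit()
    } else if (startsWith(line, "#")) {
      # other comments ignored
    } else {
      fields <- strsplit(line, "[ \t]+")[[1L]]
      if (length(fields) != 2L) {
        stop("line ", i, ": expected 2 columns (token, tag), got ", length(fields))
      }
      if (is.null(cur_label)) stop("line ", i, ": token line before '# label=' header")
      toks <- c(toks, fields[[1L]]); tags <- c(tags, fields[[2L]])
    }
  }
  flush_record()
  records
}

#' @rdname read_conll
#' @export
write_conll <- function(records, path) {
  out <- character(0)
  for (rec in records) {
    out <- c(out, paste0("# label=", rec$label))
    for (u in seq_along(rec$units)) {
      if (u > 1L) out <- c(out, "# qa")
      unit <- rec$units[[u]]
      out <- c(out, paste(unit$tokens, unit$bio_tags))
    }
    out <- c(out, "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read and write JSON-lines corpora
#'
#' One JSON object per line with keys `tokens`, `bio_tags` (parallel arrays
#' of per-unit arrays) and `label`. Equivalent data read from the CoNLL and
#' JSON-lines formats produce identical records.
#'
#' @inheritParams read_conll
#' @return `read_jsonl` returns the list of records; `write_jsonl` returns
#'   `path` invisibly.
#' @export
read_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(seq_along(lines), function(i) {
    obj <- jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE)
    if (is.null(obj$tokens) || is.null(obj$bio_tags) || is.null(obj$label)) {
      stop("line ", i, ": record must have tokens, bio_tags, label")
    }
    if (length(obj$tokens) != length(obj$bio_tags)) {
      stop("line ", i, ": tokens/bio_tags unit counts differ")
    }
    units <- lapply(seq_along(obj$tokens), function(u) {
      tk <- as.character(unlist(obj$tokens[[u]]))
      tg <- as.character(unlist(obj$bio_tags[[u]]))
      if (length(tk) != length(tg)) stop("line ", i, ", unit ", u, ": ragged unit")
      list(tokens = tk, bio_tags = tg)
    })
    new_record(units, obj$label)
  })
}

#' @rdname read_jsonl
#' @export
write_jsonl <- function(records, path) {
  lines <- vapply(records, function(rec) {
    jsonlite::toJSON(list(
      tokens = lapply(rec$units, function(u) u$tokens),
      bio_tags = lapply(rec$units, function(u) u$bio_tags),
      label = jsonlite::unbox(rec$label)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Assemble a corpus of records into model inputs
#'
#' Convenience wrapper: applies [assemble_input()] and [pad_and_truncate()]
#' to every record.
#'
#' @param records List of corpus records.
#' @param vocab A [build_vocabulary()] object.
#' @param max_len Fixed model input length.
#' @return List of [tagged_sequence()] objects, all of length `max_len`.
#' @export
assemble_corpus <- function(records, vocab, max_len) {
  lapply(records, function(rec) {
    pad_and_truncate(assemble_input(rec$units, vocab, rec$label), max_len, vocab)
  })
}

#' Build a vocabulary over a corpus
#'
#' @param records List of corpus records.
#' @return A [build_vocabulary()] object covering every corpus token.
#' @export
corpus_vocabulary <- function(records) {
  build_vocabulary(unlist(lapply(records, function(rec) {
    unlist(lapply(rec$units, function(u) u$tokens))
  })))
}
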