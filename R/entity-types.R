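# Entity-type vocabulary and BIO-tag decoding.

#' Entity types recognised by the model
#'
#' Four entity types are used throughout the package. `OTHERS` is the default
#' for untagged tokens, special tokens and padding; the medically relevant
#' subset (symptom, pain location, disease) is what the entity-aware
#' attention mechanism keys on.
#'
#' @format Character vectors. `entity_types()` returns all four codes in the
#'   canonical order used for the entity embedding table
#'   (`OTHERS`, `SYMPTOM`, `LOCATION`, `DISEASE`); `medical_entity_types()`
#'   returns the medically relevant subset.
#' @export
entity_types <- function() c("OTHERS", "SYMPTOM", "LOCATION", "DISEASE")

#' @rdname entity_types
#' @export
medical_entity_types <- function() c("SYMPTOM", "LOCATION", "DISEASE")

# integer code (0-based) for an entity-type string; row code+1 of the
# entity embedding table
entity_code <- function(type) {
  m <- match(type, entity_types())
  if (anyNA(m)) stop("unknown entity type: ", paste(type[is.na(m)], collapse = ", "))
  m - 1L
}

.bio_tag_map <- c("SYM" = "SYMPTOM", "LOC" = "LOCATION", "DIS" = "DISEASE")

#' Decode BIO tags to entity types
#'
#' Maps token-level BIO tags to the per-token entity type consumed by the
#' model. `B-X` and `I-X` both map to type `X`; `O` maps to `OTHERS`. An
#' `I-X` that does not continue a `B-X`/`I-X` span (an orphan, as can be
#' produced by an imperfect upstream NER model) is accepted leniently and
#' mapped to `X`, with a warning.
#'
#' @param bio_tags Character vector of tags from
#'   `{O, B-SYM, I-SYM, B-LOC, I-LOC, B-DIS, I-DIS}`.
#' @return Character vector of entity types, same length as `bio_tags`.
#' @examples
#' bio_to_entity_types(c("B-SYM", "I-SYM", "O", "B-LOC"))
#' @export
bio_to_entity_types <- function(bio_tags) {
  if (length(bio_tags) == 0L) return(character(0))
  if (!is.character(bio_tags)) stop("bio_tags must be a character vector")
  out <- character(length(bio_tags))
  prev <- ""
  orphans <- integer(0)
  for (i in seq_along(bio_tags)) {
    tag <- bio_tags[[i]]
    if (identical(tag, "O")) {
      out[[i]] <- "OTHERS"
    } else if (grepl("^[BI]-(SYM|LOC|DIS)$", tag)) {
      x <- substr(tag, 3L, 5L)
      if (substr(tag, 1L, 1L) == "I" && prev != x) orphans <- c(orphans, i)
      out[[i]] <- .bio_tag_map[[x]]
    } else {
      stop("malformed BIO tag at position ", i, ": '", tag, "'")
    }
    prev <- if (identical(tag, "O")) "" else substr(tag, 3L, 5L)
  }
  if (length(orphans) > 0L) {
    warning("orphan I- tag(s) at position(s) ", paste(orphans, collapse = ", "),
            "; mapped leniently to their entity type")
  }
  out
}

# inverse: entity types back to BIO tags (B- at span starts)
entity_types_to_bio <- function(types) {
  rev_map <- c(SYMPTOM = "SYM", LOCATION = "LOC", DISEASE = "DIS")
  out <- character(length(types))
  prev <- "OTHERS"
  for (i in seq_along(types)) {
    t <- types[[i]]
    if (t == "OTHERS") {
      out[[i]] <- "O"
    } else {
      out[[i]] <- paste0(if (identical(t, prev)) "I-" else "B-", rev_map[[t]])
    }
    prev <- t
  }
  out
}
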