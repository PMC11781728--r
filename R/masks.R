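# Additive attention masks and masked softmax.

#' Build the global (pad) attention mask
#'
#' Additive n x n mask: entry (i, j) is 0 when neither position i nor j is
#' padding, and -Inf otherwise. Added to scaled attention scores before the
#' softmax, it removes `[PAD]` positions from every attention distribution.
#'
#' @param pad_flags Logical vector, `TRUE` at `[PAD]` positions (suffix).
#' @return n x n numeric matrix of 0 / -Inf.
#' @export
build_global_mask <- function(pad_flags) {
  keep <- !as.logical(pad_flags)
  ifelse(outer(keep, keep, `&`), 0, -Inf)
}

#' Build the local (entity-restricted) attention mask
#'
#' Additive n x n mask implementing entity-aware attention: entry (i, j) is
#' 0 only when both tokens carry an enabled medically relevant entity type
#' and neither is padding; otherwise -Inf. Entity-type knockouts are
#' expressed through `enabled_types`. The zeros of the local mask are always
#' a subset of the zeros of the global mask.
#'
#' @param entity_types Character vector of per-token entity types.
#' @param pad_flags Logical vector, same length.
#' @param enabled_types Subset of [medical_entity_types()].
#' @return n x n numeric matrix of 0 / -Inf.
#' @export
build_local_mask <- function(entity_types, pad_flags,
                             enabled_types = medical_entity_types()) {
  stopifnot(length(entity_types) == length(pad_flags),
            all(enabled_types %in% medical_entity_types()))
  elig <- entity_types %in% enabled_types & !as.logical(pad_flags)
  ifelse(outer(elig, elig, `&`), 0, -Inf)
}

#' Row-wise softmax under an additive mask
#'
#' Applies the additive mask and normalizes each row over its unmasked
#' support. A fully masked row (all -Inf) is returned as an all-zero row:
#' the attention distribution is undefined there, and the zero row lets the
#' gate mechanism down-weight the empty path without producing NaNs.
#'
#' @param scores n x n numeric matrix of (already scaled) attention scores.
#' @param mask n x n additive mask of 0 / -Inf (e.g. from
#'   [build_global_mask()] or [build_local_mask()]).
#' @return n x n matrix; every row is either a probability vector supported
#'   on the unmasked entries or all zeros. No non-finite values.
#' @export
masked_softmax <- function(scores, mask) {
  stopifnot(all(dim(scores) == dim(mask)))
  out <- matrix(0, nrow(scores), ncol(scores))
  for (i in seq_len(nrow(scores))) {
    sup <- is.finite(mask[i, ])
    if (!any(sup)) next
    z <- scores[i, sup]
    e <- exp(z - max(z))
    out[i, sup] <- e / sum(e)
  }
  out
}
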