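# Gate and attention introspection: per-layer mean gate values by entity
# type, and attention maps averaged over heads and layers.

#' Summarize gate values by layer and entity type
#'
#' Runs the encoder with trace recording on a corpus sample and averages
#' the per-token gate values over positions grouped by entity type
#' (plus the medical-vs-OTHERS dichotomy), per entity-aware layer,
#' excluding pads. With zeroed gate parameters every cell is 0.5
#' (sigmoid of 0).
#'
#' @param fit An [train()] fit (or a list with `params`, `config`, `vocab`,
#'   `max_len`).
#' @param records Corpus records to summarize over.
#' @return Data frame with columns `layer`, `group` (one of the entity
#'   types or `MEDICAL`), `mean_gate`, `n_tokens`.
#' @export
gate_summary <- function(fit, records) {
  config <- fit$config
  if (length(config$entity_layers) == 0L) {
    stop("model has no entity-aware layers; the gate is never evaluated")
  }
  seqs <- assemble_corpus(records, fit$vocab, fit$max_len)
  acc <- list()  # per layer: sums and counts per group
  groups <- c(entity_types(), "MEDICAL")
  for (l in config$entity_layers) acc[[as.character(l)]] <-
    list(sum = stats::setNames(numeric(length(groups)), groups),
         n = stats::setNames(numeric(length(groups)), groups))
  for (s in seqs) {
    fw <- encoder_forward(s, fit$params, config, record_trace = TRUE)
    keep <- !s$pad_flags
    types <- s$entity_types
    for (l in config$entity_layers) {
      g <- fw$trace[[l]]$gate
      a <- acc[[as.character(l)]]
      for (tp in entity_types()) {
        idx <- keep & types == tp
        a$sum[[tp]] <- a$sum[[tp]] + sum(g[idx]); a$n[[tp]] <- a$n[[tp]] + sum(idx)
      }
      idx <- keep & types %in% medical_entity_types()
      a$sum[["MEDICAL"]] <- a$sum[["MEDICAL"]] + sum(g[idx])
      a$n[["MEDICAL"]] <- a$n[["MEDICAL"]] + sum(idx)
      acc[[as.character(l)]] <- a
    }
  }
  out <- do.call(rbind, lapply(names(acc), function(l) {
    a <- acc[[l]]
    data.frame(layer = as.integer(l), group = groups,
               mean_gate = ifelse(a$n > 0, a$sum / a$n, NA_real_),
               n_tokens = as.integer(a$n), row.names = NULL)
  }))
  out
}

#' Average attention map for one sequence
#'
#' Elementwise mean of the fused attention matrices over all (layer, head)
#' pairs, with pad positions dropped from the returned axes. Row and
#' column names are the tokens, annotated with their entity types.
#'
#' @param fit An [train()] fit.
#' @param record One corpus record.
#' @return An object of class `attention_map`: list with `matrix` (n x n),
#'   `tokens`, `entity_types`.
#' @export
attention_summary <- function(fit, record) {
  seq <- pad_and_truncate(assemble_input(record$units, fit$vocab, record$label),
                          fit$max_len, fit$vocab)
  fw <- encoder_forward(seq, fit$params, fit$config, record_trace = TRUE)
  n <- length(seq$tokens)
  avg <- matrix(0, n, n)
  k <- 0L
  for (l in seq_len(fit$config$L)) {
    for (h in seq_len(fit$config$H)) {
      avg <- avg + fw$trace[[l]]$heads[[h]]$fused
      k <- k + 1L
    }
  }
  avg <- avg / k
  keep <- which(!seq$pad_flags)
  avg <- avg[keep, keep, drop = FALSE]
  toks <- seq$tokens[keep]
  dimnames(avg) <- list(toks, toks)
  structure(list(matrix = avg, tokens = toks,
                 entity_types = seq$entity_types[keep]),
            class = "attention_map")
}

#' @export
print.attention_map <- function(x, ...) {
  cat("<attention_map> ", nrow(x$matrix), " x ", ncol(x$matrix),
      " (heads x layers averaged)\n", sep = "")
  invisible(x)
}

#' Render an attention map as a heatmap
#'
#' Tokens are labelled with their entity-type annotation; requires ggplot2.
#'
#' @param map An [attention_summary()] result.
#' @return A ggplot object.
#' @export
plot_attention_map <- function(map) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  n <- nrow(map$matrix)
  lab <- ifelse(map$entity_types == "OTHERS", map$tokens,
                paste0(map$tokens, " [", substr(map$entity_types, 1, 3), "]"))
  lab <- make.unique(lab)
  df <- expand.grid(query = seq_len(n), key = seq_len(n))
  df$weight <- as.numeric(map$matrix[cbind(df$query, df$key)])
  ggplot2::ggplot(df, ggplot2::aes(x = key, y = query, fill = weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_x_continuous(breaks = seq_len(n), labels = lab) +
    ggplot2::scale_y_reverse(breaks = seq_len(n), labels = lab) +
    ggplot2::scale_fill_viridis_c(name = "attention") +
    ggplot2::theme_minimal(base_size = 8) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1)) +
    ggplot2::labs(x = "key token", y = "query token")
}

#' Plot per-layer gate summaries
#'
#' @param summary A [gate_summary()] data frame.
#' @return A ggplot object.
#' @export
plot_gate_summary <- function(summary) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  df <- summary[summary$group != "MEDICAL", ]
  ggplot2::ggplot(df, ggplot2::aes(x = layer, y = mean_gate, colour = group)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "encoder layer", y = "mean gate value",
                  colour = "entity type")
}

utils::globalVariables(c("key", "query", "weight", "layer", "mean_gate", "group"))
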