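# Synthetic BIO-tagged questionnaire corpus with a planted
# entity-co-occurrence rule.
#
# Each record is a short questionnaire: several QA units, each a question
# marker followed by an answer. Two latent binary factors drive the class
# label: a pain-location group and a symptom group; their combination maps
# to one of four specialties through a fixed public lookup table
# (mirroring the clinical finding that the location x symptom interaction
# determines the appropriate department). Disease mentions are rare,
# label-irrelevant distractors.
#
# The ambiguity rate rho controls whether entity type is recoverable from
# the surface form. Ambiguous surface tokens are drawn i.i.d. for every
# answer slot *before* tags are assigned; entity mentions are then planted
# by tagging already-present tokens of the right latent group. At rho = 1
# the surface token distribution is therefore identical across classes and
# only the supplied BIO tags carry the label signal.

#' Generator configuration for synthetic questionnaire corpora
#'
#' @param n_samples Number of records.
#' @param n_classes Number of specialty classes (fixed at 4: two latent
#'   location groups x two latent symptom groups).
#' @param qa_pairs_range Inclusive range of QA units per record.
#' @param tokens_per_answer Inclusive range of answer lengths (tokens).
#' @param entity_props Target proportions of entity tokens for
#'   Symptom/Location/Disease. The default reproduces the 10983:8313:850
#'   frequency ratio of the motivating questionnaire dataset.
#' @param entity_rate Fraction of answer tokens that receive an entity tag.
#' @param ambiguity_rate rho in [0, 1]: probability that an entity mention
#'   is realized on an ambiguous surface form whose type is decidable only
#'   from the supplied tag.
#' @param amb_frac Probability that a filler slot draws its surface from
#'   the ambiguous vocabulary rather than the plain filler vocabulary.
#' @param n_ambiguous,n_entity_tokens,n_disease_tokens,n_filler,n_question
#'   Lexicon sizes: ambiguous tokens (split evenly over the four latent
#'   group combinations), dedicated tokens per (type, group), dedicated
#'   disease tokens, plain fillers, and question markers.
#' @param phrase_prob Probability that an unambiguous mention uses a
#'   two-token lexicon phrase instead of a single token.
#' @param class_prior 2 x 2 matrix of probabilities over
#'   (location group, symptom group); defaults to uniform.
#' @param seed Integer seed; generation is deterministic given it.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_samples = 3000L, n_classes = 4L,
                             qa_pairs_range = c(3L, 5L),
                             tokens_per_answer = c(5L, 9L),
                             entity_props = c(SYMPTOM = 10983, LOCATION = 8313,
                                              DISEASE = 850) / 20146,
                             entity_rate = 0.30,
                             ambiguity_rate = 0.5,
                             amb_frac = 0.55,
                             n_ambiguous = 24L, n_entity_tokens = 6L,
                             n_disease_tokens = 6L, n_filler = 20L,
                             n_question = 8L, phrase_prob = 0.2,
                             class_prior = matrix(0.25, 2L, 2L),
                             seed = 0L) {
  entity_props <- entity_props / sum(entity_props)
  stopifnot(n_classes == 4L, length(entity_props) == 3L, all(entity_props > 0),
            ambiguity_rate >= 0, ambiguity_rate <= 1,
            entity_rate > 0, entity_rate < 1,
            n_ambiguous %% 4L == 0L, all(dim(class_prior) == c(2L, 2L)),
            abs(sum(class_prior) - 1) < 1e-8)
  structure(list(n_samples = as.integer(n_samples), n_classes = 4L,
                 qa_pairs_range = as.integer(qa_pairs_range),
                 tokens_per_answer = as.integer(tokens_per_answer),
                 entity_props = entity_props, entity_rate = entity_rate,
                 ambiguity_rate = ambiguity_rate, amb_frac = amb_frac,
                 n_ambiguous = as.integer(n_ambiguous),
                 n_entity_tokens = as.integer(n_entity_tokens),
                 n_disease_tokens = as.integer(n_disease_tokens),
                 n_filler = as.integer(n_filler),
                 n_question = as.integer(n_question),
                 phrase_prob = phrase_prob, class_prior = class_prior,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Planted specialty rule
#'
#' The public lookup table mapping the two latent factors to a class:
#' rows are location groups, columns symptom groups, both 0-based:
#' \preformatted{(0,0) -> 0   (0,1) -> 1
#' (1,0) -> 2   (1,1) -> 3}
#' The table is surjective onto the four classes, so uniform latent groups
#' give a near-uniform class distribution.
#'
#' @param location_group,symptom_group 0/1 latent group indices
#'   (vectorized).
#' @return 0-based class index.
#' @export
planted_label <- function(location_group, symptom_group) {
  stopifnot(all(location_group %in% 0:1), all(symptom_group %in% 0:1))
  as.integer(2L * location_group + symptom_group)
}

#' Build the synthetic lexicon
#'
#' Surface vocabulary backing the generator and the dictionary tagger:
#' dedicated single-token and two-token entries per (entity type, latent
#' group), dedicated disease tokens, an ambiguous vocabulary shared between
#' entity types and fillers, plain filler tokens and question markers.
#' Ambiguous token `amb_k` carries latent attributes
#' `loc_group = k mod 2` and `sym_group = (k div 2) mod 2`, so the four
#' group combinations are equally represented.
#'
#' @param config A [generator_config()].
#' @return An object of class `lexicon`: list with `entries` (list of
#'   `list(tokens, type, group)`), `ambiguous` (data frame of token,
#'   loc_group, sym_group), `fillers`, `questions`.
#' @export
build_lexicon <- function(config = generator_config()) {
  entries <- list()
  add_entries <- function(prefix, type, group, n, n_phrases = 2L) {
    for (i in seq_len(n)) {
      base <- paste0(prefix, group, "_", i)
      entries[[length(entries) + 1L]] <<-
        list(tokens = base, type = type, group = group)
      if (i <= n_phrases) {
        entries[[length(entries) + 1L]] <<-
          list(tokens = c(base, paste0(base, "b")), type = type, group = group)
      }
    }
  }
  for (g in 0:1) {
    add_entries("sym", "SYMPTOM", g, config$n_entity_tokens)
    add_entries("loc", "LOCATION", g, config$n_entity_tokens)
  }
  for (i in seq_len(config$n_disease_tokens)) {
    entries[[length(entries) + 1L]] <-
      list(tokens = paste0("dis_", i), type = "DISEASE", group = NA_integer_)
  }
  k <- seq_len(config$n_ambiguous) - 1L
  ambiguous <- data.frame(token = paste0("amb_", k),
                          loc_group = k %% 2L,
                          sym_group = (k %/% 2L) %% 2L,
                          stringsAsFactors = FALSE)
  lex <- structure(list(entries = entries, ambiguous = ambiguous,
                        fillers = paste0("w_", seq_len(config$n_filler)),
                        questions = paste0("q_", seq_len(config$n_question))),
                   class = "lexicon")
  ent_tokens <- unlist(lapply(entries, `[[`, "tokens"))
  stopifnot(!any(lex$fillers %in% ent_tokens),
            !any(ambiguous$token %in% ent_tokens))
  lex
}

#' Dictionary BIO tagger
#'
#' Greedy longest-match left-to-right tagging against the lexicon's entity
#' entries: a matched span emits `B-X` (`I-X` for continuation tokens).
#' Ambiguous tokens emit `O` — their type cannot be resolved from the
#' surface form, which is exactly why externally supplied tags are
#' informative.
#'
#' @param tokens Character vector.
#' @param lexicon A [build_lexicon()] object.
#' @return Character vector of BIO tags, same length as `tokens`.
#' @export
lexicon_tag <- function(tokens, lexicon) {
  type_abbr <- c(SYMPTOM = "SYM", LOCATION = "LOC", DISEASE = "DIS")
  # index entries by first token, longest first
  by_first <- split(lexicon$entries,
                    vapply(lexicon$entries, function(e) e$tokens[[1L]], ""))
  by_first <- lapply(by_first, function(es) {
    es[order(vapply(es, function(e) length(e$tokens), 0L), decreasing = TRUE)]
  })
  n <- length(tokens)
  tags <- rep("O", n)
  i <- 1L
  while (i <= n) {
    cands <- by_first[[tokens[[i]]]]
    matched <- FALSE
    if (!is.null(cands)) {
      for (e in cands) {
        k <- length(e$tokens)
        if (i + k - 1L <= n && all(tokens[i:(i + k - 1L)] == e$tokens)) {
          ab <- type_abbr[[e$type]]
          tags[i:(i + k - 1L)] <- c(paste0("B-", ab),
                                    rep(paste0("I-", ab), k - 1L))
          i <- i + k
          matched <- TRUE
          break
        }
      }
    }
    if (!matched) i <- i + 1L
  }
  tags
}

# pick an entry of given type/group from the lexicon; phrase with prob p
pick_entry <- function(lexicon, type, group, phrase_prob) {
  ok <- vapply(lexicon$entries, function(e) {
    e$type == type && (is.na(e$group) || is.na(group) || e$group == group)
  }, TRUE)
  es <- lexicon$entries[ok]
  lens <- vapply(es, function(e) length(e$tokens), 0L)
  want2 <- stats::runif(1) < phrase_prob && any(lens == 2L)
  pool <- es[lens == (if (want2) 2L else 1L)]
  pool[[sample.int(length(pool), 1L)]]
}

#' Generate a synthetic questionnaire corpus
#'
#' Draws `n_samples` records under the planted rule (see [planted_label()]).
#' Each record's label is a deterministic function of its latent
#' (location group, symptom group) pair; entity mentions of the right
#' latent group are planted as BIO tags, with a fraction `ambiguity_rate`
#' realized on ambiguous surface forms. Generation is fully deterministic
#' given `config$seed`.
#'
#' @param config A [generator_config()].
#' @param lexicon Optional [build_lexicon()]; built from `config` if
#'   missing.
#' @return List of corpus records (`units`, `label`, plus latent
#'   `loc_group`/`sym_group` and per-record entity counts); the generator
#'   config and lexicon are attached as attributes `config` and `lexicon`.
#' @export
generate_corpus <- function(config = generator_config(), lexicon = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (is.null(lexicon)) lexicon <- build_lexicon(config)
  set.seed(config$seed)
  p <- config$entity_props
  records <- vector("list", config$n_samples)
  for (r in seq_len(config$n_samples)) {
    records[[r]] <- generate_record(config, lexicon, p)
  }
  attr(records, "config") <- config
  attr(records, "lexicon") <- lexicon
  records
}

generate_record <- function(config, lexicon, p) {
  # latent factors and label
  cell <- sample.int(4L, 1L, prob = as.numeric(t(config$class_prior)))
  lg <- (cell - 1L) %/% 2L
  sg <- (cell - 1L) %% 2L
  label <- planted_label(lg, sg)

  n_units <- sample(config$qa_pairs_range[1]:config$qa_pairs_range[2], 1L)
  ans_len <- sample(config$tokens_per_answer[1]:config$tokens_per_answer[2],
                    n_units, replace = TRUE)
  T_tot <- sum(ans_len)

  # i.i.d. surface draw for every answer slot (label-independent)
  from_amb <- stats::runif(T_tot) < config$amb_frac
  surf <- ifelse(from_amb,
                 sample(lexicon$ambiguous$token, T_tot, replace = TRUE),
                 sample(lexicon$fillers, T_tot, replace = TRUE))
  tags <- rep("O", T_tot)
  tagged <- rep(FALSE, T_tot)

  # entity budget and type allocation (symptom/location forced >= 2 each
  # so the latent groups stay decodable from every record)
  m <- max(5L, round(config$entity_rate * T_tot))
  n_dis <- stats::rbinom(1L, m, p[["DISEASE"]])
  m_sl <- m - n_dis
  n_sym <- round(m_sl * p[["SYMPTOM"]] / (p[["SYMPTOM"]] + p[["LOCATION"]]))
  n_loc <- m_sl - n_sym
  n_sym <- max(2L, n_sym); n_loc <- max(2L, n_loc)

  amb_lg <- lexicon$ambiguous$loc_group[match(surf, lexicon$ambiguous$token)]
  amb_sg <- lexicon$ambiguous$sym_group[match(surf, lexicon$ambiguous$token)]
  unit_of <- rep(seq_len(n_units), ans_len)

  plant <- function(type, count, group) {
    abbr <- c(SYMPTOM = "SYM", LOCATION = "LOC", DISEASE = "DIS")[[type]]
    for (i in seq_len(count)) {
      if (stats::runif(1) < config$ambiguity_rate) {
        # tag an already-present ambiguous token of the right group
        elig <- which(!tagged & from_amb &
                        (if (type == "SYMPTOM") amb_sg == group
                         else if (type == "LOCATION") amb_lg == group
                         else TRUE))
        if (length(elig) > 0L) {
          j <- elig[[sample.int(length(elig), 1L)]]
        } else {
          # rare fallback: overwrite a filler slot with a right-group token
          j <- which(!tagged)[[sample.int(sum(!tagged), 1L)]]
          pool <- lexicon$ambiguous[
            if (type == "SYMPTOM") lexicon$ambiguous$sym_group == group
            else if (type == "LOCATION") lexicon$ambiguous$loc_group == group
            else TRUE, , drop = FALSE]
          surf[[j]] <<- pool$token[[sample.int(nrow(pool), 1L)]]
          from_amb[[j]] <<- TRUE
          amb_lg[[j]] <<- pool$loc_group[[match(surf[[j]], pool$token)]]
          amb_sg[[j]] <<- pool$sym_group[[match(surf[[j]], pool$token)]]
        }
        tags[[j]] <<- paste0("B-", abbr); tagged[[j]] <<- TRUE
      } else {
        # dedicated (unambiguous) lexicon entry, possibly a 2-token phrase
        e <- pick_entry(lexicon, type, group, config$phrase_prob)
        k <- length(e$tokens)
        free <- which(!tagged)
        if (k == 2L) {
          # both slots free and within the same QA unit
          adj <- free[free < T_tot & !tagged[pmin(free + 1L, T_tot)] &
                        (free + 1L) %in% free &
                        unit_of[free] == unit_of[pmin(free + 1L, T_tot)]]
          if (length(adj) > 0L) {
            j <- adj[[sample.int(length(adj), 1L)]]
            surf[j:(j + 1L)] <<- e$tokens
            from_amb[j:(j + 1L)] <<- FALSE
            tags[j:(j + 1L)] <<- paste0(c("B-", "I-"), abbr)
            tagged[j:(j + 1L)] <<- TRUE
            next
          }
          e <- list(tokens = e$tokens[[1L]])  # no adjacent room: fall back
        }
        j <- free[[sample.int(length(free), 1L)]]
        surf[[j]] <<- e$tokens[[1L]]
        from_amb[[j]] <<- FALSE
        tags[[j]] <<- paste0("B-", abbr); tagged[[j]] <<- TRUE
      }
    }
  }
  plant("SYMPTOM", n_sym, sg)
  plant("LOCATION", n_loc, lg)
  if (n_dis > 0L) plant("DISEASE", n_dis, NA_integer_)

  # cut slots into QA units, each prefixed by an untagged question marker
  units <- vector("list", n_units)
  pos <- 0L
  for (u in seq_len(n_units)) {
    idx <- pos + seq_len(ans_len[[u]])
    pos <- pos + ans_len[[u]]
    units[[u]] <- list(
      tokens = c(sample(lexicon$questions, 1L), surf[idx]),
      bio_tags = c("O", tags[idx]))
  }
  rec <- new_record(units, label)
  rec$loc_group <- lg; rec$sym_group <- sg
  rec$entity_counts <- c(SYMPTOM = n_sym, LOCATION = n_loc, DISEASE = n_dis)
  rec
}

#' Write a corpus with its manifest
#'
#' Writes the records in both on-disk formats plus a JSON manifest
#' recording the generator configuration and seed.
#'
#' @param records A [generate_corpus()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(records, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_conll(records, file.path(dir, "corpus.conll"))
  write_jsonl(records, file.path(dir, "corpus.jsonl"))
  cfg <- attr(records, "config")
  if (!is.null(cfg)) {
    jsonlite::write_json(unclass(cfg)[setdiff(names(cfg), "class_prior")],
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}
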