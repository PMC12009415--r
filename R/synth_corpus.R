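#' Configuration for the synthetic Q&A corpus generator
#'
#' The generator emulates the discourse structure of an online rehabilitation
#' Q&A community: patients describe symptoms and ask a question, doctors name
#' a disease and recommend (or advise against) rehabilitation measures. Each
#' relation label plants a distinct cue lexicon next to the entity pair, so
#' the relation is recoverable from the text. The default class mix mirrors
#' the strong imbalance of annotated clinical Q&A corpora
#' (DS:SFD:NSFD:UKN = 901:3602:497:235).
#'
#' @param n_records Number of Q&A records (one gold relation each).
#' @param class_mix Named non-negative weights over DS/SFD/NSFD/UKN;
#'   normalised to sum 1.
#' @param n_diseases,n_symptoms,n_measures,n_filler Vocabulary sizes.
#' @param cues Named list of cue lexicons per relation label (UKN has none).
#' @param noise_sentence_rate Probability of inserting a cue-free filler
#'   sentence before, and independently after, the relation-bearing clause.
#' @param coref_rate Fraction of answers that add a pronoun-style follow-up
#'   ("it needs care") instead of repeating the disease name.
#' @param max_len Maximum marked-text length in whitespace tokens.
#' @param seed Integer seed; generation is a pure function of the config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_records = 200,
                             class_mix = c(DS = 901, SFD = 3602,
                                           NSFD = 497, UKN = 235),
                             n_diseases = 40, n_symptoms = 60,
                             n_measures = 60, n_filler = 80,
                             cues = default_cues(),
                             noise_sentence_rate = 0.3,
                             coref_rate = 0.3,
                             max_len = 200, seed = 1L) {
  stopifnot(n_records >= 0, all(class_mix >= 0), sum(class_mix) > 0,
            noise_sentence_rate >= 0, noise_sentence_rate <= 1,
            coref_rate >= 0, coref_rate <= 1, max_len >= 16)
  mix <- class_mix[RELATION_LABELS]
  names(mix) <- RELATION_LABELS
  mix[is.na(mix)] <- 0
  structure(list(n_records = as.integer(n_records),
                 class_mix = mix / sum(mix),
                 n_diseases = n_diseases, n_symptoms = n_symptoms,
                 n_measures = n_measures, n_filler = n_filler,
                 cues = cues,
                 noise_sentence_rate = noise_sentence_rate,
                 coref_rate = coref_rate,
                 max_len = as.integer(max_len),
                 seed = as.integer(seed)),
            class = "generator_config")
}

default_cues <- function() {
  list(DS   = c("indicates", "suggests", "presents"),
       SFD  = c("recommended", "suitable", "take", "apply"),
       NSFD = c("avoid", "reduce", "forbid", "unsuitable"))
}

#' Generate a synthetic Q&A corpus with planted relations
#'
#' Each record carries one gold relation: the question embeds a symptom
#' mention, the answer embeds the disease and (for measure relations) the
#' measure next to a label-specific cue word. UKN records place both entities
#' in the question and give a non-committal answer with no cue. Cue-free
#' filler sentences are inserted at `noise_sentence_rate` to exercise the
#' attention mechanism's noise filtering.
#'
#' @param config A [generator_config()].
#' @param labels Optional explicit label vector of length `n_records`
#'   overriding sampling from `class_mix`.
#' @return A list with `records` (list of [qa_record()]), `gold` (list of
#'   `relation_instance`), and `triples` (data.frame of gold
#'   entity1/entity2/relation).
#' @export
generate_corpus <- function(config, labels = NULL) {
  stopifnot(inherits(config, "generator_config"))
  dis_v <- paste0("dis", seq_len(config$n_diseases))
  sym_v <- paste0("sym", seq_len(config$n_symptoms))
  tre_v <- paste0("tre", seq_len(config$n_measures))
  fil_v <- paste0("w", seq_len(config$n_filler))
  if (!is.null(labels)) {
    stopifnot(length(labels) == config$n_records,
              all(labels %in% RELATION_LABELS))
    zero <- names(config$class_mix)[config$class_mix == 0]
    if (any(labels %in% zero))
      stop("config-error: requested label with zero class_mix weight")
  }
  records <- vector("list", config$n_records)
  gold <- vector("list", config$n_records)
  with_seed(config$seed, {
    if (is.null(labels)) {
      labels <- sample(RELATION_LABELS, config$n_records, replace = TRUE,
                       prob = config$class_mix)
    }
    for (i in seq_len(config$n_records)) {
      g <- generate_record(i, labels[i], config, dis_v, sym_v, tre_v, fil_v)
      records[[i]] <- g$record
      gold[[i]] <- g$instance
    }
  })
  triples <- data.frame(
    entity1 = vapply(gold, `[[`, character(1), "entity1"),
    entity2 = vapply(gold, `[[`, character(1), "entity2"),
    relation = vapply(gold, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  list(records = records, gold = gold, triples = triples)
}

filler_sentence <- function(fil_v, n_tokens = sample(4:7, 1)) {
  sample(fil_v, n_tokens, replace = TRUE)
}

# Build one record plus its gold instance; runs inside the seeded block.
generate_record <- function(i, label, config, dis_v, sym_v, tre_v, fil_v) {
  dis <- sample(dis_v, 1); sym <- sample(sym_v, 1); tre <- sample(tre_v, 1)
  noisy <- function() stats::runif(1) < config$noise_sentence_rate
  title_toks <- sample(fil_v, 2)
  if (label == "UKN") {
    # both entities in the question, non-committal answer, no cue
    content_toks <- c(filler_sentence(fil_v, 3), dis,
                      filler_sentence(fil_v, 2), tre,
                      filler_sentence(fil_v, 2))
    answer_toks <- c(filler_sentence(fil_v, 5))
    e1_tok <- dis; e2_tok <- tre
  } else {
    content_toks <- c(filler_sentence(fil_v, 3), sym,
                      filler_sentence(fil_v, 3))
    cue <- sample(config$cues[[label]], 1)
    core <- if (label == "DS") c("considering", dis, cue, "rest")
            else c("considering", dis, cue, tre)
    pre <- if (noisy()) filler_sentence(fil_v) else character()
    post <- if (noisy()) filler_sentence(fil_v) else character()
    answer_toks <- c(pre, core, post)
    if (stats::runif(1) < config$coref_rate)
      answer_toks <- c(answer_toks, "it", "needs", "care")
    e1_tok <- dis
    e2_tok <- if (label == "DS") sym else tre
  }
  parts <- list(title = title_toks, content = content_toks,
                answer = answer_toks)
  texts <- vapply(parts, paste, character(1), collapse = " ")
  concat <- paste(texts, collapse = " ")
  toks <- unlist(parts, use.names = FALSE)
  starts <- cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
  locate <- function(tok) {
    j <- which(toks == tok)[1]
    c(starts[j], starts[j] + nchar(tok))
  }
  mk_mention <- function(tok, etype) {
    sp <- locate(tok)
    data.frame(surface = tok, etype = etype, start = sp[1], end = sp[2],
               stringsAsFactors = FALSE)
  }
  etype2 <- if (label == "DS") "SYM" else "TRE"
  mentions <- rbind(mk_mention(e1_tok, "DIS"), mk_mention(e2_tok, etype2))
  # record also carries the unrelated mentions so filtering/pairing is honest
  if (label != "UKN" && label != "DS") mentions <- rbind(mentions,
    mk_mention(sym, "SYM"))
  rec <- qa_record(sprintf("r%05d", i), texts[["title"]],
                   texts[["content"]], texts[["answer"]], mentions)
  inst <- make_marked_instance(rec, mentions[1, ], mentions[2, ], label)
  ntok <- length(tokenize(inst$marked_text))
  if (ntok > config$max_len)
    stop("generated instance exceeds max_len; increase max_len")
  list(record = rec, instance = inst)
}

#' Per-label counts and proportions of a set of relation instances
#'
#' @param instances List of `relation_instance` objects, or a character
#'   vector of labels.
#' @return A data.frame with columns `label`, `n`, `proportion` (3 decimals),
#'   and an attribute `total`.
#' @export
corpus_stats <- function(instances) {
  labels <- if (is.character(instances)) instances
            else vapply(instances, `[[`, character(1), "label")
  if (length(labels) == 0) stop("empty instance set")
  n <- vapply(RELATION_LABELS, function(l) sum(labels == l), integer(1))
  out <- data.frame(label = RELATION_LABELS, n = as.integer(n),
                    proportion = round(n / sum(n), 3),
                    stringsAsFactors = FALSE)
  attr(out, "total") <- sum(n)
  out
}
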