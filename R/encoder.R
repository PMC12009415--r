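#' Tokenize marked text
#'
#' Two modes: `"whitespace"` (synthetic corpora; splits on runs of blanks)
#' and `"character"` (per-character, the natural unit for unsegmented
#' scripts). The position markers `"#"` and `"*"` are always single tokens;
#' escaped literals (`"\\#"`, `"\\*"`) stay attached to their backslash.
#'
#' @param text Character scalar.
#' @param mode `"whitespace"` or `"character"`.
#' @return Character vector of tokens.
#' @export
tokenize <- function(text, mode = c("whitespace", "character")) {
  mode <- match.arg(mode)
  if (!nzchar(text)) return(character())
  if (mode == "character") {
    return(strsplit(text, "", fixed = FALSE)[[1]])
  }
  # detach unescaped markers so they tokenize alone
  text <- gsub("(?<!\\\\)([#*])", " \\1 ", text, perl = TRUE)
  toks <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  toks[nzchar(toks)]
}

#' Build a vocabulary from tokenized instances
#'
#' @param token_lists List of token vectors (e.g. from [tokenize()]).
#' @return Character vector of unique tokens with the reserved `"<unk>"`
#'   entry first.
#' @export
build_vocab <- function(token_lists) {
  c("<unk>", sort(unique(unlist(token_lists, use.names = FALSE))))
}

#' Create a lookup (trainable token-embedding) encoder
#'
#' A self-contained embedding backend: every vocabulary token owns a trainable
#' `D`-vector, initialised from `seed`; unknown tokens map to a reserved
#' `"<unk>"` row. An optional adapter around an external contextual encoder
#' can be supplied instead via `embed_fn` with `backend = "pretrained"` (no
#' such encoder ships with the package, and none is needed: the lookup
#' backend is the default for all experiments here).
#'
#' @param vocab Character vector from [build_vocab()] (lookup backend).
#' @param D Embedding width (default 32 for the lookup backend; a contextual
#'   adapter would typically use 768).
#' @param L Maximum sequence length in tokens (default 200).
#' @param seed Seed for the embedding initialisation.
#' @param mode Tokenization mode, see [tokenize()].
#' @param backend `"lookup"` or `"pretrained"`.
#' @param embed_fn For `"pretrained"`: `function(tokens) -> length(tokens) x D`
#'   matrix of contextual embeddings.
#' @return An object of class `text_encoder`.
#' @export
lookup_encoder <- function(vocab, D = 32L, L = 200L, seed = 1L,
                           mode = "whitespace", backend = "lookup",
                           embed_fn = NULL) {
  backend <- match.arg(backend, c("lookup", "pretrained"))
  enc <- list(backend = backend, vocab = vocab, D = as.integer(D),
              L = as.integer(L), seed = as.integer(seed), mode = mode,
              embed_fn = embed_fn)
  if (backend == "lookup") {
    enc$E <- with_seed(seed,
      matrix(stats::rnorm(length(vocab) * D, sd = 0.1),
             nrow = length(vocab), ncol = D))
    rownames(enc$E) <- vocab
  } else if (is.null(embed_fn)) {
    stop("the pretrained backend needs an embed_fn adapter; ",
         "use backend = \"lookup\" for a self-contained encoder")
  }
  structure(enc, class = "text_encoder")
}

#' Map tokens to vocabulary row indices
#'
#' Unknown tokens go to the reserved `"<unk>"` row (index 1). Sequences
#' longer than `L` are truncated at the head with a warning; if truncation
#' drops a position marker the result is flagged invalid.
#'
#' @param encoder A [lookup_encoder()].
#' @param tokens Character vector of tokens.
#' @return Integer vector of row indices (length <= L) with attribute
#'   `valid` (FALSE when a marker was truncated away).
#' @export
token_ids <- function(encoder, tokens) {
  valid <- TRUE
  if (length(tokens) > encoder$L) {
    dropped <- tokens[-seq_len(encoder$L)]
    tokens <- tokens[seq_len(encoder$L)]
    warning(sprintf("sequence truncated to %d tokens", encoder$L))
    if (any(dropped %in% c("#", "*"))) valid <- FALSE
  }
  ids <- match(tokens, encoder$vocab)
  ids[is.na(ids)] <- 1L
  structure(ids, valid = valid)
}

#' Encode text as an L x D matrix with a padding mask
#'
#' @param encoder A [lookup_encoder()].
#' @param text Character scalar (marked instance text).
#' @param label Optional relation label carried on the result.
#' @return An object of class `encoded_instance`: `matrix` (L x D, padding
#'   rows all zero), `mask` (L logicals, `TRUE` = real token), `tokens`,
#'   `label`, `valid`.
#' @export
encode <- function(encoder, text, label = NULL) {
  toks <- tokenize(text, encoder$mode)
  L <- encoder$L; D <- encoder$D
  mat <- matrix(0, nrow = L, ncol = D)
  mask <- rep(FALSE, L)
  valid <- TRUE
  if (length(toks) > 0) {
    if (encoder$backend == "lookup") {
      ids <- token_ids(encoder, toks)
      valid <- attr(ids, "valid")
      n <- length(ids)
      mat[seq_len(n), ] <- encoder$E[ids, , drop = FALSE]
    } else {
      if (length(toks) > L) {
        dropped <- toks[-seq_len(L)]
        toks <- toks[seq_len(L)]
        warning(sprintf("sequence truncated to %d tokens", L))
        if (any(dropped %in% c("#", "*"))) valid <- FALSE
      }
      emb <- encoder$embed_fn(toks)
      stopifnot(is.matrix(emb), nrow(emb) == length(toks), ncol(emb) == D)
      n <- nrow(emb)
      mat[seq_len(n), ] <- emb
    }
    mask[seq_len(min(length(toks), L))] <- TRUE
  }
  structure(list(matrix = mat, mask = mask,
                 tokens = toks[seq_len(min(length(toks), L))],
                 label = label, valid = valid),
            class = "encoded_instance")
}

# Batch helper used by the training loop: pad token ids into a B x L integer
# matrix (0 = padding) plus a logical mask. Avoids materialising dense L x D
# matrices per instance; the embedding lookup happens per timestep.
batch_ids <- function(encoder, instances) {
  B <- length(instances)
  ids <- matrix(0L, nrow = B, ncol = encoder$L)
  mask <- matrix(FALSE, nrow = B, ncol = encoder$L)
  labels <- character(B)
  valid <- logical(B)
  for (b in seq_len(B)) {
    inst <- instances[[b]]
    toks <- tokenize(inst$marked_text, encoder$mode)
    tid <- suppressWarnings(token_ids(encoder, toks))
    valid[b] <- attr(tid, "valid")
    n <- length(tid)
    if (n > 0) {
      ids[b, seq_len(n)] <- tid
      mask[b, seq_len(n)] <- TRUE
    }
    labels[b] <- inst$label %||% NA_character_
  }
  list(ids = ids, mask = mask, labels = labels, valid = valid)
}
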