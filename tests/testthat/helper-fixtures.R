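# Build a record from token vectors, computing mention offsets over the
# space-joined concatenation so fixtures never hand-count characters.
record_from_tokens <- function(id, title_toks, content_toks, answer_toks,
                               mention_spec) {
  parts <- list(title_toks, content_toks, answer_toks)
  toks <- unlist(parts, use.names = FALSE)
  starts <- cumsum(c(0L, nchar(toks[-length(toks)]) + 1L))
  mentions <- do.call(rbind, lapply(mention_spec, function(ms) {
    j <- which(toks == ms$token)[ms$occurrence %||% 1]
    data.frame(surface = ms$token, etype = ms$etype, start = starts[j],
               end = starts[j] + nchar(ms$token), stringsAsFactors = FALSE)
  }))
  qa_record(id, paste(title_toks, collapse = " "),
            paste(content_toks, collapse = " "),
            paste(answer_toks, collapse = " "), mentions)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

make_instances <- function(label, n, prefix = label) {
  lapply(seq_len(n), function(i)
    relation_instance(label, paste0(prefix, "_e1_", i),
                      paste0(prefix, "_e2_", i),
                      paste("ctx # mid *", prefix, i)))
}

# dictionary with three disjoint symptom motifs, eight diseases each
planted_motif_dict <- function(kind = "DS", n_per = 8, n_vals = 4,
                               seed = 3) {
  motifs <- list(A = paste0("symA", 1:6), B = paste0("symB", 1:6),
                 C = paste0("symC", 1:6))
  entries <- list()
  withr::with_seed(seed, {
    for (m in names(motifs)) for (i in seq_len(n_per))
      entries[[paste0("dis_", m, i)]] <- sample(motifs[[m]], n_vals)
  })
  structure(list(kind = kind, entries = entries),
            class = "relation_dictionary")
}

# brute-force attention pooling, written with explicit loops
oracle_attention <- function(H, omega, mask) {
  scores <- numeric(nrow(H))
  for (t in seq_len(nrow(H)))
    scores[t] <- sum(tanh(H[t, ]) * omega)
  scores[!as.logical(mask)] <- -Inf
  e <- exp(scores - max(scores))
  alpha <- e / sum(e)
  cv <- numeric(ncol(H))
  for (t in seq_len(nrow(H))) if (alpha[t] > 0)
    cv <- cv + alpha[t] * H[t, ]
  list(alpha = alpha, c = cv)
}
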