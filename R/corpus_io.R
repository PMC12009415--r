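RELATION_LABELS <- c("DS", "SFD", "NSFD", "UKN")
ENTITY_TYPES <- c("DIS", "SYM", "TRE")

#' Construct a Q&A record
#'
#' A record is one patient inquiry (title + free-text content) together with
#' the ordered doctor answers and the typed entity mentions found in the
#' record. Mention offsets are 0-based, half-open character offsets into the
#' concatenation produced by [concat_record()] with the same separator.
#'
#' @param record_id Opaque identifier.
#' @param question_title,question_content Question parts; at least one must be
#'   non-empty.
#' @param answers Character vector of answer texts (may be empty).
#' @param mentions A data.frame with columns `surface`, `etype` (one of
#'   `"DIS"`, `"SYM"`, `"TRE"`), `start`, `end`.
#' @param sep Separator used when concatenating (must match the offsets).
#' @return An object of class `qa_record`.
#' @export
qa_record <- function(record_id, question_title = "", question_content = "",
                      answers = character(), mentions = empty_mentions(),
                      sep = " ") {
  if (!nzchar(question_title) && !nzchar(question_content) &&
      length(answers) == 0) {
    stop("degenerate-input: record has no question and no answers")
  }
  mentions <- as.data.frame(mentions, stringsAsFactors = FALSE)
  rec <- structure(
    list(record_id = as.character(record_id),
         question_title = question_title,
         question_content = question_content,
         answers = as.character(answers),
         mentions = mentions,
         sep = sep),
    class = "qa_record")
  validate_mentions(rec)
  rec
}

empty_mentions <- function() {
  data.frame(surface = character(), etype = character(),
             start = integer(), end = integer(), stringsAsFactors = FALSE)
}

validate_mentions <- function(record) {
  m <- record$mentions
  if (nrow(m) == 0) return(invisible(TRUE))
  stopifnot(all(m$etype %in% ENTITY_TYPES), all(m$start < m$end))
  text <- concat_record(record)
  slice <- substring(text, m$start + 1L, m$end)
  bad <- which(slice != m$surface)
  if (length(bad)) {
    stop(sprintf("mention %d: surface %s does not match text slice %s",
                 bad[1], dQuote(m$surface[bad[1]]), dQuote(slice[bad[1]])))
  }
  invisible(TRUE)
}

#' Concatenate a record into a single text
#'
#' Joins question title, question content and every answer, in order, with a
#' single configurable separator. Empty parts are dropped so the separator
#' never doubles up.
#'
#' @param record A [qa_record()].
#' @param sep Separator; defaults to the one stored on the record.
#' @return A single character string.
#' @export
concat_record <- function(record, sep = record$sep) {
  parts <- c(record$question_title, record$question_content, record$answers)
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0) stop("degenerate-input: empty record")
  paste(parts, collapse = sep)
}

#' Drop records whose mentions cover fewer than two entity types
#'
#' A record mentioning only one entity type (e.g. symptoms alone) carries no
#' extractable cross-type relation and is excluded.
#'
#' @param records List of [qa_record()] objects.
#' @return The retained sublist.
#' @export
filter_single_entity_type <- function(records) {
  keep <- vapply(records, function(r) {
    length(unique(r$mentions$etype)) >= 2L
  }, logical(1))
  records[keep]
}

#' Build a position-marked relation instance
#'
#' Replaces the first entity's span with `"#"` and the second entity's span
#' with `"*"` in the concatenated record text, keeping the entity surfaces in
#' header fields, so the classifier sees where each entity sat.
#'
#' @param record A [qa_record()].
#' @param e1,e2 Single-row mention data.frames (or list-like with `surface`,
#'   `etype`, `start`, `end`). For labels DS/SFD/NSFD `e1` must be a DIS
#'   mention and `e2` a SYM (DS) or TRE (SFD/NSFD) mention.
#' @param label One of `"DS"`, `"SFD"`, `"NSFD"`, `"UKN"`.
#' @param escape If `TRUE`, pre-existing `"#"`/`"*"` characters in the text
#'   are escaped as `"\\#"`/`"\\*"` instead of raising an error.
#' @return An object of class `relation_instance` with fields `label`,
#'   `entity1`, `entity2`, `marked_text`.
#' @export
make_marked_instance <- function(record, e1, e2, label, escape = FALSE) {
  label <- match.arg(label, RELATION_LABELS)
  e1 <- as.list(e1); e2 <- as.list(e2)
  if (label %in% c("DS", "SFD", "NSFD")) {
    if (e1$etype != "DIS")
      stop("entity 1 must be a DIS mention for label ", label)
    want <- if (label == "DS") "SYM" else "TRE"
    if (e2$etype != want)
      stop("entity 2 must be a ", want, " mention for label ", label)
  }
  if (max(e1$start, e2$start) < min(e1$end, e2$end))
    stop("annotation-conflict: overlapping entity spans")
  text <- concat_record(record)
  if (grepl("[#*]", text)) {
    if (!escape) stop("reserved-character collision: text contains '#' or '*'")
    # escape literals first; spans were measured on the raw text so replace
    # markers before escaping would corrupt offsets -- replace spans first on
    # the raw text, then escape leftover literals
  }
  # place sentinels first so escaping literals cannot touch the markers
  spans <- list(list(s = e1$start, e = e1$end, sentinel = "\001"),
                list(s = e2$start, e = e2$end, sentinel = "\002"))
  spans <- spans[order(-vapply(spans, `[[`, numeric(1), "s"))]
  for (sp in spans) {
    text <- paste0(substring(text, 1L, sp$s), sp$sentinel,
                   substring(text, sp$e + 1L))
  }
  if (escape) {
    text <- gsub("#", "\\#", text, fixed = TRUE)
    text <- gsub("*", "\\*", text, fixed = TRUE)
  }
  text <- gsub("\001", "#", text, fixed = TRUE)
  text <- gsub("\002", "*", text, fixed = TRUE)
  relation_instance(label, e1$surface, e2$surface, text)
}

#' Construct a relation instance
#'
#' @param label Relation label (`"NSF"` is accepted and normalised to
#'   `"NSFD"`).
#' @param entity1,entity2 Entity surfaces.
#' @param marked_text Text containing exactly one unescaped `"#"` and one
#'   unescaped `"*"`.
#' @return An object of class `relation_instance`.
#' @export
relation_instance <- function(label, entity1, entity2, marked_text) {
  if (identical(label, "NSF")) label <- "NSFD"
  if (!label %in% RELATION_LABELS)
    stop("parse-error: unknown label ", dQuote(label))
  for (mk in c("#", "*")) {
    n <- marker_count(marked_text, mk)
    if (n != 1L)
      stop(sprintf("parse-error: marker %s count %d (expected 1)",
                   dQuote(mk), n))
  }
  structure(list(label = label, entity1 = entity1, entity2 = entity2,
                 marked_text = marked_text),
            class = "relation_instance")
}

marker_count <- function(text, marker) {
  # count unescaped occurrences: strip "\#"/"\*" first
  stripped <- gsub(paste0("\\", marker), "", text, fixed = TRUE)
  lengths(regmatches(stripped, gregexpr(marker, stripped, fixed = TRUE)))
}

#' Serialize a relation instance to the annotation line format
#'
#' The line format is `label@entity1$entity2$marked_text`.
#'
#' @param instance A `relation_instance`.
#' @return A single character string.
#' @export
serialize_instance <- function(instance) {
  paste0(instance$label, "@", instance$entity1, "$", instance$entity2, "$",
         instance$marked_text)
}

#' Parse one annotation line
#'
#' Splits on the first `"@"` and the first two `"$"` only, so entity surfaces
#' and the text may contain later occurrences of either character.
#'
#' @param line A non-empty annotation line.
#' @param line_number Optional line number used in error messages.
#' @return A `relation_instance`.
#' @export
parse_annotation <- function(line, line_number = NA_integer_) {
  fail <- function(msg) {
    where <- if (is.na(line_number)) "" else sprintf(" at line %d", line_number)
    stop(sprintf("parse-error%s: %s", where, msg), call. = FALSE)
  }
  if (!nzchar(line)) fail("empty line")
  at <- regexpr("@", line, fixed = TRUE)
  if (at < 0) fail("missing '@' delimiter")
  label <- substring(line, 1L, at - 1L)
  rest <- substring(line, at + 1L)
  d1 <- regexpr("$", rest, fixed = TRUE)
  if (d1 < 0) fail("missing first '$' delimiter")
  entity1 <- substring(rest, 1L, d1 - 1L)
  rest2 <- substring(rest, d1 + 1L)
  d2 <- regexpr("$", rest2, fixed = TRUE)
  if (d2 < 0) fail("missing second '$' delimiter")
  entity2 <- substring(rest2, 1L, d2 - 1L)
  marked_text <- substring(rest2, d2 + 1L)
  tryCatch(relation_instance(label, entity1, entity2, marked_text),
           error = function(e) fail(conditionMessage(e)))
}

#' Read / write annotation files
#'
#' One `label@entity1$entity2$marked_text` instance per line, UTF-8.
#'
#' @param path File path.
#' @return `read_annotations()` returns a list of `relation_instance`;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  mapply(parse_annotation, lines, seq_along(lines),
         SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' @param instances List of `relation_instance` objects.
#' @rdname read_annotations
#' @export
write_annotations <- function(instances, path) {
  writeLines(vapply(instances, serialize_instance, character(1)),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read / write Q&A records as JSON-lines
#'
#' One record per line; mentions are carried as an embedded array of
#' `{surface, etype, start, end}` objects.
#'
#' @param path File path.
#' @return `read_qa_jsonl()` returns a list of [qa_record()];
#'   `write_qa_jsonl()` returns `path` invisibly.
#' @export
read_qa_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lapply(lines[nzchar(lines)], function(line) {
    x <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
    m <- if (is.null(x$mentions) || length(x$mentions) == 0) empty_mentions()
         else as.data.frame(x$mentions, stringsAsFactors = FALSE)
    qa_record(x$record_id, x$question_title, x$question_content,
              unlist(x$answers), m, sep = x$sep %||% " ")
  })
}

#' @param records List of [qa_record()] objects.
#' @rdname read_qa_jsonl
#' @export
write_qa_jsonl <- function(records, path) {
  lines <- vapply(records, function(r) {
    jsonlite::toJSON(list(record_id = r$record_id,
                          question_title = r$question_title,
                          question_content = r$question_content,
                          answers = r$answers,
                          mentions = r$mentions,
                          sep = r$sep),
                     auto_unbox = TRUE, dataframe = "rows")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Per class, the training share is rounded half-up; the leftover is split
#' between validation and test as evenly as the ratios allow. When a class
#' leaves an odd instance, it goes to whichever of validation/test holds the
#' smaller running total so far (tie broken toward validation), so the global
#' totals stay balanced across classes.
#'
#' @param instances List of `relation_instance` objects.
#' @param ratios Three non-negative fractions summing to 1
#'   (training/validation/test); default `c(0.6, 0.2, 0.2)`.
#' @param seed Integer seed driving the shuffle.
#' @return A list with elements `train`, `validation`, `test`.
#' @export
stratified_split <- function(instances, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios >= 0),
            abs(sum(ratios) - 1) < 1e-9)
  labels <- vapply(instances, `[[`, character(1), "label")
  classes <- unique(labels)
  out <- list(train = list(), validation = list(), test = list())
  val_total <- 0L; test_total <- 0L
  with_seed(seed, {
    for (cl in classes) {
      idx <- which(labels == cl)
      n <- length(idx)
      if (n < 3L) {
        warning(sprintf("class %s has %d (<3) instances; placed in training",
                        cl, n))
        out$train <- c(out$train, instances[idx])
        next
      }
      idx <- idx[sample.int(n)]
      n_train <- floor(ratios[1] * n + 0.5)  # round half up
      m <- n - n_train
      frac_val <- if (ratios[2] + ratios[3] > 0)
        ratios[2] / (ratios[2] + ratios[3]) else 0
      n_val <- floor(m * frac_val)
      n_test <- floor(m * (1 - frac_val))
      if (n_val + n_test < m) {
        # odd instance: give it to the side currently holding fewer
        if (val_total <= test_total) n_val <- n_val + (m - n_val - n_test)
        else n_test <- n_test + (m - n_val - n_test)
      }
      out$train <- c(out$train, instances[idx[seq_len(n_train)]])
      out$validation <- c(out$validation,
                          instances[idx[n_train + seq_len(n_val)]])
      out$test <- c(out$test,
                    instances[idx[n_train + n_val + seq_len(n_test)]])
      val_total <- val_total + n_val
      test_total <- test_total + n_test
    }
  })
  out
}

#' Enumerate candidate entity pairs for prediction
#'
#' All ordered (DIS, SYM) and (DIS, TRE) mention pairs of a record; the
#' classifier decides the relation (UKN predictions are discarded when the
#' dictionaries are assembled).
#'
#' @param record A [qa_record()].
#' @return A list of lists with elements `e1`, `e2` (single-row mention rows).
#' @export
candidate_pairs <- function(record) {
  m <- record$mentions
  dis <- which(m$etype == "DIS")
  other <- which(m$etype %in% c("SYM", "TRE"))
  pairs <- list()
  for (i in dis) for (j in other) {
    if (max(m$start[i], m$start[j]) < min(m$end[i], m$end[j])) next
    pairs[[length(pairs) + 1L]] <- list(e1 = m[i, ], e2 = m[j, ])
  }
  pairs
}

`%||%` <- function(a, b) if (is.null(a)) b else a
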