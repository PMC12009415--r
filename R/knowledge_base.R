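#' Organise relation triples into DS / SFD / NSFD dictionaries
#'
#' Each dictionary maps a disease name to the insertion-ordered unique list
#' of value phrases gathered from the triples: symptoms for DS, suitable
#' rehabilitation measures for SFD, unsuitable measures for NSFD. UKN
#' triples are dropped; exact duplicates are collapsed.
#'
#' @param triples Data.frame with columns `entity1`, `entity2`, `relation`.
#' @param normalize `"exact"` (default) or `"casefold"` (case-insensitive,
#'   whitespace-squashed matching for deduplication).
#' @return A named list of three `relation_dictionary` objects (`DS`,
#'   `SFD`, `NSFD`), with attributes `dropped_ukn` and `dropped_dup`.
#' @export
build_dictionaries <- function(triples, normalize = c("exact", "casefold")) {
  normalize <- match.arg(normalize)
  norm <- function(x) {
    if (normalize == "casefold") tolower(gsub("[[:space:]]+", " ",
                                              trimws(x))) else x
  }
  kinds <- c("DS", "SFD", "NSFD")
  dicts <- stats::setNames(lapply(kinds, function(k)
    structure(list(kind = k, entries = list()),
              class = "relation_dictionary")), kinds)
  dropped_ukn <- 0L; dropped_dup <- 0L
  for (i in seq_len(nrow(triples))) {
    rel <- triples$relation[i]
    if (rel == "UKN") { dropped_ukn <- dropped_ukn + 1L; next }
    stopifnot(rel %in% kinds)
    d <- triples$entity1[i]; v <- triples$entity2[i]
    cur <- dicts[[rel]]$entries[[d]]
    if (!is.null(cur) && norm(v) %in% norm(cur)) {
      dropped_dup <- dropped_dup + 1L
    } else {
      dicts[[rel]]$entries[[d]] <- c(cur, v)
    }
  }
  attr(dicts, "dropped_ukn") <- dropped_ukn
  attr(dicts, "dropped_dup") <- dropped_dup
  dicts
}

#' Dictionary sizes
#'
#' @param dicts Output of [build_dictionaries()].
#' @return Data.frame with `kind`, `n_diseases`, `n_pairs`.
#' @export
dictionary_sizes <- function(dicts) {
  do.call(rbind, lapply(dicts, function(d)
    data.frame(kind = d$kind, n_diseases = length(d$entries),
               n_pairs = sum(lengths(d$entries)),
               stringsAsFactors = FALSE)))
}

#' Flatten dictionaries back to a triple data.frame
#'
#' @param dicts Output of [build_dictionaries()].
#' @return Data.frame with `entity1`, `entity2`, `relation`.
#' @export
dictionaries_to_triples <- function(dicts) {
  rows <- lapply(dicts, function(d) {
    if (length(d$entries) == 0)
      return(data.frame(entity1 = character(), entity2 = character(),
                        relation = character(), stringsAsFactors = FALSE))
    data.frame(entity1 = rep(names(d$entries), lengths(d$entries)),
               entity2 = unlist(d$entries, use.names = FALSE),
               relation = d$kind, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a dictionary as JSON and as a table mirroring the key/type/size
#' layout used for knowledge-dictionary reporting
#'
#' @param dict A `relation_dictionary`.
#' @param json_path,csv_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the CSV table.
#' @export
write_dictionary <- function(dict, json_path = NULL, csv_path = NULL) {
  if (!is.null(json_path))
    jsonlite::write_json(dict$entries, json_path, auto_unbox = FALSE,
                         pretty = TRUE)
  tab <- data.frame(Key = names(dict$entries) %||% character(),
                    Type = rep("list", length(dict$entries)),
                    Size = unname(lengths(dict$entries)),
                    Value = unname(vapply(dict$entries, function(v)
                      paste0("['", paste(v, collapse = "','"), "']"),
                      character(1))),
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  if (!is.null(csv_path))
    utils::write.csv(tab, csv_path, row.names = FALSE)
  invisible(tab)
}

#' Read a dictionary back from its JSON form
#'
#' @param json_path Path written by [write_dictionary()].
#' @param kind Relation kind (`"DS"`, `"SFD"`, `"NSFD"`).
#' @return A `relation_dictionary`.
#' @export
read_dictionary <- function(json_path, kind) {
  entries <- jsonlite::fromJSON(json_path, simplifyVector = TRUE)
  entries <- lapply(entries, as.character)
  structure(list(kind = match.arg(kind, c("DS", "SFD", "NSFD")),
                 entries = entries),
            class = "relation_dictionary")
}

#' Export a disease's relation neighbourhood as a star graph
#'
#' The disease sits at the centre; one edge per value phrase, carrying the
#' relation kind as an edge attribute. Written as GraphML and/or DOT.
#'
#' @param dict A `relation_dictionary`.
#' @param disease Disease name present in the dictionary.
#' @param graphml_path,dot_path Output paths (either may be `NULL`).
#' @return The igraph object, invisibly.
#' @export
export_graph <- function(dict, disease, graphml_path = NULL,
                         dot_path = NULL) {
  values <- dict$entries[[disease]]
  if (is.null(values) && !disease %in% names(dict$entries))
    stop("lookup-error: disease ", dQuote(disease), " not in dictionary")
  g <- igraph::make_empty_graph(directed = FALSE)
  g <- igraph::add_vertices(g, 1, name = disease, role = "disease")
  if (length(values)) {
    g <- igraph::add_vertices(g, length(values), name = values,
                              role = "value")
    edges <- as.vector(rbind(1L, seq_along(values) + 1L))
    g <- igraph::add_edges(g, edges, relation = dict$kind)
  }
  if (!is.null(graphml_path))
    igraph::write_graph(g, graphml_path, format = "graphml")
  if (!is.null(dot_path))
    igraph::write_graph(g, dot_path, format = "dot")
  invisible(g)
}

#' Detect contradictory measure recommendations
#'
#' A (disease, measure) pair listed as suitable (SFD) by one answer and as
#' unsuitable (NSFD) by another is a contradiction worth surfacing.
#'
#' @param sfd_dict,nsfd_dict `relation_dictionary` objects.
#' @param casefold Match measures case-insensitively.
#' @return Data.frame with `disease`, `measure`, `sfd_values`,
#'   `nsfd_values` (the two provenance lists, collapsed with `"; "`).
#' @export
detect_contradictions <- function(sfd_dict, nsfd_dict, casefold = FALSE) {
  norm <- if (casefold) tolower else identity
  rows <- list()
  for (d in intersect(names(sfd_dict$entries), names(nsfd_dict$entries))) {
    s <- sfd_dict$entries[[d]]; nsf <- nsfd_dict$entries[[d]]
    hit <- s[norm(s) %in% norm(nsf)]
    for (m in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        disease = d, measure = m,
        sfd_values = paste(s, collapse = "; "),
        nsfd_values = paste(nsf, collapse = "; "),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(disease = character(), measure = character(),
                      sfd_values = character(), nsfd_values = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
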