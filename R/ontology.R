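#' Construct a concept graph
#'
#' A `concept_graph` holds the normalization target vocabulary: concepts with
#' a primary label, optional synonyms, `is_a`-style parent links forming a
#' DAG (multiple parents allowed), and an `is_vaccine` flag distinguishing
#' vaccine terms from the rest of the ontology.
#'
#' @param concepts a data.frame with columns `id` (unique, non-empty CURIE
#'   strings such as `"VO:0000738"`), `label` (non-empty), and optionally
#'   `synonyms` and `parents` (either list columns of character vectors or
#'   pipe-separated strings) and `is_vaccine` (logical or 0/1).
#' @return an object of class `concept_graph`.
#' @details Invariants enforced at construction: unique non-empty ids,
#'   non-empty labels, synonyms deduplicated and never equal to the label,
#'   every parent id resolving to a concept in the graph, and an acyclic
#'   parent relation (a cycle aborts with the offending ids).
#' @export
concept_graph <- function(concepts) {
  stopifnot(is.data.frame(concepts))
  need <- c("id", "label")
  miss <- setdiff(need, names(concepts))
  if (length(miss)) {
    stop_("concept_graph(): missing column(s): ", paste(miss, collapse = ", "))
  }
  id <- as.character(concepts$id)
  label <- as.character(concepts$label)
  syn <- as_pipe_list(concepts$synonyms %||% rep_len(list(character(0)), length(id)))
  par <- as_pipe_list(concepts$parents %||% rep_len(list(character(0)), length(id)))
  isv <- concepts$is_vaccine %||% rep(FALSE, length(id))
  isv <- as.logical(as.integer(as.logical(isv) | (isv == 1)))

  if (any(!nzchar(id)) || anyNA(id)) stop_("concept_graph(): empty concept id")
  if (anyDuplicated(id)) {
    stop_("concept_graph(): duplicate concept id(s): ",
          paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(!nzchar(label)) || anyNA(label)) {
    stop_("concept_graph(): empty label for id(s): ",
          paste(id[!nzchar(label) | is.na(label)], collapse = ", "))
  }
  syn <- Map(function(s, l) setdiff(unique(s[nzchar(s)]), l), syn, label)
  par <- lapply(par, function(p) unique(p[nzchar(p)]))

  unresolved <- setdiff(unlist(par, use.names = FALSE), id)
  if (length(unresolved)) {
    stop_("concept_graph(): parent id(s) not present in graph: ",
          paste(unresolved, collapse = ", "))
  }

  g <- structure(
    list(concepts = data.frame(
      id = id, label = label,
      synonyms = I(unname(syn)), parents = I(unname(par)),
      is_vaccine = isv, stringsAsFactors = FALSE
    )),
    class = "concept_graph"
  )
  cyc <- find_cycle(g)
  if (length(cyc)) {
    stop_("concept_graph(): cycle in parent links involving: ",
          paste(cyc, collapse = " -> "))
  }
  g
}

# Accept either list columns or pipe-separated character columns.
as_pipe_list <- function(x) {
  if (is.list(x) && !is.data.frame(x)) {
    lapply(x, function(e) as.character(e %||% character(0)))
  } else {
    lapply(as.character(x), function(e) {
      if (is.na(e) || !nzchar(e)) character(0)
      else strsplit(e, "|", fixed = TRUE)[[1]]
    })
  }
}

# Kahn's algorithm; returns ids stuck on a cycle (empty if acyclic).
find_cycle <- function(graph) {
  id <- graph$concepts$id
  par <- graph$concepts$parents
  indeg <- lengths(par)               # edges point child -> parent
  names(indeg) <- id
  children <- children_map(graph)
  queue <- id[indeg == 0]             # concepts with no parents
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]] %||% character(0)) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen == length(id)) character(0) else id[indeg > 0]
}

# id -> character vector of child ids.
children_map <- function(graph) {
  id <- graph$concepts$id
  par <- graph$concepts$parents
  ch <- lapply(seq_along(id), function(i) character(0))
  names(ch) <- id
  for (i in seq_along(id)) {
    for (p in par[[i]]) ch[[p]] <- c(ch[[p]], id[i])
  }
  ch
}

#' @export
print.concept_graph <- function(x, ...) {
  cat(sprintf(
    "concept_graph: %d concepts (%d vaccine), %d roots\n",
    nrow(x$concepts), sum(x$concepts$is_vaccine), length(graph_roots(x))
  ))
  invisible(x)
}

#' Roots of a concept graph
#'
#' @param graph a [concept_graph()].
#' @return character vector of ids with no parents.
#' @export
graph_roots <- function(graph) {
  stopifnot(inherits(graph, "concept_graph"))
  graph$concepts$id[lengths(graph$concepts$parents) == 0]
}

#' All-names index of a concept graph
#'
#' One row per (concept, name) pair over labels and synonyms, with a
#' case-folded form (lowercase, trademark/registration glyphs stripped) for
#' substring matching and encoding.
#'
#' @param graph a [concept_graph()].
#' @return data.frame with columns `concept_id`, `name`, `folded`.
#' @export
concept_names <- function(graph) {
  stopifnot(inherits(graph, "concept_graph"))
  co <- graph$concepts
  n_each <- 1L + lengths(co$synonyms)
  nm <- unlist(Map(c, co$label, co$synonyms), use.names = FALSE)
  out <- data.frame(
    concept_id = rep(co$id, n_each),
    name = if (is.null(nm)) character(0) else nm,
    stringsAsFactors = FALSE
  )
  out$folded <- norm_key(out$name)
  out
}

#' Load a concept vocabulary
#'
#' Reads a vocabulary either from a minimal OBO 1.4 flat file (only the
#' `[Term]` stanza tags `id`, `name`, `synonym`, `is_a` are honored; other
#' tags and stanza types are ignored) or from the package's TSV vocabulary
#' dialect (columns `id`, `label`, `synonyms`, `parents` — pipe-separated —
#' and `is_vaccine` as 0/1; UTF-8; header required).
#'
#' @param source path to the vocabulary file.
#' @param format `"tsv"` or `"obo"`.
#' @return a [concept_graph()].
#' @export
load_vocabulary <- function(source, format = c("tsv", "obo")) {
  format <- match.arg(format)
  if (!file.exists(source)) stop_("load_vocabulary(): no such file: ", source)
  switch(format, tsv = read_vocab_tsv(source), obo = read_obo(source))
}

read_vocab_tsv <- function(path) {
  tab <- tryCatch(
    utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                      colClasses = "character", fileEncoding = "UTF-8"),
    error = function(e) stop_("load_vocabulary(): cannot parse '", path,
                              "': ", conditionMessage(e))
  )
  need <- c("id", "label", "synonyms", "parents", "is_vaccine")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_("load_vocabulary(): '", path, "' is missing column(s): ",
          paste(miss, collapse = ", "))
  }
  if (nrow(tab) == 0) stop_("load_vocabulary(): '", path, "' has no records")
  concept_graph(tab)
}

#' Write a concept graph to the vocabulary TSV dialect
#'
#' @param graph a [concept_graph()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vocabulary <- function(graph, path) {
  stopifnot(inherits(graph, "concept_graph"))
  co <- graph$concepts
  out <- data.frame(
    id = co$id, label = co$label,
    synonyms = vapply(co$synonyms, paste, "", collapse = "|"),
    parents = vapply(co$parents, paste, "", collapse = "|"),
    is_vaccine = as.integer(co$is_vaccine),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_obo <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (!length(lines)) stop_("load_vocabulary(): empty OBO file: ", path)
  recs <- list()
  cur <- NULL
  cur_line <- NA_integer_
  flush <- function() {
    if (is.null(cur)) return()
    if (is.null(cur$id) || !nzchar(cur$id)) {
      stop_("load_vocabulary(): [Term] at line ", cur_line, " has no id tag")
    }
    if (is.null(cur$name) || !nzchar(cur$name)) {
      stop_("load_vocabulary(): [Term] '", cur$id, "' at line ", cur_line,
            " has no name tag")
    }
    recs[[length(recs) + 1L]] <<- cur
  }
  in_term <- FALSE
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "!")) next
    if (startsWith(line, "[")) {
      flush(); cur <- NULL
      in_term <- identical(line, "[Term]")
      if (in_term) {
        cur <- list(id = NULL, name = NULL,
                    synonyms = character(0), parents = character(0))
        cur_line <- ln
      }
      next
    }
    if (!in_term) next
    m <- regexpr(":", line, fixed = TRUE)
    if (m < 0) stop_("load_vocabulary(): malformed OBO line ", ln, ": ", line)
    tag <- substr(line, 1, m - 1)
    val <- trimws(substr(line, m + 1, nchar(line)))
    if (tag == "id") {
      cur$id <- val
    } else if (tag == "name") {
      cur$name <- val
    } else if (tag == "synonym") {
      q <- regmatches(val, regexpr('"[^"]*"', val))
      if (!length(q)) {
        stop_("load_vocabulary(): malformed synonym at line ", ln, ": ", line)
      }
      cur$synonyms <- c(cur$synonyms, substr(q, 2, nchar(q) - 1))
    } else if (tag == "is_a") {
      val <- trimws(sub("!.*$", "", val))
      if (nzchar(val)) cur$parents <- c(cur$parents, val)
    } # other tags ignored
  }
  flush()
  if (!length(recs)) {
    stop_("load_vocabulary(): no [Term] stanzas found in: ", path)
  }
  concept_graph(data.frame(
    id = vapply(recs, `[[`, "", "id"),
    label = vapply(recs, `[[`, "", "name"),
    synonyms = I(lapply(recs, `[[`, "synonyms")),
    parents = I(lapply(recs, `[[`, "parents")),
    is_vaccine = FALSE,
    stringsAsFactors = FALSE
  ))
}

#' Restrict a concept graph to its vaccine terms
#'
#' Replaces the manual curation step that separates vaccine from non-vaccine
#' terms in a mixed ontology. Two rule modes: the closure of named subtree
#' roots (everything reachable downward through `is_a` children), or a label
#' predicate. Parent links of retained concepts are restricted to retained
#' concepts, and `is_vaccine` is set on everything kept.
#'
#' @param graph a [concept_graph()].
#' @param roots character vector of subtree root ids (subtree mode).
#' @param predicate a function `label -> logical` (predicate mode). Exactly
#'   one of `roots`/`predicate` must be given.
#' @return the filtered [concept_graph()]. Idempotent under a fixed rule.
#' @export
filter_vaccine_terms <- function(graph, roots = NULL, predicate = NULL) {
  stopifnot(inherits(graph, "concept_graph"))
  if (is.null(roots) == is.null(predicate)) {
    stop_("filter_vaccine_terms(): give exactly one of roots= or predicate=")
  }
  id <- graph$concepts$id
  if (!is.null(roots)) {
    unknown <- setdiff(roots, id)
    if (length(unknown)) {
      stop_("filter_vaccine_terms(): unknown subtree root id(s): ",
            paste(unknown, collapse = ", "))
    }
    ch <- children_map(graph)
    keep <- character(0)
    queue <- unique(roots)
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      if (v %in% keep) next
      keep <- c(keep, v)
      queue <- c(queue, ch[[v]])
    }
  } else {
    stopifnot(is.function(predicate))
    keep <- id[vapply(graph$concepts$label, predicate, NA)]
  }
  co <- graph$concepts[match(intersect(id, keep), id), , drop = FALSE]
  co$parents <- I(lapply(co$parents, intersect, y = keep))
  co$is_vaccine <- TRUE
  concept_graph(co)
}

# Shortest directed path lengths (in parent-link steps) from id to each of
# its ancestors; named integer vector, excludes id itself. Plain BFS — the
# parent relation is a DAG, so first discovery level is the shortest path.
ancestor_depths <- function(graph, id) {
  par <- graph$concepts$parents
  names(par) <- graph$concepts$id
  depth <- integer(0)
  cur <- id
  level <- 0L
  while (length(cur)) {
    level <- level + 1L
    nxt <- setdiff(
      unique(unlist(par[cur], use.names = FALSE)),
      c(names(depth), id)
    )
    if (!length(nxt)) break
    depth[nxt] <- level
    cur <- nxt
  }
  depth
}

#' Classify the ontological relation between a gold and a predicted concept
#'
#' Relation taxonomy used by the error analysis: `exact` (same concept),
#' `oov` (prediction absent from the graph), `parent_child` (a direct
#' `is_a` edge in either direction), `ancestor_descendant` (a directed path
#' of length exactly 2 in either direction), `sibling` (at least one shared
#' parent, not ancestor-related), and `semantic` (everything else, including
#' directed paths spanning more than two levels and unrelated pairs).
#' Path length is the shortest directed path in the parent DAG.
#'
#' @param graph a [concept_graph()].
#' @param gold_id the gold concept id; must be present in `graph`.
#' @param pred_id the predicted concept id; may be absent (`oov`).
#' @return one of `"exact"`, `"parent_child"`, `"ancestor_descendant"`,
#'   `"sibling"`, `"semantic"`, `"oov"`.
#' @export
classify_relation <- function(graph, gold_id, pred_id) {
  stopifnot(inherits(graph, "concept_graph"))
  id <- graph$concepts$id
  if (!gold_id %in% id) {
    stop_("classify_relation(): gold id not in graph: ", gold_id)
  }
  if (!pred_id %in% id) return("oov")
  if (identical(gold_id, pred_id)) return("exact")
  up <- ancestor_depths(graph, gold_id)    # pred above gold?
  dn <- ancestor_depths(graph, pred_id)    # gold above pred?
  d <- min(up[pred_id], dn[gold_id], Inf, na.rm = TRUE)
  if (d == 1) return("parent_child")
  if (d == 2) return("ancestor_descendant")
  if (is.finite(d)) return("semantic")
  pg <- graph$concepts$parents[[match(gold_id, id)]]
  pp <- graph$concepts$parents[[match(pred_id, id)]]
  if (length(intersect(pg, pp))) return("sibling")
  "semantic"
}
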