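#' Define an encoder backend
#'
#' The pluggable contract behind candidate generation: a backend maps a list
#' of strings to a matrix of fixed-dimension, unit-L2-norm row vectors, and
#' must be deterministic (the same inputs always give the same matrix).
#' The shipped [char_ngram_backend()] satisfies the contract without any
#' model download; externally trained sentence encoders (domain-adapted
#' transformer models and the like) plug in through the same constructor —
#' the retrieval, ensembling, and evaluation layers never look past it.
#'
#' @param name short backend identifier; indexes record it so mismatched
#'   backend/index pairs are rejected at retrieval time.
#' @param dimension positive integer embedding dimension.
#' @param encode function: character vector -> numeric matrix (dense or
#'   `Matrix` sparse) with one row per string, `dimension` columns, rows of
#'   L2 norm 1 (all-zero rows are tolerated for strings the backend cannot
#'   represent; they score 0 against everything).
#' @param config optional list of backend settings kept for provenance.
#' @return an object of class `encoder_backend`.
#' @export
encoder_backend <- function(name, dimension, encode, config = list()) {
  stopifnot(is.character(name), nzchar(name),
            is.numeric(dimension), dimension >= 1,
            is.function(encode))
  structure(
    list(name = name, dimension = as.integer(dimension),
         encode = encode, config = config),
    class = "encoder_backend"
  )
}

#' @export
print.encoder_backend <- function(x, ...) {
  cat(sprintf("encoder_backend '%s' (dimension %d)\n", x$name, x$dimension))
  invisible(x)
}

#' Character n-gram TF-IDF encoder backend
#'
#' A deterministic, training-free encoder: TF-IDF over character n-grams,
#' fitted on the vocabulary names, with L2-normalized vectors. Strings are
#' case-folded and whitespace-collapsed before encoding. Different n-gram
#' ranges give usefully different rankers, so two instances (say trigram and
#' 4-gram) can serve as ensemble members.
#'
#' @param vocabulary non-empty character vector of concept names to fit on.
#' @param ngram integer length-2 n-gram range; default character trigrams.
#' @return an [encoder_backend()] named `"char-ngram-<lo>-<hi>"`.
#' @export
char_ngram_backend <- function(vocabulary, ngram = c(3L, 3L)) {
  if (length(vocabulary) == 0 || all(!nzchar(vocabulary))) {
    stop_("char_ngram_backend(): vocabulary must be non-empty")
  }
  idx <- fit_tfidf(vocabulary, ngram)
  encoder_backend(
    name = sprintf("char-ngram-%d-%d", idx$ngram[1], idx$ngram[2]),
    dimension = length(idx$vocab),
    encode = function(strings) tfidf_transform(idx, strings),
    config = list(ngram = idx$ngram, n_fit = idx$n_docs)
  )
}

#' Build an embedding index over a concept graph
#'
#' Encodes every concept name — the label and each synonym — so retrieval
#' can max-pool over a concept's names. The entry count is therefore
#' `sum(1 + n_synonyms)` over concepts.
#'
#' @param graph a non-empty [concept_graph()].
#' @param backend an [encoder_backend()].
#' @return an object of class `embedding_index` with fields `entries`
#'   (data.frame `concept_id`, `name`), `vectors` (one row per entry),
#'   `backend_name`, `dimension`.
#' @export
build_index <- function(graph, backend) {
  stopifnot(inherits(graph, "concept_graph"),
            inherits(backend, "encoder_backend"))
  if (nrow(graph$concepts) == 0) stop_("build_index(): empty graph")
  nm <- concept_names(graph)
  vec <- backend$encode(nm$name)
  if (nrow(vec) != nrow(nm) || ncol(vec) != backend$dimension) {
    stop_("build_index(): backend returned a ", nrow(vec), "x", ncol(vec),
          " matrix; expected ", nrow(nm), "x", backend$dimension)
  }
  nrm <- sqrt(Matrix::rowSums(vec^2))
  bad <- abs(nrm - 1) > 1e-6 & nrm > 0
  if (any(bad)) {
    stop_("build_index(): backend violated the unit-norm contract for ",
          sum(bad), " entr", if (sum(bad) == 1) "y" else "ies")
  }
  structure(
    list(entries = nm[, c("concept_id", "name")], vectors = vec,
         backend_name = backend$name, dimension = ncol(vec)),
    class = "embedding_index"
  )
}

#' @export
print.embedding_index <- function(x, ...) {
  cat(sprintf(
    "embedding_index: %d name entries over %d concepts (backend '%s', dim %d)\n",
    nrow(x$entries), length(unique(x$entries$concept_id)),
    x$backend_name, x$dimension
  ))
  invisible(x)
}

#' Retrieve top-K candidate concepts for a mention
#'
#' Cosine nearest-neighbor search over the embedding index. A concept's
#' score is the maximum cosine over its name entries (label and synonyms),
#' so adding a synonym can only raise a concept's score. Retrieval is exact:
#' the result equals a brute-force scan over all entries. Ties are broken by
#' concept id ascending.
#'
#' @param mention mention string.
#' @param index an [build_index()] result.
#' @param backend the [encoder_backend()] the index was built with.
#' @param k number of candidates to return (lists shorter than `k` when the
#'   graph has fewer concepts). Default 10, the usual reporting depth.
#' @return object of class `candidate_list`: `mention`, `backend_name`, and
#'   `candidates` (data.frame `concept_id`, `score`, `rank` with scores
#'   non-increasing and ranks consecutive from 1).
#' @export
retrieve <- function(mention, index, backend, k = 10L) {
  stopifnot(inherits(index, "embedding_index"),
            inherits(backend, "encoder_backend"))
  if (!identical(backend$name, index$backend_name)) {
    stop_("retrieve(): index was built with backend '", index$backend_name,
          "', not '", backend$name, "'")
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop_("retrieve(): k must be a positive integer")
  }
  v <- backend$encode(mention)
  sims <- as.numeric(index$vectors %*% Matrix::t(v))
  by_concept <- vapply(split(sims, index$entries$concept_id), max, 0)
  ids <- names(by_concept)
  ord <- order(-by_concept, ids)
  top <- utils::head(ord, k)
  structure(
    list(
      mention = mention,
      backend_name = backend$name,
      candidates = data.frame(
        concept_id = ids[top],
        score = unname(by_concept[top]),
        rank = seq_along(top),
        stringsAsFactors = FALSE
      )
    ),
    class = "candidate_list"
  )
}

#' @export
print.candidate_list <- function(x, ...) {
  cat(sprintf("candidate_list for %s (backend '%s')\n",
              dQuote(x$mention), x$backend_name))
  print(utils::head(x$candidates, 5), row.names = FALSE)
  if (nrow(x$candidates) > 5) cat("  ...\n")
  invisible(x)
}

#' Persist an embedding index as a directory
#'
#' Writes `entries.tsv` (`concept_id`, `name`), `matrix.mtx` (MatrixMarket
#' text format), and `manifest.json` (backend name, dimension, entry count).
#'
#' @param index an `embedding_index`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_index <- function(index, dir) {
  stopifnot(inherits(index, "embedding_index"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(index$entries, file.path(dir, "entries.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  Matrix::writeMM(methods::as(index$vectors, "CsparseMatrix"),
                  file.path(dir, "matrix.mtx"))
  jsonlite::write_json(
    list(backend_name = index$backend_name, dimension = index$dimension,
         n_entries = nrow(index$entries)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE
  )
  invisible(dir)
}

#' Load an embedding index written by [save_index()]
#' @param dir index directory.
#' @return an `embedding_index`.
#' @export
load_index <- function(dir) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  entries <- utils::read.delim(file.path(dir, "entries.tsv"), sep = "\t",
                               quote = "", stringsAsFactors = FALSE,
                               colClasses = "character",
                               fileEncoding = "UTF-8")
  vec <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")),
                     "CsparseMatrix")
  structure(
    list(entries = entries, vectors = vec,
         backend_name = man$backend_name, dimension = man$dimension),
    class = "embedding_index"
  )
}
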