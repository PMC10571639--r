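#' Read an interventions table
#'
#' CSV with columns `id`, `nct_id`, `intervention_type`, `name` (UTF-8,
#' header required) — the layout of a trial registry's interventions table.
#'
#' @param path CSV path.
#' @return data.frame of intervention records.
#' @export
read_interventions <- function(path) {
  if (!file.exists(path)) stop_("read_interventions(): no such file: ", path)
  tab <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_("read_interventions(): cannot parse '", path,
                              "': ", conditionMessage(e))
  )
  need <- c("id", "nct_id", "intervention_type", "name")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_("read_interventions(): '", path, "' missing column(s): ",
          paste(miss, collapse = ", "))
  }
  tab$name <- as.character(tab$name)
  tab
}

#' Write an interventions table
#' @param records data.frame of intervention records.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_interventions <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Select intervention records containing a vocabulary name
#'
#' In-memory equivalent of the registry query that keeps rows typed
#' `'Biological'` whose lower-cased name contains a lower-cased vocabulary
#' term as a contiguous substring
#' (`position(lower('<term>') IN lower(name)) > 0`). Matching is raw
#' substring — no token boundaries — to stay faithful to the SQL predicate.
#'
#' @param records data.frame with columns `id`, `nct_id`,
#'   `intervention_type`, `name`.
#' @param graph a non-empty [concept_graph()]; labels and synonyms both
#'   count as vocabulary terms.
#' @return the matching subset of `records` with a list column
#'   `matched_names` holding every vocabulary name found in each row.
#' @export
select_by_vocabulary <- function(records, graph) {
  stopifnot(inherits(graph, "concept_graph"))
  if (nrow(graph$concepts) == 0) stop_("select_by_vocabulary(): empty graph")
  if (nrow(records) == 0) {
    records$matched_names <- list()
    return(records)
  }
  nm <- concept_names(graph)
  pat <- unique(sql_fold(nm$name))
  subject <- sql_fold(records$name)
  bio <- records$intervention_type == "Biological"
  matched <- vector("list", nrow(records))
  for (p in pat) {
    hit <- which(bio & grepl(p, subject, fixed = TRUE))
    for (i in hit) matched[[i]] <- c(matched[[i]], p)
  }
  keep <- lengths(matched) > 0
  out <- records[keep, , drop = FALSE]
  # report the original-cased vocabulary names
  orig <- split(nm$name, sql_fold(nm$name))
  out$matched_names <- lapply(matched[keep], function(ps) {
    unique(unlist(orig[ps], use.names = FALSE))
  })
  rownames(out) <- NULL
  out
}

#' Select intervention records by keyword
#'
#' In-memory equivalent of the registry query keeping `'Biological'` rows
#' whose lower-cased name contains a keyword (`lower(name) LIKE
#' '%vaccine%'`).
#'
#' @inheritParams select_by_vocabulary
#' @param keywords non-empty character vector; default `"vaccine"`.
#' @return the matching subset of `records`.
#' @export
select_by_keyword <- function(records, keywords = "vaccine") {
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    stop_("select_by_keyword(): keywords must be non-empty")
  }
  subject <- sql_fold(records$name)
  hit <- records$intervention_type == "Biological" &
    Reduce(`|`, lapply(sql_fold(keywords), grepl, x = subject, fixed = TRUE))
  out <- records[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve a multi-matched mention to a single vocabulary name
#'
#' When one intervention matches several vocabulary terms, keep the term
#' most similar to the full mention under TF-IDF cosine similarity. Ties are
#' broken by the longer name, then lexicographically.
#'
#' @param mention the intervention name string.
#' @param matched_names non-empty character vector of candidate names.
#' @param index a fitted [fit_tfidf()] index.
#' @return the single winning name.
#' @export
resolve_unique_concept <- function(mention, matched_names, index) {
  if (length(matched_names) == 0) {
    stop_("resolve_unique_concept(): matched_names must be non-empty")
  }
  sims <- vapply(matched_names, tfidf_similarity, 0, a = mention, index = index)
  ord <- order(-sims, -nchar(matched_names), matched_names)
  matched_names[ord[1]]
}

#' Mine the mention corpus from an interventions table
#'
#' Runs the vocabulary query and the keyword query, unions their record
#' sets, and deduplicates on the normalized name (case-folded,
#' whitespace-collapsed), producing the unique mention corpus plus a
#' PRISMA-style stage-count report. The result is independent of input row
#' order: the union is sorted by normalized mention before deduplication.
#'
#' @inheritParams select_by_vocabulary
#' @param keywords keyword list for the second query.
#' @return list with `mentions` (data.frame `mention_id`, `nct_id`,
#'   `mention`) and `report` (an `extraction_report`).
#' @export
build_corpus <- function(records, graph, keywords = "vaccine") {
  q1 <- select_by_vocabulary(records, graph)
  q2 <- select_by_keyword(records, keywords)
  union_ids <- union(q1$id, q2$id)
  urec <- records[records$id %in% union_ids, , drop = FALSE]
  key <- norm_key(urec$name)
  ord <- order(key, urec$nct_id, urec$id)
  urec <- urec[ord, , drop = FALSE]
  key <- key[ord]
  uniq <- urec[!duplicated(key), , drop = FALSE]
  mentions <- data.frame(
    mention_id = sprintf("m%05d", seq_len(nrow(uniq))),
    nct_id = uniq$nct_id,
    mention = uniq$name,
    stringsAsFactors = FALSE
  )
  report <- structure(
    list(
      n_total = nrow(records),
      n_biological = sum(records$intervention_type == "Biological"),
      n_query1 = nrow(q1),
      n_query2 = nrow(q2),
      n_union = length(union_ids),
      n_unique = nrow(uniq)
    ),
    class = "extraction_report"
  )
  stopifnot(
    report$n_unique <= report$n_union,
    report$n_union <= report$n_query1 + report$n_query2,
    report$n_query1 <= report$n_biological,
    report$n_query2 <= report$n_biological,
    report$n_biological <= report$n_total
  )
  list(mentions = mentions, report = report)
}

#' @export
print.extraction_report <- function(x, ...) {
  cat("Extraction screening counts\n")
  cat(sprintf("  interventions rows:        %d\n", x$n_total))
  cat(sprintf("  typed 'Biological':        %d\n", x$n_biological))
  cat(sprintf("  vocabulary query matches:  %d\n", x$n_query1))
  cat(sprintf("  keyword query matches:     %d\n", x$n_query2))
  cat(sprintf("  union of both queries:     %d\n", x$n_union))
  cat(sprintf("  unique mention strings:    %d\n", x$n_unique))
  invisible(x)
}

#' Render the two extraction queries as SQL text
#'
#' For users running against a live registry database: renders the
#' vocabulary-substring query and the keyword query with every vocabulary
#' name interpolated (single quotes escaped by doubling).
#'
#' @param graph a [concept_graph()] supplying vocabulary names.
#' @param keywords keyword list for the second query.
#' @return named list of two SQL strings: `vocabulary_query`,
#'   `keyword_query`.
#' @export
emit_sql <- function(graph, keywords = "vaccine") {
  stopifnot(inherits(graph, "concept_graph"))
  esc <- function(x) gsub("'", "''", x, fixed = TRUE)
  base <- paste0("SELECT DISTINCT id, nct_id, name FROM ctgov.interventions ",
                 "WHERE intervention_type='Biological' AND (")
  nms <- concept_names(graph)$name
  if (length(nms) == 0) {
    warning("emit_sql(): empty vocabulary; query 1 has no label clauses")
    clauses1 <- "FALSE"
  } else {
    clauses1 <- paste0("position(lower('", esc(nms),
                       "') IN lower(name)) > 0", collapse = " OR ")
  }
  clauses2 <- paste0("lower(name) LIKE '%", esc(sql_fold(keywords)), "%'",
                     collapse = " OR ")
  list(
    vocabulary_query = paste0(base, clauses1, ")"),
    keyword_query = paste0(base, clauses2, ")")
  )
}

#' Write a mention corpus as TSV
#' @param mentions data.frame with columns `mention_id`, `nct_id` (optional),
#'   `mention`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_mentions_tsv <- function(mentions, path) {
  utils::write.table(mentions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write an extraction report as JSON
#' @param report an `extraction_report` from [build_corpus()].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_extraction_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE)
  invisible(path)
}
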