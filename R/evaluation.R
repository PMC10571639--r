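#' Construct a gold standard
#'
#' Maps each mention to one or more gold concept ids (a mention naming two
#' products maps to both concepts). Gold ids are normally required to exist
#' in the reference graph; ids deliberately outside the vocabulary (the OOV
#' fraction of a synthetic corpus) are permitted and scored as
#' out-of-vocabulary misses.
#'
#' @param mention_id character vector of mention ids.
#' @param mention mention strings.
#' @param gold_ids list of character vectors (or pipe-separated strings),
#'   each non-empty.
#' @return data.frame of class `gold_standard` with a `gold_ids` list
#'   column.
#' @export
gold_standard <- function(mention_id, mention, gold_ids) {
  gold_ids <- as_pipe_list(gold_ids)
  if (any(lengths(gold_ids) == 0)) {
    stop_("gold_standard(): every mention needs at least one gold id")
  }
  if (anyDuplicated(mention_id)) {
    stop_("gold_standard(): duplicate mention_id")
  }
  out <- data.frame(mention_id = as.character(mention_id),
                    mention = as.character(mention),
                    stringsAsFactors = FALSE)
  out$gold_ids <- gold_ids
  class(out) <- c("gold_standard", "data.frame")
  out
}

gold_lookup <- function(gold) {
  stats::setNames(gold$gold_ids, gold$mention_id)
}

#' Read a gold-standard TSV
#'
#' Columns `mention_id`, `mention`, `gold_ids` (pipe-separated).
#'
#' @param path TSV path.
#' @return a [gold_standard()].
#' @export
read_gold_tsv <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", quote = "",
                           stringsAsFactors = FALSE,
                           colClasses = "character", fileEncoding = "UTF-8")
  need <- c("mention_id", "mention", "gold_ids")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop_("read_gold_tsv(): '", path, "' missing column(s): ",
          paste(miss, collapse = ", "))
  }
  gold_standard(tab$mention_id, tab$mention, tab$gold_ids)
}

#' Write a gold standard as TSV
#' @param gold a [gold_standard()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_gold_tsv <- function(gold, path) {
  out <- data.frame(
    mention_id = gold$mention_id, mention = gold$mention,
    gold_ids = vapply(gold$gold_ids, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Top-n accuracy
#'
#' Fraction of mentions for which at least one gold id appears among the
#' top `min(n, list length)` candidates. Multi-valued gold uses any-match.
#'
#' @param predictions list of `ranked_prediction` objects with `mention_id`
#'   set; every mention id must be present in `gold`.
#' @param gold a [gold_standard()].
#' @param n positive integer rank cutoff.
#' @return accuracy in `[0, 1]`.
#' @export
topn_accuracy <- function(predictions, gold, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop_("topn_accuracy(): n must be a positive integer")
  }
  if (length(predictions) == 0) return(NaN)
  gl <- gold_lookup(gold)
  hits <- vapply(predictions, function(p) {
    mid <- p$mention_id
    if (is.null(mid) || !mid %in% names(gl)) {
      stop_("topn_accuracy(): mention id ", mid %||% "<NULL>",
            " absent from the gold standard")
    }
    any(utils::head(p$candidates$concept_id, n) %in% gl[[mid]])
  }, NA)
  mean(hits)
}

ERROR_TYPES <- c(
  "oov", "ner_multi_concept", "disambiguation",
  "hierarchy_parent_child", "hierarchy_ancestor_descendant",
  "hierarchy_sibling", "semantic",
  "abbreviation", "spelling", "stemming", "ner_noise"
)

RELATION_PRIORITY <- c("exact", "parent_child", "ancestor_descendant",
                       "sibling", "semantic", "oov")

#' Classify a rank-1 normalization error
#'
#' For a mention whose top-ranked prediction is wrong, assigns one error
#' type from the taxonomy: out-of-vocabulary, NER (multi-concept or noisy
#' mention), disambiguation (the gold concept was suggested but outranked),
#' the hierarchy relations (parent-child, ancestor-descendant, sibling),
#' semantic (gold and prediction more than two levels apart or unrelated),
#' and the linguistic causes abbreviation, spelling, and stemming.
#'
#' The relation label is computed with [classify_relation()] between the top
#' prediction and the nearest gold id (best relation under the priority
#' exact > parent_child > ancestor_descendant > sibling > semantic). Types
#' are assigned by a fixed priority: `oov` (no gold id in the vocabulary, or
#' the prediction itself is out of vocabulary) > `ner_multi_concept` >
#' `disambiguation` > `hierarchy_*` > `semantic`/linguistic. A `semantic`
#' relation falls through to the linguistic heuristics (abbreviation >
#' spelling > stemming > ner_noise) and is labelled `semantic` only when
#' none fires, so purely lexical failures are not masked by the catch-all.
#'
#' Default heuristics, each overridable through `hooks`:
#' * `abbreviation` — the mention contains an all-caps token of length 2-6
#'   equal to the initials of a gold label;
#' * `spelling` — some mention token is at edit distance 1-2 from a
#'   gold-label token of length >= 4;
#' * `stemming` — a mention token and a gold-label token share a >= 4-char
#'   prefix but differ in suffix;
#' * `ner_noise` — the mention carries dose/units/lot patterns.
#'
#' @param graph the reference [concept_graph()].
#' @param gold_ids character vector of gold concept ids for the mention.
#' @param pred the `ranked_prediction` (wrong at rank 1).
#' @param hooks optional named list overriding heuristics: functions
#'   `f(mention, gold_labels) -> logical` under names `abbreviation`,
#'   `spelling`, `stemming`, `ner_noise`, and/or `override(mention,
#'   gold_ids, pred_id)` returning an error type or `NULL`.
#' @return list of class `error_record`: `mention_id`, `gold_ids`,
#'   `predicted_id`, `relation`, `error_type`, `rank_of_gold` (smallest rank
#'   of any gold id, or `NA`).
#' @export
classify_error <- function(graph, gold_ids, pred, hooks = NULL) {
  stopifnot(inherits(graph, "concept_graph"),
            inherits(pred, "ranked_prediction"),
            length(gold_ids) >= 1)
  top_id <- pred$candidates$concept_id[1]
  if (top_id %in% gold_ids) {
    stop_("classify_error(): prediction is correct at rank 1")
  }
  ids <- graph$concepts$id
  in_graph <- gold_ids[gold_ids %in% ids]

  relation <- if (length(in_graph) == 0) {
    "oov"
  } else {
    rels <- vapply(in_graph, function(g) classify_relation(graph, g, top_id),
                   "")
    RELATION_PRIORITY[min(match(rels, RELATION_PRIORITY))]
  }
  pos <- match(gold_ids, pred$candidates$concept_id)
  rank_of_gold <- if (all(is.na(pos))) NA_integer_ else as.integer(min(pos, na.rm = TRUE))

  manual <- if (!is.null(hooks$override)) {
    hooks$override(pred$mention, gold_ids, top_id)
  }
  error_type <- if (!is.null(manual)) {
    match.arg(manual, ERROR_TYPES)
  } else if (length(in_graph) == 0 || relation == "oov") {
    "oov"
  } else if (length(gold_ids) >= 2) {
    "ner_multi_concept"
  } else if (!is.na(rank_of_gold) && rank_of_gold >= 2) {
    "disambiguation"
  } else if (relation %in% c("parent_child", "ancestor_descendant", "sibling")) {
    paste0("hierarchy_", relation)
  } else {
    gold_labels <- graph$concepts$label[match(in_graph, ids)]
    h <- function(nm, default) (hooks[[nm]] %||% default)(pred$mention, gold_labels)
    if (h("abbreviation", heur_abbreviation)) "abbreviation"
    else if (h("spelling", heur_spelling)) "spelling"
    else if (h("stemming", heur_stemming)) "stemming"
    else if (h("ner_noise", heur_ner_noise)) "ner_noise"
    else "semantic"
  }
  structure(
    list(mention_id = pred$mention_id, gold_ids = gold_ids,
         predicted_id = top_id, relation = relation,
         error_type = error_type, rank_of_gold = rank_of_gold),
    class = "error_record"
  )
}

heur_abbreviation <- function(mention, gold_labels) {
  toks <- strsplit(gsub("[^[:alnum:]]+", " ", mention), " ")[[1]]
  caps <- toks[grepl("^[A-Z]{2,6}$", toks)]
  if (!length(caps)) return(FALSE)
  initials <- vapply(gold_labels, function(l) {
    paste(toupper(substr(word_tokens(l), 1, 1)), collapse = "")
  }, "")
  any(caps %in% initials)
}

heur_spelling <- function(mention, gold_labels) {
  mt <- word_tokens(tolower(mention))
  gt <- unlist(lapply(tolower(gold_labels), word_tokens), use.names = FALSE)
  gt <- gt[nchar(gt) >= 4]
  if (!length(mt) || !length(gt)) return(FALSE)
  d <- utils::adist(mt, gt)
  any(d >= 1 & d <= 2)
}

heur_stemming <- function(mention, gold_labels) {
  mt <- unique(word_tokens(tolower(mention)))
  gt <- unique(unlist(lapply(tolower(gold_labels), word_tokens),
                      use.names = FALSE))
  for (a in mt[nchar(mt) >= 4]) {
    for (b in gt[nchar(gt) >= 4]) {
      if (a != b && substr(a, 1, 4) == substr(b, 1, 4)) return(TRUE)
    }
  }
  FALSE
}

heur_ner_noise <- function(mention, gold_labels) {
  grepl("\\b[0-9]+(\\.[0-9]+)?\\s*(ml|mcg|mg|ug|iu|%)|\\blot\\b|\\bdoses?\\b",
        tolower(mention))
}

#' Evaluate ranked predictions against a gold standard
#'
#' Computes the Top-n accuracy vector for n = 1..`max_n` and classifies
#' every rank-1 miss with [classify_error()].
#'
#' @inheritParams topn_accuracy
#' @param graph the reference [concept_graph()].
#' @param max_n deepest rank cutoff; default 10.
#' @param hooks passed to [classify_error()].
#' @return object of class `eval_report`: `n_mentions`, `acc` (named vector
#'   `acc@1`..`acc@max_n`, non-decreasing), `error_histogram`, `records`.
#' @export
evaluate_predictions <- function(predictions, gold, graph, max_n = 10L,
                                 hooks = NULL) {
  acc <- vapply(seq_len(max_n), topn_accuracy, 0,
                predictions = predictions, gold = gold)
  names(acc) <- paste0("acc@", seq_len(max_n))
  stopifnot(!is.unsorted(acc))
  gl <- gold_lookup(gold)
  misses <- Filter(
    function(p) !p$candidates$concept_id[1] %in% gl[[p$mention_id]],
    predictions
  )
  records <- lapply(misses, function(p) {
    classify_error(graph, gl[[p$mention_id]], p, hooks = hooks)
  })
  hist <- table(factor(vapply(records, `[[`, "", "error_type"),
                       levels = ERROR_TYPES))
  structure(
    list(n_mentions = length(predictions), acc = acc,
         error_histogram = hist, records = records),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Normalization evaluation over %d mentions\n", x$n_mentions))
  grid <- sprintf("%.1f", 100 * x$acc)
  names(grid) <- sub("acc@", "Acc@", names(x$acc))
  print(noquote(grid))
  nz <- x$error_histogram[x$error_histogram > 0]
  if (length(nz)) {
    cat("Rank-1 error types:\n")
    for (t in names(nz)) cat(sprintf("  %-28s %d\n", t, nz[[t]]))
  } else {
    cat("No rank-1 errors.\n")
  }
  invisible(x)
}

#' Write an evaluation report as JSON (plus optional plain-text grid)
#'
#' @param report an `eval_report`.
#' @param path JSON path.
#' @param grid_path optional path for a plain-text Acc@1..N grid.
#' @return `path`, invisibly.
#' @export
write_eval_report <- function(report, path, grid_path = NULL) {
  recs <- lapply(report$records, function(r) {
    list(mention_id = r$mention_id,
         gold_ids = paste(r$gold_ids, collapse = "|"),
         predicted_id = r$predicted_id, relation = r$relation,
         error_type = r$error_type,
         rank_of_gold = if (is.na(r$rank_of_gold)) NULL else r$rank_of_gold)
  })
  jsonlite::write_json(
    list(n_mentions = report$n_mentions,
         acc = as.list(report$acc),
         error_histogram = as.list(stats::setNames(
           as.integer(report$error_histogram),
           names(report$error_histogram))),
         records = recs),
    path, auto_unbox = TRUE, digits = 12, null = "null"
  )
  if (!is.null(grid_path)) {
    writeLines(c(
      paste(names(report$acc), collapse = "\t"),
      paste(sprintf("%.4f", report$acc), collapse = "\t")
    ), grid_path)
  }
  invisible(path)
}
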