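#' Ensemble fusion configuration
#'
#' Controls how several models' candidate lists are fused. Three metrics are
#' supported, all combined as a weighted sum over models:
#' \describe{
#'   \item{`score`}{raw cosine similarity; 0 for concepts absent from a
#'     model's top-K list.}
#'   \item{`scale`}{cosine min-max rescaled to `[0, 1]` within each model's
#'     top-K list for the mention (0 if absent; if a list is degenerate with
#'     max == min, every present candidate gets 1).}
#'   \item{`rank`}{Borda points `K - rank + 1` (0 if absent).}
#' }
#'
#' @param metric `"score"`, `"scale"`, or `"rank"`.
#' @param weights named non-negative numeric vector of per-model weights, at
#'   least one positive; `NULL` means equal weights over whatever models are
#'   fused. See [fit_ensemble_weights()] for accuracy-proportional weights.
#' @param k fusion depth: each model's list is truncated to its top `k`
#'   candidates before fusing. Default 10.
#' @param sm_rule logical; apply the string-matching promotion rule after
#'   fusion (see [apply_sm_rule()]).
#' @return an object of class `ensemble_config`.
#' @export
ensemble_config <- function(metric = c("scale", "score", "rank"),
                            weights = NULL, k = 10L, sm_rule = TRUE) {
  metric <- match.arg(metric)
  if (!is.null(weights)) {
    if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
      stop_("ensemble_config(): weights must be a named vector")
    }
    if (any(weights < 0)) stop_("ensemble_config(): weights must be >= 0")
    if (!any(weights > 0)) {
      stop_("ensemble_config(): at least one weight must be positive")
    }
  }
  if (!is.numeric(k) || length(k) != 1 || k < 1) {
    stop_("ensemble_config(): k must be a positive integer")
  }
  structure(
    list(metric = metric, weights = weights, k = as.integer(k),
         sm_rule = isTRUE(sm_rule)),
    class = "ensemble_config"
  )
}

new_ranked_prediction <- function(mention, candidates, mention_id = NULL,
                                  sm_promoted = NULL) {
  structure(
    list(mention = mention, mention_id = mention_id,
         candidates = candidates, sm_promoted = sm_promoted),
    class = "ranked_prediction"
  )
}

#' @export
print.ranked_prediction <- function(x, ...) {
  cat(sprintf("ranked_prediction for %s\n", dQuote(x$mention)))
  if (!is.null(x$sm_promoted)) {
    cat(sprintf("  SM-rule promoted %s (matched name %s)\n",
                x$sm_promoted$concept_id, dQuote(x$sm_promoted$name)))
  }
  print(utils::head(x$candidates, 5), row.names = FALSE)
  if (nrow(x$candidates) > 5) cat("  ...\n")
  invisible(x)
}

#' Fuse several models' candidate lists for one mention
#'
#' Per-concept fused score is the weighted sum of per-model contributions
#' under the configured metric (see [ensemble_config()]). Candidates are
#' ordered by fused score descending, ties broken by concept id ascending.
#' The result is invariant to the iteration order of the model list.
#'
#' @param lists named list of `candidate_list` objects (one per model), all
#'   for the same mention.
#' @param config an [ensemble_config()]. Models named in
#'   `config$weights` must all be present in `lists`; models present in
#'   `lists` but absent from an explicit weight vector get weight 0.
#' @return a `ranked_prediction`.
#' @export
fuse <- function(lists, config) {
  stopifnot(inherits(config, "ensemble_config"), length(lists) >= 1)
  if (is.null(names(lists)) || any(!nzchar(names(lists)))) {
    stop_("fuse(): lists must be a named list of candidate_list objects")
  }
  mentions <- unique(vapply(lists, `[[`, "", "mention"))
  if (length(mentions) != 1) {
    stop_("fuse(): candidate lists refer to different mentions: ",
          paste(dQuote(mentions), collapse = ", "))
  }
  w <- config$weights %||%
    stats::setNames(rep(1, length(lists)), names(lists))
  missing_models <- setdiff(names(w)[w > 0], names(lists))
  if (length(missing_models)) {
    stop_("fuse(): weighted model(s) missing from lists: ",
          paste(missing_models, collapse = ", "))
  }
  if (!any(w[names(w) %in% names(lists)] > 0)) {
    stop_("fuse(): all weights are zero for the supplied models")
  }
  k <- config$k
  active <- intersect(names(w)[w > 0], names(lists))
  total <- numeric(0)
  for (m in sort(active)) {
    cand <- utils::head(lists[[m]]$candidates, k)
    s <- switch(config$metric,
      score = cand$score,
      scale = {
        rng <- range(cand$score)
        if (diff(rng) == 0) rep(1, nrow(cand))
        else (cand$score - rng[1]) / diff(rng)
      },
      rank = k - cand$rank + 1
    )
    contrib <- w[[m]] * s
    hit <- match(cand$concept_id, names(total))
    new <- is.na(hit)
    total[hit[!new]] <- total[hit[!new]] + contrib[!new]
    total <- c(total, stats::setNames(contrib[new], cand$concept_id[new]))
  }
  ord <- order(-total, names(total))
  new_ranked_prediction(
    mention = mentions,
    candidates = data.frame(
      concept_id = names(total)[ord],
      score = unname(total[ord]),
      rank = seq_along(ord),
      stringsAsFactors = FALSE
    )
  )
}

#' String-matching promotion rule
#'
#' Scans the mention for vocabulary names (labels and synonyms, case-folded
#' with trademark glyphs stripped and whitespace collapsed) occurring as
#' contiguous substrings. If any name matches, the longest matched name wins
#' (ties: lexicographically smallest name, then smallest concept id) and its
#' concept is promoted to rank 1, preserving the relative order of all other
#' candidates; a concept not already in the list is inserted at rank 1 with
#' an `NA` score (the rule reorders, it does not rescore). With no match the
#' prediction is returned unchanged. Idempotent.
#'
#' @param pred a `ranked_prediction` (carries its mention text).
#' @param graph a non-empty [concept_graph()].
#' @return the updated `ranked_prediction`; `sm_promoted` records the
#'   promoted concept and the matched name.
#' @export
apply_sm_rule <- function(pred, graph) {
  stopifnot(inherits(pred, "ranked_prediction"),
            inherits(graph, "concept_graph"))
  if (nrow(graph$concepts) == 0) stop_("apply_sm_rule(): empty graph")
  nm <- concept_names(graph)
  subject <- norm_key(pred$mention)
  folded <- norm_key(nm$name)
  hit <- which(vapply(folded, grepl, NA, x = subject, fixed = TRUE,
                      USE.NAMES = FALSE))
  if (!length(hit)) return(pred)
  ord <- order(-nchar(nm$name[hit]), nm$name[hit], nm$concept_id[hit])
  best <- hit[ord[1]]
  cid <- nm$concept_id[best]
  cand <- pred$candidates
  at <- match(cid, cand$concept_id)
  if (is.na(at)) {
    cand <- rbind(
      data.frame(concept_id = cid, score = NA_real_, rank = 0L,
                 stringsAsFactors = FALSE),
      cand
    )
  } else {
    cand <- cand[c(at, setdiff(seq_len(nrow(cand)), at)), , drop = FALSE]
  }
  cand$rank <- seq_len(nrow(cand))
  rownames(cand) <- NULL
  new_ranked_prediction(
    mention = pred$mention, candidates = cand, mention_id = pred$mention_id,
    sm_promoted = list(concept_id = cid, name = nm$name[best])
  )
}

#' Normalize a mention corpus end to end
#'
#' Pipeline driver: for each mention, retrieve top-K candidates from every
#' model, fuse them under the configuration, and optionally apply the
#' string-matching rule. Deterministic; output order follows input order.
#'
#' @param mentions either a character vector of mention strings or a
#'   data.frame with columns `mention_id` and `mention`.
#' @param indexes named list of [build_index()] results, one per model.
#' @param backends named list of [encoder_backend()]s, names matching
#'   `indexes`.
#' @param config an [ensemble_config()].
#' @param graph [concept_graph()]; required when `config$sm_rule` is TRUE.
#' @return list of `ranked_prediction` objects, one per mention.
#' @export
normalize_corpus <- function(mentions, indexes, backends, config,
                             graph = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  if (!identical(sort(names(indexes)), sort(names(backends)))) {
    stop_("normalize_corpus(): indexes and backends must share model names")
  }
  if (config$sm_rule && is.null(graph)) {
    stop_("normalize_corpus(): graph is required when sm_rule is enabled")
  }
  if (is.data.frame(mentions)) {
    ids <- mentions$mention_id
    txt <- mentions$mention
  } else {
    txt <- as.character(mentions)
    ids <- if (length(txt)) sprintf("m%05d", seq_along(txt)) else character(0)
  }
  models <- names(indexes)
  lapply(seq_along(txt), function(i) {
    lists <- stats::setNames(lapply(models, function(m) {
      retrieve(txt[i], indexes[[m]], backends[[m]], k = config$k)
    }), models)
    pred <- fuse(lists, config)
    if (config$sm_rule) pred <- apply_sm_rule(pred, graph)
    pred$mention_id <- ids[i]
    pred
  })
}

#' Accuracy-proportional ensemble weights
#'
#' Default weighting scheme: each model's weight is proportional to its
#' Top-1 accuracy on a validation split, restricted to the best `top_m`
#' models (others get weight 0) so that stronger rankers carry more
#' importance.
#'
#' @param model_predictions named list; one element per model, each a list
#'   of `candidate_list` objects aligned with `mention_ids`.
#' @param mention_ids character vector of mention ids aligned with every
#'   model's prediction list.
#' @param gold a gold standard (see [read_gold_tsv()]).
#' @param top_m how many models keep a non-zero weight. Default 3.
#' @return named numeric weight vector summing to 1 (equal weights with a
#'   warning if every model scores 0).
#' @export
fit_ensemble_weights <- function(model_predictions, mention_ids, gold,
                                 top_m = 3L) {
  stopifnot(length(model_predictions) >= 1, !is.null(names(model_predictions)))
  gl <- gold_lookup(gold)
  acc1 <- vapply(model_predictions, function(preds) {
    stopifnot(length(preds) == length(mention_ids))
    hits <- vapply(seq_along(preds), function(i) {
      top <- preds[[i]]$candidates$concept_id[1]
      top %in% gl[[mention_ids[i]]]
    }, NA)
    mean(hits)
  }, 0)
  keep <- names(sort(acc1, decreasing = TRUE))[
    seq_len(min(top_m, length(acc1)))]
  w <- stats::setNames(numeric(length(acc1)), names(acc1))
  w[keep] <- acc1[keep]
  if (sum(w) == 0) {
    warning("fit_ensemble_weights(): all models scored 0; using equal weights")
    w[] <- 1
  }
  w / sum(w)
}

#' Write ranked predictions as JSON Lines
#'
#' One object per mention: `mention_id`, `mention`, `candidates` (array of
#' `{concept_id, score, rank}`), `sm_promoted` (object or null).
#'
#' @param predictions list of `ranked_prediction` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_predictions_jsonl <- function(predictions, path) {
  lines <- vapply(predictions, function(p) {
    obj <- list(
      mention_id = p$mention_id %||% NA_character_,
      mention = p$mention,
      candidates = p$candidates,
      sm_promoted = p$sm_promoted
    )
    as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 12,
                                  dataframe = "rows", null = "null",
                                  na = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read predictions written by [write_predictions_jsonl()]
#' @param path JSONL path.
#' @return list of `ranked_prediction` objects.
#' @export
read_predictions_jsonl <- function(path) {
  lapply(readLines(path, encoding = "UTF-8"), function(line) {
    obj <- jsonlite::fromJSON(line, simplifyDataFrame = TRUE)
    new_ranked_prediction(
      mention = obj$mention,
      candidates = as.data.frame(obj$candidates),
      mention_id = obj$mention_id,
      sm_promoted = obj$sm_promoted
    )
  })
}
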