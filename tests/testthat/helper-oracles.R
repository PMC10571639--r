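# Shared fixtures and independent reference implementations ("oracles")
# used to cross-check the package's own code paths.

# Toy 8-node, 3-level DAG used for relation-classification tests.
#   A is root; B, C under A; D, E under B; F, G under C; H under both B and C.
toy_dag <- function() {
  concept_graph(data.frame(
    id = c("T:A", "T:B", "T:C", "T:D", "T:E", "T:F", "T:G", "T:H"),
    label = c("alpha", "beta", "gamma", "delta", "epsilon", "zeta", "eta",
              "theta"),
    parents = I(list(
      character(0), "T:A", "T:A", "T:B", "T:B", "T:C", "T:C",
      c("T:B", "T:C")
    )),
    is_vaccine = TRUE,
    stringsAsFactors = FALSE
  ))
}

# Relation oracle built on igraph shortest paths (the implementation uses
# its own BFS; the two routes must agree).
oracle_relation <- function(graph, gold_id, pred_id) {
  ids <- graph$concepts$id
  if (!pred_id %in% ids) return("oov")
  if (gold_id == pred_id) return("exact")
  edges <- do.call(rbind, lapply(seq_along(ids), function(i) {
    ps <- graph$concepts$parents[[i]]
    if (length(ps)) cbind(ids[i], ps) else NULL
  }))
  ig <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = TRUE, vertices = ids
  )
  d1 <- igraph::distances(ig, v = gold_id, to = pred_id, mode = "out")[1, 1]
  d2 <- igraph::distances(ig, v = pred_id, to = gold_id, mode = "out")[1, 1]
  d <- min(d1, d2)
  if (d == 1) return("parent_child")
  if (d == 2) return("ancestor_descendant")
  if (is.finite(d)) return("semantic")
  pg <- graph$concepts$parents[[match(gold_id, ids)]]
  pp <- graph$concepts$parents[[match(pred_id, ids)]]
  if (length(intersect(pg, pp))) return("sibling")
  "semantic"
}

# Literal reference scans of the two registry WHERE clauses.
oracle_query1 <- function(records, graph) {
  nms <- unique(tolower(concept_names(graph)$name))
  hit <- vapply(seq_len(nrow(records)), function(i) {
    records$intervention_type[i] == "Biological" &&
      any(vapply(nms, function(p) {
        regexpr(p, tolower(records$name[i]), fixed = TRUE) > 0
      }, NA))
  }, NA)
  records$id[hit]
}

oracle_query2 <- function(records, keywords = "vaccine") {
  hit <- vapply(seq_len(nrow(records)), function(i) {
    records$intervention_type[i] == "Biological" &&
      any(vapply(tolower(keywords), function(p) {
        regexpr(p, tolower(records$name[i]), fixed = TRUE) > 0
      }, NA))
  }, NA)
  records$id[hit]
}

# Brute-force dense cosine retrieval over all index entries.
oracle_retrieve <- function(mention, index, backend, k) {
  V <- as.matrix(index$vectors)
  v <- as.numeric(as.matrix(backend$encode(mention)))
  sims <- as.numeric(V %*% v)
  ids <- unique(index$entries$concept_id)
  score <- vapply(ids, function(cid) {
    max(sims[index$entries$concept_id == cid])
  }, 0)
  ord <- order(-score, ids)
  data.frame(
    concept_id = ids[ord][seq_len(min(k, length(ids)))],
    score = unname(score[ord][seq_len(min(k, length(ids)))]),
    stringsAsFactors = FALSE
  )
}

# Brute-force weighted fusion by explicit enumeration over the union of
# candidate ids; loops instead of vectorized bookkeeping.
oracle_fuse <- function(lists, metric, weights, k) {
  ids <- sort(unique(unlist(lapply(lists, function(l) {
    head(l$candidates$concept_id, k)
  }))))
  total <- setNames(numeric(length(ids)), ids)
  for (m in names(lists)) {
    cand <- head(lists[[m]]$candidates, k)
    for (cid in ids) {
      at <- match(cid, cand$concept_id)
      if (is.na(at)) next
      s <- switch(metric,
        score = cand$score[at],
        scale = {
          lo <- min(cand$score); hi <- max(cand$score)
          if (hi == lo) 1 else (cand$score[at] - lo) / (hi - lo)
        },
        rank = k - cand$rank[at] + 1
      )
      total[cid] <- total[cid] + weights[[m]] * s
    }
  }
  ord <- order(-total, ids)
  data.frame(concept_id = ids[ord], score = unname(total[ord]),
             stringsAsFactors = FALSE)
}

# Hand-built candidate list (scores already sorted, ties by id).
mk_candidates <- function(ids, scores, mention = "x", backend = "manual") {
  structure(
    list(mention = mention, backend_name = backend,
         candidates = data.frame(concept_id = ids, score = scores,
                                 rank = seq_along(ids),
                                 stringsAsFactors = FALSE)),
    class = "candidate_list"
  )
}

mk_prediction <- function(ids, scores = rev(seq_along(ids)) / length(ids),
                          mention = "x", mention_id = NULL) {
  structure(
    list(mention = mention, mention_id = mention_id,
         candidates = data.frame(concept_id = ids, score = scores,
                                 rank = seq_along(ids),
                                 stringsAsFactors = FALSE),
         sm_promoted = NULL),
    class = "ranked_prediction"
  )
}

# Predictions with gold placed at known ranks {1, 1, 2, 3, 5, 11, 12, 4,
# 6, 20}; filler candidates pad the lists so deep ranks exist.
ranked_fixture <- function() {
  ranks <- c(1, 1, 2, 3, 5, 11, 12, 4, 6, 20)
  preds <- lapply(seq_along(ranks), function(i) {
    n <- max(ranks[i], 10)
    ids <- sprintf("F:%02d_%02d", i, seq_len(n))
    ids[ranks[i]] <- sprintf("G:%02d", i)
    mk_prediction(ids, mention = sprintf("mention %d", i),
                  mention_id = sprintf("m%02d", i))
  })
  gold <- gold_standard(sprintf("m%02d", seq_along(ranks)),
                        sprintf("mention %d", seq_along(ranks)),
                        as.list(sprintf("G:%02d", seq_along(ranks))))
  list(preds = preds, gold = gold, ranks = ranks)
}

# Local copy of the dedupe key (case fold, strip marks, collapse spaces).
norm_key_test <- function(x) {
  trimws(gsub("[[:space:]]+", " ", tolower(gsub("[®™]", "", x))))
}

# Five-concept vocabulary used across extraction and ensemble tests.
mini_graph <- function() {
  concept_graph(data.frame(
    id = c("VX:1", "VX:2", "VX:3", "VX:4", "VX:5"),
    label = c("vaccine", "conjugate vaccine",
              "meningococcal conjugate vaccine", "AIDSVAX B/E",
              "influenza vaccine"),
    synonyms = I(list(character(0), character(0), "Menveo", character(0),
                      "FluMist ®")),
    parents = I(list(character(0), "VX:1", "VX:2", "VX:1", "VX:1")),
    is_vaccine = TRUE,
    stringsAsFactors = FALSE
  ))
}
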