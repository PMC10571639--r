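test_that("single-model fusion reproduces the model ordering per metric", {
  g <- make_ontology(40, 5, 3, seed = 21)
  b <- char_ngram_backend(concept_names(g)$name)
  idx <- build_index(g, b)
  mm <- make_mentions(g, 15, noise_config(seed = 2))
  for (metric in c("score", "scale", "rank")) {
    cfg <- ensemble_config(metric, k = 10, sm_rule = FALSE)
    for (m in mm$mentions$mention) {
      cl <- retrieve(m, idx, b, 10)
      fused <- fuse(list(solo = cl), cfg)
      expect_equal(fused$candidates$concept_id, cl$candidates$concept_id,
                   info = paste(metric, m))
    }
  }
})

test_that("two-model fusion matches brute-force enumeration", {
  # hand-set scores exercising overlaps, absences, and degenerate lists
  lists <- list(
    m1 = mk_candidates(c("C:1", "C:2", "C:3"), c(0.9, 0.5, 0.1)),
    m2 = mk_candidates(c("C:2", "C:4", "C:1"), c(0.8, 0.7, 0.2))
  )
  w <- c(m1 = 1, m2 = 0.5)
  for (metric in c("score", "scale", "rank")) {
    got <- fuse(lists, ensemble_config(metric, weights = w, k = 3,
                                       sm_rule = FALSE))
    want <- oracle_fuse(lists, metric, w, 3)
    expect_equal(got$candidates$concept_id, want$concept_id, info = metric)
    expect_equal(got$candidates$score, want$score, info = metric)
  }
  # hand computation for the rank metric (Borda, K = 3):
  #   m1 gives C:1=3, C:2=2, C:3=1; m2 gives C:2=3, C:4=2, C:1=1
  #   weighted: C:1 = 3 + 0.5, C:2 = 2 + 1.5, C:3 = 1, C:4 = 1
  got <- fuse(lists, ensemble_config("rank", weights = w, k = 3,
                                     sm_rule = FALSE))
  expect_equal(got$candidates$concept_id, c("C:1", "C:2", "C:3", "C:4"))
  expect_equal(got$candidates$score, c(3.5, 3.5, 1, 1)[c(1, 2, 3, 4)])

  # degenerate max == min list under the scale metric
  flat <- list(m1 = mk_candidates(c("C:1", "C:2"), c(0.4, 0.4)))
  f <- fuse(flat, ensemble_config("scale", weights = c(m1 = 1), k = 5,
                                  sm_rule = FALSE))
  expect_equal(f$candidates$score, c(1, 1))

  # weight (1, 0) equals the single-model case
  w10 <- fuse(lists, ensemble_config("score", weights = c(m1 = 1, m2 = 0),
                                     k = 3, sm_rule = FALSE))
  solo <- fuse(lists["m1"], ensemble_config("score", weights = c(m1 = 1),
                                            k = 3, sm_rule = FALSE))
  expect_equal(w10$candidates, solo$candidates)
})

test_that("fusion validates weights and mention consistency", {
  l1 <- mk_candidates("C:1", 1, mention = "a")
  l2 <- mk_candidates("C:1", 1, mention = "b")
  expect_error(fuse(list(m1 = l1, m2 = l2), ensemble_config("score")),
               "different mentions")
  expect_error(ensemble_config("score", weights = c(m1 = 0, m2 = 0)),
               "positive")
  expect_error(fuse(list(m1 = l1),
                    ensemble_config("score", weights = c(m9 = 1))),
               "missing from lists")
})

test_that("fusion is invariant to model iteration order", {
  set.seed(31)
  for (i in 1:10) {
    ids <- paste0("C:", 1:6)
    l1 <- mk_candidates(ids, sort(runif(6), decreasing = TRUE))
    l2 <- mk_candidates(sample(ids), sort(runif(6), decreasing = TRUE))
    for (metric in c("score", "scale", "rank")) {
      cfg <- ensemble_config(metric, weights = c(a = 0.7, b = 0.3), k = 6,
                             sm_rule = FALSE)
      f1 <- fuse(list(a = l1, b = l2), cfg)
      f2 <- fuse(list(b = l2, a = l1), cfg)
      expect_equal(f1$candidates, f2$candidates)
    }
  }
})

test_that("SM-rule promotes the longest verbatim vocabulary name", {
  g <- mini_graph()
  # placebo mention maps to the vaccine itself
  pred <- mk_prediction(c("VX:5", "VX:1"), c(0.9, 0.2),
                        mention = "AIDSVAX B/E Placebo")
  out <- apply_sm_rule(pred, g)
  expect_equal(out$candidates$concept_id[1], "VX:4")
  expect_equal(out$sm_promoted$name, "AIDSVAX B/E")
  # VX:4 was absent: inserted at rank 1, others keep relative order
  expect_equal(out$candidates$concept_id, c("VX:4", "VX:5", "VX:1"))
  expect_equal(out$candidates$rank, 1:3)

  # longest of several nested matches wins (brute-force scan cross-check)
  m <- "Menveo meningococcal conjugate vaccine 0.5 mL"
  pred2 <- mk_prediction(c("VX:1", "VX:2", "VX:3"), c(0.9, 0.8, 0.7),
                         mention = m)
  out2 <- apply_sm_rule(pred2, g)
  nm <- concept_names(g)
  matches <- nm$name[vapply(tolower(nm$name), grepl, NA, x = tolower(m),
                            fixed = TRUE)]
  expect_equal(out2$sm_promoted$name,
               matches[which.max(nchar(matches))])
  expect_equal(out2$candidates$concept_id[1], "VX:3")
  # already-present candidate is moved, not duplicated
  expect_equal(sort(out2$candidates$concept_id),
               sort(pred2$candidates$concept_id))

  # no vocabulary substring: prediction unchanged
  pred3 <- mk_prediction(c("VX:1", "VX:2"), c(0.5, 0.4),
                         mention = "saline solution")
  expect_identical(apply_sm_rule(pred3, g), pred3)

  # trademark glyphs in the mention do not block the synonym match
  pred4 <- mk_prediction("VX:1", 0.3,
                         mention = "seasonal influenza (FluMist ®)")
  out4 <- apply_sm_rule(pred4, g)
  expect_equal(out4$candidates$concept_id[1], "VX:5")
})

test_that("SM-rule is idempotent", {
  g <- make_ontology(40, 5, 3, seed = 12)
  b <- char_ngram_backend(concept_names(g)$name)
  idx <- build_index(g, b)
  mm <- make_mentions(g, 25, noise_config(seed = 13))
  cfg <- ensemble_config("score", k = 10, sm_rule = FALSE)
  for (m in mm$mentions$mention) {
    p1 <- apply_sm_rule(fuse(list(a = retrieve(m, idx, b, 10)), cfg), g)
    p2 <- apply_sm_rule(p1, g)
    expect_equal(p2, p1, info = m)
  }
})

test_that("corpus normalization composes retrieve, fuse, and the SM rule", {
  g <- make_ontology(30, 5, 3, seed = 8)
  vocab <- concept_names(g)$name
  backends <- list(a = char_ngram_backend(vocab, c(3, 3)),
                   b = char_ngram_backend(vocab, c(4, 4)))
  indexes <- lapply(backends, build_index, graph = g)
  mm <- make_mentions(g, 10, noise_config(seed = 4))
  cfg <- ensemble_config("scale", k = 10, sm_rule = TRUE)
  preds <- normalize_corpus(mm$mentions, indexes, backends, cfg, g)
  expect_length(preds, 10)
  for (i in seq_along(preds)) {
    m <- mm$mentions$mention[i]
    manual <- apply_sm_rule(fuse(
      list(a = retrieve(m, indexes$a, backends$a, 10),
           b = retrieve(m, indexes$b, backends$b, 10)), cfg), g)
    expect_equal(preds[[i]]$candidates, manual$candidates, info = m)
    expect_equal(preds[[i]]$mention_id, mm$mentions$mention_id[i])
  }
  # sm_rule off: no promotions recorded; empty input: empty output
  off <- normalize_corpus(mm$mentions, indexes, backends,
                          ensemble_config("scale", sm_rule = FALSE))
  expect_true(all(vapply(off, function(p) is.null(p$sm_promoted), NA)))
  expect_length(normalize_corpus(character(0), indexes, backends,
                                 ensemble_config("score", sm_rule = FALSE)),
                0)
})

test_that("validation-accuracy weights favor the best models, top-m capped", {
  gold <- gold_standard(c("m1", "m2"), c("a", "b"),
                        list("C:1", "C:2"))
  perfect <- list(mk_candidates("C:1", 1), mk_candidates("C:2", 1))
  half <- list(mk_candidates("C:1", 1), mk_candidates("C:9", 1))
  zero <- list(mk_candidates("C:7", 1), mk_candidates("C:8", 1))
  w <- fit_ensemble_weights(
    list(good = perfect, mid = half, bad = zero, worse = zero),
    c("m1", "m2"), gold, top_m = 2
  )
  expect_equal(sum(w), 1)
  expect_equal(unname(w[c("bad", "worse")]), c(0, 0))
  expect_equal(unname(w["good"] / w["mid"]), 2)
  expect_warning(
    we <- fit_ensemble_weights(list(a = zero, b = zero), c("m1", "m2"), gold),
    "equal weights"
  )
  expect_equal(unname(we), c(0.5, 0.5))
})

test_that("predictions JSONL round-trips", {
  g <- mini_graph()
  pred <- apply_sm_rule(
    mk_prediction(c("VX:5", "VX:1"), c(0.9, 0.2),
                  mention = "AIDSVAX B/E Placebo", mention_id = "m00001"),
    g
  )
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_predictions_jsonl(list(pred), path)
  back <- read_predictions_jsonl(path)
  expect_length(back, 1)
  expect_equal(back[[1]]$mention_id, "m00001")
  expect_equal(back[[1]]$candidates$concept_id, pred$candidates$concept_id)
  expect_equal(back[[1]]$sm_promoted$concept_id, "VX:4")
  expect_true(is.na(back[[1]]$candidates$score[1]))
})
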