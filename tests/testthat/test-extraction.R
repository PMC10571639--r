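records_fixture <- function() {
  # 8 Biological rows containing a vocabulary name, 3 Biological rows with
  # only the bare keyword, 9 rows that neither query may return
  data.frame(
    id = 1:20,
    nct_id = sprintf("NCT%08d", 1:20),
    intervention_type = c(rep("Biological", 11),
                          c("Drug", "Drug", "Procedure", "Device", "Other",
                            "Drug", "Biological", "Biological", "Drug")),
    name = c(
      "Menveo meningococcal conjugate vaccine",
      "conjugate vaccine 0.5 mL",
      "AIDSVAX B/E Placebo",
      "Influenza Vaccine (FluMist)",
      "meningococcal CONJUGATE VACCINE lot 3",
      "Trivalent influenza vaccine",
      "Some Vaccine candidate",          # keyword via "vaccine" label
      "flumist quadrivalent",
      "COVID-19 Vaccinium candidate",    # keyword only ("vaccin" not term)
      "Experimental vaccinal agent",     # keyword only? contains "vaccin"
      "Adjuvanted vacc product",         # no full keyword
      "Menveo conjugate vaccine",        # Drug: excluded by type gate
      "conjugate vaccine tablets",       # Drug: excluded
      "vaccination visit",               # Procedure: excluded
      "vaccine delivery device",         # Device: excluded
      "vaccine counseling",              # Other: excluded
      "Aspirin", "Normal saline", "Adjuvant alone", "Ibuprofen"
    ),
    stringsAsFactors = FALSE
  )
}

test_that("vocabulary query matches the SQL substring semantics", {
  g <- mini_graph()
  rec <- records_fixture()
  out <- select_by_vocabulary(rec, g)
  expect_setequal(out$id, oracle_query1(rec, g))
  # type gate: same name under 'Drug' is never returned
  expect_false(12 %in% out$id)
  # matched names are attached, longest-specific ones included
  row1 <- out$matched_names[[match(1, out$id)]]
  expect_true(all(c("meningococcal conjugate vaccine", "conjugate vaccine",
                    "vaccine", "Menveo") %in% row1))
  # empty input gives empty output
  empty <- select_by_vocabulary(rec[0, ], g)
  expect_equal(nrow(empty), 0)
})

test_that("keyword query matches LIKE semantics and validates arguments", {
  rec <- records_fixture()
  out <- select_by_keyword(rec, "vaccine")
  expect_setequal(out$id, oracle_query2(rec, "vaccine"))
  expect_false(3 %in% out$id)   # "AIDSVAX B/E Placebo" has no keyword
  expect_true(7 %in% out$id)
  expect_error(select_by_keyword(rec, character(0)), "non-empty")
})

test_that("TF-IDF similarity is symmetric with unit self-similarity", {
  g <- mini_graph()
  labels <- concept_names(g)$name
  idx <- fit_tfidf(labels)
  for (s in labels) {
    expect_equal(tfidf_similarity(s, s, idx), 1.0, tolerance = 1e-12)
  }
  expect_equal(tfidf_similarity("conjugate", "vaccine conjugate", idx),
               tfidf_similarity("vaccine conjugate", "conjugate", idx))
  expect_error(tfidf_similarity("a", "b", list()), "not a fitted")
  expect_error(fit_tfidf(character(0)), "non-empty")
})

test_that("TF-IDF argmax agrees with a from-scratch dense computation", {
  corpus <- c(
    "meningococcal conjugate vaccine", "conjugate vaccine",
    "influenza vaccine", "live attenuated influenza vaccine",
    "hepatitis b vaccine", "rabies vaccine", "typhoid vaccine",
    "pneumococcal polysaccharide vaccine", "varicella vaccine",
    "measles mumps rubella vaccine"
  )
  idx <- fit_tfidf(corpus)
  # independent oracle: count trigrams by hand, apply the smoothed-idf
  # formula, and take dense cosines
  oracle_vec <- function(s) {
    s <- tolower(trimws(gsub("\\s+", " ", s)))
    grams <- substring(s, seq_len(nchar(s) - 2), 3:nchar(s))
    tf <- table(grams)
    v <- setNames(numeric(length(idx$vocab)), idx$vocab)
    common <- intersect(names(tf), idx$vocab)
    v[common] <- as.numeric(tf[common]) * idx$idf[common]
    v / sqrt(sum(v^2))
  }
  queries <- c("meningococal conjugate vacine", "flu vaccine live",
               "pneumococcal vaccine", "mmr vaccine")
  for (q in queries) {
    sims_pkg <- vapply(corpus, tfidf_similarity, 0, a = q, index = idx)
    sims_orc <- vapply(corpus, function(d) sum(oracle_vec(q) * oracle_vec(d)),
                       0)
    expect_equal(unname(sims_pkg), unname(sims_orc), tolerance = 1e-12)
    expect_equal(which.max(sims_pkg), which.max(sims_orc))
  }
})

test_that("multi-match resolution picks max similarity with declared ties", {
  g <- mini_graph()
  idx <- fit_tfidf(concept_names(g)$name)
  expect_equal(resolve_unique_concept("anything", "only name", idx),
               "only name")
  got <- resolve_unique_concept(
    "meningococcal conjugate vaccine Menveo",
    c("conjugate vaccine", "meningococcal conjugate vaccine"), idx
  )
  # brute-force check that the winner really has the higher cosine
  sims <- vapply(c("conjugate vaccine", "meningococcal conjugate vaccine"),
                 tfidf_similarity, 0,
                 a = "meningococcal conjugate vaccine Menveo", index = idx)
  expect_equal(got, names(which.max(sims)))
  expect_equal(got, "meningococcal conjugate vaccine")
  # identical vectors: longer name, then lexicographic order
  expect_equal(
    resolve_unique_concept("x", c("same words", "words same more"), idx),
    "words same more"
  )
  expect_equal(resolve_unique_concept("zzz", c("bb", "aa"), idx), "aa")
  expect_error(resolve_unique_concept("x", character(0), idx), "non-empty")
})

test_that("corpus building dedupes case-insensitively, order-independently", {
  g <- mini_graph()
  rec <- records_fixture()
  out <- build_corpus(rec, g)
  r <- out$report
  expect_equal(r$n_total, 20)
  expect_equal(r$n_biological, 13)
  expect_equal(r$n_query1, length(oracle_query1(rec, g)))
  expect_equal(r$n_query2, length(oracle_query2(rec)))
  expect_true(r$n_unique <= r$n_union)
  expect_true(r$n_union <= r$n_query1 + r$n_query2)
  expect_true(r$n_query1 <= r$n_biological && r$n_query2 <= r$n_biological)

  # duplicate names differing only in case collapse to one mention
  dup <- data.frame(
    id = 1:2, nct_id = c("NCT1", "NCT2"),
    intervention_type = "Biological",
    name = c("Influenza Vaccine", "influenza  vaccine"),
    stringsAsFactors = FALSE
  )
  both <- build_corpus(dup, g)
  expect_equal(both$report$n_union, 2)
  expect_equal(both$report$n_unique, 1)

  # permuting rows leaves the deduped corpus unchanged
  perm <- rec[rev(seq_len(nrow(rec))), ]
  out2 <- build_corpus(perm, g)
  expect_equal(out2$mentions$mention, out$mentions$mention)
  expect_equal(out2$mentions$nct_id, out$mentions$nct_id)
})

test_that("emitted SQL reproduces the query structure with safe escaping", {
  g <- mini_graph()
  sql <- emit_sql(g, "vaccine")
  expect_match(sql$keyword_query, "lower(name) LIKE '%vaccine%'",
               fixed = TRUE)
  expect_match(sql$vocabulary_query,
               "position(lower('conjugate vaccine') IN lower(name)) > 0",
               fixed = TRUE)
  expect_match(sql$vocabulary_query, "intervention_type='Biological'",
               fixed = TRUE)

  apo <- concept_graph(data.frame(id = "X:1", label = "o'nyong'nyong vaccine"))
  sql2 <- emit_sql(apo)
  expect_match(sql2$vocabulary_query, "o''nyong''nyong", fixed = TRUE)

  none <- concept_graph(data.frame(id = "X:1", label = "solo"))
  none$concepts <- none$concepts[0, ]
  expect_warning(sql3 <- emit_sql(none), "empty vocabulary")
  expect_match(sql3$vocabulary_query, "FALSE", fixed = TRUE)
})
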