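#' Run the full normalization pipeline on synthetic data
#'
#' End-to-end driver: simulate a vocabulary, gold-standard mention corpus,
#' and interventions table; mine the mention corpus back out of the table;
#' build embedding indexes for two character n-gram backends (trigram and
#' 4-gram rankers); fuse them under every requested metric with and/or
#' without the string-matching rule; and evaluate each configuration
#' against the gold standard. All artifacts are written under `out_dir` in
#' the package's text formats; repeated runs with the same seed are
#' byte-identical.
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer master seed; sub-seeds for the graph, corpus, and
#'   table are derived from it.
#' @param n_mentions gold corpus size. Default 200.
#' @param n_vaccine,n_distractor,branching graph shape, see
#'   [make_ontology()].
#' @param n_background distractor rows in the interventions table.
#' @param cfg a [noise_config()]; its seed is overridden from `seed`.
#' @param metrics fusion metrics to run.
#' @param sm_rule logical vector of SM-rule settings to run.
#' @param k retrieval and fusion depth.
#' @return invisibly, a list with the graph, gold standard, extraction
#'   report, per-configuration `eval_report`s, and the summary written to
#'   `summary.json`.
#' @export
run_pipeline <- function(out_dir, seed = 1L, n_mentions = 200L,
                         n_vaccine = 100L, n_distractor = 20L,
                         branching = 3L, n_background = 300L,
                         cfg = noise_config(),
                         metrics = c("score", "scale", "rank"),
                         sm_rule = c(FALSE, TRUE), k = 10L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)

  graph <- make_ontology(n_vaccine, n_distractor, branching, seed = seed)
  write_vocabulary(graph, file.path(out_dir, "vocabulary.tsv"))

  cfg$seed <- seed + 1L
  corpus <- make_mentions(graph, n_mentions, cfg)
  write_mentions_tsv(corpus$mentions, file.path(out_dir, "mentions.tsv"))
  write_gold_tsv(corpus$gold, file.path(out_dir, "gold.tsv"))

  interventions <- make_interventions(corpus$mentions, n_background,
                                      seed = seed + 2L)
  write_interventions(interventions, file.path(out_dir, "interventions.csv"))

  mined <- build_corpus(interventions, graph)
  write_mentions_tsv(mined$mentions,
                     file.path(out_dir, "extracted_mentions.tsv"))
  write_extraction_report(mined$report,
                          file.path(out_dir, "extraction_report.json"))
  sql <- emit_sql(graph)
  writeLines(sql$vocabulary_query, file.path(out_dir, "query_vocabulary.sql"))
  writeLines(sql$keyword_query, file.path(out_dir, "query_keyword.sql"))

  vocab_names <- concept_names(graph)$name
  backends <- list(
    `char-ngram-3-3` = char_ngram_backend(vocab_names, c(3L, 3L)),
    `char-ngram-4-4` = char_ngram_backend(vocab_names, c(4L, 4L))
  )
  indexes <- lapply(backends, build_index, graph = graph)
  for (m in names(indexes)) {
    save_index(indexes[[m]], file.path(out_dir, paste0("index-", m)))
  }

  dir.create(file.path(out_dir, "predictions"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "eval"), showWarnings = FALSE)
  reports <- list()
  summary <- list()
  for (metric in metrics) {
    for (sm in sm_rule) {
      tag <- paste0(metric, if (sm) "_sm" else "")
      config <- ensemble_config(metric = metric, k = k, sm_rule = sm)
      preds <- normalize_corpus(corpus$mentions, indexes, backends, config,
                                graph = graph)
      write_predictions_jsonl(
        preds, file.path(out_dir, "predictions", paste0(tag, ".jsonl")))
      rep <- evaluate_predictions(preds, corpus$gold, graph, max_n = k)
      write_eval_report(rep, file.path(out_dir, "eval", paste0(tag, ".json")))
      reports[[tag]] <- rep
      summary[[paste0("acc1_", tag)]] <- unname(rep$acc[1])
      summary[[paste0("acc10_", tag)]] <- unname(rep$acc[k])
    }
  }
  summary$n_mentions <- n_mentions
  summary$n_extracted_unique <- mined$report$n_unique
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 12)
  invisible(list(graph = graph, gold = corpus$gold,
                 extraction_report = mined$report,
                 reports = reports, summary = summary))
}
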