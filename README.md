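# vaxnorm

Vaccine names in clinical-trial registries are free text: the same product
appears as `"MenACWY-CRM conjugate vaccine (Menveo)"`, `"AIDSVAX B/E
Placebo"`, or just `"23vPPV, dkTpa"`. Mapping such mentions to canonical
concepts in a vaccine ontology — medical concept normalization — is what
makes trial data comparable across studies and usable for surveillance.
`vaxnorm` is an R toolkit for that workflow, aimed at biomedical text-mining
and ontology-curation work:

* **ontology** — load a concept vocabulary (minimal OBO 1.4 subset or a TSV
  dialect), restrict it to its vaccine subtree, and classify the hierarchy
  relation between any two concepts;
* **extraction** — mine candidate mentions from an interventions table with
  the registry's own SQL predicate semantics (`intervention_type =
  'Biological'` plus case-insensitive substring matching), resolve
  multi-matched rows with a TF-IDF string matcher, and report PRISMA-style
  screening counts;
* **encoder** — embed concept names and mentions behind a pluggable
  backend contract and retrieve top-K candidates by exact cosine search
  (a deterministic character n-gram TF-IDF backend ships; externally
  trained sentence encoders plug in through the same contract);
* **ensemble** — fuse several rankers with weighted metrics and apply a
  string-matching promotion rule;
* **evaluation** — Top-n accuracy against a (possibly multi-valued) gold
  standard and an error taxonomy grounded in the ontology hierarchy;
* **fixtures** — a seeded generator for the vocabulary, gold corpus, and
  interventions table, so the whole pipeline runs offline.

## The method

Each encoder backend maps strings to unit vectors; a concept's score for a
mention *m* is max-pooled over its names (label and synonyms):

```
s(c | m) = max over names x of c of  cos(e(m), e(x))
```

Candidate lists from several models are fused by a weighted sum. With
per-model weight `w_m` and top-K candidate lists, the fused score of
concept `c` is

```
score:  S(c) = sum_m w_m * s_m(c)                (raw cosine; 0 if absent)
scale:  S(c) = sum_m w_m * minmax_m(s_m(c))      (rescaled to [0,1] per list)
rank:   S(c) = sum_m w_m * (K - rank_m(c) + 1)   (Borda points; 0 if absent)
```

After fusion, the **SM rule** scans the mention for vocabulary names
occurring verbatim (case-folded) as substrings and promotes the concept of
the longest match to rank 1 — this is what maps `"AIDSVAX B/E Placebo"` to
the concept named `"AIDSVAX B/E"`. Performance is summarized by Top-n
accuracy,

```
Acc@n = (# mentions with a gold concept among the top n candidates) / (# mentions),
```

and rank-1 misses are classified as out-of-vocabulary, NER
(multi-concept / noisy mention), disambiguation, hierarchy (parent-child,
ancestor-descendant, sibling), semantic, abbreviation, spelling, or
stemming errors, using shortest directed paths in the ontology DAG.

## Worked example

```r
library(vaxnorm)

graph  <- make_ontology(n_vaccine = 100, n_distractor = 20, seed = 42)
corpus <- make_mentions(graph, 200, noise_config(seed = 43))
records <- make_interventions(corpus$mentions, n_background = 300, seed = 44)

mined <- build_corpus(records, graph)
print(mined$report)
#> Extraction screening counts
#>   interventions rows:        500
#>   typed 'Biological':        244
#>   vocabulary query matches:  182
#>   keyword query matches:     182
#>   union of both queries:     182
#>   unique mention strings:    160

vocab    <- concept_names(graph)$name
backends <- list(trigram   = char_ngram_backend(vocab, c(3, 3)),
                 tetragram = char_ngram_backend(vocab, c(4, 4)))
indexes  <- lapply(backends, build_index, graph = graph)

cfg   <- ensemble_config("scale", k = 10, sm_rule = TRUE)
preds <- normalize_corpus(corpus$mentions, indexes, backends, cfg, graph)
print(preds[[1]])
#> ranked_prediction for “Zemip kilov bubar conjugate vaccine Placebo”
#>   SM-rule promoted VX:0000044 (matched name “zemip kilov bubar conjugate vaccine”)
#>  concept_id     score rank
#>  VX:0000044 2.0000000    1
#>  VX:0000015 1.3414327    2
#>  VX:0000045 1.0536385    3
#>  VX:0000046 0.9318570    4
#>  VX:0000005 0.6671561    5
#>   ...

print(evaluate_predictions(preds, corpus$gold, graph))
#> Normalization evaluation over 200 mentions
#>  Acc@1  Acc@2  Acc@3  Acc@4  Acc@5  Acc@6  Acc@7  Acc@8  Acc@9 Acc@10
#>   84.0   85.5   85.5   85.5   85.5   85.5   85.5   85.5   85.5   85.5
#> Rank-1 error types:
#>   oov                          12
#>   disambiguation               3
#>   semantic                     1
#>   abbreviation                 16
```

The first mention carries a `"Placebo"` suffix; the SM rule still pins it
to its product concept, so it scores correct at rank 1. The residual
errors are the deliberately hard corpus fractions: mentions whose gold
concept is absent from the vocabulary (`oov`) and initials-style
abbreviations that share almost no character n-grams with their label.

A command-line front end wraps the same functions
(`inst/cli/vaxnorm.R`; subcommands `simulate`, `extract`, `index`,
`normalize`, `evaluate`, `pipeline`):

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "vaxnorm.R", package = "vaxnorm"))')" \
    pipeline --seed 11 --out run1/
```

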