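---
title: "Normalizing vaccine names from trial registries: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normalizing vaccine names from trial registries: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vaxnorm` normalizes free-text vaccine mentions from clinical-trial
intervention tables to concepts in a vaccine ontology. This vignette is the
package's account of the method: the model and its assumptions, the
parameters that matter, the design choices we made where the design was
genuinely open, and what the synthetic corpus does and does not show about
real registry data.

## The task and its assumptions

An interventions table gives free-text rows like `"MenACWY-CRM conjugate
vaccine (Menveo) 0.5 mL"`; the ontology gives concepts with a preferred
label, synonyms, and an `is_a` hierarchy forming a DAG. Normalization maps
each mention to one or more concepts. The package decomposes this into
candidate generation (embed mention and concept names in a common space,
take cosine nearest neighbors), ensemble fusion over several rankers, a
lexical promotion rule, and evaluation.

Assumptions worth making explicit:

* **The vocabulary is the closed target space.** A mention whose true
  concept is missing can only ever be an out-of-vocabulary error; the
  evaluator accounts for this explicitly rather than pretending the
  vocabulary is complete.
* **Annotation semantics follow curation practice for trial data**: a
  placebo arm maps to the vaccine itself; a mention naming two products
  maps to both concepts (scored as any-match); when a mention and the
  vocabulary both carry a product (brand) name, the product concept is the
  gold mapping.
* **Multiple parents are allowed.** OBO-style ontologies are DAGs, not
  trees, so every hierarchy computation uses shortest directed paths over
  the parent relation, never a unique-parent shortcut.

## Candidate generation

An `encoder_backend` is a contract, not an implementation: a deterministic
function from strings to unit-L2-norm row vectors of fixed dimension.
Transformer-based sentence encoders (including domain-adapted models
fine-tuned on registry text and the ontology itself; a typical recipe is a
single epoch at batch size 256, learning rate 2e-5, and a short maximum
sequence length around 25 tokens) enter through this contract as
user-supplied plug-ins. The package ships a character n-gram TF-IDF
backend that needs no model files and is exactly reproducible, which is
what the tests and the acceptance pipeline run on.

Choices inside the shipped backend and retrieval layer:

* **Character n-grams (default trigrams) on case-folded,
  whitespace-collapsed text.** Intervention strings are short and noisy
  (doses, lot numbers, parentheticals, inconsistent casing); character
  n-grams degrade gracefully under that noise where word-level features
  shatter. The TF-IDF form uses the smoothed inverse document frequency
  `log((1 + N) / (1 + df)) + 1` and L2-normalized vectors, so cosine is an
  inner product and a string's self-similarity is exactly 1.
* **Max-pooling over concept names.** A concept is scored by the best of
  its label and synonyms. This is the standard convention in entity
  linking, and it gives a testable monotonicity property: adding a synonym
  can never lower a concept's score.
* **Exact retrieval.** `retrieve()` must equal a brute-force cosine scan;
  no approximate index is permitted to change results. At vocabulary
  scales typical for a curated vaccine ontology (thousands of names) exact
  search is cheap, and exactness is what makes the oracle tests decisive.
* **K = 10 candidates** by default, matching the usual reporting depth of
  Top-1 through Top-10 accuracy.
* **Ties break by concept id ascending**, everywhere a ranking is
  produced. Identical scores occur routinely (identical synonym vectors,
  all-zero vectors for mentions with no in-vocabulary n-gram), and a
  deterministic tie-break is what makes runs byte-reproducible.

## Extraction semantics

The miner reproduces, in memory, the two SQL queries a registry user would
run: rows typed exactly `'Biological'` whose lower-cased name contains a
lower-cased vocabulary term (`position(lower(term) IN lower(name)) > 0`),
and rows containing a keyword (`lower(name) LIKE '%vaccine%'`). Matching
is raw substring — no token boundaries — because fidelity to the SQL
predicates is the point; `emit_sql()` renders the same queries as text for
live-database use. Two folding regimes coexist deliberately: extraction
uses plain lower-casing (the SQL semantics), while the ontology name index
and the SM rule additionally strip trademark glyphs (® and ™) so that
`"FluMist ®"` indexes as `flumist`.

When one row matches several vocabulary terms, `resolve_unique_concept()`
keeps the term with the highest TF-IDF cosine against the full mention,
breaking ties by longer name and then lexicographic order. Deduplication
of the combined query results keys on the case-folded,
whitespace-collapsed name; the union is sorted before deduplication so the
corpus is independent of input row order. The screening report carries the
stage counts (total, biological, per-query, union, unique) and enforces
their inequalities on every run.

## Ensemble fusion

Three fusion metrics are supported, all weighted sums over models of a
per-model contribution for each concept in that model's top-K list
(absent concepts contribute 0 — the natural score for "not suggested"):

* **score** — the raw cosine;
* **scale** — the cosine min-max rescaled to [0, 1] *within that model's
  top-K list for that mention*. Rescaling per list, rather than
  corpus-wide, is what makes heterogeneous models comparable mention by
  mention, which is the purpose of scaling; a degenerate list
  (max == min) contributes 1 for every present candidate;
* **rank** — Borda points `K − rank + 1`. "Ranking score" admits several
  formulas; Borda is the simplest order-consistent one, and the config
  records the metric name so alternatives (reciprocal rank, say) can be
  added without ambiguity.

For a single model with weight 1, all three metrics reproduce the model's
own ordering (min-max is monotone within a list; Borda is strictly
decreasing in rank) — this identity is asserted corpus-wide in the tests.
Default weights, when none are given, are equal; `fit_ensemble_weights()`
implements the recommended alternative of weighting models by Top-1
accuracy on a validation split, restricted to the best three models so
that weak rankers do not dilute the ensemble.

## The string-matching rule

`apply_sm_rule()` promotes to rank 1 the concept of the longest vocabulary
name occurring verbatim (case-folded, glyphs stripped, whitespace
collapsed) inside the mention, with ties broken by lexicographically
smallest name and then smallest concept id. Both labels and synonyms are
eligible: product names usually live as synonyms, and the product concept
is the preferred gold mapping, so excluding synonyms would defeat the
rule's main use. The rule *reorders* rather than rescores — other
candidates keep their fused scores and relative order, and a promoted
concept absent from the list is inserted with an `NA` score — so
downstream accuracy is affected only through rank. It is idempotent by
construction.

The rule's guarantee and its failure mode are both worth stating. When a
mention contains its gold label verbatim (placebo suffixes and dose noise
only), promotion is always correct and Top-1 accuracy reaches 1.0 — the
test suite asserts exactly this. But under misspelling, the specific label
no longer matches while a generic term (`"vaccine"`, or a category label
like `"conjugate vaccine"`) still does, and the rule then promotes a
high-level concept over a possibly-correct retrieval result. On the
default mixed-noise corpus this makes the rule's net Acc@1 contribution
slightly negative (the acceptance script computes the exact gain each
run). A production deployment would gate the rule on match specificity;
we keep the faithful longest-match semantics and surface the effect
instead.

## Evaluation and the error taxonomy

`Acc@n` is the fraction of mentions with at least one gold concept among
the top `min(n, list length)` candidates, computed mention-level for
n = 1..10. Multi-valued gold uses any-match — the least-assumption reading
of multi-concept annotations. The accuracy vector is monotone in n by
construction and asserted so on every evaluation.

Every rank-1 miss gets one error type. The hierarchy relation between the
top prediction and the nearest gold concept is computed on the DAG:
`parent_child` for a directed path of length 1 (either direction),
`ancestor_descendant` for length exactly 2, `sibling` for a shared parent
without ancestry, and `semantic` for everything else — including directed
paths spanning more than two levels, which is the boundary we fixed where
"more than two levels" needed a formal rule. Types are assigned by fixed
priority: `oov` (no gold concept in the vocabulary, or the prediction
itself out of vocabulary) > `ner_multi_concept` (multi-concept gold) >
`disambiguation` (the gold concept was suggested at rank 2 or deeper) >
`hierarchy_*` > the lexical types. One deliberate refinement: a `semantic`
relation falls through to the lexical heuristics — abbreviation (an
all-caps token matching the initials of a gold label), spelling (a token
at edit distance 1–2 from a gold-label token), stemming (shared ≥ 4-char
prefix, different suffix), noise (dose/lot patterns) — and is labelled
`semantic` only when none fires. Placing the catch-all above the lexical
types would have made them unreachable; the chosen order keeps each
category meaningful while leaving every heuristic overridable through
`hooks`, since lexical error typing is ultimately a judgment call that
real audits resolve manually.

## The synthetic corpus: what it emulates, what it does not

`make_ontology()` builds a vaccine subtree whose second level carries
vaccine class labels and whose deeper labels nest a synthetic stem onto
the parent label, plus brand-style synonyms on deep nodes, a second parent
on every seventh deep node (a genuine DAG), and a separate non-vaccine
subtree of distractors. `make_mentions()` perturbs sampled labels with the
noise phenomena real intervention strings show: product parentheticals,
placebo suffixes, two-product mentions, initials, dose/lot tokens,
character transpositions, and an out-of-vocabulary fraction. Default rates
(20% parenthetical, 15% placebo, 10% multi-concept, 10% abbreviation, 25%
dose noise, 5% misspelling, 3% OOV) keep most mentions near-verbatim —
registry names are noisy but rarely mangled — while exercising every
branch at the default corpus size. All random material is drawn up front
in fixed shape, so corpora generated under different noise switches from
the same seed stay paired mention-for-mention; that is what makes
"placebo noise leaves gold ids unchanged" a testable statement.

What the generator does *not* emulate: the lexical statistics of real
trade names, multilingual mentions, annotator disagreement, and the
long-tail distribution of registry text. Passing tests on this corpus
demonstrate the machinery — exact retrieval, correct fusion arithmetic,
rule semantics, metric correctness — not the absolute accuracy one would
obtain on curated registry data with trained encoders, which depends on
model quality and vocabulary coverage.

## Problem sizes and numerical choices

The study-scale configuration used throughout the tests and the acceptance
pipeline is a 100-concept vaccine graph with 20 distractors, 200 annotated
mentions, and a 500-row interventions table — large enough that every
noise branch and both queries fire, small enough that the whole suite runs
in well under a minute per configuration. Oracle tests run at reduced
sizes (8-node DAG for the exhaustive 64-pair relation check, 24
constructed fusion cases) where exhaustive enumeration is the point.

Numerical conventions: cosine scores are compared exactly where the same
arithmetic path is used and at tolerance 1e-12 against dense re-implementations;
ranking ties always break by id; degenerate inputs (empty files, empty
candidate sets, all-zero vectors, K beyond the vocabulary size) are
defined behaviors, not errors, except where a contract is genuinely
violated (unknown ids, mismatched backend/index pairs, cyclic parent
links — each a typed, early error). Every generator and the pipeline
driver take explicit integer seeds; no ambient RNG state leaks between
stages.

## Known limitations

* The shipped backend is lexical; it cannot resolve abbreviations or
  semantic paraphrases, which is visible in the synthetic error histogram
  (abbreviation and OOV dominate). Plug in trained encoders for those.
* The SM rule's longest-match semantics can promote generic concepts on
  misspelled mentions, as discussed above.
* The OBO reader covers the minimal `[Term]`/`id`/`name`/`synonym`/`is_a`
  subset only — deliberate scope, not an OWL reasoner.
* Ensemble weights are not learned; only accuracy-proportional weighting
  on a validation split is provided.
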