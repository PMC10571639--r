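# Shared string folding helpers.
#
# Two folds are used deliberately:
#  * sql_fold()  — plain lowercase, the exact semantics of the registry SQL
#    predicates (position(lower(x) IN lower(name)), LIKE '%kw%'); used by the
#    extraction module only.
#  * fold_case() — lowercase with trademark/registration glyphs stripped;
#    used by the ontology all-names index and the string-matching rule,
#    where "FluMist ®" must index as "flumist".

sql_fold <- function(x) tolower(x)

strip_marks <- function(x) gsub("[®™]", "", x)

fold_case <- function(x) tolower(strip_marks(x))

# Case fold + collapse runs of whitespace + trim: the dedupe / encoding key.
norm_key <- function(x) {
  x <- fold_case(x)
  trimws(gsub("[[:space:]]+", " ", x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Alphanumeric word tokens, lower-cased (error heuristics, abbreviations).
word_tokens <- function(x) {
  toks <- strsplit(gsub("[^[:alnum:]]+", " ", x), " ", fixed = TRUE)[[1]]
  toks[nzchar(toks)]
}

stop_ <- function(...) stop(..., call. = FALSE)
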