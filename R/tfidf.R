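#' Fit a character n-gram TF-IDF index
#'
#' Fits a TF-IDF vectorizer over character n-grams of a corpus of strings
#' (typically the concept names of a vocabulary). Strings are case-folded and
#' whitespace-collapsed before n-gram extraction, which makes the similarity
#' robust to the punctuation, casing, and dose noise typical of intervention
#' names. Inverse document frequency uses the smoothed form
#' \eqn{\log((1+N)/(1+df)) + 1} and document vectors are L2-normalized, so
#' cosine similarity is a plain inner product.
#'
#' @param corpus character vector of documents; must be non-empty.
#' @param ngram integer vector of length 2, the minimum and maximum n-gram
#'   size. Default `c(3, 3)`: character trigrams.
#' @return an object of class `tfidf_index`.
#' @seealso [tfidf_transform()], [tfidf_similarity()]
#' @export
#' @examples
#' idx <- fit_tfidf(c("meningococcal conjugate vaccine", "conjugate vaccine"))
#' tfidf_similarity("conjugate vaccine", "conjugate vaccine", idx)
fit_tfidf <- function(corpus, ngram = c(3L, 3L)) {
  if (length(corpus) == 0 || all(!nzchar(corpus))) {
    stop_("fit_tfidf(): corpus must be a non-empty character vector")
  }
  ngram <- as.integer(ngram)
  stopifnot(length(ngram) == 2, ngram[1] >= 1, ngram[2] >= ngram[1])
  docs <- norm_key(corpus)
  grams <- lapply(docs, char_ngrams, n_lo = ngram[1], n_hi = ngram[2])
  vocab <- sort(unique(unlist(grams, use.names = FALSE)))
  if (length(vocab) == 0) {
    stop_("fit_tfidf(): corpus produced no n-grams (strings shorter than ",
          ngram[1], " characters?)")
  }
  df <- tabulate(
    match(unlist(lapply(grams, unique), use.names = FALSE), vocab),
    nbins = length(vocab)
  )
  n <- length(docs)
  idf <- log((1 + n) / (1 + df)) + 1
  names(idf) <- vocab
  structure(
    list(vocab = vocab, idf = idf, ngram = ngram, n_docs = n),
    class = "tfidf_index"
  )
}

# All character n-grams of one (already folded) string, sizes n_lo..n_hi.
char_ngrams <- function(x, n_lo = 3L, n_hi = 3L) {
  nc <- nchar(x)
  out <- character(0)
  for (n in n_lo:n_hi) {
    if (nc >= n) out <- c(out, substring(x, seq_len(nc - n + 1), n:nc))
  }
  out
}

#' Map strings to L2-normalized TF-IDF vectors
#'
#' @param index a fitted [fit_tfidf()] object.
#' @param strings character vector.
#' @return a sparse `dgCMatrix` with one row per string and one column per
#'   vocabulary n-gram. Rows with no in-vocabulary n-gram are all-zero.
#' @export
tfidf_transform <- function(index, strings) {
  if (!inherits(index, "tfidf_index")) {
    stop_("tfidf_transform(): index is not a fitted tfidf_index")
  }
  docs <- norm_key(strings)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (i in seq_along(docs)) {
    g <- char_ngrams(docs[i], index$ngram[1], index$ngram[2])
    j <- match(g, index$vocab)
    j <- j[!is.na(j)]
    if (!length(j)) next
    tab <- table(j)
    cols <- as.integer(names(tab))
    v <- as.numeric(tab) * index$idf[cols]
    v <- v / sqrt(sum(v^2))
    ii <- c(ii, rep.int(i, length(cols)))
    jj <- c(jj, cols)
    xx <- c(xx, v)
  }
  Matrix::sparseMatrix(
    i = ii, j = jj, x = xx,
    dims = c(length(docs), length(index$vocab))
  )
}

#' TF-IDF cosine similarity between two strings
#'
#' Symmetric; identical strings score 1 whenever the string has at least one
#' in-vocabulary n-gram (otherwise both vectors are zero and the score is 0).
#'
#' @inheritParams tfidf_transform
#' @param a,b strings to compare.
#' @return cosine similarity in `[0, 1]`.
#' @export
tfidf_similarity <- function(a, b, index) {
  if (!inherits(index, "tfidf_index")) {
    stop_("tfidf_similarity(): index is not a fitted tfidf_index")
  }
  m <- tfidf_transform(index, c(a, b))
  as.numeric(Matrix::tcrossprod(m[1, , drop = FALSE], m[2, , drop = FALSE]))
}

#' @export
print.tfidf_index <- function(x, ...) {
  cat(sprintf(
    "TF-IDF char %d-%d gram index: %d n-grams over %d documents\n",
    x$ngram[1], x$ngram[2], length(x$vocab), x$n_docs
  ))
  invisible(x)
}
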