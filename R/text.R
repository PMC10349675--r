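#' Token pipeline configuration
#'
#' The four document operators applied in order: tokenize (maximal alphabetic
#' runs; numerals and punctuation dropped), transform case (lowercase),
#' filter stopwords (after lowercasing), and Porter stemming.
#'
#' @param lowercase lowercase before stopword filtering? (default TRUE)
#' @param stopwords character vector of stopword tokens; defaults to the
#'   English list shipped with the package (see [default_stopwords()]).
#' @param stem apply the Porter stemmer? (default TRUE)
#' @return An object of class `token_pipeline`.
#' @export
token_pipeline <- function(lowercase = TRUE, stopwords = default_stopwords(),
                           stem = TRUE) {
  structure(list(lowercase = isTRUE(lowercase),
                 stopwords = as.character(stopwords),
                 stem = isTRUE(stem)),
            class = "token_pipeline")
}

#' English stopword list shipped with the package
#'
#' A fixed file-backed list so results do not depend on the runtime
#' environment.
#'
#' @return Character vector of stopwords.
#' @export
default_stopwords <- function() {
  path <- system.file("extdata", "stopwords_en.txt", package = "swarmrec")
  if (!nzchar(path)) stop("stopword fixture missing from installation")
  readLines(path, encoding = "UTF-8")
}

#' Preprocess a document into a token list
#'
#' Tokens are maximal runs of letters, in original order; lowercasing,
#' stopword removal and stemming follow per the pipeline config.  The
#' pipeline is idempotent on its own output when the stopword list is closed
#' under stemming of its own members (true of the shipped list for practical
#' purposes; see the package vignette).
#'
#' @param text a character scalar (or vector, treated as one document per
#'   element and returned as a list).
#' @param config a [token_pipeline()].
#' @return Character vector of tokens for scalar input; list of such vectors
#'   otherwise.
#' @examples
#' preprocess("The RUNNING dogs", token_pipeline())
#' @export
preprocess <- function(text, config = token_pipeline()) {
  stopifnot(inherits(config, "token_pipeline"))
  one <- function(doc) {
    if (is.na(doc) || !nzchar(doc)) return(character(0))
    toks <- regmatches(doc, gregexpr("[A-Za-z]+", doc))[[1]]
    if (config$lowercase) toks <- tolower(toks)
    toks <- toks[!(toks %in% config$stopwords)]
    if (config$stem) toks <- porter_stem(toks)
    # stemming can surface stopwords again (e.g. inflected forms); drop them
    toks[!(toks %in% config$stopwords)]
  }
  if (length(text) == 1L) one(text) else lapply(text, one)
}

#' Term-frequency / inverse-document-frequency weights
#'
#' Computes `w[t, d] = tf[t, d] * log10(N / df[t])` over a corpus of token
#' vectors: raw counts, no normalisation, log base 10.  Terms never observed
#' are absent from the vocabulary, so `df >= 1` for every retained term, and
#' a term present in all documents gets weight 0 everywhere.
#'
#' @param corpus list of token character vectors (e.g. from [preprocess()]).
#' @return An object of class `term_weights`: list with sparse term x doc
#'   matrices `w` and `tf`, per-term document frequency `df`, corpus size `N`.
#' @examples
#' tw <- tfidf(list(c("a", "b"), c("a"), c("b", "b")))
#' tw$w["b", 3]
#' @export
tfidf <- function(corpus) {
  if (!length(corpus)) stop("empty corpus", call. = FALSE)
  stopifnot(is.list(corpus))
  n_docs <- length(corpus)
  counts <- lapply(corpus, function(toks) table(toks))
  vocab <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  if (!length(vocab)) stop("corpus contains no tokens", call. = FALSE)
  triplets_i <- integer(0); triplets_j <- integer(0); triplets_x <- numeric(0)
  for (d in seq_len(n_docs)) {
    ct <- counts[[d]]
    if (!length(ct)) next
    triplets_i <- c(triplets_i, match(names(ct), vocab))
    triplets_j <- c(triplets_j, rep.int(d, length(ct)))
    triplets_x <- c(triplets_x, as.numeric(ct))
  }
  tf <- Matrix::sparseMatrix(i = triplets_i, j = triplets_j, x = triplets_x,
                             dims = c(length(vocab), n_docs),
                             dimnames = list(vocab, NULL))
  df <- Matrix::rowSums(tf > 0)
  idf <- log10(n_docs / df)
  w <- Matrix::Diagonal(x = idf) %*% tf
  dimnames(w) <- dimnames(tf)
  structure(list(w = methods::as(w, "CsparseMatrix"), tf = tf, df = df,
                 N = n_docs),
            class = "term_weights")
}

#' @export
print.term_weights <- function(x, ...) {
  cat(sprintf("term_weights: %d terms x %d documents, %d nonzero weights\n",
              nrow(x$w), ncol(x$w), Matrix::nnzero(x$w)))
  invisible(x)
}

#' Export a term-weight matrix as MatrixMarket plus a terms index
#'
#' Writes `<stem>.mtx` (sparse coordinate format) and `<stem>.terms.txt`
#' (one term per line, row order).
#'
#' @param tw a `term_weights` object.
#' @param stem output path stem.
#' @return The MTX path, invisibly.
#' @export
write_term_weights <- function(tw, stem) {
  stopifnot(inherits(tw, "term_weights"))
  mtx <- paste0(stem, ".mtx")
  Matrix::writeMM(tw$w, mtx)
  writeLines(rownames(tw$w), paste0(stem, ".terms.txt"), useBytes = TRUE)
  invisible(mtx)
}
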