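#' Sparse user-by-item ratings container
#'
#' Wraps a long-format ratings table into a sparse user x item matrix
#' (`Matrix::dgCMatrix`, zero = unobserved) plus the rating scale and the
#' relevance threshold used by top-N evaluation.  Duplicate (user, item)
#' pairs keep the last occurrence with a warning.
#'
#' @param df data frame with columns `user_id`, `item_id`, `rating` and
#'   optionally `timestamp` (integer epoch seconds).
#' @param scale numeric length-2 rating scale bounds (default 1--5).
#' @param relevance threshold at or above which a rating counts as relevant
#'   (default 4).
#' @return An object of class `ratings_matrix`: list with `matrix` (sparse),
#'   `scale`, `relevance`, `ratings` (the deduplicated long table).
#' @export
ratings_matrix <- function(df, scale = c(1, 5), relevance = 4) {
  need <- c("user_id", "item_id", "rating")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_field(miss[1], "column missing from ratings table")
  }
  if (nrow(df) > 0) {
    if (any(!nzchar(as.character(df$user_id))) ||
        any(!nzchar(as.character(df$item_id)))) {
      stop_field("user_id/item_id", "ids must be non-empty")
    }
    bad <- which(df$rating < scale[1] | df$rating > scale[2])
    if (length(bad)) {
      stop_field("rating", sprintf("value %s outside scale [%g, %g] at row %d",
                                   df$rating[bad[1]], scale[1], scale[2],
                                   bad[1]))
    }
  }
  key <- paste(df$user_id, df$item_id, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sprintf("%d duplicate (user, item) pairs; keeping last",
                    sum(duplicated(key))), call. = FALSE)
    df <- df[!duplicated(key, fromLast = TRUE), , drop = FALSE]
  }
  users <- sort(unique(as.character(df$user_id)))
  items <- sort(unique(as.character(df$item_id)))
  m <- Matrix::sparseMatrix(
    i = match(as.character(df$user_id), users),
    j = match(as.character(df$item_id), items),
    x = as.numeric(df$rating),
    dims = c(length(users), length(items)),
    dimnames = list(users, items)
  )
  structure(list(matrix = m, scale = scale, relevance = relevance,
                 ratings = df),
            class = "ratings_matrix")
}

#' @export
print.ratings_matrix <- function(x, ...) {
  cat(sprintf(
    "ratings_matrix: %d users x %d items, %d observed (density %.3f), scale [%g, %g], relevant >= %g\n",
    nrow(x$matrix), ncol(x$matrix), Matrix::nnzero(x$matrix),
    Matrix::nnzero(x$matrix) / max(1, prod(dim(x$matrix))),
    x$scale[1], x$scale[2], x$relevance))
  invisible(x)
}

#' Transaction database container
#'
#' An ordered collection of itemsets (character vectors).  Duplicates inside
#' a transaction are collapsed; the item universe is the union of all
#' transactions.
#'
#' @param transactions list of character vectors (empty vectors allowed).
#' @return An object of class `transaction_db`: list with `transactions` and
#'   `items` (sorted universe).
#' @export
transaction_db <- function(transactions) {
  stopifnot(is.list(transactions))
  tx <- lapply(transactions, function(t) {
    t <- as.character(t)
    t[nzchar(t)]
  })
  tx <- lapply(tx, function(t) sort(unique(t)))
  structure(list(transactions = tx,
                 items = sort(unique(unlist(tx, use.names = FALSE)))),
            class = "transaction_db")
}

#' @export
print.transaction_db <- function(x, ...) {
  cat(sprintf("transaction_db: %d transactions over %d items\n",
              length(x$transactions), length(x$items)))
  invisible(x)
}

#' @export
length.transaction_db <- function(x) length(x$transactions)
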