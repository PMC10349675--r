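# Shared fixtures and independent mini-oracles used across test files.

# the worked five-transaction database used throughout the mining tests
worked_db <- function() {
  transaction_db(list(c("a", "b"), c("a", "b", "c"), c("a", "c"), "b",
                      c("a", "b", "c")))
}

# independent brute-force support count straight from the definition
brute_support <- function(db, candidate) {
  sum(vapply(db$transactions, function(t) all(candidate %in% t), logical(1)))
}

# exhaustive frequent-itemset enumeration over the full powerset of items --
# independent of both mine_frequent and apriori_oracle
brute_frequent <- function(db, min_support) {
  items <- db$items
  out <- list()
  if (length(items)) {
    for (k in seq_along(items)) {
      combos <- utils::combn(items, k, simplify = FALSE)
      for (s in combos) {
        supp <- brute_support(db, s)
        if (supp >= min_support) {
          out[[paste(s, collapse = " ")]] <- supp
        }
      }
    }
  }
  out
}

random_db <- function(n_items = 8L, n_tx = 25L) {
  items <- letters[seq_len(sample.int(n_items, 1L))]
  n <- sample.int(n_tx, 1L)
  transaction_db(lapply(seq_len(n), function(i) {
    sample(items, sample.int(length(items), 1L))
  }))
}

# tiny ratings table helper
ratings_df <- function(...) {
  d <- data.frame(...)
  names(d) <- c("user_id", "item_id", "rating")[seq_along(d)]
  d
}

# breadth-first shortest-path oracle over an rfd_environment with unit
# distances; independent of the drop dynamics it checks
bfs_distance <- function(env, from, to) {
  src <- match(from, env$nodes)
  dst <- match(to, env$nodes)
  dist <- rep(Inf, length(env$nodes))
  dist[src] <- 0
  frontier <- src
  while (length(frontier) && !is.finite(dist[dst])) {
    nxt <- integer(0)
    for (i in frontier) {
      for (j in env$adj[[i]]) {
        if (!is.finite(dist[j])) {
          dist[j] <- dist[i] + 1
          nxt <- c(nxt, j)
        }
      }
    }
    frontier <- nxt
  }
  dist[dst]
}
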