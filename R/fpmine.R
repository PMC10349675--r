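# Software emulation of a systolic tree of processing elements (PEs) for
# frequent-pattern mining.  The hardware formulation streams transactions
# through pipelined PEs in three modes: WRITE builds the item-prefix tree,
# SCAN/COUNT match candidate itemsets against stored paths and accumulate
# support.  Here the modes become traversal procedures over an explicit
# leftmost-child / right-sibling node store; there is no clocked dataflow.

#' Canonical item ordering for tree construction
#'
#' Items sorted by descending support, ties broken lexicographically -- the
#' FP-tree convention, so shared prefixes maximise node reuse.
#'
#' @param db a [transaction_db()].
#' @return Character vector of items, most frequent first.
#' @export
order_items <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  if (!length(db$items)) return(character(0))
  supp <- item_supports(db)
  names(supp)[order(-supp, names(supp))]
}

#' Per-item supports of a transaction database
#'
#' @param db a [transaction_db()].
#' @return Named integer vector of supports, lexicographic item order.
#' @export
item_supports <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  tab <- table(unlist(db$transactions, use.names = FALSE))
  out <- stats::setNames(as.integer(tab), names(tab))
  out[order(names(out))]
}

#' Build the systolic tree for a transaction database (WRITE mode)
#'
#' Each transaction is reordered canonically (see [order_items()]) and
#' streamed through the tree from the control PE at level 0, sharing
#' prefixes; every PE it touches increments its support count.  Nodes are
#' held in parallel vectors with leftmost-child / right-sibling links, the
#' structure the hardware description prescribes.
#'
#' @param db a [transaction_db()].
#' @return An object of class `systolic_tree`: list with vectors `item`,
#'   `count`, `level`, `parent`, `child` (leftmost child), `sibling` (right
#'   sibling); node 1 is the control PE (empty item, level 0), plus the
#'   canonical `ordering`.
#' @export
build_tree <- function(db) {
  stopifnot(inherits(db, "transaction_db"))
  ordering <- order_items(db)
  rank <- stats::setNames(seq_along(ordering), ordering)
  n_guess <- 1L + sum(lengths(db$transactions))
  item <- character(n_guess); count <- integer(n_guess)
  level <- integer(n_guess); parent <- integer(n_guess)
  child <- integer(n_guess); sibling <- integer(n_guess)
  item[1] <- ""; n_nodes <- 1L

  for (tx in db$transactions) {
    if (!length(tx)) next
    path <- tx[order(rank[tx])]
    cur <- 1L
    for (it in path) {
      # follow the leftmost-child / right-sibling chain looking for `it`
      nxt <- child[cur]
      prev <- 0L
      while (nxt != 0L && item[nxt] != it) {
        prev <- nxt
        nxt <- sibling[nxt]
      }
      if (nxt == 0L) {
        n_nodes <- n_nodes + 1L
        nxt <- n_nodes
        item[nxt] <- it
        level[nxt] <- level[cur] + 1L
        parent[nxt] <- cur
        if (prev == 0L) child[cur] <- nxt else sibling[prev] <- nxt
      }
      count[nxt] <- count[nxt] + 1L
      cur <- nxt
    }
  }
  keep <- seq_len(n_nodes)
  structure(list(item = item[keep], count = count[keep], level = level[keep],
                 parent = parent[keep], child = child[keep],
                 sibling = sibling[keep], ordering = ordering,
                 n_transactions = length(db$transactions)),
            class = "systolic_tree")
}

#' @export
print.systolic_tree <- function(x, ...) {
  cat(sprintf("systolic_tree: %d PEs (control + %d), depth %d, %d transactions\n",
              length(x$item), length(x$item) - 1L, max(x$level),
              x$n_transactions))
  invisible(x)
}

#' Support of a candidate itemset from the tree (SCAN/COUNT modes)
#'
#' A transaction containing candidate `S` deposits its count on exactly one
#' PE: the one storing the canonically-last item of `S` along that
#' transaction's path.  So support(S) is the sum of counts over PEs holding
#' that last item whose root path contains all of `S`.
#'
#' @param tree a `systolic_tree` from [build_tree()].
#' @param candidate character vector of items (duplicates ignored).
#' @return Integer support count; the empty candidate returns the number of
#'   transactions, a candidate with an unseen item returns 0.
#' @export
count_support <- function(tree, candidate) {
  stopifnot(inherits(tree, "systolic_tree"))
  candidate <- unique(as.character(candidate))
  if (!length(candidate)) return(tree$n_transactions)
  if (!all(candidate %in% tree$ordering)) return(0L)
  rank <- match(candidate, tree$ordering)
  last_item <- candidate[which.max(rank)]
  rest <- setdiff(candidate, last_item)
  total <- 0L
  for (n in which(tree$item == last_item)) {
    anc <- character(0)
    p <- tree$parent[n]
    while (p > 1L) {
      anc <- c(anc, tree$item[p])
      p <- tree$parent[p]
    }
    if (all(rest %in% anc)) total <- total + tree$count[n]
  }
  total
}

#' Mine all frequent itemsets via the systolic tree
#'
#' Level-wise candidate generation with anti-monotone pruning; every
#' candidate's support comes from [count_support()] on the tree (the
#' SCAN/COUNT emulation), never from rescanning transactions.  Output is
#' canonically sorted: by itemset size, then lexicographically.
#'
#' @param db a [transaction_db()].
#' @param min_support minimum absolute support (count >= 1).
#' @param min_support_frac optional fractional convenience threshold in
#'   (0, 1]; converted with `ceiling(frac * n_transactions)` and overriding
#'   `min_support` when given.
#' @return Data frame with columns `itemset` (list of character vectors),
#'   `items` (space-joined label) and `support`.
#' @export
mine_frequent <- function(db, min_support = 1L, min_support_frac = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.null(min_support_frac)) {
    f <- check_number(min_support_frac, "min_support_frac", lower = 0,
                      upper = 1, open_lower = TRUE)
    min_support <- ceiling(f * length(db$transactions))
  }
  min_support <- check_count(min_support, "min_support")
  tree <- build_tree(db)
  freq_sets <- list(); freq_supp <- integer(0)
  current <- lapply(tree$ordering, identity)
  current <- Filter(function(s) count_support(tree, s) >= min_support,
                    current)
  while (length(current)) {
    supp <- vapply(current, function(s) count_support(tree, s), integer(1))
    freq_sets <- c(freq_sets, lapply(current, sort))
    freq_supp <- c(freq_supp, supp)
    current <- .apriori_gen(current, min_support,
                            function(s) count_support(tree, s))
  }
  .itemset_result(freq_sets, freq_supp)
}

#' Brute-force Apriori oracle
#'
#' Independent reference implementation: supports are counted by direct
#' subset tests over the raw transactions, with the same level-wise
#' generation.  Exists purely so [mine_frequent()] has an oracle to be
#' tested against; identical contract and output format.
#'
#' @inheritParams mine_frequent
#' @return Same shape as [mine_frequent()].
#' @export
apriori_oracle <- function(db, min_support = 1L, min_support_frac = NULL) {
  stopifnot(inherits(db, "transaction_db"))
  if (!is.null(min_support_frac)) {
    f <- check_number(min_support_frac, "min_support_frac", lower = 0,
                      upper = 1, open_lower = TRUE)
    min_support <- ceiling(f * length(db$transactions))
  }
  min_support <- check_count(min_support, "min_support")
  count_direct <- function(s) {
    sum(vapply(db$transactions, function(t) all(s %in% t), logical(1)))
  }
  freq_sets <- list(); freq_supp <- integer(0)
  current <- Filter(function(s) count_direct(s) >= min_support,
                    lapply(sort(db$items), identity))
  while (length(current)) {
    supp <- vapply(current, count_direct, integer(1))
    freq_sets <- c(freq_sets, lapply(current, sort))
    freq_supp <- c(freq_supp, supp)
    current <- .apriori_gen(current, min_support, count_direct)
  }
  .itemset_result(freq_sets, freq_supp)
}

# join frequent k-sets sharing a (k-1)-prefix, prune by anti-monotonicity,
# then keep candidates meeting min_support under `counter`
.apriori_gen <- function(frequent_k, min_support, counter) {
  if (length(frequent_k) < 2L) return(list())
  frequent_k <- lapply(frequent_k, sort)
  keys <- vapply(frequent_k, paste, character(1), collapse = "\r")
  k <- length(frequent_k[[1]])
  out <- list()
  for (a in seq_along(frequent_k)) {
    for (b in seq_along(frequent_k)) {
      if (a >= b) next
      sa <- frequent_k[[a]]; sb <- frequent_k[[b]]
      if (k > 1L && !identical(sa[-k], sb[-k])) next
      cand <- sort(union(sa, sb))
      if (length(cand) != k + 1L) next
      subs_ok <- all(vapply(seq_along(cand), function(d) {
        paste(cand[-d], collapse = "\r") %in% keys
      }, logical(1)))
      if (subs_ok && counter(cand) >= min_support) {
        out[[paste(cand, collapse = "\r")]] <- cand
      }
    }
  }
  unname(out)
}

.itemset_result <- function(sets, supports) {
  if (!length(sets)) {
    return(data.frame(items = character(0), support = integer(0),
                      stringsAsFactors = FALSE))
  }
  labels <- vapply(sets, paste, character(1), collapse = " ")
  ord <- order(lengths(sets), labels)
  out <- data.frame(items = labels[ord], support = as.integer(supports[ord]),
                    stringsAsFactors = FALSE)
  out$itemset <- sets[ord]
  out[, c("itemset", "items", "support")]
}
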