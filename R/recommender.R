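# User-based collaborative filtering with top-N precision/recall evaluation.
# Similarities are computed over co-rated items only; prediction is the
# user's mean plus the similarity-weighted mean-centred deviation of the
# top-k neighbours who rated the item, with a user-mean then global-mean
# fallback chain.

#' Similarity between two users
#'
#' Cosine or Pearson correlation over co-rated items only.  Fewer than two
#' co-rated items, or a constant co-rated vector, give 0 by convention.
#'
#' @param rm a [ratings_matrix()].
#' @param u,v user ids (names) or indices.
#' @param method `"pearson"` (default) or `"cosine"`.
#' @return A value in \[-1, 1\].
#' @export
similarity <- function(rm, u, v, method = c("pearson", "cosine")) {
  method <- match.arg(method)
  m <- rm$matrix
  ui <- if (is.character(u)) match(u, rownames(m)) else as.integer(u)
  vi <- if (is.character(v)) match(v, rownames(m)) else as.integer(v)
  if (is.na(ui) || is.na(vi)) stop_field("user", "unknown user id")
  xu <- m[ui, ]; xv <- m[vi, ]
  co <- which(xu != 0 & xv != 0)
  if (length(co) < 2L) return(0)
  a <- xu[co]; b <- xv[co]
  if (method == "pearson") {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  } else {
    denom <- sqrt(sum(a^2)) * sqrt(sum(b^2))
    if (denom == 0) return(0)
    sum(a * b) / denom
  }
}

# similarities of user u against every user (self = 0), via sparse products
# over the co-rated pattern; same conventions as similarity().  Similarities
# backed by few co-rated items are unreliable, so they are deflated by the
# standard significance weight min(n_co, gamma) / gamma before use in
# prediction.
.sims_all <- function(m, ui, method = "pearson", gamma = NULL) {
  o <- m != 0
  xu <- m[ui, ]
  ou <- as.numeric(xu != 0)
  n_co <- as.numeric(o %*% ou)
  s_uv <- as.numeric(m %*% xu)
  s_u <- as.numeric(o %*% (xu * ou))
  s_uu <- as.numeric(o %*% (xu^2))
  s_v <- as.numeric((m * o) %*% ou)
  s_vv <- as.numeric((m^2) %*% ou)
  if (method == "pearson") {
    num <- s_uv - s_u * s_v / pmax(1, n_co)
    den <- sqrt(pmax(0, s_uu - s_u^2 / pmax(1, n_co))) *
      sqrt(pmax(0, s_vv - s_v^2 / pmax(1, n_co)))
    sims <- ifelse(n_co >= 2 & den > 0, num / den, 0)
  } else {
    den <- sqrt(s_uu) * sqrt(s_vv)
    sims <- ifelse(n_co >= 2 & den > 0, s_uv / den, 0)
  }
  sims[ui] <- 0
  sims <- pmin(1, pmax(-1, sims))
  if (!is.null(gamma)) sims <- sims * pmin(n_co, gamma) / gamma
  sims
}

#' Predict a single rating by user-based CF
#'
#' @param rm a [ratings_matrix()].
#' @param user,item ids or indices; the item should be unrated by the user.
#' @param k_neighbors neighbourhood size (default 20); negative similarities
#'   are discarded.
#' @param method similarity method.
#' @param shrinkage added to the deviation denominator, pulling predictions
#'   with weak neighbourhood support toward the user mean (0 recovers the
#'   plain weighted-deviation formula).
#' @param significance co-rating count at which a similarity gets full
#'   weight (Herlocker-style significance weighting); `NULL` disables it.
#' @return Predicted rating, clipped to the rating scale.
#' @export
predict_rating <- function(rm, user, item, k_neighbors = 20L,
                           method = c("pearson", "cosine"),
                           shrinkage = 1, significance = 20) {
  method <- match.arg(method)
  m <- rm$matrix
  ui <- if (is.character(user)) match(user, rownames(m)) else as.integer(user)
  ii <- if (is.character(item)) match(item, colnames(m)) else as.integer(item)
  if (is.na(ui)) stop_field("user", "unknown user id")
  if (is.na(ii)) stop_field("item", "unknown item id")
  sims <- .sims_all(m, ui, method, gamma = significance)
  mu <- .user_means(m)
  pred <- .predict_one(m, ui, ii, sims, mu, k_neighbors,
                       shrinkage = shrinkage)
  pmin(rm$scale[2], pmax(rm$scale[1], pred))
}

.user_means <- function(m) {
  cnt <- Matrix::rowSums(m != 0)
  tot <- Matrix::rowSums(m)
  mu <- ifelse(cnt > 0, tot / cnt, NA_real_)
  global <- if (any(cnt > 0)) sum(tot) / sum(cnt) else 0
  ifelse(is.na(mu), global, mu)
}

# shrinkage: the deviation denominator carries a +1 so predictions backed by
# a single weak neighbour are pulled toward the user mean instead of pinning
# the top of the ranking
.predict_one <- function(m, ui, ii, sims, mu, k_neighbors, shrinkage = 1) {
  raters <- which(m[, ii] != 0)
  raters <- raters[raters != ui]
  s <- sims[raters]
  keep <- s > 0
  raters <- raters[keep]; s <- s[keep]
  if (!length(raters)) return(mu[ui])  # fallback: user mean (global-backed)
  if (length(raters) > k_neighbors) {
    ord <- order(s, decreasing = TRUE)[seq_len(k_neighbors)]
    raters <- raters[ord]; s <- s[ord]
  }
  dev <- m[raters, ii] - mu[raters]
  mu[ui] + sum(s * dev) / (sum(abs(s)) + shrinkage)
}

#' Top-N recommendations for a user
#'
#' Candidates default to the user's unrated items; ties in predicted score
#' are broken by item index.  Fewer candidates than N yields a shorter list
#' with a warning.
#'
#' @param rm a [ratings_matrix()].
#' @param user user id or index.
#' @param N list length.
#' @param candidates optional item ids restricting the candidate pool.
#' @param k_neighbors,method as in [predict_rating()].
#' @return Character vector of item ids, best first, with predicted scores
#'   in the `scores` attribute.
#' @export
top_n <- function(rm, user, N, candidates = NULL, k_neighbors = 20L,
                  method = c("pearson", "cosine")) {
  method <- match.arg(method)
  m <- rm$matrix
  ui <- if (is.character(user)) match(user, rownames(m)) else as.integer(user)
  if (is.na(ui)) stop_field("user", "unknown user id")
  cand <- if (is.null(candidates)) {
    which(m[ui, ] == 0)
  } else {
    ci <- match(candidates, colnames(m))
    if (anyNA(ci)) stop_field("candidates", "unknown item id")
    ci
  }
  if (length(cand) < N) {
    warning(sprintf("only %d candidates for N = %d", length(cand), N),
            call. = FALSE)
  }
  sims <- .sims_all(m, ui, method, gamma = 20)
  mu <- .user_means(m)
  preds <- vapply(cand, function(ii) {
    .predict_one(m, ui, ii, sims, mu, k_neighbors)
  }, numeric(1))
  ord <- order(-preds, cand)[seq_len(min(N, length(cand)))]
  out <- colnames(m)[cand[ord]]
  attr(out, "scores") <- pmin(rm$scale[2], pmax(rm$scale[1], preds[ord]))
  out
}

#' Per-user train/test split of a ratings matrix
#'
#' Holds out `test_frac` of each user's ratings (at least one when the user
#' has two or more), either at random or temporally (most recent ratings by
#' `timestamp` go to the test side).
#'
#' @param rm a [ratings_matrix()].
#' @param test_frac fraction held out per user (default 0.2).
#' @param scheme `"random"` or `"temporal"`.
#' @param seed integer seed.
#' @return List with `train` (a `ratings_matrix`) and `test` (long data
#'   frame of held-out ratings).
#' @export
split_ratings <- function(rm, test_frac = 0.2, scheme = c("random", "temporal"),
                          seed = 1L) {
  scheme <- match.arg(scheme)
  test_frac <- check_number(test_frac, "test_frac", lower = 0, upper = 1,
                            open_lower = TRUE, open_upper = TRUE)
  df <- rm$ratings
  with_seed(seed, {
    test_rows <- unlist(lapply(split(seq_len(nrow(df)), df$user_id),
                               function(rows) {
      if (length(rows) < 2L) return(integer(0))
      n_test <- max(1L, floor(test_frac * length(rows)))
      if (scheme == "temporal" && !is.null(df$timestamp) &&
          !anyNA(df$timestamp[rows])) {
        rows[order(df$timestamp[rows], decreasing = TRUE)][seq_len(n_test)]
      } else {
        sample(rows, n_test)
      }
    }), use.names = FALSE)
    train_df <- df[-test_rows, , drop = FALSE]
    # keep only test items that exist in the training item universe
    test_df <- df[test_rows, , drop = FALSE]
    test_df <- test_df[test_df$item_id %in% unique(train_df$item_id), ,
                       drop = FALSE]
    list(train = ratings_matrix(train_df, scale = rm$scale,
                                relevance = rm$relevance),
         test = test_df)
  })
}

#' Precision and recall at N over a grid
#'
#' For every user with at least one relevant held-out item (rating at or
#' above the relevance threshold), recommend the top `max(N_grid)` unrated
#' items once and read off hits for each N prefix:
#' precision@N = hits / N, recall@N = hits / n_relevant, macro-averaged.
#'
#' @param train a `ratings_matrix` (the training side of [split_ratings()]).
#' @param test held-out long data frame (`user_id`, `item_id`, `rating`).
#' @param N_grid integer vector of list lengths (default 2, 4, ..., 18).
#' @param k_neighbors,method as in [predict_rating()].
#' @param scorer optional function(train, user_id, candidate_ids) returning
#'   numeric scores -- replaces the CF predictor (used by non-CF pipeline
#'   variants); ties still break by item index.
#' @return An object of class `eval_result`: data frame `summary` (columns
#'   `N`, `precision`, `recall`) plus `per_user` hit counts.
#' @export
precision_recall_at_n <- function(train, test, N_grid = seq(2L, 18L, 2L),
                                  k_neighbors = 20L,
                                  method = c("pearson", "cosine"),
                                  scorer = NULL) {
  method <- match.arg(method)
  if (!nrow(test)) stop("empty test split", call. = FALSE)
  m <- train$matrix
  rel <- test[test$rating >= train$relevance, , drop = FALSE]
  rel <- rel[rel$user_id %in% rownames(m), , drop = FALSE]
  users <- unique(rel$user_id)
  if (!length(users)) stop("no user has relevant held-out items", call. = FALSE)
  n_max <- max(N_grid)
  mu <- .user_means(m)
  hits <- matrix(0, length(users), length(N_grid),
                 dimnames = list(users, paste0("N", N_grid)))
  n_rel <- stats::setNames(numeric(length(users)), users)
  for (k in seq_along(users)) {
    u <- users[k]
    ui <- match(u, rownames(m))
    cand <- which(m[ui, ] == 0)
    relevant <- unique(rel$item_id[rel$user_id == u])
    n_rel[k] <- length(relevant)
    if (!length(cand)) next
    preds <- if (is.null(scorer)) {
      sims <- .sims_all(m, ui, method, gamma = 20)
      vapply(cand, function(ii) {
        .predict_one(m, ui, ii, sims, mu, k_neighbors)
      }, numeric(1))
    } else {
      scorer(train, u, colnames(m)[cand])
    }
    ranked <- colnames(m)[cand[order(-preds, cand)]]
    ranked <- ranked[seq_len(min(n_max, length(ranked)))]
    hit_flags <- ranked %in% relevant
    for (g in seq_along(N_grid)) {
      hits[k, g] <- sum(hit_flags[seq_len(min(N_grid[g], length(hit_flags)))])
    }
  }
  summary <- data.frame(
    N = N_grid,
    precision = colMeans(sweep(hits, 2, N_grid, `/`)),
    recall = colMeans(hits / n_rel),
    row.names = NULL
  )
  structure(list(summary = summary, per_user = hits, n_relevant = n_rel),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("eval_result over %d users:\n", nrow(x$per_user)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
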