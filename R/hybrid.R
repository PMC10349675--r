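# Hybrid RFD-PSO wrapper feature selection.  Drops explore a layered feature
# graph (source -> increasing feature subsequence -> sink), so every
# source-to-sink walk is a candidate feature subset; subset fitness is the
# held-out error of a downstream model.  Good paths receive extra erosion,
# the best masks seed a PSO refinement in the [0,1]^D relaxation, and the
# refined global best reinforces the riverbed before the next exploration
# round.  The phase schedule is this package's documented reconstruction --
# the method's published description names the scheme without fixing it.

#' Feature graph for drop-based subset search
#'
#' Nodes: `source`, features `f1..fD`, `sink`; directed edges from source to
#' every feature, from each feature to every higher-indexed feature, and
#' from every feature to the sink; all distances 1.  Every source-to-sink
#' path visits a strictly increasing feature sequence, so paths and binary
#' masks are in bijection.
#'
#' @param n_features number of features D.
#' @param init_altitude starting altitude.
#' @return An `rfd_environment` with goal `sink` and attribute `source`.
#' @export
feature_graph <- function(n_features, init_altitude = 100) {
  n_features <- check_count(n_features, "n_features")
  f <- paste0("f", seq_len(n_features))
  src <- rep("source", n_features)
  e_src <- data.frame(src = src, dst = f, distance = 1,
                      stringsAsFactors = FALSE)
  pairs <- which(upper.tri(matrix(0, n_features, n_features)), arr.ind = TRUE)
  e_ff <- data.frame(src = f[pairs[, "row"]], dst = f[pairs[, "col"]],
                     distance = 1, stringsAsFactors = FALSE)
  e_sink <- data.frame(src = f, dst = rep("sink", n_features), distance = 1,
                       stringsAsFactors = FALSE)
  env <- rfd_environment(rbind(e_src, e_ff, e_sink), goal = "sink",
                         init_altitude = init_altitude, directed = TRUE)
  attr(env, "source") <- "source"
  attr(env, "n_features") <- n_features
  env
}

#' Convert a drop path on the feature graph to a binary mask
#'
#' @param path character vector of node names, `source` first, `sink` last
#'   (a `drop_path` from [move_drop()] is also accepted, resolved against
#'   `env`).
#' @param n_features mask length.
#' @param env the `feature_graph` environment (only needed for `drop_path`
#'   input).
#' @return Integer 0/1 vector of length `n_features`.
#' @export
path_to_mask <- function(path, n_features, env = NULL) {
  if (inherits(path, "drop_path")) {
    stopifnot(!is.null(env))
    path <- env$nodes[path$nodes]
  }
  if (path[1] != "source" || path[length(path)] != "sink") {
    stop("illegal path: must run source -> sink", call. = FALSE)
  }
  feats <- path[-c(1L, length(path))]
  idx <- as.integer(sub("^f", "", feats))
  if (anyNA(idx) || any(idx < 1L | idx > n_features) || is.unsorted(idx, strictly = TRUE)) {
    stop("illegal path: features must be a strictly increasing sequence",
         call. = FALSE)
  }
  mask <- integer(n_features)
  mask[idx] <- 1L
  mask
}

#' Convert a binary mask to its canonical feature-graph path
#'
#' @param mask integer 0/1 vector.
#' @return Character vector of node names (`source`, selected features in
#'   index order, `sink`).
#' @export
mask_to_path <- function(mask) {
  sel <- which(mask != 0)
  if (!length(sel)) return(c("source", "sink"))
  c("source", paste0("f", sel), "sink")
}

#' Wrapper evaluator: held-out k-nearest-neighbour accuracy
#'
#' Builds a deterministic evaluator over a [gen_feature_table()]-shaped
#' dataset: one fixed train/test split drawn from `seed`, then
#' `quality(mask)` = k-NN accuracy using only the masked columns.
#'
#' @param data a `labelled_features` list (`x`, `y`).
#' @param k neighbourhood size (default 3).
#' @param train_frac fraction of rows in the training side (default 0.7).
#' @param seed integer seed fixing the split.
#' @return A function `(mask) -> quality in [0, 1]`.
#' @export
make_knn_evaluator <- function(data, k = 3L, train_frac = 0.7, seed = 1L) {
  stopifnot(!is.null(data$x), !is.null(data$y))
  x <- as.matrix(data$x); y <- as.integer(data$y)
  n <- nrow(x)
  k <- check_count(k, "k")
  idx_train <- with_seed(seed, sample.int(n, floor(train_frac * n)))
  xtr <- x[idx_train, , drop = FALSE]; ytr <- y[idx_train]
  xte <- x[-idx_train, , drop = FALSE]; yte <- y[-idx_train]
  function(mask) {
    sel <- which(mask != 0)
    if (!length(sel)) return(0)
    a <- xte[, sel, drop = FALSE]
    b <- xtr[, sel, drop = FALSE]
    d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
      outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
    pred <- apply(d2, 1, function(row) {
      nb <- ytr[order(row)[seq_len(k)]]
      as.integer(mean(nb) >= 0.5)
    })
    mean(pred == yte)
  }
}

#' Wrapper evaluator: held-out precision at 10 of a feature-restricted CF
#' recommender
#'
#' User similarity is computed on rating-weighted item-feature profiles
#' restricted to the masked features; quality is mean precision@10 on the
#' held-out split.
#'
#' @param rm a [ratings_matrix()].
#' @param item_features binary items x features matrix (rows named by item
#'   id), e.g. from [fp_item_features()].
#' @param seed integer seed fixing the train/test split.
#' @param N list length for precision (default 10).
#' @return A function `(mask) -> quality in [0, 1]`.
#' @export
make_cf_evaluator <- function(rm, item_features, seed = 1L, N = 10L) {
  sp <- split_ratings(rm, seed = seed)
  f_all <- as.matrix(item_features)
  f_all <- f_all[colnames(sp$train$matrix), , drop = FALSE]
  function(mask) {
    sel <- which(mask != 0)
    if (!length(sel)) return(0)
    prof <- as.matrix(sp$train$matrix %*% f_all[, sel, drop = FALSE])
    scorer <- function(train, u, cand_ids) {
      p <- prof[match(u, rownames(train$matrix)), ]
      sims <- tcrossprod(prof, matrix(p, 1))[, 1]
      norms <- sqrt(rowSums(prof^2)) * sqrt(sum(p^2))
      sims <- ifelse(norms > 0, sims / norms, 0)
      sims[match(u, rownames(train$matrix))] <- 0
      m <- train$matrix
      ci <- match(cand_ids, colnames(m))
      vapply(ci, function(ii) {
        raters <- which(m[, ii] != 0)
        s <- sims[raters]
        keep <- s > 0
        if (!any(keep)) return(0)
        sum(s[keep] * m[raters[keep], ii]) / sum(s[keep])
      }, numeric(1))
    }
    res <- try(precision_recall_at_n(sp$train, sp$test, N_grid = N,
                                     scorer = scorer), silent = TRUE)
    if (inherits(res, "try-error")) return(0)
    res$summary$precision[1]
  }
}

#' Fitness of a feature subset
#'
#' `score = 1 - quality(mask) + lambda * sum(mask)`: minimisation, with an
#' optional per-feature cardinality penalty (default 0).  An empty mask gets
#' the worst score with a warning.
#'
#' @param mask integer 0/1 vector.
#' @param evaluator a quality function from [make_knn_evaluator()] or
#'   [make_cf_evaluator()].
#' @param lambda per-feature penalty (default 0).
#' @return Numeric score (lower is better).
#' @export
fitness <- function(mask, evaluator, lambda = 0) {
  if (!sum(mask != 0)) {
    warning("empty feature mask scored at worst fitness", call. = FALSE)
    return(1 + lambda)
  }
  1 - evaluator(mask) + lambda * sum(mask != 0)
}

# memoised minimising fitness with empty-mask guard (no warning storm inside
# optimisation loops); environment-backed cache keyed by the mask string
.make_cached_fitness <- function(evaluator, lambda = 0) {
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fn <- function(mask) {
    mask <- as.integer(mask != 0)
    if (!sum(mask)) return(1 + lambda)
    key <- paste(mask, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- 1 - evaluator(mask) + lambda * sum(mask)
    n_evals <<- n_evals + 1L
    cache[[key]] <- val
    val
  }
  attr(fn, "count") <- function() n_evals
  fn
}

#' Hybrid selection parameters
#'
#' Reconstruction knobs for the phase schedule; see the methods vignette for
#' the rationale behind each default.
#'
#' @param n_phases number of RFD-exploration / PSO-refinement rounds.
#' @param rfd_iters drop iterations per RFD phase.
#' @param pso_iters PSO iterations per refinement phase.
#' @param swarm_size particles per refinement (= top-k masks carried over).
#' @param threshold binarisation threshold on relaxed positions.
#' @param reinforce scale of the fitness-driven extra erosion on good paths.
#' @param gbest_bonus the small constant (times the erosion coefficient E)
#'   carved from the global-best path before the next exploration round.
#' @param lambda per-feature fitness penalty.
#' @param v_max velocity clamp of the refinement swarm (looser than the PSO
#'   default so bits can flip within a few iterations).
#' @return An object of class `hybrid_params`.
#' @export
hybrid_params <- function(n_phases = 3L, rfd_iters = 10L, pso_iters = 15L,
                          swarm_size = 12L, threshold = 0.5,
                          reinforce = 30, gbest_bonus = 0.1, lambda = 0,
                          v_max = 0.5) {
  structure(list(
    n_phases = check_count(n_phases, "n_phases"),
    rfd_iters = check_count(rfd_iters, "rfd_iters", min = 0L),
    pso_iters = check_count(pso_iters, "pso_iters", min = 0L),
    swarm_size = check_count(swarm_size, "swarm_size", min = 2L),
    threshold = check_number(threshold, "threshold", lower = 0, upper = 1,
                             open_lower = TRUE, open_upper = TRUE),
    reinforce = check_number(reinforce, "reinforce", lower = 0),
    gbest_bonus = check_number(gbest_bonus, "gbest_bonus", lower = 0),
    lambda = check_number(lambda, "lambda", lower = 0),
    v_max = check_number(v_max, "v_max", lower = 0, open_lower = TRUE)
  ), class = "hybrid_params")
}

# bookkeeping closure: best-so-far subset and running mean quality
.make_book <- function(n_features) {
  best_mask <- NULL; best_fit <- Inf
  q_sum <- 0; q_n <- 0
  trace <- numeric(0)
  list(
    note = function(mask, f) {
      q_sum <<- q_sum + (1 - f); q_n <<- q_n + 1
      if (f < best_fit) {
        best_fit <<- f
        best_mask <<- as.integer(mask != 0)
      }
      trace <<- c(trace, best_fit)
    },
    mean_quality = function() if (q_n > 0) q_sum / q_n else 0.5,
    best = function() list(mask = best_mask, fitness = best_fit),
    trace = function() trace
  )
}

#' Hybrid RFD-PSO wrapper feature selection
#'
#' Alternates (1) RFD exploration on the [feature_graph()], where each
#' goal-reaching drop path is scored as a feature mask and its fitness
#' drives extra erosion along the path; (2) PSO refinement, where the top
#' `swarm_size` distinct masks seen so far become particles in the
#' `[0, 1]^D` relaxation (re-binarised at `threshold` for every evaluation);
#' and (3) a small constant erosion bonus along the refined global-best
#' path before the next exploration round.  Returns the best subset ever
#' evaluated; fixed seed gives a fixed result.
#'
#' @param evaluator quality function from [make_knn_evaluator()] or
#'   [make_cf_evaluator()].
#' @param n_features number of features D.
#' @param hy a [hybrid_params()].
#' @param rfd_par an [rfd_params()] for the exploration drops.
#' @param seed integer seed.
#' @return An object of class `feature_subset`: `mask`, `fitness`,
#'   `provenance` (`"hybrid"`), `trace` (best fitness after each
#'   evaluation), `n_evaluations`.
#' @export
run_rfd_pso <- function(evaluator, n_features, hy = hybrid_params(),
                        rfd_par = rfd_params(), seed = 1L) {
  n_features <- check_count(n_features, "n_features", min = 2L)
  fit <- .make_cached_fitness(evaluator, hy$lambda)
  with_seed(seed, {
    env <- feature_graph(n_features, init_altitude = rfd_par$init_altitude)
    book <- .make_book(n_features)
    pool <- list()   # distinct masks seen, with fitness
    pool_note <- function(mask, f) {
      key <- paste(mask, collapse = "")
      if (is.null(pool[[key]]) || pool[[key]]$fitness > f) {
        pool[[key]] <<- list(mask = mask, fitness = f)
      }
    }
    # seed the pool with singletons' worth of random masks so a zero-phase
    # budget still returns the best of an initial random draw
    for (r in seq_len(hy$swarm_size)) {
      mask <- as.integer(stats::runif(n_features) < 0.3)
      if (!sum(mask)) mask[sample.int(n_features, 1L)] <- 1L
      f <- fit(mask)
      book$note(mask, f)
      pool_note(mask, f)
    }
    for (phase in seq_len(hy$n_phases)) {
      # (1) RFD exploration
      if (hy$rfd_iters > 0L) {
        n_feat_env <- attr(env, "n_features")
        for (it in seq_len(hy$rfd_iters)) {
          paths <- lapply(seq_len(rfd_par$n_drops), function(k) {
            move_drop(env, "source", rfd_par)
          })
          er <- erode(env, paths, rfd_par)
          env2 <- er$env
          attr(env2, "n_features") <- n_feat_env
          attr(env2, "source") <- "source"
          extra <- 0
          for (p in paths) {
            if (!p$reached_goal) next
            mask <- path_to_mask(env2$nodes[p$nodes], n_features)
            if (!sum(mask)) next
            f <- fit(mask)
            book$note(mask, f)
            pool_note(mask, f)
            adv <- (1 - f) - book$mean_quality()
            nds <- p$nodes[!env2$nodes[p$nodes] %in% c("source", "sink")]
            delta <- hy$reinforce * rfd_par$E * adv / max(1, length(nds))
            for (nd in nds) {
              old <- env2$altitude[nd]
              env2$altitude[nd] <- max(rfd_par$epsilon, old - delta)
              extra <- extra + (old - env2$altitude[nd])
            }
          }
          env <- deposit_sediment(env2, max(0, er$erosion_produced + extra))
          attr(env, "n_features") <- n_feat_env
          attr(env, "source") <- "source"
        }
      }
      # (2) PSO refinement of the top-k masks in the [0,1]^D relaxation
      if (hy$pso_iters > 0L) {
        ord <- order(vapply(pool, `[[`, numeric(1), "fitness"))
        top <- pool[ord][seq_len(min(hy$swarm_size, length(pool)))]
        n_sw <- hy$swarm_size
        x <- matrix(stats::runif(n_sw * n_features), n_sw, n_features)
        for (r in seq_along(top)) {
          # place particles at their mask, nudged off the threshold
          x[r, ] <- ifelse(top[[r]]$mask != 0, 0.8, 0.2) +
            stats::runif(n_features, -0.1, 0.1)
        }
        v <- matrix(stats::runif(n_sw * n_features, -hy$v_max, hy$v_max),
                    n_sw, n_features)
        ppar <- pso_params(dim = n_features, bounds = c(0, 1),
                           swarm_size = n_sw, max_iter = hy$pso_iters,
                           v_max = hy$v_max)
        binar <- function(xr) as.integer(xr >= hy$threshold)
        pfit <- vapply(seq_len(n_sw), function(r) fit(binar(x[r, ])),
                       numeric(1))
        for (r in seq_len(n_sw)) {
          book$note(binar(x[r, ]), pfit[r]); pool_note(binar(x[r, ]), pfit[r])
        }
        pbest <- x
        gi <- which.min(pfit)
        gbest <- x[gi, ]; gfit <- pfit[gi]
        for (it in seq_len(hy$pso_iters)) {
          w <- .pso_w_at(ppar, it)
          for (r in seq_len(n_sw)) {
            vn <- update_velocity(x[r, ], v[r, ], pbest[r, ], gbest, ppar,
                                  w = w)
            xn <- update_position(x[r, ], vn, ppar)
            v[r, ] <- attr(xn, "velocity")
            x[r, ] <- as.numeric(xn)
            mask <- binar(x[r, ])
            f <- fit(mask)
            book$note(mask, f)
            pool_note(mask, f)
            if (f < pfit[r]) {
              pfit[r] <- f; pbest[r, ] <- x[r, ]
              if (f < gfit) {
                gfit <- f; gbest <- x[r, ]
              }
            }
          }
        }
        # (3) small constant erosion bonus on the refined global-best path
        gmask <- binar(gbest)
        if (sum(gmask)) {
          nodes <- match(paste0("f", which(gmask != 0)), env$nodes)
          env$altitude[nodes] <- pmax(rfd_par$epsilon,
                                      env$altitude[nodes] -
                                        hy$gbest_bonus * rfd_par$E)
        }
      }
    }
    best <- book$best()
    structure(list(mask = best$mask, fitness = best$fitness,
                   provenance = "hybrid", trace = book$trace(),
                   n_evaluations = attr(fit, "count")()),
              class = "feature_subset")
  })
}

#' Pure-RFD feature selection (exploration phases only)
#'
#' @inheritParams run_rfd_pso
#' @param n_iter total drop iterations.
#' @return A `feature_subset` with provenance `"rfd"`.
#' @export
rfd_select <- function(evaluator, n_features, n_iter = 45L,
                       hy = hybrid_params(), rfd_par = rfd_params(),
                       seed = 1L) {
  n_features <- check_count(n_features, "n_features", min = 2L)
  fit <- .make_cached_fitness(evaluator, hy$lambda)
  with_seed(seed, {
    env <- feature_graph(n_features, init_altitude = rfd_par$init_altitude)
    book <- .make_book(n_features)
    for (it in seq_len(n_iter)) {
      paths <- lapply(seq_len(rfd_par$n_drops), function(k) {
        move_drop(env, "source", rfd_par)
      })
      er <- erode(env, paths, rfd_par)
      env2 <- er$env
      extra <- 0
      for (p in paths) {
        if (!p$reached_goal) next
        mask <- path_to_mask(env2$nodes[p$nodes], n_features)
        if (!sum(mask)) next
        f <- fit(mask)
        book$note(mask, f)
        adv <- (1 - f) - book$mean_quality()
        nds <- p$nodes[!env2$nodes[p$nodes] %in% c("source", "sink")]
        delta <- hy$reinforce * rfd_par$E * adv / max(1, length(nds))
        for (nd in nds) {
          old <- env2$altitude[nd]
          env2$altitude[nd] <- max(rfd_par$epsilon, old - delta)
          extra <- extra + (old - env2$altitude[nd])
        }
      }
      env <- deposit_sediment(env2, max(0, er$erosion_produced + extra))
      attr(env, "source") <- "source"
    }
    best <- book$best()
    if (is.null(best$mask)) {
      mask <- integer(n_features); mask[1L] <- 1L
      best <- list(mask = mask, fitness = fit(mask))
    }
    structure(list(mask = best$mask, fitness = best$fitness,
                   provenance = "rfd", trace = book$trace(),
                   n_evaluations = attr(fit, "count")()),
              class = "feature_subset")
  })
}

#' Pure-PSO feature selection (relaxed binary masks)
#'
#' @inheritParams run_rfd_pso
#' @param swarm_size,max_iter swarm shape.
#' @return A `feature_subset` with provenance `"pso"`.
#' @export
pso_select <- function(evaluator, n_features, swarm_size = 12L,
                       max_iter = 45L, hy = hybrid_params(), seed = 1L) {
  n_features <- check_count(n_features, "n_features", min = 2L)
  fit <- .make_cached_fitness(evaluator, hy$lambda)
  with_seed(seed, {
    book <- .make_book(n_features)
    ppar <- pso_params(dim = n_features, bounds = c(0, 1),
                       swarm_size = swarm_size, max_iter = max_iter,
                       v_max = hy$v_max)
    binar <- function(xr) as.integer(xr >= hy$threshold)
    obj <- function(xr) {
      mask <- binar(xr)
      f <- fit(mask)
      book$note(mask, f)
      f
    }
    res <- run_pso(obj, ppar)
    best <- book$best()
    structure(list(mask = best$mask, fitness = best$fitness,
                   provenance = "pso", trace = book$trace(),
                   n_evaluations = attr(fit, "count")()),
              class = "feature_subset")
  })
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("feature_subset (%s): %d of %d features, fitness %.4f (%d evaluations)\n",
              x$provenance, sum(x$mask), length(x$mask), x$fitness,
              x$n_evaluations))
  invisible(x)
}

#' Frequent-pattern item features for the recommender
#'
#' Treats each user's relevant item set as a transaction, mines frequent
#' item co-occurrence patterns with the systolic tree, and returns a binary
#' items x patterns membership matrix -- the wiring by which mined patterns
#' feed the feature selector and the CF evaluator.
#'
#' @param rm a [ratings_matrix()].
#' @param min_support_frac fractional support threshold (default 0.1).
#' @param max_patterns cap on the number of pattern columns (most frequent
#'   kept; default 30).
#' @return Binary matrix, rows = item ids, columns = mined patterns
#'   (`size >= 2` patterns preferred, padded with singletons when scarce).
#' @export
fp_item_features <- function(rm, min_support_frac = 0.1, max_patterns = 30L) {
  m <- rm$matrix
  tx <- lapply(seq_len(nrow(m)), function(u) {
    colnames(m)[which(m[u, ] >= rm$relevance)]
  })
  tx <- tx[lengths(tx) > 0]
  if (!length(tx)) stop("no relevant item sets to mine", call. = FALSE)
  db <- transaction_db(tx)
  res <- mine_frequent(db, min_support_frac = min_support_frac)
  if (!nrow(res)) stop("no frequent patterns at this support", call. = FALSE)
  res <- res[order(-(lengths(res$itemset) > 1), -res$support), , drop = FALSE]
  res <- utils::head(res, max_patterns)
  items <- colnames(m)
  out <- vapply(res$itemset, function(s) as.numeric(items %in% s),
                numeric(length(items)))
  rownames(out) <- items
  colnames(out) <- res$items
  out
}
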