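test_that("feature graph paths and masks are in bijection", {
  env <- feature_graph(5)
  expect_identical(path_to_mask(c("source", "f2", "f5", "sink"), 5),
                   c(0L, 1L, 0L, 0L, 1L))
  expect_identical(path_to_mask(c("source", "sink"), 5), integer(5))
  expect_error(path_to_mask(c("f1", "sink"), 5), "illegal")
  expect_error(path_to_mask(c("source", "f3", "f2", "sink"), 5), "illegal")

  set.seed(101)
  for (rep in 1:25) {
    mask <- as.integer(runif(8) < 0.5)
    expect_identical(path_to_mask(mask_to_path(mask), 8), mask)
  }

  # every drop walk on the graph is a legal increasing path
  set.seed(102)
  for (rep in 1:10) {
    p <- move_drop(env, "source", rfd_params())
    if (p$reached_goal) {
      expect_silent(path_to_mask(env$nodes[p$nodes], 5))
    }
  }
})

test_that("fitness contracts: empty mask, determinism, informative signal", {
  data <- gen_feature_table(300, 6, 2, seed = 103, effect_size = 3)
  ev <- make_knn_evaluator(data, seed = 1)
  expect_warning(f <- fitness(integer(6), ev), "empty")
  expect_equal(f, 1)

  mask <- as.integer(seq_len(6) %in% data$informative)
  expect_identical(fitness(mask, ev), fitness(mask, ev))
  # informative features separate well on strongly separable data
  expect_lt(fitness(mask, ev), 0.25)
  # the cardinality penalty adds lambda per selected feature
  expect_equal(fitness(mask, ev, lambda = 0.01),
               fitness(mask, ev) + 0.01 * sum(mask))
})

test_that("selector recovers the informative feature in a two-feature world", {
  # only three non-empty masks exist; the informative one must win
  for (s in 1:10) {
    data <- gen_feature_table(300, 2, 1, seed = 200 + s, effect_size = 3)
    ev <- make_knn_evaluator(data, seed = s)
    res <- run_rfd_pso(ev, 2,
                       hy = hybrid_params(n_phases = 1, rfd_iters = 3,
                                          pso_iters = 3, swarm_size = 4),
                       seed = s)
    expect_true(data$informative %in% which(res$mask == 1L))
  }
})

test_that("hybrid selection is deterministic and degrades gracefully", {
  data <- gen_feature_table(300, 8, 2, seed = 105, effect_size = 3)
  ev <- make_knn_evaluator(data, seed = 2)
  a <- run_rfd_pso(ev, 8, hy = hybrid_params(n_phases = 1, rfd_iters = 4,
                                             pso_iters = 4), seed = 7)
  b <- run_rfd_pso(ev, 8, hy = hybrid_params(n_phases = 1, rfd_iters = 4,
                                             pso_iters = 4), seed = 7)
  expect_identical(a$mask, b$mask)
  expect_identical(a$fitness, b$fitness)

  # zero-iteration budget returns the best of the initial random masks
  z <- run_rfd_pso(ev, 8, hy = hybrid_params(n_phases = 1, rfd_iters = 0,
                                             pso_iters = 0), seed = 7)
  expect_gte(sum(z$mask), 1)
  expect_lte(z$n_evaluations, hybrid_params()$swarm_size)

  # best-so-far trace is monotone non-increasing
  expect_true(all(diff(a$trace) <= 1e-12))
})

test_that("hybrid matches or beats the pure strategies on most tasks", {
  wins <- 0L
  n_tasks <- 10L
  for (s in seq_len(n_tasks)) {
    data <- gen_feature_table(400, 15, 3, seed = 300 + s, effect_size = 2)
    ev <- make_knn_evaluator(data, seed = s)
    hyb <- run_rfd_pso(ev, 15, seed = s)
    rfd <- rfd_select(ev, 15, n_iter = 45, seed = s)
    pso <- pso_select(ev, 15, swarm_size = 12, max_iter = 38, seed = s)
    wins <- wins + (hyb$fitness <= min(rfd$fitness, pso$fitness))
  }
  expect_gte(wins / n_tasks, 0.7)
})

test_that("fp_item_features produces binary pattern membership columns", {
  spec <- synthetic_spec(seed = 106, n_users = 60, n_items = 20,
                         density = 0.5)
  rm <- gen_ratings(spec)
  f <- fp_item_features(rm, min_support_frac = 0.15, max_patterns = 10)
  expect_identical(rownames(f), colnames(rm$matrix))
  expect_true(all(f %in% c(0, 1)))
  expect_lte(ncol(f), 10)
  # each pattern column marks exactly its member items
  pat <- strsplit(colnames(f)[1], " ")[[1]]
  expect_identical(unname(which(f[, 1] == 1)), which(rownames(f) %in% pat))
})

test_that("the CF evaluator scores masks deterministically", {
  spec <- synthetic_spec(seed = 107, n_users = 80, n_items = 25,
                         density = 0.4)
  rm <- gen_ratings(spec)
  f <- fp_item_features(rm, min_support_frac = 0.1, max_patterns = 8)
  ev <- make_cf_evaluator(rm, f, seed = 3)
  mask <- rep(1L, ncol(f))
  q1 <- ev(mask)
  expect_identical(q1, ev(mask))
  expect_gte(q1, 0)
  expect_lte(q1, 1)
})
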