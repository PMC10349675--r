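# helper: star environment with one centre node `i` and leaves at chosen
# altitudes, so gradients from `i` are exactly altitude(i) - altitude(leaf)
star_env <- function(leaf_altitudes, centre_altitude = 10) {
  leaves <- paste0("n", seq_along(leaf_altitudes))
  env <- rfd_environment(
    data.frame(src = "i", dst = leaves, distance = 1),
    goal = leaves[1], directed = TRUE)
  env$altitude[match("i", env$nodes)] <- centre_altitude
  env$altitude[match(leaves, env$nodes)] <- leaf_altitudes
  env$altitude[env$goal] <- leaf_altitudes[1]
  env
}

test_that("gradient is the altitude drop over distance", {
  env <- rfd_environment(data.frame(src = "a", dst = "b", distance = 2),
                         goal = "b", directed = TRUE)
  env$altitude[match("a", env$nodes)] <- 10
  env$altitude[match("b", env$nodes)] <- 4
  expect_equal(gradient(env, "a", "b"), 3)
  expect_error(gradient(env, "b", "a"), "no edge")

  # equal altitudes give zero; antisymmetry at unit distance
  e2 <- rfd_environment(data.frame(src = c("a", "b"), dst = c("b", "a"),
                                   distance = 1), goal = "b", directed = TRUE)
  e2$altitude <- c(7, 7)
  expect_equal(gradient(e2, "a", "b"), 0)
  e2$altitude <- c(9, 5)
  expect_equal(gradient(e2, "a", "b"), -gradient(e2, "b", "a"))
})

test_that("transition probabilities match the three-branch rule", {
  # downhill gradients {3, 1}, one flat, one uphill gradient -2
  env <- star_env(c(7, 9, 10, 12))
  p <- transition_probabilities(env, "i", rfd_params(omega = 0.5, delta = 1))
  expect_equal(p$total, 5.25)
  got <- p$prob[match(paste0("n", 1:4), env$nodes[p$neighbors])]
  expect_equal(got, c(0.5714, 0.1905, 0.1905, 0.0476), tolerance = 1e-3)
  expect_equal(sum(p$prob), 1, tolerance = 1e-12)

  # single downhill neighbour takes all the mass
  env1 <- star_env(4)
  p1 <- transition_probabilities(env1, "i", rfd_params())
  expect_equal(p1$prob, 1)

  # all flat: uniform
  envf <- star_env(c(10, 10, 10))
  pf <- transition_probabilities(envf, "i", rfd_params())
  expect_equal(pf$prob, rep(1 / 3, 3))

  # isolated node (all neighbours excluded) errors
  expect_error(transition_probabilities(env1, "i", rfd_params(),
                                        exclude = "n1"),
               "admissible")
})

test_that("probability normalisation holds on random environments", {
  set.seed(71)
  for (rep in 1:100) {
    alts <- runif(sample(2:6, 1), 0, 20)
    env <- star_env(alts, centre_altitude = runif(1, 0, 20))
    p <- transition_probabilities(env, "i",
                                  rfd_params(omega = runif(1, 0.1, 2),
                                             delta = runif(1, 0.05, 1)))
    expect_equal(sum(p$prob), 1, tolerance = 1e-9)
  }
})

test_that("move_drop walks legally and respects the length cap", {
  # start at goal
  env <- grid_environment(3)
  p <- move_drop(env, env$nodes[env$goal], rfd_params())
  expect_identical(p$nodes, env$goal)
  expect_true(p$reached_goal)

  # strictly decreasing chain is deterministic
  chain <- rfd_environment(
    data.frame(src = c("a", "b", "c"), dst = c("b", "c", "d"), distance = 1),
    goal = "d", directed = TRUE)
  chain$altitude <- c(30, 20, 10, 0)[match(c("a", "b", "c", "d"),
                                           chain$nodes)]
  p <- move_drop(chain, "a", rfd_params())
  expect_identical(chain$nodes[p$nodes], c("a", "b", "c", "d"))
  expect_equal(p$cost, 3)

  # legality and length bound on a grid with random walks
  env <- grid_environment(4)
  set.seed(72)
  for (rep in 1:20) {
    p <- move_drop(env, "r1c1", rfd_params())
    expect_lte(length(p$nodes), length(env$nodes))
    for (s in seq_len(length(p$nodes) - 1)) {
      expect_true(p$nodes[s + 1] %in% env$adj[[p$nodes[s]]])
    }
  }
})

test_that("sampled fork frequencies match the stated probabilities", {
  # two-leaf fork: downhill gradients 3 and 1 -> P = 0.75 / 0.25
  env <- star_env(c(7, 9))
  env$altitude[env$goal] <- 7
  set.seed(73)
  picks <- replicate(1000, {
    p <- move_drop(env, "i", rfd_params(delta = 1e-9))
    env$nodes[p$nodes[2]]
  })
  phat <- mean(picks == "n1")
  se <- sqrt(0.75 * 0.25 / 1000)
  expect_lt(abs(phat - 0.75), 3 * se)
})

test_that("erode applies the per-pair rule and conserves soil via sediment", {
  # E=4, N=5, D=2, gradient 2 -> decrement 1.0
  chain <- rfd_environment(
    data.frame(src = c("a", "b", "c", "d"), dst = c("b", "c", "d", "e"),
               distance = 1), goal = "e", directed = TRUE)
  chain$altitude[match(c("a", "b"), chain$nodes)] <- c(12, 10)
  par <- rfd_params(E = 4, n_drops = 2, sediment_fraction = 0)
  path <- structure(list(nodes = match(c("a", "b"), chain$nodes),
                         reached_goal = FALSE, cost = Inf),
                    class = "drop_path")
  er <- erode(chain, list(path), par)
  expect_equal(chain$altitude[match("a", chain$nodes)] -
                 er$env$altitude[match("a", chain$nodes)], 1.0)
  expect_equal(er$erosion_produced, 1.0)

  # empty path set: nothing changes
  er0 <- erode(chain, list(), par)
  expect_identical(er0$env$altitude, chain$altitude)
  expect_equal(er0$erosion_produced, 0)

  # uphill step raises the node (signed rule)
  up <- chain
  up$altitude[match(c("a", "b"), up$nodes)] <- c(10, 12)
  eru <- erode(up, list(path), par)
  expect_gt(eru$env$altitude[match("a", up$nodes)], 10)

  # deposit: erosion 6 over N=4 -> +2 per non-goal node, total conserved
  env4 <- rfd_environment(
    data.frame(src = c("a", "b", "c"), dst = c("b", "c", "d"), distance = 1),
    goal = "d", directed = TRUE)
  before <- env4$altitude
  after <- deposit_sediment(env4, 6)
  delta <- after$altitude - before
  expect_equal(unname(delta[-env4$goal]), rep(2, 3))
  expect_equal(sum(delta), 6)
  expect_equal(after$altitude[env4$goal], 0)
  expect_identical(deposit_sediment(env4, 0)$altitude, env4$altitude)
})

test_that("run_rfd solves trivial and grid routing problems deterministically", {
  two <- rfd_environment(data.frame(src = "s", dst = "g", distance = 1),
                         goal = "g")
  attr(two, "source") <- "s"
  r <- run_rfd(two, params = rfd_params(max_iter = 5, patience = 2), seed = 1)
  expect_identical(r$best_path, c("s", "g"))
  expect_equal(r$best_cost, 1)

  env <- grid_environment(6)
  r1 <- run_rfd(env, params = rfd_params(max_iter = 60, patience = 15),
                seed = 99)
  r2 <- run_rfd(env, params = rfd_params(max_iter = 60, patience = 15),
                seed = 99)
  expect_identical(r1$best_path, r2$best_path)
  expect_identical(r1$history, r2$history)
  expect_true(r1$reached_goal)
  # best-cost history is non-increasing
  h <- r1$history[is.finite(r1$history)]
  expect_true(all(diff(h) <= 0))

  # a goal no drop can reach reports an explicit no-solution result
  one_way <- rfd_environment(data.frame(src = c("g", "s"), dst = c("s", "x"),
                                        distance = 1),
                             goal = "g", directed = TRUE)
  rno <- run_rfd(one_way, start = "s",
                 params = rfd_params(max_iter = 5, patience = 2), seed = 3)
  expect_false(rno$reached_goal)
  expect_null(rno$best_path)
  expect_identical(rno$best_cost, Inf)

  # a goal absent from the graph is a validation error
  expect_error(rfd_environment(data.frame(src = "s", dst = "x", distance = 1),
                               goal = "g"), "goal")
})
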