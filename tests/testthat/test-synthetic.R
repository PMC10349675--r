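test_that("synthetic_spec validates its fields", {
  expect_s3_class(synthetic_spec(), "synthetic_spec")
  expect_error(synthetic_spec(density = 0), "density")
  expect_error(synthetic_spec(density = 1.2), "density")
  expect_error(synthetic_spec(n_users = 0), "n_users")
  expect_error(synthetic_spec(n_features = 4, n_informative = 5),
               "n_informative")
})

test_that("gen_ratings honours the latent model and the density contract", {
  # noiseless full world: observed ratings are exactly the clipped, rounded
  # latent scores retained as ground truth
  spec <- synthetic_spec(seed = 3, n_users = 20, n_items = 15, n_factors = 1,
                         noise_sd = 0, density = 1)
  r <- gen_ratings(spec)
  u <- attr(r, "user_factors"); v <- attr(r, "item_factors")
  full <- u %*% t(v)
  full <- 3 + 1.5 * full / sd(full)
  expected <- matrix(pmin(5, pmax(1, round(full))), 20, 15)
  got <- as.matrix(r$matrix)
  got <- got[paste0("u", 1:20), paste0("i", 1:15)]
  expect_equal(unname(got), expected)

  # determinism
  r2 <- gen_ratings(spec)
  expect_identical(r$ratings, r2$ratings)

  # observed-cell count at partial density
  spec <- synthetic_spec(seed = 7, n_users = 50, n_items = 100, density = 0.1)
  r <- gen_ratings(spec)
  expect_lte(abs(nrow(r$ratings) - 500), 1)
  expect_true(all(r$ratings$rating >= 1 & r$ratings$rating <= 5))
})

test_that("gen_transactions plants recoverable patterns", {
  db <- gen_transactions(5, list(list(items = c("a", "b"), freq = 3L)),
                         seed = 2)
  expect_gte(brute_support(db, c("a", "b")), 3)

  # no patterns, no noise: all transactions empty
  db0 <- gen_transactions(4, seed = 1)
  expect_true(all(lengths(db0$transactions) == 0))
  expect_length(db0, 4)

  # planted plan recovered exactly by brute-force counting (no noise)
  db2 <- gen_transactions(5, list(list(items = c("a", "b"), freq = 3L),
                                  list(items = "c", freq = 4L)), seed = 5)
  expect_identical(brute_support(db2, c("a", "b")), 3L)
  expect_identical(brute_support(db2, "c"), 4L)

  expect_error(gen_transactions(3, list(list(items = "a", freq = 4L))),
               "frequency")
})

test_that("gen_corpus plants class-conditional signal words", {
  spec <- synthetic_spec(seed = 11, n_docs = 10, vocab_size = 100)
  corp <- gen_corpus(spec)
  expect_identical(as.integer(table(corp$label)), c(5L, 5L))

  sig_freq <- function(corp) {
    toks <- strsplit(corp$text, " ", fixed = TRUE)
    rate <- vapply(toks, function(t) mean(t %in% corp$signal_words),
                   numeric(1))
    c(neg = mean(rate[corp$label == "neg"]),
      pos = mean(rate[corp$label == "pos"]))
  }
  big <- synthetic_spec(seed = 12, n_docs = 2000, vocab_size = 100,
                        signal_strength = 5)
  f <- sig_freq(gen_corpus(big))
  expect_gt(f["pos"], 2 * f["neg"])

  null <- synthetic_spec(seed = 13, n_docs = 2000, vocab_size = 100,
                         signal_strength = 0)
  f0 <- sig_freq(gen_corpus(null))
  expect_lt(abs(f0["pos"] - f0["neg"]), 0.02)
})

test_that("gen_actigraphy emits per-minute records with the planted group effect", {
  spec <- synthetic_spec(seed = 21, n_subjects = 2, n_days = 1)
  b <- gen_actigraphy(spec)
  expect_length(b$records, 2)
  expect_identical(nrow(b$records[[1]]), 1440L)
  expect_named(b$records[[1]], c("timestamp", "date", "activity"))
  expect_setequal(names(b$groups), b$scores$number)

  daytime_mean <- function(b, group) {
    ids <- names(b$groups)[b$groups == group]
    mean(vapply(ids, function(id) {
      d <- b$records[[id]]
      hr <- as.integer(substr(d$timestamp, 12, 13))
      mean(d$activity[hr >= 8 & hr < 20])
    }, numeric(1)))
  }
  big <- synthetic_spec(seed = 22, n_subjects = 20, n_days = 7)
  b5 <- gen_actigraphy(big, attenuation = 0.5)
  ratio <- daytime_mean(b5, "condition") / daytime_mean(b5, "control")
  expect_lt(abs(ratio - 0.5), 0.07)

  b0 <- gen_actigraphy(big, attenuation = 0)
  ratio0 <- daytime_mean(b0, "condition") / daytime_mean(b0, "control")
  expect_lt(abs(ratio0 - 1), 0.05)
})

test_that("gen_feature_table separates informative from noise columns", {
  d <- gen_feature_table(100, 10, 3, seed = 4)
  d2 <- gen_feature_table(100, 10, 3, seed = 4)
  expect_identical(d, d2)
  expect_length(d$informative, 3)

  # null world: labels carry no signal
  d0 <- gen_feature_table(2000, 10, 0, seed = 5)
  expect_length(d0$informative, 0)
  expect_lt(max(abs(cor(d0$x, d0$y))), 0.08)

  # univariate AUC (rank-sum) of informative columns beats noise on average
  d5 <- gen_feature_table(2000, 20, 5, seed = 6)
  auc <- vapply(seq_len(20), function(j) {
    r <- rank(d5$x[, j])
    n1 <- sum(d5$y == 1)
    n0 <- sum(d5$y == 0)
    a <- (sum(r[d5$y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
    abs(a - 0.5)
  }, numeric(1))
  expect_gt(mean(auc[d5$informative]), mean(auc[-d5$informative]))
})
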