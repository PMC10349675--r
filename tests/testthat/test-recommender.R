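test_that("similarity follows the co-rated conventions", {
  df <- ratings_df(rep(c("u", "v"), each = 3), rep(c("i1", "i2", "i3"), 2),
                   c(5, 3, 1, 1, 3, 5))
  rm <- ratings_matrix(df)
  expect_equal(similarity(rm, "u", "v", "pearson"), -1)
  expect_equal(similarity(rm, "u", "u", "cosine"), 1)
  expect_error(similarity(rm, "u", "v", "manhattan"))

  # one co-rated item -> 0 by convention
  df1 <- ratings_df(c("u", "u", "v"), c("i1", "i2", "i1"), c(5, 4, 5))
  expect_equal(similarity(ratings_matrix(df1), "u", "v", "pearson"), 0)

  # constant co-rated vector -> 0
  dfc <- ratings_df(rep(c("u", "v"), each = 2), rep(c("i1", "i2"), 2),
                    c(3, 3, 2, 5))
  expect_equal(similarity(ratings_matrix(dfc), "u", "v", "pearson"), 0)
})

test_that("predict_rating uses the neighbour formula with fallbacks", {
  # v co-rates i1,i2 identically with u (sim 1) and rated i3 one point above
  # own mean: prediction = mean(u) + 1 at zero shrinkage
  df <- ratings_df(c("u", "u", "v", "v", "v"),
                   c("i1", "i2", "i1", "i2", "i3"),
                   c(4, 2, 4, 2, 4))
  rm <- ratings_matrix(df)
  # mean(v) over i1,i2,i3 = 10/3; deviation on i3 = 4 - 10/3 = 2/3
  expect_equal(predict_rating(rm, "u", "i3", shrinkage = 0,
                              significance = NULL),
               3 + 2 / 3)

  # no neighbour rated the item -> user mean
  df2 <- ratings_df(c("u", "u", "w"), c("i1", "i2", "i9"), c(5, 3, 2))
  rm2 <- ratings_matrix(df2)
  expect_equal(predict_rating(rm2, "u", "i9"), 4)

  # prediction clipped to the scale
  df3 <- ratings_df(c("u", "u", "v", "v", "v"),
                    c("i1", "i2", "i1", "i2", "i3"),
                    c(5, 5, 5, 5, 5))
  expect_lte(predict_rating(ratings_matrix(df3), "u", "i3"), 5)
})

test_that("top_n ranks by prediction with index tie-breaks", {
  spec <- synthetic_spec(seed = 91, n_users = 30, n_items = 20, density = 0.5)
  rm <- gen_ratings(spec)
  lst <- top_n(rm, "u1", 5)
  expect_lte(length(lst), 5)
  expect_true(all(!lst %in% colnames(rm$matrix)[rm$matrix["u1", ] != 0]))
  sc <- attr(lst, "scores")
  expect_true(all(diff(sc) <= 1e-12))

  # ties: a user with no usable neighbours gets constant predictions ->
  # candidates come back in item-index order
  df <- ratings_df(c("u", "v"), c("i1", "i5"), c(4, 4))
  rmt <- ratings_matrix(df)
  expect_warning(lst2 <- top_n(rmt, "u", 3), "candidates")
  expect_identical(as.character(lst2), "i5")

  dfb <- ratings_df(c("u", "v", "v", "v"), c("i9", "i1", "i2", "i3"),
                    c(4, 4, 4, 4))
  rmb <- ratings_matrix(dfb)
  lst3 <- top_n(rmb, "u", 3)
  expect_identical(as.character(lst3), c("i1", "i2", "i3"))
})

test_that("split_ratings holds out per-user fractions reproducibly", {
  spec <- synthetic_spec(seed = 92, n_users = 40, n_items = 30, density = 0.4)
  rm <- gen_ratings(spec)
  sp <- split_ratings(rm, seed = 9)
  sp2 <- split_ratings(rm, seed = 9)
  expect_identical(sp$test, sp2$test)
  expect_identical(nrow(sp$test) + nrow(sp$train$ratings), nrow(rm$ratings))
  # roughly 20% per user
  frac <- nrow(sp$test) / nrow(rm$ratings)
  expect_lt(abs(frac - 0.2), 0.07)

  # temporal scheme holds out the most recent ratings
  spt <- split_ratings(rm, scheme = "temporal", seed = 9)
  u <- spt$test$user_id[1]
  expect_gte(min(spt$test$timestamp[spt$test$user_id == u]),
             max(spt$train$ratings$timestamp[spt$train$ratings$user_id == u]))
})

test_that("precision and recall at N count hits per the definitions", {
  # constructed case: 6 relevant, a scorer that puts 3 relevant in the top 4
  train_df <- ratings_df(c("u", paste0("v", 1:10)),
                         c("i0", paste0("i", 1:10)),
                         c(4, rep(4, 10)))
  train <- ratings_matrix(train_df)
  test_df <- data.frame(user_id = "u", item_id = paste0("i", 1:6),
                        rating = 5)
  scorer <- function(train, u, cand) {
    # ranks i1, i2, i7, i3 on top: exactly 3 of the first 4 are relevant
    pref <- c(i1 = 10, i2 = 9, i7 = 8, i3 = 7)
    out <- pref[cand]
    out[is.na(out)] <- 0
    unname(out)
  }
  res <- precision_recall_at_n(train, test_df, N_grid = 4, scorer = scorer)
  expect_equal(res$summary$precision, 0.75)
  expect_equal(res$summary$recall, 0.5)

  # every candidate recommended: recall saturates at 1
  res2 <- precision_recall_at_n(train, test_df, N_grid = 10, scorer = scorer)
  expect_equal(res2$summary$recall, 1)
  expect_equal(res2$summary$precision, 0.6)
  test_small <- test_df[1:3, ]
  res3 <- precision_recall_at_n(train, test_small, N_grid = 4,
                                scorer = scorer)
  expect_equal(res3$summary$recall, 1)

  expect_error(precision_recall_at_n(train, test_df[0, ]), "empty")
})

test_that("recall is non-decreasing in N and random lists hit at base rate", {
  spec <- synthetic_spec(seed = 93, n_users = 60, n_items = 40, density = 0.4)
  rm <- gen_ratings(spec)
  sp <- split_ratings(rm, seed = 3)
  res <- precision_recall_at_n(sp$train, sp$test, N_grid = seq(2, 18, 2))
  expect_true(all(diff(res$summary$recall) >= -1e-12))
  expect_true(all(res$summary$precision >= 0 & res$summary$precision <= 1))

  # a random scorer's precision approximates the base relevance rate
  base_rates <- c(); precs <- c()
  for (s in 1:10) {
    rnd_scorer <- local({
      s0 <- s
      function(train, u, cand) {
        set.seed(s0 * 1000L + match(u, rownames(train$matrix)))
        stats::runif(length(cand))
      }
    })
    res_r <- precision_recall_at_n(sp$train, sp$test, N_grid = 10,
                                   scorer = rnd_scorer)
    m <- sp$train$matrix
    rel <- sp$test[sp$test$rating >= 4, ]
    users <- rownames(res_r$per_user)
    base <- mean(vapply(users, function(u) {
      n_cand <- sum(m[match(u, rownames(m)), ] == 0)
      sum(rel$user_id == u) / n_cand
    }, numeric(1)))
    base_rates <- c(base_rates, base)
    precs <- c(precs, res_r$summary$precision)
  }
  expect_lt(abs(mean(precs) - mean(base_rates)), 0.02)
})
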