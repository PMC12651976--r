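# Small separable toy: one informative feature per class, wide margins.
separable_table <- function(n_per = 8, seed = 1) {
  planted_feature_table(seed, n_per = n_per, shift = 6)
}

test_that("the SVM fits separable data and rejects degenerate labels", {
  tbl <- separable_table()
  std <- zscore_fit(tbl)
  m <- train_svm(zscore_apply(std, tbl))
  expect_equal(mean(predict(m, zscore_apply(std, tbl)) == tbl$label), 1)
  one <- tbl[tbl$label == "crown", ]
  expect_error(train_svm(one), "degenerate")
})

test_that("duplicating a feature column matches the single column at halved gamma", {
  withr::with_seed(5, {
    n <- 40
    x <- c(rnorm(n, -2), rnorm(n, 2))
    tbl <- tibble::tibble(Contrast0 = x, label = rep(c("filling", "crown"), each = n))
    tbl2 <- tbl
    tbl2$Contrast45 <- tbl2$Contrast0
    te <- tibble::tibble(Contrast0 = seq(-3, 3, length.out = 25))
    te2 <- te
    te2$Contrast45 <- te2$Contrast0
    m1 <- train_svm(tbl, C = 10, gamma = 0.2, features = "Contrast0")
    m2 <- train_svm(tbl2, C = 10, gamma = 0.1,
                    features = c("Contrast0", "Contrast45"))
    expect_identical(predict(m1, te), predict(m2, te2))
  })
})

test_that("grid search breaks ties toward the smaller C then smaller gamma", {
  tbl <- separable_table(n_per = 10)
  std <- zscore_fit(tbl)
  gs <- grid_search_svm(zscore_apply(std, tbl), folds = 3, seed = 2)
  top <- gs$results[abs(gs$results$accuracy - max(gs$results$accuracy)) < 1e-12, ]
  top <- top[order(top$C, top$gamma), ]
  expect_equal(gs$C, top$C[1])
  expect_equal(gs$gamma, top$gamma[1])
})

test_that("the fitness evaluator scores masks deterministically from training rows only", {
  tbl <- separable_table(n_per = 10)
  std <- zscore_fit(tbl)
  ev <- fitness_evaluator(zscore_apply(std, tbl), folds = 3, seed = 4)

  # all five informative features: perfect internal-CV accuracy
  mask <- rep(FALSE, 25); mask[c(3, 8, 13, 19, 24)] <- TRUE
  expect_equal(evaluator_accuracy(ev, mask), 1)

  # identical (mask, seed) -> identical accuracy
  expect_identical(evaluator_accuracy(ev, mask), evaluator_accuracy(ev, mask))
  expect_error(evaluator_accuracy(ev, rep(FALSE, 25)), "empty mask")
  expect_error(fitness_evaluator(tbl[1:3, ], folds = 5), "fold error")
})

test_that("pure-noise features give chance-level wrapper accuracy", {
  tbl <- planted_feature_table(11, n_per = 40, shift = 0)   # all noise, balanced
  std <- zscore_fit(tbl)
  ev <- fitness_evaluator(zscore_apply(std, tbl), folds = 5, seed = 11)
  mask <- rep(FALSE, 25); mask[c(1, 5, 9)] <- TRUE
  acc <- evaluator_accuracy(ev, mask)
  # 99% binomial band around chance = 0.2 at n = 200 aggregated predictions
  expect_gte(acc, qbinom(0.005, 200, 0.2) / 200)
  expect_lte(acc, qbinom(0.995, 200, 0.2) / 200)
})

test_that("K-NN, decision tree and random forest honor their contracts", {
  tbl <- separable_table(n_per = 8)
  std <- zscore_fit(tbl)
  s <- zscore_apply(std, tbl)

  # 1-NN reproduces the training labels
  m1 <- train_knn(s, k = 1)
  expect_equal(mean(predict(m1, s) == s$label), 1)
  expect_error(train_knn(s, k = 1e4), "parameter error")

  # a single-feature threshold toy yields a one-split perfect tree
  toy <- tibble::tibble(Contrast0 = c(rnorm(20, -3), rnorm(20, 3)),
                        label = rep(c("filling", "crown"), each = 20))
  md <- train_dt(toy, features = "Contrast0")
  expect_equal(mean(predict(md, toy) == toy$label), 1)
  expect_equal(nrow(md$fit$frame[md$fit$frame$var != "<leaf>", , drop = FALSE]), 1)

  # seeded forests are reproducible
  mr1 <- train_rf(s, seed = 9)
  mr2 <- train_rf(s, seed = 9)
  expect_identical(predict(mr1, s), predict(mr2, s))
})

test_that("class weighting protects minority-class recall on imbalanced data", {
  withr::with_seed(21, {
    n_maj <- 180; n_min <- 20
    tbl <- tibble::tibble(
      Contrast0 = c(rnorm(n_maj, 0), rnorm(n_min, 1.6)),
      label = c(rep("filling", n_maj), rep("implant", n_min)))
    te <- tibble::tibble(Contrast0 = c(rnorm(200, 0), rnorm(200, 1.6)),
                         label = c(rep("filling", 200), rep("implant", 200)))
    mw <- train_svm(tbl, C = 1, gamma = 0.5, features = "Contrast0",
                    class_weighted = TRUE)
    mu <- train_svm(tbl, C = 1, gamma = 0.5, features = "Contrast0",
                    class_weighted = FALSE)
    rec <- function(m) mean(predict(m, te[te$label == "implant", ]) == "implant")
    expect_gte(rec(mw), rec(mu))
  })
})

test_that("predictions provide normalized scores and enforce the schema", {
  tbl <- separable_table(n_per = 8)
  std <- zscore_fit(tbl)
  s <- zscore_apply(std, tbl)
  for (m in list(train_svm(s), train_knn(s, k = 3), train_dt(s), train_rf(s, seed = 1))) {
    sc <- predict(m, s[1:6, ], type = "scores")
    expect_equal(dim(sc), c(6, 5))
    expect_true(all(abs(rowSums(sc) - 1) < 1e-6))
    expect_length(predict(m, s[0, ]), 0)
  }
  expect_error(predict(train_svm(s), s[setdiff(names(s), "ASM")]), "ASM")
})
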