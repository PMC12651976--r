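test_that("patient splits keep whole patients together at the target fraction", {
  man <- tibble::tibble(image_id = sprintf("i%02d", 1:20),
                        patient_id = rep(sprintf("P%02d", 1:10), each = 2),
                        path = "x.png",
                        label = rep(restoration_classes(), 4))
  plan <- patient_split(man, test_frac = 0.2, seed = 5)
  expect_length(plan$test_patients, 2)
  expect_length(intersect(plan$train_patients, plan$test_patients), 0)
  expect_identical(plan, patient_split(man, test_frac = 0.2, seed = 5))
  expect_error(patient_split(man[1:4, ], 0.2, 1), "at least 5 patients")
})

test_that("no patient ever straddles the train/test boundary or two folds", {
  for (s in 1:25) {
    man <- random_manifest_tbl(s)
    plan <- patient_split(man, 0.2, seed = s)
    expect_true(all(lengths(split(man$patient_id %in% plan$test_patients,
                                  man$patient_id) |> lapply(unique)) == 1))
    expect_length(intersect(plan$train_patients, plan$test_patients), 0)
  }
})

test_that("grouped k-fold balances image counts without splitting patients", {
  man <- tibble::tibble(image_id = sprintf("i%02d", 1:25),
                        patient_id = sprintf("P%02d", 1:25),
                        path = "x.png",
                        label = rep(restoration_classes(), 5))
  folds <- grouped_kfold(man, k = 5, seed = 1)
  expect_true(all(table(folds$fold) == 5))
  expect_setequal(folds$patient_id, man$patient_id)
  expect_error(grouped_kfold(man[1:3, ], k = 5), "fold error")

  # fold image counts differ at most by the largest patient
  man2 <- random_manifest_tbl(40)
  f2 <- grouped_kfold(man2, k = 3, seed = 2)
  sizes <- table(man2$patient_id)
  per_fold <- tapply(as.integer(sizes[f2$patient_id]), f2$fold, sum)
  expect_lte(max(per_fold) - min(per_fold), max(sizes))
})

test_that("confusion matrices count predictions in canonical order", {
  y <- c("crown", "crown", "crown")
  cm <- confusion(y, rep("bridge", 3))
  expect_equal(cm["crown", "bridge"], 3L)
  expect_equal(sum(cm), 3L)

  y2 <- rep(restoration_classes(), 3)
  cm2 <- confusion(y2, y2)
  expect_true(all(cm2[upper.tri(cm2)] == 0) && all(cm2[lower.tri(cm2)] == 0))
  expect_error(confusion(y, "bridge"), "equal length")
  expect_error(confusion("veneer", "crown"), "outside the class set")
})

test_that("metrics match hand arithmetic including the 0/0 convention", {
  # perfect predictions give all ones for any covered class
  y <- c("filling", "implant", "implant", "crown")
  m <- eval_metrics(confusion(y, y))
  expect_equal(m$accuracy, 1)
  covered <- m$per_class$class %in% y
  expect_true(all(m$per_class$f1[covered] == 1))

  # two-class block embedded in the 5-class matrix
  cm <- matrix(0L, 5, 5, dimnames = list(restoration_classes(), restoration_classes()))
  cm["filling", "filling"] <- 50L; cm["filling", "implant"] <- 10L
  cm["implant", "filling"] <- 5L; cm["implant", "implant"] <- 35L
  class(cm) <- c("confusion_matrix", class(cm))
  m2 <- eval_metrics(cm)
  expect_equal(m2$accuracy, 85 / 100)
  pc <- m2$per_class
  expect_equal(pc$precision[pc$class == "filling"], 50 / 55)
  expect_equal(pc$recall[pc$class == "filling"], 50 / 60)
  # absent classes contribute zeros but stay in the macro average
  expect_equal(m2$macro_precision, (50 / 55 + 35 / 45 + 0 + 0 + 0) / 5)

  # macro-F1 is invariant under permutation of the class order
  y_t <- rep(restoration_classes(), times = c(5, 3, 4, 2, 6))
  y_p <- withr::with_seed(3, sample(y_t))
  perm <- c("crown", "filling", "bridge", "implant", "root_canal")
  expect_equal(eval_metrics(confusion(y_t, y_p))$macro_f1,
               eval_metrics(confusion(y_t, y_p, classes = perm))$macro_f1)
})

test_that("stratified bootstrap intervals behave", {
  y <- rep(restoration_classes(), times = c(10, 6, 8, 6, 10))
  # all correct: every interval collapses to [1, 1]
  ci <- bootstrap_ci(y, y, B = 100, seed = 1)
  expect_true(all(ci$lower == 1 & ci$upper == 1))

  # the point estimate always lies inside its interval
  for (s in 1:5) {
    y_p <- withr::with_seed(s, ifelse(runif(length(y)) < 0.3,
                                      sample(restoration_classes(),
                                             length(y), TRUE), y))
    ci <- bootstrap_ci(y, y_p, B = 200, seed = s)
    expect_true(all(ci$estimate >= ci$lower - 1e-12 & ci$estimate <= ci$upper + 1e-12))
  }

  # intervals tighten with sample size at a fixed error rate
  width_at <- function(n, s) {
    yt <- rep(restoration_classes(), length.out = n)
    yp <- withr::with_seed(s, ifelse(runif(n) < 0.2,
                                     sample(restoration_classes(), n, TRUE), yt))
    ci <- bootstrap_ci(yt, yp, B = 300, seed = s)
    ci$upper[ci$metric == "accuracy"] - ci$lower[ci$metric == "accuracy"]
  }
  w50 <- mean(sapply(1:10, function(s) width_at(50, s)))
  w500 <- mean(sapply(1:10, function(s) width_at(500, s)))
  expect_lt(w500, w50)

  expect_error(bootstrap_ci(y[1:5], y[1:5], B = 10), "n >= 10")
  expect_warning(bootstrap_ci(rep(c("crown", "bridge"), 10),
                              rep(c("crown", "bridge"), 10), B = 10, seed = 1),
                 "stratum skipped")
})

test_that("the paired t-test handles its degenerate branches by convention", {
  expect_identical(paired_t(c(0.7, 0.8, 0.9), c(0.7, 0.8, 0.9)),
                   list(t = 0, p = 1, mean_diff = 0, df = 2))
  expect_warning(res <- paired_t(c(0.8, 0.8, 0.8), c(0.7, 0.7, 0.7)),
                 "zero variance")
  expect_identical(res$t, Inf)
  expect_identical(res$p, 0)
  # regular branch agrees with stats::t.test
  a <- c(0.71, 0.74, 0.70, 0.78, 0.73); b <- c(0.69, 0.70, 0.72, 0.71, 0.70)
  expect_equal(paired_t(a, b)$p, t.test(a, b, paired = TRUE)$p.value)
})

test_that("Cohen's kappa matches hand arithmetic and its null", {
  y <- rep(restoration_classes(), 4)
  expect_equal(cohen_kappa(y, y), 1)

  # agreement table [[20, 5], [10, 15]] -> po 0.7, pe 0.5, kappa 0.4
  a <- c(rep("crown", 25), rep("bridge", 25))
  b <- c(rep("crown", 20), rep("bridge", 5), rep("crown", 10), rep("bridge", 15))
  expect_equal(cohen_kappa(a, b), 0.4)

  # independent raters: kappa near zero
  withr::with_seed(10, {
    r1 <- sample(c("crown", "bridge"), 10000, TRUE)
    r2 <- sample(c("crown", "bridge"), 10000, TRUE)
  })
  expect_lt(abs(cohen_kappa(r1, r2)), 0.05)
  expect_warning(k1 <- cohen_kappa(rep("crown", 5), rep("crown", 5)), "constant")
  expect_equal(k1, 1)
})
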