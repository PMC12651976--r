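#' Patient-level train/test split
#'
#' Patients (never individual images) are assigned to the held-out test set.
#' Patients are shuffled with the seed, ordered round-robin across dominant
#' patient labels (best-effort grouped stratification), and greedily added
#' to the test side while that strictly moves the test image count closer to
#' `test_frac` of all images.
#'
#' @param manifest A manifest tibble (needs >= 5 patients).
#' @param test_frac Target test fraction of images (default 0.2).
#' @param seed Integer seed.
#' @return A `split_plan`: tibble `patients` (patient_id, n_images,
#'   dominant_label, partition) plus `train_patients`, `test_patients`.
#' @export
patient_split <- function(manifest, test_frac = 0.2, seed = 1L) {
  pts <- manifest |>
    dplyr::count(.data$patient_id, .data$label) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::summarise(n_images = sum(.data$n),
                     dominant_label = .data$label[which.max(.data$n)],
                     .groups = "drop")
  if (nrow(pts) < 5) abort("split error: need at least 5 patients")
  ord <- withr::with_seed(seed, {
    shuffled <- pts[sample(nrow(pts)), ]
    # round-robin across dominant-label groups spreads classes over both sides
    shuffled |>
      dplyr::group_by(.data$dominant_label) |>
      dplyr::mutate(.rr = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$.rr) |>
      dplyr::select(-".rr")
  })
  target <- test_frac * sum(ord$n_images)
  test_n <- 0
  in_test <- logical(nrow(ord))
  for (i in seq_len(nrow(ord))) {
    if (abs(test_n + ord$n_images[i] - target) < abs(test_n - target)) {
      in_test[i] <- TRUE
      test_n <- test_n + ord$n_images[i]
    }
  }
  if (!any(in_test)) in_test[1] <- TRUE
  if (all(in_test)) in_test[length(in_test)] <- FALSE
  ord$partition <- ifelse(in_test, "test", "train")
  structure(list(patients = ord[order(ord$patient_id), ],
                 train_patients = sort(ord$patient_id[!in_test]),
                 test_patients = sort(ord$patient_id[in_test]),
                 test_frac = test_frac, seed = as.integer(seed)),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d train / %d test patients (target test frac %.2f)>\n",
              length(x$train_patients), length(x$test_patients), x$test_frac))
  invisible(x)
}

#' Grouped k-fold assignment of training patients
#'
#' Partitions patients into `k` folds of near-equal image counts (greedy
#' assignment of shuffled patients, largest first, to the currently
#' smallest fold); no patient appears in two folds, so fold image counts
#' differ by at most the largest per-patient image count.
#'
#' @param manifest A manifest tibble restricted to training patients.
#' @param k Fold count (default 5; needs >= k patients).
#' @param seed Integer seed.
#' @return Tibble `patient_id`, `fold`.
#' @export
grouped_kfold <- function(manifest, k = 5L, seed = 1L) {
  pts <- manifest |> dplyr::count(.data$patient_id, name = "n_images")
  if (nrow(pts) < k) abort(sprintf("fold error: %d patients < k = %d", nrow(pts), k))
  pts <- withr::with_seed(seed, pts[sample(nrow(pts)), ])
  pts <- pts[order(-pts$n_images), ]
  sizes <- numeric(k)
  fold <- integer(nrow(pts))
  for (i in seq_len(nrow(pts))) {
    f <- which.min(sizes)
    fold[i] <- f
    sizes[f] <- sizes[f] + pts$n_images[i]
  }
  tibble::tibble(patient_id = pts$patient_id, fold = fold) |>
    dplyr::arrange(.data$patient_id)
}

#' Confusion matrix over the five classes
#'
#' @param y_true,y_pred Equal-length label vectors from the class set.
#' @param classes Class ordering (default canonical).
#' @return A `confusion_matrix` (5x5 integer matrix, rows = true class,
#'   columns = predicted).
#' @export
confusion <- function(y_true, y_pred, classes = restoration_classes()) {
  if (length(y_true) != length(y_pred)) {
    abort("y_true and y_pred must have equal length")
  }
  bad <- setdiff(unique(c(as.character(y_true), as.character(y_pred))), classes)
  if (length(bad) > 0) abort(sprintf("labels outside the class set: %s",
                                     paste(bad, collapse = ", ")))
  tt <- table(factor(y_true, levels = classes), factor(y_pred, levels = classes))
  m <- matrix(as.integer(tt), length(classes), length(classes),
              dimnames = list(true = classes, predicted = classes))
  structure(m, class = c("confusion_matrix", class(m)))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy is `trace / total` (the multi-class reading of the one-vs-rest
#' `(TP + TN) / (TP + TN + FP + FN)` form). Per-class precision
#' `TP / (TP + FP)`, recall `TP / (TP + FN)` and `F1 = 2 P R / (P + R)`,
#' with `0/0` defined as 0. Macro metrics are unweighted means over all
#' classes of the matrix, present or not.
#'
#' @param cm A [confusion()] matrix.
#' @return List of class `eval_metrics`: `accuracy`, `per_class` tibble,
#'   `macro_precision`, `macro_recall`, `macro_f1`, `n`.
#' @export
eval_metrics <- function(cm) {
  total <- sum(cm)
  if (total == 0) abort("empty confusion matrix")
  classes <- rownames(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  div0 <- function(a, b) ifelse(b == 0, 0, a / b)
  precision <- div0(tp, tp + fp)
  recall <- div0(tp, tp + fn)
  f1 <- div0(2 * precision * recall, precision + recall)
  per_class <- tibble::tibble(class = classes, tp = as.integer(tp),
                              fp = as.integer(fp), fn = as.integer(fn),
                              tn = as.integer(total - tp - fp - fn),
                              precision = unname(precision),
                              recall = unname(recall), f1 = unname(f1))
  structure(list(accuracy = sum(tp) / total, per_class = per_class,
                 macro_precision = mean(precision), macro_recall = mean(recall),
                 macro_f1 = mean(f1), n = total),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("<eval_metrics: accuracy %.4f, macro P/R/F1 %.4f/%.4f/%.4f (n = %d)>\n",
              x$accuracy, x$macro_precision, x$macro_recall, x$macro_f1, x$n))
  invisible(x)
}

#' @rdname eval_metrics
#' @param x An `eval_metrics` object.
#' @param ... Unused.
#' @export
tidy.eval_metrics <- function(x, ...) x$per_class

#' @rdname eval_metrics
#' @export
glance.eval_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, macro_precision = x$macro_precision,
                 macro_recall = x$macro_recall, macro_f1 = x$macro_f1, n = x$n)
}

#' Stratified bootstrap confidence intervals
#'
#' Resamples prediction indices with replacement within each true-class
#' stratum, recomputes accuracy and macro precision/recall/F1 per
#' replicate, and reports percentile intervals.
#'
#' @param y_true,y_pred Aggregated test labels and predictions (n >= 10).
#' @param B Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Tibble `metric`, `estimate`, `lower`, `upper`.
#' @export
bootstrap_ci <- function(y_true, y_pred, B = 1000L, level = 0.95, seed = 1L) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 10) abort("bootstrap requires n >= 10 predictions")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  absent <- setdiff(restoration_classes(), unique(y_true))
  if (length(absent) > 0) {
    warn(sprintf("bootstrap: no true instances of %s; stratum skipped",
                 paste(absent, collapse = ", ")))
  }
  strata <- split(seq_along(y_true), y_true)
  stat <- function(idx) {
    m <- eval_metrics(confusion(y_true[idx], y_pred[idx]))
    c(accuracy = m$accuracy, macro_precision = m$macro_precision,
      macro_recall = m$macro_recall, macro_f1 = m$macro_f1)
  }
  est <- stat(seq_along(y_true))
  reps <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- unlist(lapply(strata, function(s) s[sample.int(length(s), length(s),
                                                            replace = TRUE)]),
                    use.names = FALSE)
      stat(idx)
    }, numeric(4))
  })
  alpha <- (1 - level) / 2
  tibble::tibble(metric = names(est), estimate = unname(est),
                 lower = apply(reps, 1, quantile, probs = alpha, names = FALSE),
                 upper = apply(reps, 1, quantile, probs = 1 - alpha, names = FALSE))
}

#' Paired t-test on fold-level accuracies
#'
#' Two-sided paired t-test on the per-fold accuracy differences. Degenerate
#' cases follow a documented convention: identical vectors give `t = 0`,
#' `p = 1`; a constant nonzero difference gives `t = +-Inf`, `p = 0`, with a
#' warning.
#'
#' @param acc_a,acc_b Equal-length (>= 2) fold accuracy vectors, paired by
#'   fold.
#' @return List `t`, `p`, `mean_diff`, `df`.
#' @export
paired_t <- function(acc_a, acc_b) {
  stopifnot(length(acc_a) == length(acc_b), length(acc_a) >= 2)
  d <- acc_a - acc_b
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, mean_diff = 0, df = length(d) - 1))
    }
    warn("zero variance of paired differences; reporting t = +-Inf")
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                df = length(d) - 1))
  }
  tt <- t.test(acc_a, acc_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), df = unname(tt$parameter))
}

#' Cohen's kappa
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)` with the
#' expected agreement `pe` from the marginal products. If both raters are
#' constant and identical (`pe = 1`), kappa is defined as 1 with a warning.
#'
#' @param labels_a,labels_b Equal-length label vectors over the same label
#'   space.
#' @return Kappa in `[-1, 1]`.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  stopifnot(length(labels_a) == length(labels_b))
  lv <- sort(unique(c(as.character(labels_a), as.character(labels_b))))
  a <- factor(as.character(labels_a), levels = lv)
  b <- factor(as.character(labels_b), levels = lv)
  tab <- table(a, b)
  n <- sum(tab)
  po <- sum(diag(tab)) / n
  pe <- sum(rowSums(tab) * colSums(tab)) / n^2
  if (1 - pe == 0) {
    warn("both raters constant and equal; kappa defined as 1")
    return(1)
  }
  (po - pe) / (1 - pe)
}
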