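#' Classifier bank configuration
#'
#' Hyperparameters for the conventional classifiers: RBF-SVM with `C = 10`,
#' `gamma = 0.1` (grid search over `C_grid` x `gamma_grid` when requested)
#' and inverse-frequency class weights; K-NN with `k = 5` (grid 3, 5, ...,
#' 11); Gini decision tree of maximum depth 20; random forest of 100 trees,
#' maximum depth 20. `internal_folds` is the stratified fold count used
#' inside the wrapper fitness.
#'
#' @param svm,knn,dt,rf Named lists overriding individual defaults.
#' @param internal_folds Folds for the wrapper-fitness internal CV.
#' @param seed Integer seed.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(svm = list(), knn = list(), dt = list(),
                              rf = list(), internal_folds = 5L, seed = 1L) {
  cfg <- list(
    svm = modifyList(list(C = 10, gamma = 0.1, C_grid = c(0.1, 1, 10, 100),
                          gamma_grid = c(0.001, 0.01, 0.1, 1),
                          class_weighted = TRUE), svm),
    knn = modifyList(list(k = 5L, k_grid = seq(3L, 11L, 2L)), knn),
    dt = modifyList(list(max_depth = 20L), dt),
    rf = modifyList(list(n_trees = 100L, max_depth = 20L), rf),
    internal_folds = as.integer(internal_folds),
    seed = as.integer(seed)
  )
  stopifnot(cfg$svm$C > 0, cfg$svm$gamma > 0, cfg$knn$k >= 1, cfg$knn$k %% 2 == 1,
            cfg$rf$n_trees >= 1)
  structure(cfg, class = "classifier_config")
}

# Deterministic stratified fold assignment: shuffle within each class, deal
# round-robin starting at a rotating fold.
stratified_folds <- function(y, k, seed) {
  y <- as.character(y)
  fold <- integer(length(y))
  withr::with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
  })
  fold
}

label_factor <- function(y) factor(as.character(y), levels = restoration_classes())

inverse_freq_weights <- function(y) {
  tab <- table(as.character(y))
  wts <- sum(tab) / (length(tab) * tab)
  setNames(as.numeric(wts), names(tab))
}

feature_cols_of <- function(data, features) {
  if (is.null(features)) intersect(feature_names(), names(data)) else features
}

new_resto_model <- function(fit, type, features, extra = list()) {
  structure(c(list(fit = fit, type = type, features = features), extra),
            class = "resto_model")
}

#' Train an RBF-SVM
#'
#' Fits \pkg{e1071}'s C-classification SVM with an RBF kernel on the given
#' feature columns, with inverse-frequency class weights when
#' `class_weighted` is on. Features are expected to be standardized already
#' ([zscore_fit()]).
#'
#' @param data Feature table with a `label` column.
#' @param C,gamma SVM hyperparameters.
#' @param features Feature columns (default: all canonical feature columns
#'   present).
#' @param class_weighted Apply inverse-frequency class weights.
#' @return A `resto_model`.
#' @export
train_svm <- function(data, C = 10, gamma = 0.1, features = NULL,
                      class_weighted = TRUE) {
  features <- feature_cols_of(data, features)
  y <- label_factor(data$label)
  if (length(unique(as.character(y[!is.na(y)]))) < 2) {
    abort("degenerate-label error: need >= 2 classes to train")
  }
  x <- as.matrix(data[features])
  cw <- if (class_weighted) inverse_freq_weights(y) else NULL
  fit <- e1071::svm(x = x, y = droplevels(y), kernel = "radial", cost = C,
                    gamma = gamma, class.weights = cw, scale = FALSE)
  new_resto_model(fit, "svm", features, list(C = C, gamma = gamma))
}

#' Grid search for SVM hyperparameters
#'
#' Seeded stratified cross-validation over `C_grid x gamma_grid`; ties are
#' broken toward the smaller `C`, then the smaller `gamma`.
#'
#' @param data Standardized feature table with `label`.
#' @param folds CV fold count.
#' @param C_grid,gamma_grid Candidate values.
#' @param features Feature columns.
#' @param class_weighted Apply class weights inside the CV fits.
#' @param seed Integer seed for the fold assignment.
#' @return List with `C`, `gamma`, `accuracy` and the full `results` tibble.
#' @export
grid_search_svm <- function(data, folds = 3L, C_grid = c(0.1, 1, 10, 100),
                            gamma_grid = c(0.001, 0.01, 0.1, 1),
                            features = NULL, class_weighted = TRUE, seed = 1L) {
  features <- feature_cols_of(data, features)
  fold <- stratified_folds(data$label, folds, seed)
  grid <- expand.grid(gamma = sort(gamma_grid), C = sort(C_grid))[, c("C", "gamma")]
  grid <- grid[order(grid$C, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    cv_accuracy_svm(data, features, fold, grid$C[g], grid$gamma[g], class_weighted)
  }, numeric(1))
  best <- which(acc > max(acc) - 1e-12)[1]   # first hit in (C, gamma) order
  list(C = grid$C[best], gamma = grid$gamma[best], accuracy = acc[best],
       results = tibble::tibble(C = grid$C, gamma = grid$gamma, accuracy = acc))
}

cv_accuracy_svm <- function(data, features, fold, C, gamma, class_weighted) {
  k <- max(fold)
  correct <- 0L; total <- 0L
  for (f in seq_len(k)) {
    tr <- data[fold != f, ]
    va <- data[fold == f, ]
    if (nrow(va) == 0 || length(unique(tr$label)) < 2) next
    mdl <- train_svm(tr, C = C, gamma = gamma, features = features,
                     class_weighted = class_weighted)
    pred <- predict(mdl, va)
    correct <- correct + sum(as.character(pred) == as.character(va$label))
    total <- total + nrow(va)
  }
  if (total == 0) 0 else correct / total
}

#' Wrapper-fitness evaluator bound to training rows only
#'
#' Holds a frozen copy of the training-fold feature matrix, labels, a fixed
#' stratified internal-CV fold assignment and the SVM settings. By
#' construction it can never see held-out rows, and
#' [evaluator_accuracy()] is a pure, deterministic function of the mask.
#'
#' @param train Standardized training feature table with `label`.
#' @param features Feature columns (default canonical 25).
#' @param folds Internal CV fold count (default 3).
#' @param C,gamma SVM hyperparameters used inside the fitness.
#' @param class_weighted Apply inverse-frequency class weights.
#' @param seed Integer seed fixing the internal folds.
#' @return An object of class `fitness_evaluator`.
#' @export
fitness_evaluator <- function(train, features = NULL, folds = 3L, C = 10,
                              gamma = 0.1, class_weighted = TRUE, seed = 1L) {
  features <- feature_cols_of(train, features)
  if (nrow(train) < folds) abort("fold error: fewer training rows than folds")
  structure(list(x = as.matrix(train[features]),
                 y = label_factor(train$label),
                 features = features,
                 fold = stratified_folds(train$label, folds, seed),
                 folds = as.integer(folds), C = C, gamma = gamma,
                 class_weighted = class_weighted, seed = as.integer(seed),
                 image_ids = if ("image_id" %in% names(train)) train$image_id else NULL),
            class = "fitness_evaluator")
}

#' Internal-CV accuracy of a feature mask
#'
#' Mean stratified internal-CV accuracy of the RBF-SVM restricted to the
#' mask-selected columns, using the evaluator's frozen folds and seed.
#'
#' @param evaluator A [fitness_evaluator()].
#' @param mask Logical/0-1 vector over the evaluator's features.
#' @return Accuracy in `[0, 1]`.
#' @export
evaluator_accuracy <- function(evaluator, mask) {
  stopifnot(inherits(evaluator, "fitness_evaluator"))
  mask <- as.logical(mask)
  if (!any(mask)) abort("empty mask: wrapper accuracy undefined")
  x <- evaluator$x[, mask, drop = FALSE]
  y <- evaluator$y
  correct <- 0L; total <- 0L
  for (f in seq_len(evaluator$folds)) {
    tr <- evaluator$fold != f
    if (sum(!tr) == 0 || length(unique(as.character(y[tr]))) < 2) next
    cw <- if (evaluator$class_weighted) inverse_freq_weights(y[tr]) else NULL
    fit <- e1071::svm(x = x[tr, , drop = FALSE], y = droplevels(y[tr]),
                      kernel = "radial", cost = evaluator$C,
                      gamma = evaluator$gamma, class.weights = cw, scale = FALSE)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    correct <- correct + sum(as.character(pred) == as.character(y[!tr]))
    total <- total + sum(!tr)
  }
  if (total == 0) 0 else correct / total
}

#' Train a K-nearest-neighbour classifier
#'
#' Lazy learner: stores the (standardized) training rows; `k` is chosen by
#' seeded stratified CV over `k_grid` when supplied.
#'
#' @param data Standardized feature table with `label`.
#' @param k Neighbour count (odd).
#' @param k_grid Optional grid for CV selection of `k`.
#' @param features Feature columns.
#' @param folds,seed CV controls for the `k` grid.
#' @return A `resto_model`.
#' @export
train_knn <- function(data, k = 5L, k_grid = NULL, features = NULL,
                      folds = 3L, seed = 1L) {
  features <- feature_cols_of(data, features)
  if (!is.null(k_grid)) {
    fold <- stratified_folds(data$label, folds, seed)
    acc <- vapply(sort(k_grid), function(kk) {
      ok <- 0L; tot <- 0L
      for (f in seq_len(max(fold))) {
        tr <- data[fold != f, ]; va <- data[fold == f, ]
        if (nrow(va) == 0 || kk > nrow(tr)) next
        pred <- class::knn(as.matrix(tr[features]), as.matrix(va[features]),
                           cl = label_factor(tr$label), k = kk, use.all = TRUE)
        ok <- ok + sum(as.character(pred) == as.character(va$label))
        tot <- tot + nrow(va)
      }
      if (tot == 0) 0 else ok / tot
    }, numeric(1))
    k <- sort(k_grid)[which.max(acc)]
  }
  if (k > nrow(data)) abort("parameter error: k exceeds the number of training rows")
  new_resto_model(list(x = as.matrix(data[features]),
                       y = label_factor(data$label)),
                  "knn", features, list(k = as.integer(k)))
}

#' Train a Gini decision tree
#'
#' @param data Feature table with `label`.
#' @param max_depth Maximum tree depth (default 20).
#' @param features Feature columns.
#' @return A `resto_model`.
#' @export
train_dt <- function(data, max_depth = 20L, features = NULL) {
  features <- feature_cols_of(data, features)
  df <- as.data.frame(data[features])
  df$.label <- label_factor(data$label)
  fit <- rpart::rpart(.label ~ ., data = df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(maxdepth = min(max_depth, 30L),
                                                     xval = 0, cp = 0))
  new_resto_model(fit, "dt", features)
}

#' Train a random forest
#'
#' 100 Gini trees of maximum depth 20 by default (via \pkg{ranger}, seeded,
#' single-threaded for determinism).
#'
#' @param data Feature table with `label`.
#' @param n_trees Number of trees.
#' @param max_depth Maximum depth.
#' @param features Feature columns.
#' @param seed Integer seed.
#' @return A `resto_model`.
#' @export
train_rf <- function(data, n_trees = 100L, max_depth = 20L, features = NULL,
                     seed = 1L) {
  features <- feature_cols_of(data, features)
  df <- as.data.frame(data[features])
  df$.label <- droplevels(label_factor(data$label))
  fit <- ranger::ranger(dependent.variable.name = ".label", data = df,
                        num.trees = n_trees, max.depth = max_depth,
                        seed = seed, num.threads = 1L, probability = TRUE)
  new_resto_model(fit, "rf", features)
}

#' Predict labels (and class scores) from a fitted model
#'
#' @param object A `resto_model`.
#' @param newdata Feature table with the training feature columns.
#' @param type `"label"` (default) or `"scores"` (per-class probabilities /
#'   normalized vote fractions, rows summing to 1).
#' @param ... Unused.
#' @return A character vector of labels, or a numeric matrix of scores.
#' @export
predict.resto_model <- function(object, newdata, type = c("label", "scores"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("feature schema mismatch: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(newdata) == 0) {
    if (type == "label") return(character(0))
    return(matrix(numeric(0), 0, 5, dimnames = list(NULL, restoration_classes())))
  }
  x <- as.matrix(newdata[object$features])
  if (object$type == "svm") {
    pred <- as.character(predict(object$fit, x))
    if (type == "label") return(pred)
    dec <- attr(predict(object$fit, x, decision.values = TRUE), "decision.values")
    return(scores_from_votes(pred, dec, levels(object$fit$fitted)))
  }
  if (object$type == "knn") {
    pred <- as.character(class::knn(object$fit$x, x, cl = object$fit$y,
                                    k = object$k, use.all = TRUE))
    if (type == "label") return(pred)
    return(knn_vote_scores(object$fit$x, object$fit$y, x, object$k))
  }
  if (object$type == "dt") {
    probs <- predict(object$fit, as.data.frame(newdata[object$features]), type = "prob")
    if (type == "scores") return(full_score_matrix(probs))
    return(colnames(probs)[max.col(probs, ties.method = "first")])
  }
  # rf (ranger probability forest)
  probs <- predict(object$fit, data = as.data.frame(newdata[object$features]),
                   num.threads = 1L)$predictions
  if (type == "scores") return(full_score_matrix(probs))
  colnames(probs)[max.col(probs, ties.method = "first")]
}

# expand a score matrix over observed classes to all 5 canonical classes
full_score_matrix <- function(probs) {
  out <- matrix(0, nrow(probs), 5, dimnames = list(NULL, restoration_classes()))
  out[, colnames(probs)] <- probs
  out
}

# one-vs-one decision values folded into per-class vote fractions, with the
# predicted label guaranteed the arg-max
scores_from_votes <- function(pred, dec, classes) {
  n <- length(pred)
  votes <- matrix(0, n, length(classes), dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(dec), "/")
  for (k in seq_along(pairs)) {
    a <- pairs[[k]][1]; b <- pairs[[k]][2]
    win_a <- dec[, k] > 0
    votes[, a] <- votes[, a] + win_a
    votes[, b] <- votes[, b] + !win_a
  }
  votes <- votes + 1e-9   # avoid 0/0 on a single-pair model
  full_score_matrix(votes / rowSums(votes))
}

knn_vote_scores <- function(train_x, train_y, x, k) {
  n <- nrow(x)
  out <- matrix(0, n, 5, dimnames = list(NULL, restoration_classes()))
  for (i in seq_len(n)) {
    d2 <- colSums((t(train_x) - x[i, ])^2)
    nb <- train_y[order(d2)[seq_len(k)]]
    tab <- table(nb) / k
    out[i, names(tab)] <- as.numeric(tab)
  }
  out
}
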