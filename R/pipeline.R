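#' Experiment configuration
#'
#' One config drives the whole three-stage experiment: data source
#' (phantom spec or existing manifest), enhancement, GLCM features, the
#' HGWO-PSO search, the classifier bank, the patient-level split (test
#' fraction 0.2, 5 grouped folds), and the bootstrap. All stage seeds are
#' derived deterministically from the single global seed. The default
#' optimizer preset uses 30 iterations, a desk-sized setting that keeps the
#' full experiment in the minutes range on one CPU; the full 100-iteration
#' setting is a config switch away.
#'
#' @param phantom A [phantom_spec()] used when no manifest is supplied.
#' @param enhance An [enhance_config()].
#' @param glcm A [glcm_config()].
#' @param optimizer An [hgwo_pso_config()].
#' @param classifiers A [classifier_config()].
#' @param models Which model rows to compute.
#' @param test_frac Held-out test fraction of images.
#' @param k_folds Grouped CV folds on the training portion.
#' @param bootstrap_B Bootstrap replicates for the test-set CIs.
#' @param grid_search Run the SVM (C, gamma) grid search on the training
#'   set instead of using the configured values.
#' @param seed Global integer seed.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(phantom = phantom_spec(),
                              enhance = enhance_config(),
                              glcm = glcm_config(),
                              optimizer = hgwo_pso_config(iterations = 30L),
                              classifiers = classifier_config(),
                              models = c("svm", "knn", "dt", "rf", "hgwo_pso_svm"),
                              test_frac = 0.2, k_folds = 5L,
                              bootstrap_B = 1000L, grid_search = FALSE,
                              seed = 1L) {
  structure(list(phantom = phantom, enhance = enhance, glcm = glcm,
                 optimizer = optimizer, classifiers = classifiers,
                 models = models, test_frac = test_frac,
                 k_folds = as.integer(k_folds),
                 bootstrap_B = as.integer(bootstrap_B),
                 grid_search = isTRUE(grid_search), seed = as.integer(seed)),
            class = "experiment_config")
}

fit_model_for <- function(model, train_std, cfg, seed, features = NULL) {
  cls <- cfg$classifiers
  switch(model,
    svm = train_svm(train_std, C = cls$svm$C, gamma = cls$svm$gamma,
                    features = features, class_weighted = cls$svm$class_weighted),
    hgwo_pso_svm = train_svm(train_std, C = cls$svm$C, gamma = cls$svm$gamma,
                             features = features,
                             class_weighted = cls$svm$class_weighted),
    knn = train_knn(train_std, k = cls$knn$k, k_grid = cls$knn$k_grid,
                    features = features, folds = cfg$classifiers$internal_folds,
                    seed = seed),
    dt = train_dt(train_std, max_depth = cls$dt$max_depth, features = features),
    rf = train_rf(train_std, n_trees = cls$rf$n_trees,
                  max_depth = cls$rf$max_depth, features = features, seed = seed),
    abort(sprintf("unknown model: %s", model))
  )
}

select_features_hgwo <- function(train_std, cfg, seed) {
  ev <- fitness_evaluator(train_std, folds = cfg$classifiers$internal_folds,
                          C = cfg$classifiers$svm$C,
                          gamma = cfg$classifiers$svm$gamma,
                          class_weighted = cfg$classifiers$svm$class_weighted,
                          seed = seed)
  opt_cfg <- cfg$optimizer
  opt_cfg$seed <- seed
  run_hgwo_pso(ev, d = length(feature_names()), cfg = opt_cfg)
}

#' Run the full experiment
#'
#' End-to-end, leakage-safe protocol: enhance images, extract the 25 GLCM
#' features, split patients 80/20, run grouped k-fold CV on the training
#' portion (per fold: fit the standardizer on the fold-train rows only, run
#' HGWO-PSO selection on the fold-train rows only, refit the SVM on the
#' selected features, score the fold-validation rows), then fit each final
#' model on the full training set (for HGWO-PSO + SVM, with a final
#' selection run on the full training set, the per-fold masks being logged)
#' and assess it once on the patient-held-out test set with stratified
#' bootstrap CIs. The HGWO-PSO + SVM and plain-SVM fold accuracies are
#' compared with a paired t-test. Identical seeds reproduce the report
#' byte-for-byte.
#'
#' @param manifest A manifest tibble, or `NULL` to generate the phantom
#'   dataset of `config$phantom`.
#' @param config An [experiment_config()].
#' @param feature_table Optional precomputed feature table (skips image
#'   loading and enhancement).
#' @return A `comparison_report`.
#' @export
run_experiment <- function(manifest = NULL, config = experiment_config(),
                           feature_table = NULL) {
  withr::with_seed(derive_seed(config$seed, 0), {
    if (is.null(feature_table)) {
      if (is.null(manifest)) {
        manifest <- generate_dataset(config$phantom)
      }
      feature_table <- features_from_manifest(manifest, config$glcm, config$enhance)
    }

    plan <- patient_split(feature_table, config$test_frac,
                          seed = derive_seed(config$seed, 1))
    train_tbl <- feature_table[feature_table$patient_id %in% plan$train_patients, ]
    test_tbl <- feature_table[feature_table$patient_id %in% plan$test_patients, ]
    folds <- grouped_kfold(train_tbl, config$k_folds,
                           seed = derive_seed(config$seed, 2))
    fold_of <- folds$fold[match(train_tbl$patient_id, folds$patient_id)]

    audit <- list(test_image_ids = test_tbl$image_id,
                  standardizer_ids = character(0),
                  optimizer_ids = character(0),
                  grid_search_ids = character(0))
    note_std <- function(tbl) {
      audit$standardizer_ids <<- union(audit$standardizer_ids, tbl$image_id)
    }

    # optional grid search for (C, gamma), on training rows only
    if (config$grid_search) {
      std0 <- zscore_fit(train_tbl); note_std(train_tbl)
      gs <- grid_search_svm(zscore_apply(std0, train_tbl),
                            folds = config$classifiers$internal_folds,
                            C_grid = config$classifiers$svm$C_grid,
                            gamma_grid = config$classifiers$svm$gamma_grid,
                            class_weighted = config$classifiers$svm$class_weighted,
                            seed = derive_seed(config$seed, 3))
      audit$grid_search_ids <- train_tbl$image_id
      config$classifiers$svm$C <- gs$C
      config$classifiers$svm$gamma <- gs$gamma
    }

    selection <- list(fold_masks = list(), final = NULL)
    results <- list()
    fold_acc <- list()

    for (model in config$models) {
      accs <- numeric(config$k_folds)
      for (f in seq_len(config$k_folds)) {
        ftr <- train_tbl[fold_of != f, ]
        fva <- train_tbl[fold_of == f, ]
        std <- zscore_fit(ftr); note_std(ftr)
        ftr_s <- zscore_apply(std, ftr)
        fva_s <- zscore_apply(std, fva)
        feats <- NULL
        if (model == "hgwo_pso_svm") {
          opt <- select_features_hgwo(ftr_s, config,
                                      seed = derive_seed(config$seed, 10 + f))
          audit$optimizer_ids <- union(audit$optimizer_ids, ftr$image_id)
          feats <- feature_names()[opt$best_mask]
          selection$fold_masks[[f]] <- opt$best_mask
        }
        mdl <- fit_model_for(model, ftr_s, config,
                             seed = derive_seed(config$seed, 20 + f),
                             features = feats)
        pred <- predict(mdl, fva_s)
        accs[f] <- mean(as.character(pred) == as.character(fva_s$label))
      }
      fold_acc[[model]] <- accs

      # final fit on the full training set, one-shot test evaluation
      std <- zscore_fit(train_tbl); note_std(train_tbl)
      train_s <- zscore_apply(std, train_tbl)
      test_s <- zscore_apply(std, test_tbl)
      feats <- NULL
      if (model == "hgwo_pso_svm") {
        opt <- select_features_hgwo(train_s, config,
                                    seed = derive_seed(config$seed, 30))
        audit$optimizer_ids <- union(audit$optimizer_ids, train_tbl$image_id)
        feats <- feature_names()[opt$best_mask]
        selection$final <- opt
      }
      mdl <- fit_model_for(model, train_s, config,
                           seed = derive_seed(config$seed, 40), features = feats)
      pred <- as.character(predict(mdl, test_s))
      cm <- confusion(test_s$label, pred)
      met <- eval_metrics(cm)
      # bootstrap CIs need at least 10 test predictions to be meaningful
      ci <- if (nrow(test_s) >= 10) {
        bootstrap_ci(test_s$label, pred, B = config$bootstrap_B,
                     seed = derive_seed(config$seed, 50))
      } else {
        NULL
      }
      results[[model]] <- list(confusion = cm, metrics = met, ci = ci,
                               fold_accuracies = accs,
                               test_predictions = pred,
                               selected_features = feats)
    }

    paired <- NULL
    if (all(c("svm", "hgwo_pso_svm") %in% config$models)) {
      paired <- paired_t(fold_acc[["hgwo_pso_svm"]], fold_acc[["svm"]])
    }

    comparison <- dplyr::bind_rows(lapply(config$models, function(m) {
      met <- results[[m]]$metrics
      tibble::tibble(model = m, precision = met$macro_precision,
                     recall = met$macro_recall, f1 = met$macro_f1,
                     accuracy = met$accuracy,
                     cv_accuracy = mean(results[[m]]$fold_accuracies))
    }))

    structure(list(comparison = comparison, results = results,
                   selection = selection, paired_test = paired,
                   split = plan, folds = folds, audit = audit,
                   config = config),
              class = "comparison_report")
  })
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison (held-out test set):\n")
  print(as.data.frame(x$comparison), row.names = FALSE, digits = 4)
  if (!is.null(x$paired_test)) {
    cat(sprintf("\nPaired t-test (HGWO-PSO+SVM vs SVM fold accuracies): t = %.3f, p = %.4f\n",
                x$paired_test$t, x$paired_test$p))
  }
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `comparison_report`.
#' @param ... Unused.
#' @export
tidy.comparison_report <- function(x, ...) x$comparison

#' @rdname run_experiment
#' @export
glance.comparison_report <- function(x, ...) {
  best <- x$comparison[which.max(x$comparison$accuracy), ]
  tibble::tibble(best_model = best$model, best_accuracy = best$accuracy,
                 best_macro_f1 = best$f1, n_models = nrow(x$comparison),
                 n_test = x$results[[1]]$metrics$n, seed = x$config$seed)
}

report_to_list <- function(report) {
  list(
    comparison = report$comparison,
    per_model = lapply(report$results, function(r) {
      list(confusion = unclass(r$confusion),
           accuracy = r$metrics$accuracy,
           per_class = r$metrics$per_class,
           macro = list(precision = r$metrics$macro_precision,
                        recall = r$metrics$macro_recall,
                        f1 = r$metrics$macro_f1),
           bootstrap_ci = r$ci,
           fold_accuracies = r$fold_accuracies,
           selected_features = r$selected_features)
    }),
    selection = list(
      fold_masks = lapply(report$selection$fold_masks, as.integer),
      final_mask = if (!is.null(report$selection$final))
        as.integer(report$selection$final$best_mask),
      final_fitness = if (!is.null(report$selection$final))
        report$selection$final$best_fitness[c("f", "acc", "fr")]
    ),
    paired_test = report$paired_test,
    split = list(train_patients = report$split$train_patients,
                 test_patients = report$split$test_patients),
    seed = report$config$seed
  )
}

#' Render a comparison report to JSON and a text table
#'
#' @param report A `comparison_report`.
#' @param dir Output directory, or `NULL` to render in memory only.
#' @return Invisibly, a list with `json` (character) and `text` lines;
#'   written to `report.json` / `comparison.txt` when `dir` is given.
#' @export
report_render <- function(report, dir = NULL) {
  json <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                           digits = 10, pretty = TRUE, na = "null")
  cmp_fmt <- report$comparison
  for (col in c("precision", "recall", "f1", "accuracy", "cv_accuracy")) {
    cmp_fmt[[col]] <- sprintf("%.4f", cmp_fmt[[col]])
  }
  txt <- c("Model comparison (held-out test set)",
           utils::capture.output(print(as.data.frame(cmp_fmt),
                                       row.names = FALSE)),
           "", "Confusion matrices (rows = true, cols = predicted):",
           unlist(lapply(names(report$results), function(m) {
             c(paste0("-- ", m),
               utils::capture.output(print(unclass(report$results[[m]]$confusion))))
           })))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeLines(json, file.path(dir, "report.json"))
    writeLines(txt, file.path(dir, "comparison.txt"))
  }
  invisible(list(json = as.character(json), text = txt))
}
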