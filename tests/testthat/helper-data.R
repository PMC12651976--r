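# Shared fixtures, all generated in code at test time.

write_tiny_manifest <- function(dir = withr::local_tempdir(.local_envir = parent.frame()),
                                n_img = 4, n_patients = 2) {
  labels <- rep(restoration_classes(), length.out = n_img)
  rows <- lapply(seq_len(n_img), function(i) {
    img <- matrix(as.integer((i * 37 + seq_len(64) * 3) %% 256), 8)
    fn <- file.path(dir, sprintf("t%02d.png", i))
    png::writePNG(img / 255, fn)
    data.frame(image_id = sprintf("t%02d", i),
               patient_id = sprintf("P%d", (i - 1) %% n_patients + 1),
               path = fn, label = labels[i])
  })
  path <- file.path(dir, "manifest.csv")
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  path
}

# Feature table with `info` planted informative columns (one per class,
# class-mean shift `shift` SDs); all other columns pure noise.
planted_feature_table <- function(seed, n_per = 40, shift = 2,
                                  info = c(3, 8, 13, 19, 24)) {
  withr::with_seed(seed, {
    cls <- rep(restoration_classes(), each = n_per)
    X <- matrix(rnorm(length(cls) * 25), length(cls), 25)
    for (k in seq_along(info)) {
      sel <- cls == restoration_classes()[k]
      X[sel, info[k]] <- X[sel, info[k]] + shift
    }
    tbl <- tibble::as_tibble(stats::setNames(as.data.frame(X), feature_names()))
    tbl$image_id <- sprintf("r%03d", seq_along(cls))
    tbl$patient_id <- tbl$image_id
    tbl$label <- cls
    tbl[feature_table_columns()]
  })
}

# Random manifest tibble (no files on disk) for split-plan property tests.
random_manifest_tbl <- function(seed) {
  withr::with_seed(seed, {
    n_pat <- sample(6:15, 1)
    sizes <- sample(1:5, n_pat, replace = TRUE)
    pid <- rep(sprintf("P%02d", seq_len(n_pat)), sizes)
    tibble::tibble(image_id = sprintf("i%03d", seq_along(pid)),
                   patient_id = pid,
                   path = paste0(pid, ".png"),
                   label = sample(restoration_classes(), length(pid), replace = TRUE))
  })
}

# Deterministic planted-optimum toy fitness over d = 10 bits (no CV noise):
# accuracy rises with coverage of the planted set {1, 3, 5} and every
# extraneous feature costs a fixed penalty.
toy_planted_acc <- function(mask, planted = c(1, 3, 5)) {
  idx <- which(mask)
  0.5 + 0.5 * length(intersect(idx, planted)) / length(planted) -
    0.03 * length(setdiff(idx, planted))
}

toy_brute_force_best <- function(acc_fn = toy_planted_acc, d = 10) {
  best_f <- -Inf; best_mask <- NULL
  for (m in seq_len(2^d - 1)) {
    mask <- as.logical(bitwAnd(m, 2^(seq_len(d) - 1)))
    f <- 0.9 * acc_fn(mask) + 0.1 * (1 - sum(mask) / d)
    if (f > best_f) { best_f <- f; best_mask <- mask }
  }
  list(mask = best_mask, f = best_f)
}
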