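#' Read and validate a dataset manifest
#'
#' The manifest is a CSV with header columns `image_id`, `patient_id`,
#' `path`, `label`. Labels must come from the closed five-class set
#' ([restoration_classes()]), image ids must be unique, and (optionally)
#' every referenced image file must exist.
#'
#' @param path Path to the manifest CSV.
#' @param check_files Verify that every `path` exists (default `TRUE`).
#' @return A tibble with one row per image (class `manifest`), relative
#'   paths resolved against the manifest's directory.
#' @export
read_manifest <- function(path, check_files = TRUE) {
  if (!file.exists(path)) abort(sprintf("manifest not found: %s", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  need <- c("image_id", "patient_id", "path", "label")
  missing <- setdiff(need, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("manifest schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  # resolve image paths relative to the manifest location
  base <- dirname(path)
  tbl$path <- ifelse(file.exists(tbl$path) | grepl("^(/|[A-Za-z]:)", tbl$path),
                     tbl$path, file.path(base, tbl$path))
  validate_manifest(tbl[need], check_files = check_files)
}

validate_manifest <- function(tbl, check_files = TRUE) {
  tbl <- tibble::as_tibble(tbl)
  bad <- setdiff(unique(tbl$label), restoration_classes())
  if (length(bad) > 0) {
    abort(sprintf("unknown label(s) %s; valid classes are: %s",
                  paste(sQuote(bad), collapse = ", "),
                  paste(restoration_classes(), collapse = ", ")))
  }
  dup <- tbl$image_id[duplicated(tbl$image_id)]
  if (length(dup) > 0) {
    abort(sprintf("duplicate image_id(s): %s", paste(unique(dup), collapse = ", ")))
  }
  if (check_files) {
    gone <- tbl$path[!file.exists(tbl$path)]
    if (length(gone) > 0) {
      abort(sprintf("missing image file(s): %s", paste(head(gone, 5), collapse = ", ")))
    }
  }
  class(tbl) <- c("manifest", class(tbl))
  tbl
}

#' Write a manifest back to CSV
#'
#' @param manifest A manifest tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest[c("image_id", "patient_id", "path", "label")], path)
  invisible(path)
}

#' Load a grayscale image
#'
#' Reads PNG (via \pkg{png}), TIFF (via \pkg{tiff}) or JPEG (via
#' \pkg{EBImage}, if installed) into an integer matrix at native bit depth.
#' Multi-channel inputs are collapsed to luminance (0.299 R + 0.587 G +
#' 0.114 B).
#'
#' @param x A file path, or a one-row manifest slice with a `path` column.
#' @return An [new_image2d()] matrix with a `depth` attribute (8 or 16).
#' @export
load_image <- function(x) {
  path <- if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    x$path
  } else {
    x
  }
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("unreadable or zero-size image file: %s", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
    depth <- png_bit_depth(path)
  } else if (ext %in% c("tif", "tiff")) {
    arr <- tiff::readTIFF(path, as.is = TRUE, info = TRUE)
    bps <- attr(arr, "bits.per.sample")
    depth <- if (!is.null(bps)) as.integer(max(bps)) else if (max(arr) > 255) 16L else 8L
    return(new_image2d(to_luminance(arr), depth = max(8L, depth)))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      abort("JPEG input requires the EBImage package")
    }
    arr <- EBImage::imageData(EBImage::readImage(path))
    if (length(dim(arr)) == 3) arr <- aperm(arr, c(2, 1, 3)) else arr <- t(arr)
    depth <- 8L
  } else {
    abort(sprintf("unsupported image format: .%s (use PNG, TIFF or JPEG)", ext))
  }
  arr <- to_luminance(arr)
  new_image2d(round(arr * bit_max(depth)), depth = depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

to_luminance <- function(arr) {
  if (length(dim(arr)) == 3) {
    k <- dim(arr)[3]
    if (k >= 3) {
      0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr[, , 1]
    }
  } else {
    arr
  }
}

# PNG stores the bit depth in byte 25 of the file (IHDR chunk).
png_bit_depth <- function(path) {
  hdr <- readBin(path, "raw", n = 26)
  as.integer(hdr[25])
}

#' Canonical feature-table schema
#'
#' @return Character vector: `image_id`, `patient_id`, `label`, then the 25
#'   canonical texture feature names ([feature_names()]).
#' @export
feature_table_columns <- function() {
  c("image_id", "patient_id", "label", feature_names())
}

#' Write / read a feature table
#'
#' Feature tables are CSVs in the canonical column order
#' ([feature_table_columns()]); the round-trip is lossless to at least 12
#' significant digits. Reading validates the header.
#'
#' @param table A feature table tibble.
#' @param path CSV path.
#' @return `write_feature_table()` returns `path` invisibly;
#'   `read_feature_table()` returns the validated tibble.
#' @export
write_feature_table <- function(table, path) {
  missing <- setdiff(feature_table_columns(), names(table))
  if (length(missing) > 0) {
    abort(sprintf("feature table schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  readr::write_csv(table[feature_table_columns()], path)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE)
  missing <- setdiff(feature_table_columns(), names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("feature table schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(tbl) > 0 && any(is.na(tbl[feature_names()]))) {
    abort("feature table contains missing values")
  }
  tibble::as_tibble(tbl[feature_table_columns()])
}
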