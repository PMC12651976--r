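#' GLCM configuration
#'
#' Co-occurrence statistics are computed globally (whole image) at a fixed
#' displacement along four angles, on an image quantized to a small number of
#' gray levels; matrices are symmetrized and normalized.
#'
#' @param levels Number of quantization gray levels (default 64).
#' @param distance Pixel displacement d (default 1).
#' @param angles Angle set in degrees; fixed to `c(0, 45, 90, 135)`.
#' @return A list of class `glcm_config`.
#' @export
glcm_config <- function(levels = 64L, distance = 1L, angles = c(0, 45, 90, 135)) {
  stopifnot(levels >= 2, distance >= 1, setequal(angles, c(0, 45, 90, 135)))
  structure(list(levels = as.integer(levels), distance = as.integer(distance),
                 angles = c(0, 45, 90, 135)),
            class = "glcm_config")
}

#' Quantize an image to a fixed number of gray levels
#'
#' Per-image min-max rescale to `[0, 1]` followed by uniform binning into
#' `levels` bins (values `0 .. levels - 1`). A constant image maps to level
#' 0 everywhere.
#'
#' @param img An [new_image2d()] matrix (any numeric matrix accepted).
#' @param levels Number of bins.
#' @return Integer matrix of levels `0 .. levels - 1`.
#' @export
quantize <- function(img, levels = 64L) {
  stopifnot(length(img) >= 1)
  levels <- as.integer(levels)
  rng <- range(img)
  if (rng[1] == rng[2]) {
    return(matrix(0L, nrow(img), ncol(img)))
  }
  u <- (img - rng[1]) / (rng[2] - rng[1])
  q <- pmin(as.integer(floor(u * levels)), levels - 1L)
  matrix(q, nrow(img))
}

# row/col offsets for the ordered neighbour at displacement d along each angle
angle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0"   = c(0L, d),
         "45"  = c(-d, d),
         "90"  = c(-d, 0L),
         "135" = c(-d, -d),
         abort(sprintf("unsupported GLCM angle: %s", angle)))
}

#' Grey-level co-occurrence matrix for one angle
#'
#' Counts ordered pixel pairs at displacement `distance` along `angle`
#' (0 deg = (0,+d), 45 = (-d,+d), 90 = (-d,0), 135 = (-d,-d) in row/col
#' offsets), truncating at image borders, then adds the transpose
#' (symmetrization) and normalizes to sum 1.
#'
#' @param qimg Quantized integer matrix (values `0 .. levels - 1`).
#' @param levels Number of gray levels.
#' @param angle One of 0, 45, 90, 135 (degrees).
#' @param distance Displacement in pixels.
#' @return A `levels x levels` symmetric probability matrix (class
#'   `glcm_matrix`).
#' @export
glcm <- function(qimg, levels = 64L, angle = 0, distance = 1L) {
  levels <- as.integer(levels)
  if (any(qimg >= levels) || any(qimg < 0)) abort("quantized values must lie in [0, levels)")
  off <- angle_offset(angle, as.integer(distance))
  h <- nrow(qimg); w <- ncol(qimg)
  rlo <- max(1L, 1L - off[1]); rhi <- min(h, h - off[1])
  clo <- max(1L, 1L - off[2]); chi <- min(w, w - off[2])
  if (rlo > rhi || clo > chi) {
    abort("image too small for the requested displacement: no pixel pairs")
  }
  r1 <- rlo:rhi
  c1 <- clo:chi
  i <- qimg[r1, c1, drop = FALSE]
  j <- qimg[r1 + off[1], c1 + off[2], drop = FALSE]
  counts <- tabulate(as.integer(i) * levels + as.integer(j) + 1L, nbins = levels^2)
  m <- matrix(counts, levels, levels, byrow = TRUE)   # rows = i, cols = j
  m <- m + t(m)
  p <- m / sum(m)
  structure(p, class = c("glcm_matrix", class(p)))
}

#' Haralick-style descriptors of one GLCM
#'
#' Given a normalized symmetric co-occurrence matrix `p(i, j)`:
#' contrast `= sum p (i - j)^2`; correlation `= sum p (i - mux)(j - muy) /
#' (sx sy)` from the marginal means/SDs (defined as 1 when `sx sy = 0`);
#' ASM (energy) `= sum p^2`; homogeneity `= sum p / (1 + |i - j|)`;
#' entropy `= -sum p log2 p` over nonzero entries (bits).
#'
#' @param p A GLCM probability matrix.
#' @return Named numeric vector `contrast`, `correlation`, `asm`,
#'   `homogeneity`, `entropy`.
#' @export
glcm_descriptors <- function(p) {
  n <- nrow(p)
  idx <- seq_len(n) - 1
  I <- matrix(idx, n, n)
  J <- t(I)
  contrast <- sum(p * (I - J)^2)
  px <- rowSums(p); py <- colSums(p)
  mux <- sum(idx * px); muy <- sum(idx * py)
  sx <- sqrt(sum((idx - mux)^2 * px)); sy <- sqrt(sum((idx - muy)^2 * py))
  correlation <- if (sx * sy == 0) 1 else sum(p * (I - mux) * (J - muy)) / (sx * sy)
  asm <- sum(p^2)
  homogeneity <- sum(p / (1 + abs(I - J)))
  nz <- p[p > 0]
  entropy <- -sum(nz * log2(nz))
  c(contrast = contrast, correlation = correlation, asm = asm,
    homogeneity = homogeneity, entropy = entropy)
}

#' Canonical names of the 25 texture features
#'
#' Descriptor-major ordering: for each descriptor in Contrast, Correlation,
#' ASM, Homogeneity, Entropy, the four per-angle values (0, 45, 90, 135
#' degrees) followed by the across-angle arithmetic mean, named by the bare
#' descriptor (e.g. `Contrast0`, `Contrast45`, `Contrast90`, `Contrast135`,
#' `Contrast`).
#'
#' @return Character vector of length 25.
#' @export
feature_names <- function() {
  desc <- c("Contrast", "Correlation", "ASM", "Homogeneity", "Entropy")
  unlist(lapply(desc, function(d) c(paste0(d, c("0", "45", "90", "135")), d)),
         use.names = FALSE)
}

#' Extract the 25-dimensional GLCM feature vector of one image
#'
#' Quantizes the image, computes one symmetric normalized GLCM per angle,
#' derives the five descriptors for each, and appends the across-angle
#' arithmetic means, in canonical order ([feature_names()]).
#'
#' @param img An [new_image2d()] (typically preprocessed) image.
#' @param cfg A [glcm_config()].
#' @return One-row tibble with 25 named feature columns.
#' @export
extract_features <- function(img, cfg = glcm_config()) {
  q <- quantize(img, cfg$levels)
  per_angle <- vapply(cfg$angles, function(a) {
    glcm_descriptors(glcm(q, levels = cfg$levels, angle = a, distance = cfg$distance))
  }, numeric(5))                                  # 5 descriptors x 4 angles
  vals <- as.vector(t(cbind(per_angle, rowMeans(per_angle))))
  tibble::as_tibble(as.list(setNames(vals, feature_names())))
}

#' Build a feature table for a whole manifest
#'
#' Loads each image, optionally applies the enhancement chain, and extracts
#' the 25 canonical GLCM features.
#'
#' @param manifest A manifest tibble ([read_manifest()]).
#' @param cfg A [glcm_config()].
#' @param enhance_cfg Optional [enhance_config()]; `NULL` skips enhancement.
#' @return A feature table tibble in canonical column order.
#' @export
features_from_manifest <- function(manifest, cfg = glcm_config(), enhance_cfg = NULL) {
  feats <- purrr::map(seq_len(nrow(manifest)), function(i) {
    img <- load_image(manifest$path[i])
    if (!is.null(enhance_cfg)) img <- enhance(img, enhance_cfg)
    extract_features(img, cfg)
  })
  dplyr::bind_cols(
    manifest[c("image_id", "patient_id", "label")],
    dplyr::bind_rows(feats)
  )
}

#' Leakage-safe z-score standardization
#'
#' `zscore_fit()` learns per-column means and SDs from *training rows only*;
#' `zscore_apply()` transforms any table with those statistics. Columns with
#' zero training SD map to 0 for all rows.
#'
#' @param train Training feature table (or any data frame holding `columns`).
#' @param columns Columns to standardize (default the 25 features).
#' @return `zscore_fit()` returns a `standardizer`; `zscore_apply()` returns
#'   the transformed tibble.
#' @export
zscore_fit <- function(train, columns = feature_names()) {
  missing <- setdiff(columns, names(train))
  if (length(missing) > 0) {
    abort(sprintf("standardizer schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  x <- as.matrix(train[columns])
  structure(list(columns = columns,
                 mean = colMeans(x),
                 sd = apply(x, 2, stats::sd)),
            class = "standardizer")
}

#' @rdname zscore_fit
#' @param std A fitted `standardizer`.
#' @param table Table to transform.
#' @export
zscore_apply <- function(std, table) {
  stopifnot(inherits(std, "standardizer"))
  missing <- setdiff(std$columns, names(table))
  if (length(missing) > 0) {
    abort(sprintf("standardizer schema error: missing column(s) %s",
                  paste(missing, collapse = ", ")))
  }
  out <- table
  for (k in seq_along(std$columns)) {
    col <- std$columns[k]
    if (std$sd[k] == 0 || is.na(std$sd[k])) {
      out[[col]] <- rep(0, nrow(table))
    } else {
      out[[col]] <- (table[[col]] - std$mean[k]) / std$sd[k]
    }
  }
  tibble::as_tibble(out)
}
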