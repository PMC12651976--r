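#' Restoration class labels
#'
#' The closed five-class label set, in canonical order. Labels are
#' lower-snake-case tokens; their clinical display names are
#' "filling", "implant", "root-canal treatment", "fixed partial denture
#' (bridge)" and "crown".
#'
#' @return Character vector of the 5 class labels.
#' @export
#' @examples
#' restoration_classes()
restoration_classes <- function() {
  c("filling", "implant", "root_canal", "bridge", "crown")
}

#' Construct a grayscale image matrix
#'
#' Images are plain integer matrices (rows = image height) carrying a
#' `depth` attribute (8 or 16 bits). All enhancement and texture code
#' operates on this representation; intensity normalization is never hidden
#' inside I/O.
#'
#' @param mat Numeric matrix of non-negative integers.
#' @param depth Bit depth, 8 or 16.
#' @return An `image2d` object (integer matrix with `depth` attribute).
#' @export
new_image2d <- function(mat, depth = 8L) {
  stopifnot(is.matrix(mat))
  depth <- as.integer(depth)
  if (!depth %in% c(8L, 16L)) abort("`depth` must be 8 or 16.")
  m <- matrix(as.integer(round(mat)), nrow = nrow(mat))
  if (any(m < 0L) || any(m > bit_max(depth))) {
    abort(sprintf("pixel values must lie in [0, %d] for depth %d", bit_max(depth), depth))
  }
  structure(m, depth = depth, class = c("image2d", class(m)))
}

bit_max <- function(depth) as.integer(2^depth - 1)

image_depth <- function(img) {
  d <- attr(img, "depth")
  if (is.null(d)) 8L else as.integer(d)
}

#' @export
print.image2d <- function(x, ...) {
  cat(sprintf("<image2d %d x %d, %d-bit, range [%d, %d]>\n",
              nrow(x), ncol(x), image_depth(x), min(x), max(x)))
  invisible(x)
}
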