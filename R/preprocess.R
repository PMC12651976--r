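#' Enhancement configuration
#'
#' Defaults follow the enhancement chain used on 2775 x 1504 panoramic
#' radiographs: centered crop to 1700 x 880 to discard non-diagnostic
#' margins, global histogram equalization, then CLAHE with clip limit 2.0 on
#' an 8 x 8 tile grid. Cropping is only applied when the source exceeds the
#' target, so small synthetic frames pass through unchanged.
#'
#' @param crop_to Target `c(width, height)` in pixels.
#' @param clahe_clip CLAHE clip limit, a multiple of the uniform tile
#'   histogram height; must be positive.
#' @param clahe_grid CLAHE tile grid `c(rows, cols)`.
#' @param apply_he,apply_clahe Stage switches.
#' @return A list of class `enhance_config`.
#' @export
enhance_config <- function(crop_to = c(1700, 880), clahe_clip = 2.0,
                           clahe_grid = c(8, 8), apply_he = TRUE,
                           apply_clahe = TRUE) {
  stopifnot(length(crop_to) == 2, all(crop_to >= 1),
            clahe_clip > 0, length(clahe_grid) == 2, all(clahe_grid >= 1))
  structure(list(crop_to = as.integer(crop_to), clahe_clip = clahe_clip,
                 clahe_grid = as.integer(clahe_grid),
                 apply_he = isTRUE(apply_he), apply_clahe = isTRUE(apply_clahe)),
            class = "enhance_config")
}

#' Centered crop
#'
#' Crops to exactly `target = c(width, height)` with top-left offset
#' `floor((source - target) / 2)` in each dimension.
#'
#' @param img An [new_image2d()] matrix.
#' @param target `c(width, height)` in pixels; must fit inside the image.
#' @return The cropped `image2d`.
#' @export
crop_center <- function(img, target) {
  tw <- as.integer(target[1]); th <- as.integer(target[2])
  h <- nrow(img); w <- ncol(img)
  if (tw > w || th > h) {
    abort(sprintf("crop target %dx%d exceeds source %dx%d (no padding)", tw, th, w, h))
  }
  off_c <- (w - tw) %/% 2L
  off_r <- (h - th) %/% 2L
  new_image2d(img[(off_r + 1L):(off_r + th), (off_c + 1L):(off_c + tw), drop = FALSE],
              depth = image_depth(img))
}

# Clipped-CDF lookup table mapping gray value v (0-based) to the full bit
# range; the classic HE map T(v) = round((cdf(v) - cdf_min) / (n - cdf_min)
# * (L - 1)). Returns NULL for a degenerate (constant) histogram, which
# callers treat as the identity map.
he_lut <- function(counts, L) {
  n <- sum(counts)
  cdf <- cumsum(counts)
  nz <- which(counts > 0)
  cdf_min <- cdf[nz[1]]
  if (n == cdf_min && length(nz) == 1) return(NULL)
  as.integer(round((cdf - cdf_min) / (n - cdf_min) * (L - 1)))
}

#' Global histogram equalization
#'
#' Standard cumulative-histogram mapping to the full bit range; the mapping
#' is monotone, so pixel rank order is preserved. A constant image is
#' returned unchanged. Idempotent up to +-1 gray level.
#'
#' @param img An [new_image2d()] matrix.
#' @return The equalized `image2d`, same shape and depth.
#' @export
hist_equalize <- function(img) {
  depth <- image_depth(img)
  L <- bit_max(depth) + 1L
  counts <- tabulate(as.integer(img) + 1L, nbins = L)
  lut <- he_lut(counts, L)
  if (is.null(lut)) return(img)
  new_image2d(matrix(lut[as.integer(img) + 1L], nrow = nrow(img)), depth = depth)
}

#' Contrast-limited adaptive histogram equalization (CLAHE)
#'
#' Tile-wise histogram equalization with a clip limit, bilinearly
#' interpolated between tile mappings. The clip limit is expressed as a
#' multiple of the uniform tile histogram height (`clip * n_tile_pixels /
#' n_bins`); excess mass is redistributed uniformly over all bins. Each tile
#' uses the same full-bit-range CDF map as [hist_equalize()], so with a
#' single tile and an unbounded clip limit CLAHE reduces exactly to global
#' HE.
#'
#' @param img An [new_image2d()] matrix, at least as large as the tile grid.
#' @param clip Clip limit (> 0); `Inf` disables clipping.
#' @param grid Tile grid `c(rows, cols)`.
#' @return The enhanced `image2d`, same shape and depth.
#' @export
clahe <- function(img, clip = 2.0, grid = c(8, 8)) {
  depth <- image_depth(img)
  L <- bit_max(depth) + 1L
  h <- nrow(img); w <- ncol(img)
  ny <- as.integer(grid[1]); nx <- as.integer(grid[2])
  if (h < ny || w < nx) {
    abort(sprintf("image %dx%d smaller than CLAHE grid %dx%d", w, h, nx, ny))
  }
  row_edges <- round(seq(0, h, length.out = ny + 1))
  col_edges <- round(seq(0, w, length.out = nx + 1))

  # per-tile clipped LUTs; identity for degenerate tiles
  luts <- vector("list", ny * nx)
  identity_lut <- 0:(L - 1L)
  for (ti in seq_len(ny)) {
    for (tj in seq_len(nx)) {
      vals <- img[(row_edges[ti] + 1):row_edges[ti + 1],
                  (col_edges[tj] + 1):col_edges[tj + 1]]
      counts <- tabulate(as.integer(vals) + 1L, nbins = L)
      if (is.finite(clip)) {
        limit <- clip * length(vals) / L
        excess <- sum(pmax(counts - limit, 0))
        counts <- pmin(counts, limit) + excess / L
      }
      lut <- he_lut(counts, L)
      luts[[(ti - 1L) * nx + tj]] <- if (is.null(lut)) identity_lut else lut
    }
  }

  centers_r <- (row_edges[-1] + row_edges[-(ny + 1)] + 1) / 2
  centers_c <- (col_edges[-1] + col_edges[-(nx + 1)] + 1) / 2
  rw <- interp_index(seq_len(h), centers_r, ny)
  cw <- interp_index(seq_len(w), centers_c, nx)

  out <- matrix(0, h, w)
  v1 <- as.integer(img) + 1L
  # group pixels into blocks sharing the same 4 neighbouring tiles
  rgrp <- split(seq_len(h), paste(rw$i1, rw$i2))
  cgrp <- split(seq_len(w), paste(cw$i1, cw$i2))
  for (rg in rgrp) {
    i1 <- rw$i1[rg[1]]; i2 <- rw$i2[rg[1]]
    wr <- rw$w[rg]
    for (cg in cgrp) {
      j1 <- cw$i1[cg[1]]; j2 <- cw$i2[cg[1]]
      wc <- cw$w[cg]
      v <- matrix(v1[as.vector(outer(rg, (cg - 1L) * h, `+`))], length(rg))
      m11 <- matrix(luts[[(i1 - 1L) * nx + j1]][v], length(rg))
      m12 <- matrix(luts[[(i1 - 1L) * nx + j2]][v], length(rg))
      m21 <- matrix(luts[[(i2 - 1L) * nx + j1]][v], length(rg))
      m22 <- matrix(luts[[(i2 - 1L) * nx + j2]][v], length(rg))
      W <- outer(wr, wc)
      out[rg, cg] <- W * m11 + outer(wr, 1 - wc) * m12 +
        outer(1 - wr, wc) * m21 + outer(1 - wr, 1 - wc) * m22
    }
  }
  new_image2d(pmin(pmax(round(out), 0), L - 1L), depth = depth)
}

# For each coordinate, the two neighbouring tile centers (i1 <= i2) and the
# weight of the first; coordinates outside the outermost centers clamp to
# the nearest tile (weight 1).
interp_index <- function(pos, centers, n) {
  i1 <- findInterval(pos, centers)
  i1 <- pmin(pmax(i1, 1L), n)
  i2 <- pmin(i1 + 1L, n)
  wgt <- ifelse(i2 > i1, (centers[i2] - pos) / (centers[i2] - centers[i1]), 1)
  wgt[pos <= centers[1]] <- 1
  i2[pos <= centers[1]] <- 1L
  list(i1 = as.integer(i1), i2 = as.integer(i2), w = pmin(pmax(wgt, 0), 1))
}

#' Run the full enhancement chain
#'
#' Centered crop (only when the source exceeds the target), then global HE,
#' then CLAHE, each stage switchable via the config.
#'
#' @param img An [new_image2d()] matrix.
#' @param cfg An [enhance_config()].
#' @return The enhanced `image2d`.
#' @export
enhance <- function(img, cfg = enhance_config()) {
  stopifnot(inherits(cfg, "enhance_config"))
  tw <- min(cfg$crop_to[1], ncol(img))
  th <- min(cfg$crop_to[2], nrow(img))
  out <- crop_center(img, c(tw, th))
  if (cfg$apply_he) out <- hist_equalize(out)
  if (cfg$apply_clahe) out <- clahe(out, clip = cfg$clahe_clip, grid = cfg$clahe_grid)
  out
}
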