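# Independent brute-force oracles for the GLCM machinery: plain double loops
# over pixel pairs and matrix entries, sharing no code with the package
# implementation.

oracle_offset <- function(angle, d = 1L) {
  switch(as.character(angle),
         "0" = c(0L, d), "45" = c(-d, d), "90" = c(-d, 0L), "135" = c(-d, -d))
}

oracle_glcm <- function(qimg, levels, angle, d = 1L) {
  off <- oracle_offset(angle, d)
  counts <- matrix(0, levels, levels)
  for (r in seq_len(nrow(qimg))) {
    for (cc in seq_len(ncol(qimg))) {
      r2 <- r + off[1]; c2 <- cc + off[2]
      if (r2 >= 1 && r2 <= nrow(qimg) && c2 >= 1 && c2 <= ncol(qimg)) {
        i <- qimg[r, cc] + 1; j <- qimg[r2, c2] + 1
        counts[i, j] <- counts[i, j] + 1
        counts[j, i] <- counts[j, i] + 1   # symmetrization
      }
    }
  }
  counts / sum(counts)
}

oracle_descriptors <- function(p) {
  n <- nrow(p)
  contrast <- 0; asm <- 0; homog <- 0; ent <- 0
  px <- rep(0, n); py <- rep(0, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    v <- p[i, j]
    contrast <- contrast + v * (i - j)^2
    asm <- asm + v^2
    homog <- homog + v / (1 + abs(i - j))
    if (v > 0) ent <- ent - v * log2(v)
    px[i] <- px[i] + v
    py[j] <- py[j] + v
  }
  mux <- sum((seq_len(n) - 1) * px); muy <- sum((seq_len(n) - 1) * py)
  sx <- sqrt(sum(((seq_len(n) - 1) - mux)^2 * px))
  sy <- sqrt(sum(((seq_len(n) - 1) - muy)^2 * py))
  corr <- if (sx * sy == 0) 1 else {
    s <- 0
    for (i in seq_len(n)) for (j in seq_len(n)) {
      s <- s + p[i, j] * ((i - 1) - mux) * ((j - 1) - muy)
    }
    s / (sx * sy)
  }
  c(contrast = contrast, correlation = corr, asm = asm,
    homogeneity = homog, entropy = ent)
}

oracle_quantize <- function(img, levels) {
  lo <- min(img); hi <- max(img)
  if (lo == hi) return(matrix(0L, nrow(img), ncol(img)))
  q <- floor((img - lo) / (hi - lo) * levels)
  matrix(as.integer(pmin(q, levels - 1)), nrow(img))
}

oracle_features <- function(img, levels = 8L) {
  q <- oracle_quantize(img, levels)
  angles <- c(0, 45, 90, 135)
  per <- sapply(angles, function(a) oracle_descriptors(oracle_glcm(q, levels, a)))
  vals <- c()
  for (d in 1:5) vals <- c(vals, per[d, ], mean(per[d, ]))
  stats::setNames(vals, feature_names())
}
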