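#' Phantom dataset specification
#'
#' Describes a synthetic radiograph-like dataset: per-patient grouping, five
#' imbalanced classes with one dominant label per image, and class-dependent
#' bright high-density inserts emulating metallic restorations on a
#' correlated-noise background. Defaults loosely mirror a small single-center
#' panoramic collection (160 images, imbalanced five-class priors) while
#' remaining fast on one CPU. These images are statistical stand-ins for
#' texture analysis, not anatomically realistic radiographs.
#'
#' @param n_patients Number of patients (>= 2).
#' @param images_per_patient Images per patient.
#' @param class_priors Named or ordered probabilities for the 5 classes
#'   (order of [restoration_classes()]); must sum to 1.
#' @param image_size `c(height, width)`, each >= 64.
#' @param effect_size Scale of between-class texture differences (>= 0); at
#'   0 the class-conditional components vanish.
#' @param noise_sd Additive white-noise SD on the `[0, 1]` intensity scale.
#' @param seed Integer seed controlling every random draw.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(n_patients = 40L, images_per_patient = 4L,
                         class_priors = c(filling = 0.30, implant = 0.15,
                                          root_canal = 0.20, bridge = 0.15,
                                          crown = 0.20),
                         image_size = c(96L, 96L), effect_size = 2,
                         noise_sd = 0.05, seed = 1L) {
  stopifnot(length(class_priors) == 5, all(class_priors >= 0),
            length(image_size) == 2, effect_size >= 0, noise_sd >= 0)
  if (abs(sum(class_priors) - 1) > 1e-9) abort("class_priors must sum to 1")
  if (any(image_size < 64)) abort("image_size dimensions must be >= 64")
  structure(list(n_patients = as.integer(n_patients),
                 images_per_patient = as.integer(images_per_patient),
                 class_priors = setNames(as.numeric(class_priors), restoration_classes()),
                 image_size = as.integer(image_size),
                 effect_size = effect_size, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Deterministic 31-bit hash of a patient id string.
patient_hash <- function(patient_id) {
  codes <- utf8ToInt(as.character(patient_id))
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

# Stationary correlated-noise background: white noise smoothed with a
# separable Gaussian kernel (correlation length ~ 8 px), standardized.
gaussian_field <- function(h, w, sigma = 4) {
  half <- ceiling(3 * sigma)
  g <- exp(-((-half:half)^2) / (2 * sigma^2))
  g <- g / sum(g)
  z <- matrix(rnorm((h + 2 * half) * (w + 2 * half)), h + 2 * half)
  smooth1 <- function(m) {
    out <- matrix(0, nrow(m) - 2 * half, ncol(m))
    for (k in seq_along(g)) out <- out + g[k] * m[k:(k + nrow(out) - 1), , drop = FALSE]
    out
  }
  f <- t(smooth1(t(smooth1(z))))
  (f - mean(f)) / stats::sd(f)
}

soft_disk <- function(H, W, cr, cc, radius, edge = 1) {
  d <- sqrt(outer((seq_len(H) - cr)^2, (seq_len(W) - cc)^2, `+`))
  1 / (1 + exp((d - radius) / edge))
}

# Class-conditional bright component on the [0, 1] scale (before amplitude
# scaling). Shapes emulate the radiographic appearance of metallic inserts:
# implant = one bright high-intensity disk; crown = compact blob with a
# smooth border; bridge = elongated bar; filling = several small sharp
# speckles; root_canal = thin linear streaks.
class_component <- function(class_label, H, W) {
  cr <- runif(1, 0.3 * H, 0.7 * H)
  cc <- runif(1, 0.3 * W, 0.7 * W)
  switch(class_label,
    implant = soft_disk(H, W, cr, cc, radius = runif(1, 8, 10), edge = 0.4),
    crown = {
      # broad blob with a smooth gradient border: low edge contrast
      r <- runif(1, 18, 24)
      d2 <- outer((seq_len(H) - cr)^2, (seq_len(W) - cc)^2, `+`)
      exp(-d2 / (2 * (r / 1.5)^2))
    },
    bridge = {
      # elongated near-horizontal bar
      len <- runif(1, 0.6, 0.85) * W; th <- runif(1, 5, 8)
      ang <- runif(1, -8, 8) * pi / 180
      u <- cos(ang) * outer(rep(1, H), seq_len(W) - cc) +
        sin(ang) * outer(seq_len(H) - cr, rep(1, W))
      v <- -sin(ang) * outer(rep(1, H), seq_len(W) - cc) +
        cos(ang) * outer(seq_len(H) - cr, rep(1, W))
      1 / (1 + exp((abs(u) - len / 2) / 1.2)) * 1 / (1 + exp((abs(v) - th / 2) / 0.6))
    },
    filling = {
      # many small sharp speckles: high-frequency transitions everywhere
      n <- sample(10:16, 1)
      comp <- matrix(0, H, W)
      for (s in seq_len(n)) {
        comp <- pmax(comp, soft_disk(H, W, runif(1, 5, H - 5), runif(1, 5, W - 5),
                                     radius = runif(1, 1.5, 3), edge = 0.3))
      }
      comp
    },
    root_canal = {
      # thin near-vertical streaks (orthogonal to the bridge orientation)
      n <- sample(4:6, 1)
      comp <- matrix(0, H, W)
      cols <- matrix(seq_len(W), H, W, byrow = TRUE)
      rows <- matrix(seq_len(H), H, W)
      for (s in seq_len(n)) {
        r0 <- runif(1, 0.15 * H, 0.45 * H); c0 <- runif(1, 0.15 * W, 0.85 * W)
        ang <- (90 + runif(1, -8, 8)) * pi / 180
        len <- runif(1, 0.45, 0.75) * H
        u <- cos(ang) * (cols - c0) + sin(ang) * (rows - r0)
        v <- -sin(ang) * (cols - c0) + cos(ang) * (rows - r0)
        streak <- exp(-v^2 / (2 * 0.9^2)) * (u >= 0 & u <= len)
        comp <- pmax(comp, streak)
      }
      comp
    },
    abort(sprintf("unknown class %s; valid classes are: %s", sQuote(class_label),
                  paste(restoration_classes(), collapse = ", ")))
  )
}

#' Generate one phantom image
#'
#' Background = standardized Gaussian random field (white noise convolved
#' with a Gaussian kernel, correlation length about 8 px) shifted to a
#' mid-gray working range, multiplied by a deterministic per-patient gain
#' (so images within a patient are correlated), plus a class-conditional
#' bright component whose contrast scales with `effect_size`, plus additive
#' white noise; clipped to `[0, 1]` and quantized to 8 bits.
#'
#' @param class_label One of [restoration_classes()].
#' @param patient_id Patient identifier string (drives the per-patient gain).
#' @param spec A [phantom_spec()].
#' @param seed Integer seed; the same (class, patient, seed) triple always
#'   yields a bit-identical image.
#' @return An 8-bit [new_image2d()] matrix.
#' @export
generate_phantom <- function(class_label, patient_id, spec = phantom_spec(),
                             seed = spec$seed) {
  if (!class_label %in% restoration_classes()) {
    abort(sprintf("unknown class %s; valid classes are: %s", sQuote(class_label),
                  paste(restoration_classes(), collapse = ", ")))
  }
  H <- spec$image_size[1]; W <- spec$image_size[2]
  gain <- 1 + 0.06 * sin(patient_hash(patient_id) %% 10007 / 10007 * 2 * pi)
  img <- withr::with_seed(seed, {
    bg <- 0.40 + 0.085 * gaussian_field(H, W)
    bg <- bg * gain
    if (spec$effect_size > 0) {
      amp <- 0.15 * spec$effect_size
      bg <- bg + amp * class_component(class_label, H, W)
    }
    bg + rnorm(H * W, sd = spec$noise_sd)
  })
  new_image2d(round(pmin(pmax(img, 0), 1) * 255), depth = 8L)
}

#' Generate a full phantom dataset on disk
#'
#' Draws one dominant label per image from the class priors, renders each
#' phantom, writes 8-bit PNGs plus a `manifest.csv`, and returns the
#' validated manifest. Two runs with the same spec are identical.
#'
#' @param spec A [phantom_spec()] (needs `n_patients >= 2`).
#' @param dir Output directory (created if needed).
#' @return The manifest tibble.
#' @export
generate_dataset <- function(spec = phantom_spec(), dir = tempfile("phantom")) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (spec$n_patients < 2) abort("phantom spec error: n_patients must be >= 2")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n_img <- spec$n_patients * spec$images_per_patient
  patients <- sprintf("P%03d", seq_len(spec$n_patients))
  labels <- withr::with_seed(spec$seed, {
    sample(restoration_classes(), n_img, replace = TRUE, prob = spec$class_priors)
  })
  records <- purrr::map(seq_len(n_img), function(i) {
    pid <- patients[(i - 1L) %/% spec$images_per_patient + 1L]
    img_seed <- derive_seed(spec$seed, i)
    img <- generate_phantom(labels[i], pid, spec, seed = img_seed)
    fn <- file.path(dir, sprintf("img%04d.png", i))
    png::writePNG(unclass(img) / 255, fn)
    tibble::tibble(image_id = sprintf("img%04d", i), patient_id = pid,
                   path = fn, label = labels[i])
  })
  manifest <- validate_manifest(dplyr::bind_rows(records))
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}
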