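# Synthetic liver-phantom generator.
#
# Emulates pre-cropped 8-bit abdominal-CT-like frames: an elliptical "organ"
# carrying correlated Gaussian texture on a constant zero background, with
# four texture classes -- normal parenchyma, cancer-like irregular focal
# lesions, cirrhosis-like diffuse roughness, and cyst-like homogeneous round
# lesions. Ground-truth lesion masks make every downstream stage testable
# without clinical data.

PHANTOM_CLASSES <- c("normal", "cancer", "cirrhosis", "cyst")

#' Configuration for one synthetic phantom image
#'
#' Per-class defaults follow the qualitative radiological picture each class
#' emulates: cirrhosis gets globally rougher parenchyma (larger `base_std`,
#' shorter `texture_correlation_length`); cancer gets one to three irregular
#' hypodense focal lesions with rough internal texture; cyst gets a single
#' round, sharply bounded, internally homogeneous hypodense lesion. Lesion
#' parameters are ignored (and the lesion mask is all zero) for the
#' `normal` and `cirrhosis` classes.
#'
#' @param class_name One of `"normal"`, `"cancer"`, `"cirrhosis"`, `"cyst"`.
#' @param image_side Frame side in pixels (square), at least 64. Default 512.
#' @param organ_fraction Fraction of the frame area covered by the organ
#'   ellipse, in (0, 1). Default 0.45.
#' @param base_mean,base_std Mean and standard deviation of the parenchyma
#'   intensity texture (8-bit units).
#' @param texture_correlation_length Gaussian smoothing scale (pixels) of the
#'   correlated noise field; shorter means rougher texture.
#' @param lesion_count_range Integer pair: inclusive range of focal-lesion
#'   counts (cancer class).
#' @param lesion_radius_range Pair of pixel radii for focal lesions.
#' @param lesion_contrast Intensity offset of lesion vs parenchyma (negative
#'   = hypodense).
#' @param lesion_texture_std Intensity standard deviation inside lesions.
#' @param seed Integer seed; the phantom is a deterministic function of the
#'   full configuration including this seed.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(class_name,
                           image_side = 512,
                           organ_fraction = 0.45,
                           base_mean = 120,
                           base_std = NULL,
                           texture_correlation_length = NULL,
                           lesion_count_range = NULL,
                           lesion_radius_range = NULL,
                           lesion_contrast = NULL,
                           lesion_texture_std = NULL,
                           seed = 1) {
  if (!is.character(class_name) || length(class_name) != 1 ||
      !class_name %in% PHANTOM_CLASSES) {
    stop_param(sprintf("`class_name` must be one of %s",
                       paste(PHANTOM_CLASSES, collapse = ", ")),
               field = "class_name")
  }
  base_std <- base_std %||% switch(class_name, cirrhosis = 28, 12)
  texture_correlation_length <- texture_correlation_length %||%
    switch(class_name, cirrhosis = 1.2, 3)
  lesion_count_range <- lesion_count_range %||%
    switch(class_name, cancer = c(1L, 3L), cyst = c(1L, 1L), c(0L, 0L))
  lesion_radius_range <- lesion_radius_range %||%
    switch(class_name, cyst = c(25, 50), c(20, 45))
  lesion_contrast <- lesion_contrast %||%
    switch(class_name, cancer = -45, cyst = -60, 0)
  lesion_texture_std <- lesion_texture_std %||%
    switch(class_name, cyst = 1, 18)

  cfg <- list(class_name = class_name, image_side = image_side,
              organ_fraction = organ_fraction, base_mean = base_mean,
              base_std = base_std,
              texture_correlation_length = texture_correlation_length,
              lesion_count_range = lesion_count_range,
              lesion_radius_range = lesion_radius_range,
              lesion_contrast = lesion_contrast,
              lesion_texture_std = lesion_texture_std,
              seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (!is_scalar_num(cfg$image_side) || cfg$image_side < 64) {
    stop_param("`image_side` must be a single number >= 64", "image_side")
  }
  if (!is_scalar_num(cfg$organ_fraction) ||
      cfg$organ_fraction <= 0 || cfg$organ_fraction >= 1) {
    stop_param("`organ_fraction` must lie strictly in (0, 1)", "organ_fraction")
  }
  # worst-case semi-major axis (aspect jitter <= exp(0.08)) must fit strictly
  a_max <- cfg$image_side * sqrt(cfg$organ_fraction * 1.25 * exp(0.08) / pi)
  if (a_max + 0.02 * cfg$image_side >= cfg$image_side / 2 - 1) {
    stop_param("`organ_fraction` too large: organ would touch the frame",
               "organ_fraction")
  }
  if (!is_scalar_num(cfg$base_mean) || cfg$base_mean < 0 || cfg$base_mean > 255) {
    stop_param("`base_mean` must lie in [0, 255]", "base_mean")
  }
  if (!is_scalar_num(cfg$base_std) || cfg$base_std < 0) {
    stop_param("`base_std` must be >= 0", "base_std")
  }
  if (!is_scalar_num(cfg$texture_correlation_length) ||
      cfg$texture_correlation_length <= 0) {
    stop_param("`texture_correlation_length` must be > 0",
               "texture_correlation_length")
  }
  if (cfg$class_name %in% c("cancer", "cyst")) {
    lr <- cfg$lesion_count_range
    if (length(lr) != 2 || any(lr < 0) || lr[1] > lr[2] ||
        (cfg$class_name == "cancer" && lr[2] < 1)) {
      stop_param("`lesion_count_range` must be a non-decreasing pair (>= 1 lesion for cancer)",
                 "lesion_count_range")
    }
    rr <- cfg$lesion_radius_range
    if (length(rr) != 2 || any(rr <= 0) || rr[1] > rr[2]) {
      stop_param("`lesion_radius_range` must be a positive non-decreasing pair",
                 "lesion_radius_range")
    }
  }
  invisible(cfg)
}

# Separable Gaussian smoothing with circular boundary, used to give the
# white-noise field its correlation length.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  sm <- stats::filter(mat, k, sides = 2, circular = TRUE)       # columns
  sm <- stats::filter(t(sm), k, sides = 2, circular = TRUE)     # rows
  matrix(as.numeric(t(sm)), nrow(mat), ncol(mat))
}

correlated_field <- function(n, sigma) {
  f <- gaussian_smooth(matrix(rnorm(n * n), n, n), sigma)
  (f - mean(f)) / sd(f)
}

#' Generate one synthetic phantom image
#'
#' Deterministic function of the configuration (including its seed). Organ
#' pixels carry correlated Gaussian texture affine-mapped around
#' `base_mean`; every pixel outside the organ ellipse is exactly 0, so a
#' block tiled entirely from background has a single gray level (and hence
#' GLCM angular second moment 1). The cancer class embeds irregular focal
#' lesions (unions of 3--7 jittered disks); the cyst class a single round
#' homogeneous disk; both are recorded in the returned lesion mask.
#'
#' @param config A [phantom_config()].
#' @return A `phantom_sample`: list with `image` (integer matrix), `bag_label`
#'   (+1 for cancer, -1 otherwise), `class_name`, `lesion_mask` (0/1 integer
#'   matrix), `seed_used`.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  n <- as.integer(config$image_side)
  withr::with_seed(config$seed, {
    ratio <- 1.25 * exp(runif(1, -0.08, 0.08))
    cx <- (n + 1) / 2 + runif(1, -0.015, 0.015) * n
    cy <- (n + 1) / 2 + runif(1, -0.015, 0.015) * n
    ab <- config$organ_fraction * n^2 / pi
    b <- sqrt(ab / ratio)
    a <- ratio * b

    row_idx <- matrix(seq_len(n), n, n)
    col_idx <- matrix(seq_len(n), n, n, byrow = TRUE)
    organ <- ((col_idx - cx) / a)^2 + ((row_idx - cy) / b)^2 <= 1

    field <- correlated_field(n, config$texture_correlation_length)
    img <- matrix(0, n, n)
    img[organ] <- config$base_mean + config$base_std * field[organ]

    mask <- matrix(0L, n, n)
    if (config$class_name %in% c("cancer", "cyst")) {
      lesion_field <- correlated_field(n, 1.5)
      k_lesions <- if (config$lesion_count_range[1] == config$lesion_count_range[2]) {
        config$lesion_count_range[1]
      } else {
        sample(seq(config$lesion_count_range[1], config$lesion_count_range[2]), 1)
      }
      for (li in seq_len(k_lesions)) {
        radius <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
        reff <- if (config$class_name == "cancer") 1.8 * radius else radius
        reff <- min(reff, 0.8 * b)
        phi <- runif(1, 0, 2 * pi)
        t0 <- sqrt(runif(1))
        x0 <- cx + t0 * (a - reff) * cos(phi)
        y0 <- cy + t0 * (b - reff) * sin(phi)
        lesion <- matrix(FALSE, n, n)
        if (config$class_name == "cancer") {
          # irregular: union of jittered overlapping disks
          for (di in seq_len(sample(3:7, 1))) {
            dx <- runif(1, -0.7, 0.7) * radius
            dy <- runif(1, -0.7, 0.7) * radius
            rd <- runif(1, 0.45, 0.85) * radius
            lesion <- lesion |
              ((col_idx - x0 - dx)^2 + (row_idx - y0 - dy)^2 <= rd^2)
          }
        } else {
          lesion <- (col_idx - x0)^2 + (row_idx - y0)^2 <= radius^2
        }
        lesion <- lesion & organ
        img[lesion] <- config$base_mean + config$lesion_contrast +
          config$lesion_texture_std * lesion_field[lesion]
        mask[lesion] <- 1L
      }
    }

    img <- matrix(as.integer(round(clamp255(img))), n, n)
    structure(list(image = img,
                   bag_label = if (config$class_name == "cancer") 1L else -1L,
                   class_name = config$class_name,
                   lesion_mask = mask,
                   seed_used = config$seed,
                   config = config),
              class = "phantom_sample")
  })
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("<phantom_sample> %s, %dx%d, bag label %+d, lesion pixels %d\n",
              x$class_name, nrow(x$image), ncol(x$image), x$bag_label,
              sum(x$lesion_mask)))
  invisible(x)
}

#' Generate a labelled phantom dataset
#'
#' Draws `per_class_counts[class]` phantoms per class with per-sample seeds
#' derived reproducibly from `master_seed`, and assigns a stratified random
#' 50/50 train/test split within each class.
#'
#' @param per_class_counts Named integer vector, e.g.
#'   `c(cancer = 80, normal = 120)`; names from
#'   `normal`, `cancer`, `cirrhosis`, `cyst`.
#' @param config_overrides Named list of [phantom_config()] arguments applied
#'   to every class (e.g. `list(image_side = 256)`), or a list of per-class
#'   lists keyed by class name.
#' @param master_seed Integer master seed.
#' @return A `phantom_dataset`: list with `samples` (list of
#'   `phantom_sample`) and `manifest` (tibble with columns
#'   `path`, `class`, `label`, `split`, `seed`).
#' @export
generate_dataset <- function(per_class_counts, config_overrides = list(),
                             master_seed = 1) {
  counts <- unlist(per_class_counts)
  if (is.null(names(counts)) || !all(names(counts) %in% PHANTOM_CLASSES)) {
    stop_param("`per_class_counts` must be named with phantom class names")
  }
  if (any(counts < 0)) stop_param("class counts must be >= 0")
  per_class_over <- all(names(config_overrides) %in% PHANTOM_CLASSES) &&
    length(config_overrides) > 0 && all(vapply(config_overrides, is.list, TRUE))

  samples <- list()
  rows <- list()
  idx <- 0L
  for (cls in names(counts)) {
    n_cls <- counts[[cls]]
    if (n_cls == 0) next
    over <- if (per_class_over) config_overrides[[cls]] %||% list() else config_overrides
    split <- withr::with_seed(derive_seed(master_seed, idx), {
      s <- rep("test", n_cls)
      s[sample(n_cls, ceiling(n_cls / 2))] <- "train"
      s
    })
    for (i in seq_len(n_cls)) {
      idx <- idx + 1L
      seed_i <- derive_seed(master_seed, idx)
      cfg <- do.call(phantom_config,
                     c(list(class_name = cls, seed = seed_i), over))
      sm <- generate_phantom(cfg)
      id <- sprintf("%s_%03d", cls, i)
      sm$sample_id <- id
      samples[[id]] <- sm
      rows[[id]] <- tibble(path = paste0(id, ".png"), class = cls,
                           label = sm$bag_label, split = split[i],
                           seed = seed_i)
    }
  }
  structure(list(samples = samples, manifest = bind_rows(rows)),
            class = "phantom_dataset")
}

#' Write a phantom dataset to disk
#'
#' Writes each image as an 8-bit PNG or BMP, each lesion mask as a 0/255
#' PNG alongside it (`<id>_mask.png`), and the manifest as a CSV with
#' columns `path,class,label,split`.
#'
#' @param dataset A `phantom_dataset` from [generate_dataset()], or a bare
#'   list of `phantom_sample` objects.
#' @param directory Output directory (created if missing).
#' @param format `"png"` (default) or `"bmp"` for the images.
#' @return The manifest file path, invisibly.
#' @export
write_dataset <- function(dataset, directory, format = c("png", "bmp")) {
  format <- match.arg(format)
  if (inherits(dataset, "phantom_dataset")) {
    samples <- dataset$samples
    manifest <- dataset$manifest
  } else {
    samples <- dataset
    manifest <- tibble(
      path = vapply(seq_along(samples), function(i) {
        id <- samples[[i]]$sample_id %||% sprintf("sample_%03d", i)
        paste0(id, ".png")
      }, ""),
      class = vapply(samples, function(s) s$class_name, ""),
      label = vapply(samples, function(s) as.integer(s$bag_label), 1L),
      split = rep(NA_character_, length(samples)))
  }
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  if (!dir.exists(directory)) stop_io(sprintf("cannot create %s", directory))
  manifest$path <- sub("\\.(png|bmp)$", paste0(".", format), manifest$path)
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    write_gray_image(sm$image, file.path(directory, manifest$path[i]))
    mask_path <- sub(paste0("\\.", format, "$"), "_mask.png", manifest$path[i])
    write_gray_image(sm$lesion_mask * 255L, file.path(directory, mask_path))
  }
  manifest_path <- file.path(directory, "manifest.csv")
  write.csv(manifest[, c("path", "class", "label", "split")],
            manifest_path, row.names = FALSE)
  invisible(manifest_path)
}

#' Load a dataset written by [write_dataset()]
#'
#' @param manifest_path Path to the `manifest.csv`.
#' @return List with `samples` (images and masks re-read from disk) and the
#'   `manifest` tibble.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path)) {
    stop_io(sprintf("manifest not found: %s", manifest_path), manifest_path)
  }
  manifest <- as_tibble(read.csv(manifest_path, stringsAsFactors = FALSE))
  dir <- dirname(manifest_path)
  samples <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- read_gray_image(file.path(dir, manifest$path[i]))
    mask_path <- file.path(dir, sub("\\.(png|bmp)$", "_mask.png", manifest$path[i]))
    mask <- if (file.exists(mask_path)) {
      matrix(as.integer(read_gray_image(mask_path) > 127),
             nrow(img), ncol(img))
    } else {
      matrix(0L, nrow(img), ncol(img))
    }
    structure(list(image = img, bag_label = as.integer(manifest$label[i]),
                   class_name = manifest$class[i], lesion_mask = mask,
                   seed_used = NA_integer_,
                   sample_id = sub("\\.(png|bmp)$", "", basename(manifest$path[i]))),
              class = "phantom_sample")
  })
  names(samples) <- vapply(samples, function(s) s$sample_id, "")
  list(samples = samples, manifest = manifest)
}
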