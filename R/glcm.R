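# Gray-level co-occurrence matrix (GLCM) texture features.
#
# For each block, co-occurrence tables are accumulated symmetrically at
# distances d = {1, 2} and directions theta = {0, 45, 90, 135} degrees, and
# four Haralick-style statistics are read off each table: angular second
# moment (ASM), entropy (ENT), contrast (CON) and correlation (COR). The
# per-instance feature vector is the mean and population variance of each
# statistic across the four directions, per distance: 16 values by default.

GLCM_DIRECTIONS <- c(0, 45, 90, 135)
GLCM_STAT_NAMES <- c("asm", "ent", "con", "cor")

glcm_offset <- function(d, theta) {
  switch(as.character(theta),
         "0"   = c(0L, d),   # along a row, rightward
         "45"  = c(-d, d),   # up-right
         "90"  = c(-d, 0L),  # up a column
         "135" = c(-d, -d),  # up-left
         stop_param("`theta` must be one of 0, 45, 90, 135", "theta"))
}

#' Compute a normalized gray-level co-occurrence matrix
#'
#' Intensities are quantized to `levels` equal-width bins on `[0, 255]`;
#' ordered intensity pairs at the pixel offset given by `(d, theta)` are
#' counted over all in-bounds positions, accumulated symmetrically (both
#' orderings), and normalized to sum to one. The result is therefore a
#' symmetric probability table.
#'
#' @param block Integer matrix in `[0, 255]`.
#' @param d Offset distance in pixels (1 or 2 in the standard recipe).
#' @param theta Direction in degrees: 0, 45, 90 or 135.
#' @param levels Number of gray-level bins `G` (default 64).
#' @return A `glcm` object: list with `P` (G x G probability matrix), `G`,
#'   `d`, `theta`.
#' @export
compute_glcm <- function(block, d, theta, levels = 64) {
  assert_gray_image(block, "block")
  if (!is_scalar_num(d) || d < 1 || d >= min(dim(block))) {
    stop_param("`d` must satisfy 1 <= d < min block side", "d")
  }
  if (!is_scalar_num(levels) || levels < 2) {
    stop_param("`levels` must be >= 2", "levels")
  }
  d <- as.integer(d); G <- as.integer(levels)
  q <- matrix(pmin(as.integer(floor(block * (G / 256))), G - 1L),
              nrow(block), ncol(block))
  off <- glcm_offset(d, theta)
  nr <- nrow(q); nc <- ncol(q)
  rows <- seq_len(nr)[seq_len(nr) + off[1] >= 1 & seq_len(nr) + off[1] <= nr]
  cols <- seq_len(nc)[seq_len(nc) + off[2] >= 1 & seq_len(nc) + off[2] <= nc]
  if (length(rows) == 0 || length(cols) == 0) {
    stop_param("offset leaves no valid pixel pairs", "d")
  }
  i1 <- q[rows, cols, drop = FALSE]
  i2 <- q[rows + off[1], cols + off[2], drop = FALSE]
  counts <- tabulate(as.integer(i1) * G + as.integer(i2) + 1L, nbins = G * G) +
    tabulate(as.integer(i2) * G + as.integer(i1) + 1L, nbins = G * G)
  P <- matrix(counts / sum(counts), G, G, byrow = TRUE) # row = first index
  structure(list(P = P, G = G, d = d, theta = theta), class = "glcm")
}

#' GLCM texture statistics
#'
#' Evaluates, on a normalized co-occurrence table `I(i, j)` with 0-based bin
#' indices:
#' \deqn{ASM = \sum_{i,j} I(i,j)^2, \quad
#'       ENT = -\sum_{i,j} I(i,j) \log I(i,j), \quad
#'       CON = \sum_{i,j} (i-j)^2 I(i,j),}
#' \deqn{COR = \frac{\sum_{i,j} i\,j\,I(i,j) - u_x u_y}{\sigma_x \sigma_y},}
#' with the standard GLCM marginal means and standard deviations
#' \eqn{u_x = \sum_i i \sum_j I(i,j)},
#' \eqn{\sigma_x^2 = \sum_i (i-u_x)^2 \sum_j I(i,j)} (likewise for `y`),
#' the convention `0 log 0 = 0`, and `COR = 0` when
#' \eqn{\sigma_x \sigma_y = 0} (a degenerate single-row/column table).
#' Entropy uses base-10 logarithms by default.
#'
#' @param glcm A `glcm` from [compute_glcm()] (must be normalized).
#' @param entropy_base Logarithm base for ENT (default 10).
#' @return Named numeric vector `c(asm, ent, con, cor)`.
#' @export
glcm_stats <- function(glcm, entropy_base = 10) {
  if (!inherits(glcm, "glcm")) stop_param("`glcm` must come from compute_glcm()")
  P <- glcm$P
  if (abs(sum(P) - 1) > 1e-8 || any(P < 0)) {
    stop_state("co-occurrence table is not a normalized probability table")
  }
  idx <- 0:(glcm$G - 1)
  asm <- sum(P^2)
  nz <- P[P > 0]
  ent <- -sum(nz * log(nz, base = entropy_base))
  con <- sum(outer(idx, idx, function(i, j) (i - j)^2) * P)
  px <- rowSums(P); py <- colSums(P)
  ux <- sum(idx * px); uy <- sum(idx * py)
  sx <- sqrt(sum((idx - ux)^2 * px)); sy <- sqrt(sum((idx - uy)^2 * py))
  cor <- if (sx * sy == 0) 0 else (sum(outer(idx, idx) * P) - ux * uy) / (sx * sy)
  c(asm = asm, ent = ent, con = con, cor = cor)
}

#' Names of the per-instance feature columns
#'
#' @param distances Integer vector of GLCM distances (default `c(1, 2)`).
#' @param pool_distances If `TRUE`, directional statistics are pooled across
#'   distances (8 features); otherwise each distance contributes its own
#'   mean/variance block (16 features, the default layout).
#' @return Character vector of feature column names, e.g. `"asm_mean_d1"`.
#' @export
glcm_feature_names <- function(distances = c(1, 2), pool_distances = FALSE) {
  if (pool_distances) {
    c(paste0(GLCM_STAT_NAMES, "_mean"), paste0(GLCM_STAT_NAMES, "_var"))
  } else {
    unlist(lapply(distances, function(d) {
      c(paste0(GLCM_STAT_NAMES, "_mean_d", d),
        paste0(GLCM_STAT_NAMES, "_var_d", d))
    }))
  }
}

#' Per-instance GLCM feature vector
#'
#' For each distance, the four statistics of [glcm_stats()] are computed on
#' the four directional co-occurrence tables; their mean and population
#' variance across directions are emitted in the layout of
#' [glcm_feature_names()].
#'
#' @param block Integer matrix in `[0, 255]`.
#' @param distances GLCM distances (default `c(1, 2)`).
#' @param levels Gray-level bins `G` (default 64).
#' @param entropy_base Base for the entropy logarithm (default 10).
#' @param pool_distances Pool directional statistics across distances
#'   (default `FALSE`).
#' @return Named numeric feature vector.
#' @export
instance_features <- function(block, distances = c(1, 2), levels = 64,
                              entropy_base = 10, pool_distances = FALSE) {
  per_dist <- lapply(distances, function(d) {
    vapply(GLCM_DIRECTIONS,
           function(th) glcm_stats(compute_glcm(block, d, th, levels),
                                   entropy_base = entropy_base),
           numeric(4))  # 4 stats x 4 directions
  })
  if (pool_distances) {
    all_dir <- do.call(cbind, per_dist)
    out <- c(apply(all_dir, 1, mean), apply(all_dir, 1, pop_var))
  } else {
    out <- unlist(lapply(per_dist, function(m) {
      c(apply(m, 1, mean), apply(m, 1, pop_var))
    }))
  }
  setNames(out, glcm_feature_names(distances, pool_distances))
}

# Feature columns present in a tidy instance table (either layout).
feature_cols <- function(tbl) {
  grep("^(asm|ent|con|cor)_(mean|var)", names(tbl), value = TRUE)
}

#' Featurize a set of bags into a tidy instance table
#'
#' The tidy currency of the package: one row per instance, carrying bag
#' identity and label, grid position, the GLCM feature columns, the
#' background-reservation flag and the key-instance flag `a_j`. When a bag
#' carries a ground-truth lesion mask (phantoms), the per-tile lesion
#' fraction is included as `lesion_frac`.
#'
#' @param bags A list of `mil_bag` objects (see [extract_instances()]).
#' @param masks Optional list of 0/1 matrices, parallel to `bags`, at the
#'   same resolution as the tiled images.
#' @param distances,levels,entropy_base,pool_distances Passed to
#'   [instance_features()].
#' @return A tibble with columns `bag_id`, `bag_label`, `instance_id`,
#'   `grid_row`, `grid_col`, `label`, `a_j`, `reserved`, the feature
#'   columns, and optionally `lesion_frac`.
#' @export
featurize_bags <- function(bags, masks = NULL, distances = c(1, 2),
                           levels = 64, entropy_base = 10,
                           pool_distances = FALSE) {
  feat_names <- glcm_feature_names(distances, pool_distances)
  rows <- lapply(seq_along(bags), function(bi) {
    bag <- bags[[bi]]
    inst <- bag$instances
    fm <- t(vapply(inst$block, function(b) {
      instance_features(b, distances, levels, entropy_base, pool_distances)
    }, numeric(length(feat_names))))
    out <- tibble(bag_id = bag$bag_id,
                  bag_label = bag$label,
                  instance_id = inst$instance_id,
                  grid_row = inst$grid_row,
                  grid_col = inst$grid_col,
                  label = inst$label,
                  a_j = inst$a_j,
                  reserved = inst$reserved)
    out <- dplyr::bind_cols(out, as_tibble(fm))
    if (!is.null(masks)) {
      mk <- masks[[bi]]
      out$lesion_frac <- vapply(seq_len(nrow(inst)), function(i) {
        r <- inst[i, ]
        mean(mk[r$row_start:r$row_end, r$col_start:r$col_end])
      }, 0)
    }
    out
  })
  bind_rows(rows)
}
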