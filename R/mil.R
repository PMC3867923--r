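# Bag/instance data model. One preprocessed image is a bag; its equal-size
# square blocks, tiled over the whole frame, are the instances. A bag is
# positive iff it contains at least one lesion-class instance; under weak
# supervision every instance initially inherits its bag's label.

#' Tile an image into equal blocks (one bag of instances)
#'
#' The grid count per dimension is `k = round(side / block_length)` and the
#' tile boundaries are `round(i * side / k)` for `i = 0..k`, so tiles are
#' disjoint, cover every pixel, and differ in side by at most one pixel even
#' for fractional block lengths. Instances are ordered row-major.
#'
#' @param img Integer matrix in `[0, 255]` (need not be square).
#' @param block_length Target block side in pixels; may be fractional;
#'   must satisfy `1 <= block_length <= min(dim(img))`.
#' @param bag_id Identifier carried by every instance.
#' @param label Bag label: `+1`, `-1`, or `NA` (unlabeled).
#' @return A `mil_bag`: list with `bag_id`, `label`, `block_length`,
#'   `image_dim`, and `instances`, a tibble with one row per tile
#'   (`grid_row`, `grid_col`, pixel bounds, `block` list-column, `label`,
#'   `a_j`, `reserved`).
#' @export
extract_instances <- function(img, block_length, bag_id = "bag", label = NA) {
  assert_gray_image(img)
  if (!is_scalar_num(block_length) || block_length < 1 ||
      block_length > min(dim(img))) {
    stop_param("`block_length` must lie in [1, min image side]", "block_length")
  }
  bounds <- function(n) {
    k <- max(1L, as.integer(round(n / block_length)))
    round((0:k) * n / k)
  }
  rb <- bounds(nrow(img))
  cb <- bounds(ncol(img))
  kr <- length(rb) - 1L
  kc <- length(cb) - 1L
  grid <- expand.grid(grid_col = seq_len(kc), grid_row = seq_len(kr))
  grid <- grid[order(grid$grid_row, grid$grid_col), ]
  inst <- tibble(
    instance_id = seq_len(nrow(grid)),
    grid_row = grid$grid_row,
    grid_col = grid$grid_col,
    row_start = rb[grid$grid_row] + 1L,
    row_end = rb[grid$grid_row + 1L],
    col_start = cb[grid$grid_col] + 1L,
    col_end = cb[grid$grid_col + 1L])
  inst$block <- purrr::pmap(
    inst[c("row_start", "row_end", "col_start", "col_end")],
    function(row_start, row_end, col_start, col_end) {
      img[row_start:row_end, col_start:col_end, drop = FALSE]
    })
  inst$label <- NA_integer_
  inst$a_j <- 0L
  inst$reserved <- TRUE
  structure(list(bag_id = bag_id,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 block_length = block_length,
                 image_dim = dim(img),
                 instances = inst),
            class = "mil_bag")
}

#' Propagate the bag label to every instance
#'
#' Under weak supervision each instance is marked with the label of the bag
#' it belongs to: `+1` in a positive bag, `-1` in a negative bag.
#'
#' @param bag A `mil_bag` with `label` in `{+1, -1}`.
#' @return The bag with every instance label set.
#' @export
label_instances <- function(bag) {
  if (!inherits(bag, "mil_bag")) stop_param("`bag` must be a mil_bag")
  if (is.na(bag$label) || !bag$label %in% c(-1L, 1L)) {
    stop_state("bag is unlabeled; cannot propagate a label to instances")
  }
  bag$instances$label <- rep(bag$label, nrow(bag$instances))
  bag
}

#' @export
print.mil_bag <- function(x, ...) {
  cat(sprintf("<mil_bag> %s: %d instances (block length %s), label %s\n",
              x$bag_id, nrow(x$instances), format(x$block_length),
              if (is.na(x$label)) "unlabeled" else sprintf("%+d", x$label)))
  invisible(x)
}

#' Reassemble a bag's tiles into the original image
#'
#' Inverse of [extract_instances()]; mainly a correctness check that the
#' tiling is exact and disjoint.
#'
#' @param bag A `mil_bag`.
#' @return Integer matrix of the original image dimensions.
#' @export
reassemble_bag <- function(bag) {
  out <- matrix(NA_integer_, bag$image_dim[1], bag$image_dim[2])
  for (i in seq_len(nrow(bag$instances))) {
    r <- bag$instances[i, ]
    out[r$row_start:r$row_end, r$col_start:r$col_end] <- r$block[[1]]
  }
  out
}
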