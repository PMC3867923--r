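# Preprocessing: size normalization to a fixed square frame followed by
# global histogram equalization. Input frames are assumed pre-cropped to the
# organ region; no segmentation is attempted here.

#' Preprocessing configuration
#'
#' @param target_side Output side in pixels (square), default 339.
#' @param equalize Apply 256-bin global histogram equalization after
#'   resizing (default `TRUE`).
#' @param resize_method `"bilinear"` (default) or `"nearest"`.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(target_side = 339, equalize = TRUE,
                              resize_method = c("bilinear", "nearest")) {
  resize_method <- match.arg(resize_method)
  if (!is_scalar_num(target_side) || target_side < 2) {
    stop_param("`target_side` must be a single number >= 2", "target_side")
  }
  structure(list(target_side = as.integer(target_side),
                 equalize = isTRUE(equalize),
                 resize_method = resize_method),
            class = "preprocess_config")
}

#' Resize a grayscale image to a square frame
#'
#' Bilinear (or nearest-neighbour) resampling followed by rounding to the
#' nearest integer intensity. A constant image maps to a constant image of
#' the same value, and resizing to the input size is the identity.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @param config A [preprocess_config()].
#' @return `target_side` x `target_side` integer matrix in `[0, 255]`.
#' @export
normalize_size <- function(img, config = preprocess_config()) {
  assert_gray_image(img)
  side <- config$target_side
  filt <- if (config$resize_method == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(img, w = side, h = side, filter = filt)
  matrix(as.integer(round(clamp255(out))), side, side)
}

#' Global histogram equalization
#'
#' Classic 256-bin cumulative-distribution remap: intensity `p` maps to
#' `round(255 * (cdf(p) - cdf_min) / (1 - cdf_min))`. The remap is monotone
#' non-decreasing (rank order of pixels is preserved) and a constant image
#' is returned unchanged.
#'
#' @param img Integer matrix in `[0, 255]`.
#' @return Equalized integer matrix of the same shape.
#' @export
equalize_histogram <- function(img) {
  assert_gray_image(img)
  px <- as.integer(round(img))
  h <- tabulate(px + 1L, nbins = 256L)
  cdf <- cumsum(h) / length(px)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min >= 1) return(matrix(px, nrow(img), ncol(img))) # constant image
  lut <- as.integer(round(255 * (cdf - cdf_min) / (1 - cdf_min)))
  matrix(lut[px + 1L], nrow(img), ncol(img))
}

#' Preprocess one image
#'
#' Size normalization then (optionally) histogram equalization, in that
#' order.
#'
#' @inheritParams normalize_size
#' @return Preprocessed integer matrix, `target_side` square.
#' @export
preprocess_image <- function(img, config = preprocess_config()) {
  out <- normalize_size(img, config)
  if (config$equalize) out <- equalize_histogram(out)
  out
}
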