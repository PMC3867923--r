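# Convenience pipeline: phantom dataset -> preprocessed bags -> tidy
# instance feature table. This is the front door most analyses use.

#' Featurize a phantom dataset end to end
#'
#' Preprocesses each phantom image (size normalization + histogram
#' equalization), carries its lesion mask through the same resize with
#' nearest-neighbour sampling so it stays binary, tiles the result into a
#' bag, and computes the GLCM feature table. Adds `class` and `lesion_frac`
#' columns for ground-truth-aware analyses.
#'
#' @param dataset A `phantom_dataset` from [generate_dataset()] (or any
#'   list with `samples` of `phantom_sample` objects).
#' @param preprocess A [preprocess_config()].
#' @param block_length Tile side in pixels at the preprocessed resolution
#'   (default 113).
#' @param distances,levels,entropy_base,pool_distances GLCM settings; see
#'   [instance_features()].
#' @return Tidy instance tibble (one row per instance) with bag metadata,
#'   feature columns, `class` and `lesion_frac`.
#' @export
phantom_instance_table <- function(dataset,
                                   preprocess = preprocess_config(),
                                   block_length = 113,
                                   distances = c(1, 2), levels = 64,
                                   entropy_base = 10,
                                   pool_distances = FALSE) {
  samples <- dataset$samples
  mask_cfg <- preprocess_config(preprocess$target_side, equalize = FALSE,
                                resize_method = "nearest")
  bags <- list(); masks <- list(); classes <- character()
  for (i in seq_along(samples)) {
    sm <- samples[[i]]
    id <- sm$sample_id %||% sprintf("bag_%03d", i)
    img <- preprocess_image(sm$image, preprocess)
    bag <- extract_instances(img, block_length, bag_id = id,
                             label = sm$bag_label)
    bags[[i]] <- label_instances(bag)
    masks[[i]] <- matrix(as.integer(normalize_size(sm$lesion_mask * 255L,
                                                   mask_cfg) > 127),
                         preprocess$target_side, preprocess$target_side)
    classes[i] <- sm$class_name
  }
  feats <- featurize_bags(bags, masks, distances, levels, entropy_base,
                          pool_distances)
  class_tbl <- tibble(bag_id = vapply(bags, function(b) b$bag_id, ""),
                      class = classes)
  left_join(feats, class_tbl, by = "bag_id")
}
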