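# Comparison baselines: minimum-Hausdorff Citation-kNN, traditional
# single-instance SVM on whole-image features, and a bag-dissolution SVM
# ("WEMISVM-style") that averages instance decision values.

#' Citation-kNN configuration
#'
#' @param R Number of references: nearest training bags to the query
#'   (default 2).
#' @param C_cite Citer rank: a training bag is a citer when the query is
#'   among its `C_cite` nearest neighbours (default 4, the customary
#'   `R + 2`).
#' @return A `citation_config` list.
#' @export
citation_config <- function(R = 2, C_cite = 4) {
  stopifnot(R >= 1, C_cite >= 1)
  structure(list(R = as.integer(R), C_cite = as.integer(C_cite)),
            class = "citation_config")
}

#' Minimum Hausdorff distance between two bags
#'
#' The smallest Euclidean distance between any instance feature vector of
#' one bag and any of the other: symmetric, zero when the bags share an
#' identical instance, but not a metric (the triangle inequality can fail).
#'
#' @param bagA,bagB Numeric matrices, one row per instance feature vector.
#' @return Non-negative scalar.
#' @export
min_hausdorff_distance <- function(bagA, bagB) {
  a <- as.matrix(bagA); b <- as.matrix(bagB)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("bags must contain at least one instance", class = "iomil_value_error")
  }
  cross <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(cross)))
}

# distance from each bag in `bag_list` to every other, as a full matrix
bag_distance_matrix <- function(bag_list) {
  n <- length(bag_list)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) D[i, j] <- D[j, i] <- min_hausdorff_distance(bag_list[[i]],
                                                              bag_list[[j]])
    }
  }
  D
}

#' Citation-kNN bag prediction under minimum Hausdorff distance
#'
#' References are the `R` training bags nearest to the test bag; citers are
#' the training bags whose `C_cite`-nearest neighbourhood (among the other
#' training bags plus the test bag) contains the test bag. The predicted
#' label is the majority vote of reference and citer labels, with ties
#' broken to `-1` (non-malignant).
#'
#' @param train_features Tidy instance table of the training bags (reserved
#'   instances are used; run [first_instance_optimization()] upstream if
#'   background removal is wanted).
#' @param test_bag_features Tidy instance rows of one test bag.
#' @param config A [citation_config()].
#' @return `+1` or `-1`, with attribute `votes`.
#' @export
citation_knn_predict <- function(train_features, test_bag_features,
                                 config = citation_config()) {
  fc <- feature_cols(train_features)
  ids <- unique(train_features$bag_id)
  if (length(ids) < config$R) {
    abort(sprintf("need at least R = %d training bags", config$R),
          class = "iomil_configuration_error")
  }
  train_list <- lapply(ids, function(id) {
    as.matrix(train_features[train_features$bag_id == id, fc])
  })
  labels <- vapply(ids, function(id) {
    as.integer(train_features$bag_label[train_features$bag_id == id][1])
  }, 1L)
  test_m <- as.matrix(test_bag_features[, fc])
  d_test <- vapply(train_list, function(b) min_hausdorff_distance(b, test_m), 0)
  refs <- order(d_test)[seq_len(config$R)]
  D <- bag_distance_matrix(train_list)
  n <- length(ids)
  citers <- which(vapply(seq_len(n), function(i) {
    # neighbourhood of training bag i among the other bags plus the query
    d_all <- c(D[i, -i], d_test[i])
    rank_test <- sum(d_all <= d_test[i]) # query's rank (ties count against)
    rank_test <= config$C_cite
  }, TRUE))
  votes <- c(labels[refs], labels[citers])
  s <- sum(votes)
  out <- if (s > 0) 1L else -1L # tie -> -1, conservative
  structure(out, votes = votes)
}

#' Whole-image feature table for the single-instance baseline
#'
#' Applies the identical GLCM recipe to the full preprocessed frame, one
#' feature vector per image, so the traditional SVM sees exactly the same
#' texture descriptors as the instance-level method.
#'
#' @inheritParams phantom_instance_table
#' @return Tibble with one row per image: `bag_id`, `bag_label`, `class`,
#'   and the feature columns.
#' @export
whole_image_features <- function(dataset, preprocess = preprocess_config(),
                                 distances = c(1, 2), levels = 64,
                                 entropy_base = 10, pool_distances = FALSE) {
  samples <- dataset$samples
  rows <- lapply(seq_along(samples), function(i) {
    sm <- samples[[i]]
    img <- preprocess_image(sm$image, preprocess)
    fv <- instance_features(img, distances, levels, entropy_base,
                            pool_distances)
    dplyr::bind_cols(tibble(bag_id = sm$sample_id %||% sprintf("bag_%03d", i),
                            bag_label = as.integer(sm$bag_label),
                            class = sm$class_name),
                     as_tibble(as.list(fv)))
  })
  bind_rows(rows)
}

#' Traditional single-instance SVM baseline
#'
#' One CPSO-tuned RBF SVM on whole-image features, evaluated under the same
#' stratified 50/50 split and five-group protocol as the instance-level
#' method.
#'
#' @param image_features Output of [whole_image_features()].
#' @param pso,lo CPSO configurations.
#' @param n_groups Number of validation groups (default 5).
#' @param seed Master seed.
#' @param split Optional `bag_id`/`split` tibble to reuse a precomputed
#'   split.
#' @return List with `summary`, `groups`, `predictions`, `params`.
#' @export
single_instance_svm_baseline <- function(image_features, pso = pso_config(),
                                         lo = lo_config(), n_groups = 5,
                                         seed = 1, split = NULL) {
  bags <- image_features
  if (is.null(split)) {
    bags$split <- NA_character_
    withr::with_seed(derive_seed(seed, 101), {
      for (cl in unique(bags$class)) {
        idx <- which(bags$class == cl)
        tr <- sample(idx, floor(length(idx) / 2))
        bags$split[idx] <- "test"
        bags$split[tr] <- "train"
      }
    })
  } else {
    bags <- left_join(bags, split, by = "bag_id")
  }
  fc <- feature_cols(bags)
  tr <- bags$split == "train"
  pso$seed <- derive_seed(seed, 102)
  tuned <- cpso_optimize(as.matrix(bags[tr, fc]), bags$bag_label[tr], pso, lo)
  clf <- train_svm(as.matrix(bags[tr, fc]), bags$bag_label[tr], tuned$params)
  test <- bags[!tr, ]
  test$prediction <- predict_instances(clf, as.matrix(test[, fc]))
  test$group <- NA_integer_
  withr::with_seed(derive_seed(seed, 104), {
    for (cl in unique(test$class)) {
      idx <- sample(which(test$class == cl))
      test$group[idx] <- rep_len(seq_len(n_groups), length(idx))
    }
  })
  groups <- bind_rows(lapply(seq_len(n_groups), function(gi) {
    gp <- test[test$group == gi, ]
    dplyr::bind_cols(tibble(group = gi, n_bags = nrow(gp)),
                     evaluate_predictions(gp$prediction, gp$bag_label))
  }))
  list(summary = tibble(ACC = mean(groups$ACC, na.rm = TRUE),
                        SEN = mean(groups$SEN, na.rm = TRUE),
                        SPE = mean(groups$SPE, na.rm = TRUE)),
       groups = groups,
       predictions = test[c("bag_id", "class", "bag_label", "prediction", "group")],
       params = tuned$params)
}

#' Train a bag-dissolution ("WEMISVM-style") SVM
#'
#' Dissolves every training bag by labelling each reserved instance with
#' its bag's label and fits one CPSO-tuned SVM on the pooled instances.
#'
#' @param features Tidy instance table of the training bags.
#' @param pso,lo CPSO configurations.
#' @return An `iomil_svm` with the tuned parameters attached.
#' @export
wemisvm_train <- function(features, pso = pso_config(), lo = lo_config()) {
  res <- features
  if (!"reserved" %in% names(res)) res$reserved <- TRUE
  res <- filter(res, .data$reserved)
  fc <- feature_cols(res)
  labels <- as.integer(res$bag_label)
  tuned <- cpso_optimize(as.matrix(res[, fc]), labels, pso, lo)
  clf <- train_svm(as.matrix(res[, fc]), labels, tuned$params)
  clf$tuning <- tuned
  clf
}

#' Bag prediction by mean instance decision value
#'
#' The bag label is the sign of the mean of the pre-sign decision values of
#' its instances, with a mean of exactly zero mapping to `+1`.
#'
#' @param clf An `iomil_svm` from [wemisvm_train()].
#' @param bag_features Tidy instance rows of one bag.
#' @return `+1` or `-1`, with attribute `mean_decision`.
#' @export
wemisvm_predict <- function(clf, bag_features) {
  fc <- clf$feature_names
  if (nrow(bag_features) == 0) {
    abort("empty bag", class = "iomil_prediction_error")
  }
  dv <- decision_values(clf, as.matrix(bag_features[, fc]))
  m <- mean(dv)
  structure(if (m >= 0) 1L else -1L, mean_decision = m)
}
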