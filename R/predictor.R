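# Threshold-based bag prediction, confusion-matrix evaluation, and the
# five-group validation protocol.

#' Bag-prediction configuration
#'
#' @param P Negative-ratio threshold in `[0.5, 1]`: a bag is predicted
#'   negative when the fraction of its reserved instances predicted `-1`
#'   strictly exceeds `P` (default 0.86).
#' @param block_length Block side used when tiling test images (default
#'   113).
#' @param asm_tolerance Background-rule tolerance applied to test bags
#'   before the ratio is formed.
#' @return A `predictor_config` list.
#' @export
predictor_config <- function(P = 0.86, block_length = 113,
                             asm_tolerance = 1e-9) {
  if (!is_scalar_num(P) || P < 0.5 || P > 1) {
    stop_param("threshold `P` must lie in [0.5, 1]", "P")
  }
  structure(list(P = P, block_length = block_length,
                 asm_tolerance = asm_tolerance),
            class = "predictor_config")
}

#' Predict the label of one bag
#'
#' Applies the background rule to the bag's instances, predicts each
#' reserved instance with the instance-level SVM, and forms the negative
#' ratio `r` = (#predicted -1) / (#reserved). The bag is negative when
#' `r > P` (strictly), positive otherwise.
#'
#' @param clf An `iomil_classifier` from [build_classifier()].
#' @param bag_features Tidy feature rows of a single bag.
#' @param config Optional [predictor_config()]; defaults to the one the
#'   classifier was built with.
#' @return `+1` or `-1`, with attributes `neg_ratio`, `n_reserved` and
#'   `instance_predictions`.
#' @export
predict_bag <- function(clf, bag_features, config = NULL) {
  config <- config %||% clf$predictor
  if (length(unique(bag_features$bag_id)) > 1) {
    stop_param("`bag_features` must contain a single bag; see predict_bags()")
  }
  res <- first_instance_optimization(bag_features, config$asm_tolerance)
  res <- filter(res, .data$reserved)
  if (nrow(res) == 0) {
    abort(sprintf("bag '%s' has no reserved instances (all background)",
                  bag_features$bag_id[1]),
          class = "iomil_prediction_error")
  }
  preds <- predict_instances(clf$svm, as.matrix(res[clf$feature_cols]))
  r <- mean(preds == -1L)
  out <- if (r > config$P) -1L else 1L
  structure(out, neg_ratio = r, n_reserved = nrow(res),
            instance_predictions = preds)
}

#' Predict many bags into a tidy table
#'
#' @param clf An `iomil_classifier`.
#' @param features Tidy instance table covering one or more bags.
#' @param config Optional [predictor_config()] override.
#' @return Tibble with one row per bag: `bag_id`, `truth`, `n_reserved`,
#'   `neg_ratio`, `prediction`.
#' @export
predict_bags <- function(clf, features, config = NULL) {
  ids <- unique(features$bag_id)
  rows <- lapply(ids, function(id) {
    bf <- features[features$bag_id == id, ]
    p <- predict_bag(clf, bf, config)
    tibble(bag_id = id,
           truth = bf$bag_label[1],
           n_reserved = attr(p, "n_reserved"),
           neg_ratio = attr(p, "neg_ratio"),
           prediction = as.integer(p))
  })
  bind_rows(rows)
}

#' Confusion counts and ACC/SEN/SPE
#'
#' The positive class is the lesion (`+1`) class, so sensitivity is the
#' lesion recall and specificity the non-malignant recall:
#' `ACC = (TP + TN) / (TP + FN + TN + FP)`, `SEN = TP / (TP + FN)`,
#' `SPE = TN / (TN + FP)`. Ratios with empty denominators are reported as
#' `NA`, not 0.
#'
#' @param prediction,truth Equal-length integer vectors over `{+1, -1}`, or
#'   a [predict_bags()] tibble as the first argument.
#' @return One-row tibble with `TP`, `FN`, `TN`, `FP`, `ACC`, `SEN`, `SPE`.
#' @export
evaluate_predictions <- function(prediction, truth = NULL) {
  if (is.data.frame(prediction)) {
    truth <- prediction$truth
    prediction <- prediction$prediction
  }
  if (length(prediction) != length(truth)) {
    stop_param("`prediction` and `truth` must have equal length")
  }
  if (!all(c(prediction, truth) %in% c(-1, 1))) {
    stop_param("labels must be +1 or -1")
  }
  tp <- sum(prediction == 1 & truth == 1)
  fn <- sum(prediction == -1 & truth == 1)
  tn <- sum(prediction == -1 & truth == -1)
  fp <- sum(prediction == 1 & truth == -1)
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble(TP = tp, FN = fn, TN = tn, FP = fp,
         ACC = ratio(tp + tn, tp + fn + tn + fp),
         SEN = ratio(tp, tp + fn),
         SPE = ratio(tn, tn + fp))
}

#' Five-group validation protocol
#'
#' Splits the bags of each class 50/50 into train and test halves
#' (stratified, random under `seed`), builds the classifier on the training
#' half, deals the test half into five class-stratified groups, evaluates
#' each group with the same classifier, and averages the five groups'
#' ACC/SEN/SPE without weighting.
#'
#' @param features Tidy instance table with a `class` column (phantom class
#'   names) alongside `bag_id`/`bag_label`; see [phantom_instance_table()].
#' @param pso,lo,io,predictor Component configurations, as in
#'   [build_classifier()].
#' @param n_groups Number of validation groups (default 5).
#' @param seed Master seed for the split, folds, and swarm.
#' @param split Optional precomputed split: a tibble `bag_id`/`split`
#'   (values `"train"`/`"test"`), e.g. from a dataset manifest. When
#'   supplied the random 50/50 split is skipped.
#' @return A `five_group_report`: list with `summary` (one-row tibble of
#'   averaged ACC/SEN/SPE), `groups` (per-group metrics), `predictions`
#'   (per-bag), and the fitted `classifier`.
#' @export
five_group_validation <- function(features, pso = pso_config(),
                                  lo = lo_config(), io = io_config(),
                                  predictor = predictor_config(),
                                  n_groups = 5, seed = 1, split = NULL) {
  if (!"class" %in% names(features)) {
    stop_param("`features` must carry a `class` column for stratification")
  }
  bags <- distinct(features, .data$bag_id, .data$bag_label, .data$class)
  class_sizes <- table(bags$class)
  if (is.null(split) && any(class_sizes < 10)) {
    abort("need at least 10 bags per class to split and deal 5 groups",
          class = "iomil_configuration_error")
  }
  if (is.null(split)) {
    bags$split <- NA_character_
    withr::with_seed(derive_seed(seed, 101), {
      for (cl in names(class_sizes)) {
        idx <- which(bags$class == cl)
        tr <- sample(idx, floor(length(idx) / 2))
        bags$split[idx] <- "test"
        bags$split[tr] <- "train"
      }
    })
  } else {
    bags <- left_join(bags, split, by = "bag_id")
    if (anyNA(bags$split)) stop_param("`split` must cover every bag")
  }
  train_ids <- bags$bag_id[bags$split == "train"]
  test_bags <- bags[bags$split == "test", ]
  pso$seed <- derive_seed(seed, 102)
  clf <- build_classifier(features[features$bag_id %in% train_ids, ],
                          pso = pso, lo = lo, io = io, predictor = predictor,
                          seed = derive_seed(seed, 103))
  # deal the test bags into class-stratified groups
  test_bags$group <- NA_integer_
  withr::with_seed(derive_seed(seed, 104), {
    for (cl in unique(test_bags$class)) {
      idx <- sample(which(test_bags$class == cl))
      test_bags$group[idx] <- rep_len(seq_len(n_groups), length(idx))
    }
  })
  preds <- predict_bags(clf, features[features$bag_id %in% test_bags$bag_id, ],
                        predictor)
  preds <- left_join(preds, test_bags[c("bag_id", "class", "group")],
                     by = "bag_id")
  groups <- bind_rows(lapply(seq_len(n_groups), function(gi) {
    gp <- preds[preds$group == gi, ]
    dplyr::bind_cols(tibble(group = gi, n_bags = nrow(gp)),
                     evaluate_predictions(gp))
  }))
  summary <- tibble(ACC = mean(groups$ACC, na.rm = TRUE),
                    SEN = mean(groups$SEN, na.rm = TRUE),
                    SPE = mean(groups$SPE, na.rm = TRUE))
  structure(list(summary = summary, groups = groups, predictions = preds,
                 classifier = clf, split = bags[c("bag_id", "split")]),
            class = "five_group_report")
}

#' @export
print.five_group_report <- function(x, ...) {
  cat(sprintf("<five_group_report> mean of %d groups: ACC %.3f, SEN %.3f, SPE %.3f\n",
              nrow(x$groups), x$summary$ACC, x$summary$SEN, x$summary$SPE))
  invisible(x)
}
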