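# Two-stage instance optimization and classifier construction.
#
# Stage one removes uniform background blocks by the ASM rule (a block with
# a single gray level has ASM exactly 1). Stage two scores every reserved
# instance with bag-level cross-validated CPSO-SVMs and retains the
# correctly classified instances of high-accuracy bags -- the "excellent"
# or key instances -- as the deployable training set.

#' Instance-optimization configuration
#'
#' @param asm_tolerance Non-negative tolerance for the background rule: an
#'   instance is discarded when its mean d = 1 ASM is at least
#'   `1 - asm_tolerance` (default `1e-9`).
#' @param excellent_bag_quantile Quantile in `(0, 1]` of the per-bag
#'   instance accuracy distribution; bags at or above it contribute
#'   excellent instances (default 0.5, the median).
#' @param selection_folds Bag-level cross-validation folds used to score
#'   instances without training on them (default 5).
#' @param strict_aj_mask If `TRUE`, the final SVM down-weights the slack of
#'   negative-bag key instances (whose `a_j` is 0) instead of treating all
#'   key instances as full training rows. Default `FALSE`.
#' @return An `io_config` list.
#' @export
io_config <- function(asm_tolerance = 1e-9, excellent_bag_quantile = 0.5,
                      selection_folds = 5, strict_aj_mask = FALSE) {
  stopifnot(asm_tolerance >= 0,
            excellent_bag_quantile > 0, excellent_bag_quantile <= 1,
            selection_folds >= 2)
  structure(list(asm_tolerance = asm_tolerance,
                 excellent_bag_quantile = excellent_bag_quantile,
                 selection_folds = as.integer(selection_folds),
                 strict_aj_mask = isTRUE(strict_aj_mask)),
            class = "io_config")
}

#' First instance optimization: drop uniform background blocks
#'
#' A block tiled entirely from constant background has ASM 1 on every
#' co-occurrence table, while any block containing organ texture has
#' ASM < 1; instances whose mean d = 1 ASM reaches `1 - asm_tolerance`
#' are therefore marked not reserved. Rows are kept (flagged, not dropped)
#' so the removal is recorded.
#'
#' @param features Tidy instance table from [featurize_bags()] (must contain
#'   `asm_mean_d1`).
#' @param asm_tolerance See [io_config()].
#' @return The table with its `reserved` column updated.
#' @export
first_instance_optimization <- function(features, asm_tolerance = 1e-9) {
  if (!"asm_mean_d1" %in% names(features)) {
    stop_state("features must contain `asm_mean_d1`; run featurize_bags() first")
  }
  mutate(features, reserved = .data$asm_mean_d1 < 1 - asm_tolerance)
}

#' Score instances by bag-level cross-validation
#'
#' Deals bags into `selection_folds` folds stratified by bag label (all
#' instances of a bag share a fold), trains a CPSO-tuned SVM on the reserved
#' instances of the remaining folds, and records, per reserved instance,
#' the predicted label and whether it matches the instance's (bag-inherited)
#' label, plus each bag's fraction of correctly classified instances.
#'
#' @param features Tidy instance table with labels propagated and the first
#'   optimization applied.
#' @param pso A [pso_config()] used for the per-fold tuning.
#' @param lo An [lo_config()] for the per-fold line search.
#' @param config An [io_config()].
#' @param seed Seed for fold dealing (re-dealt with derived seeds, at most
#'   10 attempts, if a training split ends up single-class).
#' @return List with `instances` (the table plus `fold`, `predicted`,
#'   `correct`) and `bag_accuracy` (tibble `bag_id`, `bag_label`,
#'   `n_scored`, `accuracy`).
#' @export
score_instances <- function(features, pso = pso_config(), lo = lo_config(),
                            config = io_config(), seed = 1) {
  res <- filter(features, .data$reserved)
  if (anyNA(res$label)) stop_state("instance labels missing; run label_instances()")
  bag_tbl <- distinct(res, .data$bag_id, .data$bag_label)
  if (nrow(bag_tbl) < config$selection_folds) {
    abort(sprintf("need at least %d bags to deal %d folds",
                  config$selection_folds, config$selection_folds),
          class = "iomil_configuration_error")
  }
  if (length(unique(bag_tbl$bag_label)) < 2) {
    abort("need bags of both classes", class = "iomil_configuration_error")
  }
  k <- config$selection_folds
  fold_by_bag <- NULL
  for (attempt in seq_len(10)) {
    f <- stratified_folds(bag_tbl$bag_label, k, derive_seed(seed, attempt - 1))
    ok <- all(vapply(seq_len(k), function(fi) {
      tr <- bag_tbl$bag_label[f != fi]
      any(f == fi) && length(unique(tr)) == 2
    }, TRUE))
    if (ok) { fold_by_bag <- f; break }
  }
  if (is.null(fold_by_bag)) {
    abort("could not deal folds with both classes in every training split",
          class = "iomil_configuration_error")
  }
  bag_tbl$fold <- fold_by_bag
  res <- left_join(res, bag_tbl[c("bag_id", "fold")], by = "bag_id")
  feat_cols <- feature_cols(res)
  res$predicted <- NA_integer_
  for (fi in seq_len(k)) {
    tr <- res$fold != fi
    xtr <- as.matrix(res[tr, feat_cols])
    tuned <- cpso_optimize(xtr, res$label[tr], pso, lo)
    clf <- train_svm(xtr, res$label[tr], tuned$params)
    res$predicted[!tr] <- predict_instances(clf, as.matrix(res[!tr, feat_cols]))
  }
  res$correct <- res$predicted == res$label
  bag_accuracy <- summarise(group_by(res, .data$bag_id, .data$bag_label),
                            n_scored = dplyr::n(),
                            accuracy = mean(.data$correct), .groups = "drop")
  list(instances = res, bag_accuracy = bag_accuracy)
}

#' Second instance optimization: retain the excellent instances
#'
#' Bags whose per-bag instance accuracy reaches the
#' `excellent_bag_quantile` quantile of the accuracy distribution are the
#' high-accuracy bags; their correctly classified instances form the key
#' instance set, with `a_j = 1` for positive-bag members and `a_j = 0` for
#' negative-bag members. All members are retained as training rows.
#'
#' The quantile is taken within each bag class separately. Positive bags
#' necessarily score lower than negative bags whenever selection works as
#' intended -- most instances of a lesion bag are not lesion tiles, so most
#' of their inherited labels are wrong -- and a single pooled cutoff would
#' then discard every positive bag and leave a one-class training set.
#'
#' @param scored Output of [score_instances()].
#' @param config An [io_config()].
#' @return A `key_instance_set`: list with `instances` (tibble of key
#'   instances), `provenance` (per-bag accuracy table with an
#'   `excellent` flag) and `cutoff` (named per-class accuracy thresholds).
#' @export
second_instance_optimization <- function(scored, config = io_config()) {
  acc <- scored$bag_accuracy
  acc$excellent <- FALSE
  cutoff <- c()
  for (lv in sort(unique(acc$bag_label), decreasing = TRUE)) {
    in_class <- acc$bag_label == lv
    cut_lv <- unname(quantile(acc$accuracy[in_class],
                              probs = config$excellent_bag_quantile))
    acc$excellent[in_class] <- acc$accuracy[in_class] >= cut_lv
    cutoff[as.character(lv)] <- cut_lv
  }
  keep_bags <- acc$bag_id[acc$excellent]
  key <- filter(scored$instances, .data$bag_id %in% keep_bags, .data$correct)
  if (nrow(key) == 0) {
    abort("no excellent instances selected; lower `excellent_bag_quantile`",
          class = "iomil_selection_error")
  }
  key$a_j <- ifelse(key$bag_label == 1, 1L, 0L)
  structure(list(instances = key, provenance = acc, cutoff = cutoff),
            class = "key_instance_set")
}

#' @export
print.key_instance_set <- function(x, ...) {
  cat(sprintf("<key_instance_set> %d instances from %d excellent bags (accuracy cutoffs %s)\n",
              nrow(x$instances), sum(x$provenance$excellent),
              paste(names(x$cutoff), round(x$cutoff, 3), sep = ": ",
                    collapse = ", ")))
  invisible(x)
}

#' Build the bag classifier
#'
#' End-to-end classifier construction over a featurized training set:
#' background removal (first optimization), bag-level scoring, key-instance
#' selection (second optimization), CPSO tuning of `(C, g)` on the key
#' instance set, and the final SVM fit on that set.
#'
#' @param features Tidy instance table of the training bags
#'   ([featurize_bags()]) with `bag_label` in `{+1, -1}`; instance labels
#'   are propagated from bag labels if missing.
#' @param pso,lo,io Component configurations.
#' @param predictor A [predictor_config()] supplying the bag threshold `P`.
#' @param seed Master seed for fold dealing.
#' @return An `iomil_classifier`: list with the final `svm`, tuned
#'   `params`, `key_instances`, `threshold`, the scoring `provenance`,
#'   the swarm/line-search diagnostics (`tuning`), and `feature_cols`.
#' @export
build_classifier <- function(features, pso = pso_config(), lo = lo_config(),
                             io = io_config(),
                             predictor = predictor_config(), seed = 1) {
  if (anyNA(features$bag_label)) stop_state("training bags must be labeled")
  features$label <- as.integer(features$bag_label)
  features <- first_instance_optimization(features, io$asm_tolerance)
  scored <- score_instances(features, pso, lo, io, seed = seed)
  key <- second_instance_optimization(scored, io)
  feat_cols <- feature_cols(features)
  xkey <- as.matrix(key$instances[feat_cols])
  tuned <- cpso_optimize(xkey, key$instances$label, pso, lo)
  final <- if (io$strict_aj_mask) {
    # realize the a_j slack mask as a small class weight on a_j = 0 rows
    y <- factor(key$instances$label, levels = c(1, -1))
    model <- e1071::svm(xkey, y, type = "C-classification", kernel = "radial",
                        cost = tuned$params$C, gamma = tuned$params$g,
                        scale = TRUE,
                        class.weights = c("1" = 1, "-1" = 1e-3))
    structure(list(model = model, params = tuned$params,
                   feature_names = colnames(xkey), n = nrow(xkey)),
              class = "iomil_svm")
  } else {
    train_svm(xkey, key$instances$label, tuned$params)
  }
  structure(list(svm = final, params = tuned$params,
                 key_instances = key, threshold = predictor$P,
                 predictor = predictor, io = io,
                 tuning = tuned, feature_cols = feat_cols,
                 provenance = scored$bag_accuracy, seed = seed),
            class = "iomil_classifier")
}

#' @export
print.iomil_classifier <- function(x, ...) {
  cat(sprintf(paste0("<iomil_classifier> C = %.4f, g = %.4f, threshold P = %.2f\n",
                     "  key instances: %d; support vectors: %d; CV fitness: %.3f\n"),
              x$params$C, x$params$g, x$threshold,
              nrow(x$key_instances$instances), x$svm$model$tot.nSV,
              x$tuning$fitness))
  invisible(x)
}
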