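# End-to-end experiment orchestration: dataset generation, training,
# five-group validation, baseline comparison, and parameter sweeps. A single
# master seed fans out to every stochastic component via derive_seed().

#' Assemble a full experiment configuration
#'
#' @param classes Named integer vector of per-class phantom counts.
#' @param phantom Named list of [phantom_config()] overrides applied to all
#'   classes (e.g. `list(image_side = 256)`).
#' @param preprocess A [preprocess_config()].
#' @param block_length Tile side in pixels (default 113).
#' @param glcm List of GLCM settings: `distances`, `levels`,
#'   `entropy_base`, `pool_distances`.
#' @param pso,lo,io,predictor Component configurations.
#' @param methods Character subset of
#'   `c("iomil", "svm", "citation-knn", "wemisvm")`.
#' @param seed Master seed.
#' @param out_dir Optional report directory; reports are written only when
#'   set.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(classes = c(cancer = 20, normal = 30),
                              phantom = list(),
                              preprocess = preprocess_config(),
                              block_length = 113,
                              glcm = list(distances = c(1, 2), levels = 64,
                                          entropy_base = 10,
                                          pool_distances = FALSE),
                              pso = pso_config(), lo = lo_config(),
                              io = io_config(),
                              predictor = predictor_config(),
                              methods = "iomil",
                              seed = 1, out_dir = NULL) {
  methods <- match.arg(methods, c("iomil", "svm", "citation-knn", "wemisvm"),
                       several.ok = TRUE)
  structure(list(classes = classes, phantom = phantom,
                 preprocess = preprocess, block_length = block_length,
                 glcm = glcm, pso = pso, lo = lo, io = io,
                 predictor = predictor, methods = methods,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "experiment_config")
}

#' Read an experiment configuration from YAML
#'
#' Scalar fields map one-to-one onto [experiment_config()] arguments;
#' sub-configurations are given as named lists (e.g.
#' `predictor: {P: 0.86}`). Validation errors name the offending field.
#'
#' @param path YAML file path.
#' @return An `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$classes)) args$classes <- unlist(raw$classes)
  for (nm in c("phantom", "glcm")) if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  if (!is.null(raw$preprocess)) args$preprocess <- do.call(preprocess_config, raw$preprocess)
  if (!is.null(raw$block_length)) args$block_length <- raw$block_length
  if (!is.null(raw$pso)) args$pso <- do.call(pso_config, raw$pso)
  if (!is.null(raw$lo)) args$lo <- do.call(lo_config, raw$lo)
  if (!is.null(raw$io)) args$io <- do.call(io_config, raw$io)
  if (!is.null(raw$predictor)) args$predictor <- do.call(predictor_config, raw$predictor)
  for (nm in c("methods", "seed", "out_dir")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(experiment_config, args)
}

featurize_for_experiment <- function(config, dataset) {
  do.call(phantom_instance_table,
          c(list(dataset = dataset, preprocess = config$preprocess,
                 block_length = config$block_length),
            config$glcm))
}

#' Run a full experiment
#'
#' Generates the phantom dataset, featurizes it, runs the requested methods
#' under the shared 50/50 split from the dataset manifest, and (when
#' `out_dir` is set) writes JSON/CSV reports recording the complete
#' resolved configuration.
#'
#' @param config An [experiment_config()] or a path to a YAML file for
#'   [read_experiment_config()].
#' @return An `experiment_report`: list with `results` (per-method
#'   summaries), `reports` (full per-method objects), `manifest`, and
#'   `config`.
#' @export
run_experiment <- function(config) {
  if (is.character(config)) config <- read_experiment_config(config)
  dataset <- generate_dataset(config$classes, config$phantom,
                              master_seed = derive_seed(config$seed, 1))
  features <- featurize_for_experiment(config, dataset)
  split <- dataset$manifest
  split$bag_id <- sub("\\.(png|bmp)$", "", split$path)
  split <- split[c("bag_id", "split")]
  results <- list(); reports <- list()
  for (m in config$methods) {
    if (m == "iomil") {
      rep <- five_group_validation(features, config$pso, config$lo,
                                   config$io, config$predictor,
                                   seed = derive_seed(config$seed, 2),
                                   split = split)
      results[[m]] <- rep$summary
      reports[[m]] <- rep
    } else if (m == "svm") {
      imf <- do.call(whole_image_features,
                     c(list(dataset = dataset, preprocess = config$preprocess),
                       config$glcm))
      rep <- single_instance_svm_baseline(imf, config$pso, config$lo,
                                          seed = derive_seed(config$seed, 3),
                                          split = split)
      results[[m]] <- rep$summary
      reports[[m]] <- rep
    } else if (m == "wemisvm") {
      res <- first_instance_optimization(features, config$io$asm_tolerance)
      tr_ids <- split$bag_id[split$split == "train"]
      pso2 <- config$pso; pso2$seed <- derive_seed(config$seed, 4)
      clf <- wemisvm_train(res[res$bag_id %in% tr_ids, ], pso2, config$lo)
      te <- res[!res$bag_id %in% tr_ids & res$reserved, ]
      preds <- bind_rows(lapply(unique(te$bag_id), function(id) {
        bf <- te[te$bag_id == id, ]
        tibble(bag_id = id, truth = bf$bag_label[1],
               prediction = as.integer(wemisvm_predict(clf, bf)))
      }))
      results[[m]] <- evaluate_predictions(preds)[c("ACC", "SEN", "SPE")]
      reports[[m]] <- list(predictions = preds, params = clf$params)
    } else if (m == "citation-knn") {
      res <- filter(first_instance_optimization(features,
                                                config$io$asm_tolerance),
                    .data$reserved)
      tr <- res[res$bag_id %in% split$bag_id[split$split == "train"], ]
      te_ids <- setdiff(unique(res$bag_id), unique(tr$bag_id))
      preds <- bind_rows(lapply(te_ids, function(id) {
        bf <- res[res$bag_id == id, ]
        tibble(bag_id = id, truth = bf$bag_label[1],
               prediction = as.integer(citation_knn_predict(tr, bf)))
      }))
      results[[m]] <- evaluate_predictions(preds)[c("ACC", "SEN", "SPE")]
      reports[[m]] <- list(predictions = preds)
    }
  }
  out <- structure(list(results = results, reports = reports,
                        manifest = dataset$manifest, config = config),
                   class = "experiment_report")
  if (!is.null(config$out_dir)) write_experiment_report(out, config$out_dir)
  out
}

write_experiment_report <- function(report, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  summary <- bind_rows(lapply(names(report$results), function(m) {
    dplyr::bind_cols(tibble(method = m), report$results[[m]])
  }))
  write.csv(summary, file.path(out_dir, "summary.csv"), row.names = FALSE)
  strip_classes <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip_classes) else unname(unclass(x))
  }
  cfg <- report$config
  cfg_plain <- strip_classes(report$config)
  cfg_plain$classes <- as.list(cfg$classes)
  jsonlite::write_json(list(config = cfg_plain,
                            results = lapply(report$results, as.list)),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' Sweep one pipeline parameter over a grid
#'
#' Re-evaluates the pipeline on a shared phantom dataset and shared seeds
#' for each grid value of `block_length` or the bag threshold `P`, or
#' sweeps the CV fitness over `C` or `g` (at the configuration's other
#' parameter held fixed) the same way the local line search does.
#'
#' @param config An [experiment_config()].
#' @param parameter One of `"block_length"`, `"P"`, `"C"`, `"g"`.
#' @param grid Numeric grid of parameter values.
#' @param at An [svm_params()] supplying the fixed complementary value for
#'   `C`/`g` sweeps (the swept entry is ignored).
#' @return Tibble with one row per grid point: the parameter value plus
#'   ACC/SEN/SPE (for pipeline parameters) or CV `fitness` (for `C`/`g`),
#'   and the elapsed seconds (machine-dependent, reported but never
#'   asserted).
#' @export
sweep_parameter <- function(config, parameter = c("block_length", "P", "C", "g"),
                            grid, at = svm_params(1, 1)) {
  parameter <- match.arg(parameter)
  dataset <- generate_dataset(config$classes, config$phantom,
                              master_seed = derive_seed(config$seed, 1))
  split <- dataset$manifest
  split$bag_id <- sub("\\.(png|bmp)$", "", split$path)
  split <- split[c("bag_id", "split")]

  if (parameter %in% c("C", "g")) {
    features <- featurize_for_experiment(config, dataset)
    features$label <- as.integer(features$bag_label)
    res <- filter(first_instance_optimization(features, config$io$asm_tolerance),
                  .data$reserved)
    fc <- feature_cols(res)
    x <- as.matrix(res[, fc])
    rows <- lapply(grid, function(v) {
      t0 <- proc.time()[3]
      params <- if (parameter == "C") svm_params(v, at$g) else svm_params(at$C, v)
      fit <- cv_accuracy(x, res$label, params,
                         folds = config$pso$fitness_folds,
                         seed = config$pso$seed)
      tibble(!!parameter := v, fitness = fit,
             elapsed_s = unname(proc.time()[3] - t0))
    })
    return(bind_rows(rows))
  }

  if (parameter == "P") {
    # the classifier does not depend on P: train once under the shared
    # seeds, then re-apply the bag threshold per grid point
    features <- featurize_for_experiment(config, dataset)
    base <- five_group_validation(features, config$pso, config$lo, config$io,
                                  config$predictor,
                                  seed = derive_seed(config$seed, 2),
                                  split = split)
    test_feats <- features[features$bag_id %in% base$predictions$bag_id, ]
    groups <- base$predictions[c("bag_id", "group")]
    rows <- lapply(grid, function(v) {
      t0 <- proc.time()[3]
      cfg_v <- predictor_config(P = v, config$predictor$block_length,
                                config$predictor$asm_tolerance)
      preds <- left_join(predict_bags(base$classifier, test_feats, cfg_v),
                         groups, by = "bag_id")
      per_group <- bind_rows(lapply(sort(unique(preds$group)), function(gi) {
        evaluate_predictions(preds[preds$group == gi, ])
      }))
      tibble(P = v,
             ACC = mean(per_group$ACC, na.rm = TRUE),
             SEN = mean(per_group$SEN, na.rm = TRUE),
             SPE = mean(per_group$SPE, na.rm = TRUE),
             n_negative = sum(preds$prediction == -1),
             elapsed_s = unname(proc.time()[3] - t0))
    })
    return(bind_rows(rows))
  }

  rows <- lapply(grid, function(v) {
    t0 <- proc.time()[3]
    cfg <- config
    cfg$block_length <- v
    features <- featurize_for_experiment(cfg, dataset)
    rep <- five_group_validation(features, cfg$pso, cfg$lo, cfg$io,
                                 cfg$predictor,
                                 seed = derive_seed(cfg$seed, 2),
                                 split = split)
    n_inst <- nrow(features) / length(unique(features$bag_id))
    dplyr::bind_cols(tibble(!!parameter := v),
                     rep$summary,
                     tibble(n_negative = sum(rep$predictions$prediction == -1),
                            instances_per_bag = n_inst,
                            elapsed_s = unname(proc.time()[3] - t0)))
  })
  bind_rows(rows)
}
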