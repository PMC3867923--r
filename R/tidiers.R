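# broom-style tidiers and ggplot2 methods for the fitted objects.

#' Tidy a fitted bag classifier
#'
#' One row per key instance: origin bag, grid position, label and the
#' `a_j` flag.
#'
#' @param x An `iomil_classifier`.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.iomil_classifier <- function(x, ...) {
  ki <- x$key_instances$instances
  select(ki, "bag_id", "bag_label", "instance_id", "grid_row", "grid_col",
         "label", "a_j")
}

#' One-row summary of a fitted bag classifier
#'
#' @param x An `iomil_classifier`.
#' @param ... Unused.
#' @return A one-row tibble with the tuned `C` and `g`, threshold `P`,
#'   key-instance and support-vector counts, and the CV fitness.
#' @exportS3Method generics::glance
glance.iomil_classifier <- function(x, ...) {
  tibble(C = x$params$C, g = x$params$g, P = x$threshold,
         n_key_instances = nrow(x$key_instances$instances),
         n_excellent_bags = sum(x$key_instances$provenance$excellent),
         n_support_vectors = x$svm$model$tot.nSV,
         cv_fitness = x$tuning$fitness)
}

#' @rdname tidy.iomil_classifier
#' @exportS3Method generics::tidy
tidy.five_group_report <- function(x, ...) x$groups

#' @rdname glance.iomil_classifier
#' @exportS3Method generics::glance
glance.five_group_report <- function(x, ...) {
  dplyr::bind_cols(x$summary, tibble(n_groups = nrow(x$groups),
                                     n_test_bags = sum(x$groups$n_bags)))
}

#' Plot per-group validation metrics
#'
#' @param object A `five_group_report`.
#' @param ... Unused.
#' @return A ggplot: ACC/SEN/SPE per validation group with the averaged
#'   value as a dashed line.
#' @exportS3Method ggplot2::autoplot
autoplot.five_group_report <- function(object, ...) {
  long <- tidyr::pivot_longer(object$groups, c("ACC", "SEN", "SPE"),
                              names_to = "metric", values_to = "value")
  means <- tidyr::pivot_longer(object$summary, dplyr::everything(),
                               names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$group), y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(data = means,
                        ggplot2::aes(yintercept = .data$value),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "validation group", y = NULL) +
    ggplot2::ylim(0, 1)
}

#' Plot the swarm's best-fitness trace
#'
#' @param object An `iomil_classifier` (plots its tuning trace).
#' @param ... Unused.
#' @return A ggplot of best CV fitness per swarm iteration.
#' @exportS3Method ggplot2::autoplot
autoplot.iomil_classifier <- function(object, ...) {
  ggplot2::ggplot(object$tuning$pso$trace,
                  ggplot2::aes(x = .data$iteration, y = .data$best_fitness)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "swarm iteration", y = "best CV fitness")
}

#' Plot a parameter sweep
#'
#' @param sweep A tibble from [sweep_parameter()] (or a line-search sweep
#'   table with columns `value`/`fitness`).
#' @return A ggplot of the swept metric(s) against the parameter.
#' @export
plot_sweep <- function(sweep) {
  xcol <- setdiff(names(sweep), c("ACC", "SEN", "SPE", "fitness",
                                  "n_negative", "instances_per_bag",
                                  "elapsed_s"))[1]
  ycols <- intersect(c("ACC", "SEN", "SPE", "fitness"), names(sweep))
  long <- tidyr::pivot_longer(sweep[c(xcol, ycols)], all_of(ycols),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data[[xcol]], y = .data$value,
                                     colour = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xcol, y = NULL, colour = NULL)
}

#' Display a phantom sample
#'
#' @param object A `phantom_sample`.
#' @param ... Unused.
#' @return A ggplot raster of the image with the lesion mask outlined.
#' @exportS3Method ggplot2::autoplot
autoplot.phantom_sample <- function(object, ...) {
  df <- expand.grid(row = seq_len(nrow(object$image)),
                    col = seq_len(ncol(object$image)))
  df$intensity <- as.vector(object$image)
  df$lesion <- as.vector(object$lesion_mask) == 1
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = object$class_name, x = NULL, y = NULL)
  if (any(df$lesion)) {
    p <- p + ggplot2::geom_point(data = df[df$lesion, ], colour = "red",
                                 size = 0.01, alpha = 0.15)
  }
  p
}
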