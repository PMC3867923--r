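# RBF-SVM machinery and combined PSO + coordinate line-search (CPSO)
# hyperparameter tuning of the penalty C and kernel control factor g.
#
# The soft-margin dual problem itself is solved by e1071/libsvm; this module
# owns the decision-function contract (sign rule, tie to +1), the
# cross-validation fitness, the global-best particle swarm in log2(C, g)
# space, and the coordinate line search around the swarm's optimum.

#' SVM hyperparameters
#'
#' @param C Penalty factor, strictly positive.
#' @param g RBF kernel control factor (the `gamma` in
#'   `K(u, v) = exp(-g ||u - v||^2)`), strictly positive.
#' @return An `svm_params` list.
#' @export
svm_params <- function(C, g) {
  if (!is_scalar_num(C) || C <= 0) stop_param("`C` must be > 0", "C")
  if (!is_scalar_num(g) || g <= 0) stop_param("`g` must be > 0", "g")
  structure(list(C = C, g = g), class = "svm_params")
}

#' Particle-swarm configuration for (C, g) tuning
#'
#' The swarm searches in `log2(C), log2(g)` space inside the given box with
#' a linearly decaying inertia weight and the usual cognitive/social
#' accelerations. Fitness is mean stratified k-fold cross-validation
#' accuracy at instance level.
#'
#' @param swarm_size Particles (default 20).
#' @param iterations Swarm iterations (default 50).
#' @param inertia Length-2 vector: inertia weight decays linearly from
#'   `inertia[1]` to `inertia[2]` (default 0.9 to 0.4).
#' @param c1,c2 Cognitive and social acceleration (default 2 each).
#' @param C_range,g_range Search box in raw units (defaults
#'   `[2^-2, 2^7]` and `[2^-4, 2^4]`).
#' @param fitness_folds Stratified CV folds for the fitness (default 5).
#' @param seed Integer seed controlling swarm initialisation and fold
#'   dealing.
#' @return A `pso_config` list.
#' @export
pso_config <- function(swarm_size = 20, iterations = 50,
                       inertia = c(0.9, 0.4), c1 = 2, c2 = 2,
                       C_range = c(2^-2, 2^7), g_range = c(2^-4, 2^4),
                       fitness_folds = 5, seed = 1) {
  stopifnot(swarm_size >= 2, iterations >= 1, length(inertia) == 2,
            c1 >= 0, c2 >= 0, fitness_folds >= 2)
  if (C_range[1] <= 0 || C_range[1] >= C_range[2] ||
      g_range[1] <= 0 || g_range[1] >= g_range[2]) {
    stop_param("search ranges must be positive with lower < upper")
  }
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations),
                 inertia = inertia, c1 = c1, c2 = c2,
                 C_range = C_range, g_range = g_range,
                 fitness_folds = as.integer(fitness_folds),
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' Line-search configuration for local (C, g) refinement
#'
#' @param C_step,g_step Grid increments in raw units (defaults 0.05).
#' @param C_halfwidth,g_halfwidth Search radii around the starting point
#'   (defaults 1.0 and 3.5).
#' @return An `lo_config` list.
#' @export
lo_config <- function(C_step = 0.05, g_step = 0.05,
                      C_halfwidth = 1.0, g_halfwidth = 3.5) {
  stopifnot(C_step > 0, g_step > 0, C_halfwidth > 0, g_halfwidth > 0)
  structure(list(C_step = C_step, g_step = g_step,
                 C_halfwidth = C_halfwidth, g_halfwidth = g_halfwidth),
            class = "lo_config")
}

#' Train a soft-margin RBF SVM
#'
#' Thin wrapper over the libsvm dual solver with the package's label
#' convention: labels are `{+1, -1}` and a positive decision value means the
#' positive class. Feature columns are standardized internally.
#'
#' @param features Numeric matrix or data frame of instance features
#'   (rows = instances).
#' @param labels Integer vector in `{+1, -1}`, one per row.
#' @param params An [svm_params()].
#' @param scale Standardize feature columns before fitting (default `TRUE`;
#'   disable when features are already on a common scale).
#' @return An `iomil_svm`: list with the fitted `model`, `params`,
#'   `feature_names`, `n` (training rows).
#' @export
train_svm <- function(features, labels, params, scale = TRUE) {
  x <- as.matrix(features)
  if (!all(labels %in% c(-1, 1))) stop_param("labels must be +1/-1")
  if (length(unique(labels)) < 2) {
    abort("training data contains a single class",
          class = "iomil_configuration_error")
  }
  if (nrow(x) != length(labels)) stop_param("features/labels length mismatch")
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  y <- factor(labels, levels = c(1, -1))
  model <- e1071::svm(x, y, type = "C-classification", kernel = "radial",
                      cost = params$C, gamma = params$g, scale = scale)
  structure(list(model = model, params = params,
                 feature_names = colnames(x), n = nrow(x)),
            class = "iomil_svm")
}

#' Decision values of a trained SVM
#'
#' Pre-sign values of the kernel decision function
#' `f(x) = sum_i w_i* y_i K(x_i, x) + b*`; positive means the `+1` class.
#'
#' @param clf An `iomil_svm`.
#' @param features Matrix/data frame with the training feature columns.
#' @return Numeric vector of decision values.
#' @export
decision_values <- function(clf, features) {
  x <- as.matrix(features)
  if (ncol(x) != length(clf$feature_names)) {
    abort(sprintf("feature dimension %d does not match training dimension %d",
                  ncol(x), length(clf$feature_names)),
          class = "iomil_shape_error")
  }
  colnames(x) <- clf$feature_names
  p <- predict(clf$model, x, decision.values = TRUE)
  dvm <- attr(p, "decision.values")
  dv <- drop(dvm)
  # libsvm orients decision values toward the class named first in the
  # column label; flip if that is the negative class
  if (startsWith(colnames(dvm)[1], "-1")) dv <- -dv
  unname(dv)
}

#' Predict instance labels
#'
#' Sign of the decision value, with the documented tie rule that a decision
#' value of exactly zero maps to `+1`.
#'
#' @inheritParams decision_values
#' @return Integer vector in `{+1, -1}`.
#' @export
predict_instances <- function(clf, features) {
  dv <- decision_values(clf, features)
  ifelse(dv >= 0, 1L, -1L)
}

# Recompute the decision function directly from stored support vectors and
# dual weights (standardized space). Used by tests as the explicit form of
# the kernel expansion.
svm_decision_manual <- function(clf, features) {
  m <- clf$model
  x <- as.matrix(features)
  if (!is.null(m$x.scale)) {
    x <- scale(x, m$x.scale$`scaled:center`, m$x.scale$`scaled:scale`)
  }
  sv <- m$SV
  cross <- outer(rowSums(sv^2), rowSums(x^2), "+") - 2 * tcrossprod(sv, x)
  K <- exp(-m$gamma * pmax(cross, 0))
  f <- drop(t(m$coefs) %*% K) - m$rho
  # orient toward the +1 class, as decision_values() does
  if (m$levels[m$labels[1]] == "-1") f <- -f
  f
}

# Stratified fold assignment: one fold id per row, deterministic under seed.
stratified_folds <- function(labels, k, seed) {
  withr::with_seed(seed, {
    fold <- integer(length(labels))
    for (lv in unique(labels)) {
      idx <- sample(which(labels == lv))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' Cross-validated accuracy of an RBF SVM at fixed (C, g)
#'
#' Mean accuracy over stratified k-fold splits; the fitness used by both the
#' swarm and the line search.
#'
#' @inheritParams train_svm
#' @param folds Number of stratified folds.
#' @param seed Seed for the fold dealing.
#' @return Mean fold accuracy in `[0, 1]`.
#' @export
cv_accuracy <- function(features, labels, params, folds = 5, seed = 1) {
  x <- as.matrix(features)
  fold <- stratified_folds(labels, folds, seed)
  accs <- vapply(seq_len(folds), function(f) {
    tr <- fold != f
    if (length(unique(labels[tr])) < 2 || !any(!tr)) return(NA_real_)
    clf <- train_svm(x[tr, , drop = FALSE], labels[tr], params)
    mean(predict_instances(clf, x[!tr, , drop = FALSE]) == labels[!tr])
  }, 0)
  mean(accs, na.rm = TRUE)
}

#' Particle-swarm optimization of (C, g)
#'
#' Global-best PSO in `log2(C), log2(g)` space. Particles are clipped to the
#' search box; the inertia weight decays linearly over iterations. The
#' fitness defaults to stratified CV accuracy ([cv_accuracy()]) but can be
#' replaced, e.g. for testing against analytic surfaces.
#'
#' @inheritParams train_svm
#' @param config A [pso_config()].
#' @param fitness Optional function `(C, g) -> numeric` overriding the CV
#'   fitness.
#' @return List with `params` (best [svm_params()]), `fitness` (its fitness
#'   value) and `trace` (tibble of per-iteration best fitness).
#' @export
pso_optimize <- function(features = NULL, labels = NULL,
                         config = pso_config(), fitness = NULL) {
  if (is.null(fitness)) {
    if (is.null(features) || is.null(labels)) {
      stop_param("either data or a `fitness` function must be supplied")
    }
    if (length(unique(labels)) < 2) {
      abort("need two classes to tune hyperparameters",
            class = "iomil_configuration_error")
    }
    if (min(table(labels)) < config$fitness_folds) {
      abort("minority class smaller than the number of fitness folds",
            class = "iomil_configuration_error")
    }
    x <- as.matrix(features)
    fitness <- function(C, g) {
      cv_accuracy(x, labels, svm_params(C, g),
                  folds = config$fitness_folds, seed = config$seed)
    }
  }
  lo <- log2(c(config$C_range[1], config$g_range[1]))
  hi <- log2(c(config$C_range[2], config$g_range[2]))
  ns <- config$swarm_size
  withr::with_seed(config$seed, {
    pos <- cbind(runif(ns, lo[1], hi[1]), runif(ns, lo[2], hi[2]))
    vel <- matrix(0, ns, 2)
    pbest <- pos
    pbest_fit <- vapply(seq_len(ns),
                        function(i) fitness(2^pos[i, 1], 2^pos[i, 2]), 0)
    gi <- which.max(pbest_fit)
    gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
    trace <- numeric(config$iterations)
    for (it in seq_len(config$iterations)) {
      w <- config$inertia[1] +
        (config$inertia[2] - config$inertia[1]) *
        (it - 1) / max(1, config$iterations - 1)
      r1 <- matrix(runif(ns * 2), ns, 2)
      r2 <- matrix(runif(ns * 2), ns, 2)
      vel <- w * vel + config$c1 * r1 * (pbest - pos) +
        config$c2 * r2 * (matrix(gbest, ns, 2, byrow = TRUE) - pos)
      pos <- pos + vel
      pos[, 1] <- pmin(pmax(pos[, 1], lo[1]), hi[1])
      pos[, 2] <- pmin(pmax(pos[, 2], lo[2]), hi[2])
      fit <- vapply(seq_len(ns),
                    function(i) fitness(2^pos[i, 1], 2^pos[i, 2]), 0)
      better <- fit > pbest_fit
      pbest[better, ] <- pos[better, , drop = FALSE]
      pbest_fit[better] <- fit[better]
      gi <- which.max(pbest_fit)
      if (pbest_fit[gi] > gbest_fit) {
        gbest <- pbest[gi, ]; gbest_fit <- pbest_fit[gi]
      }
      trace[it] <- gbest_fit
    }
    list(params = svm_params(2^gbest[1], 2^gbest[2]),
         fitness = gbest_fit,
         trace = tibble(iteration = seq_len(config$iterations),
                        best_fitness = trace))
  })
}

#' Coordinate line search around a starting (C, g)
#'
#' Sweeps `C` over `[start$C - C_halfwidth, start$C + C_halfwidth]` in steps
#' of `C_step` at the starting `g`, keeps the fitness-maximizing `C`
#' (ties broken toward the smallest `C`), then sweeps `g` likewise at the
#' kept `C` (ties toward the smallest `g`). The starting point is always on
#' both grids, so the returned fitness never falls below the start's.
#'
#' @param start An [svm_params()] starting point.
#' @inheritParams pso_optimize
#' @param config An [lo_config()].
#' @param fitness_folds,seed CV fitness settings (must match the swarm's to
#'   keep the two stages comparable).
#' @return List with `params`, `fitness`, and `sweeps` (named list of the
#'   two sweep tibbles `value`/`fitness`).
#' @export
local_optimize <- function(start, features = NULL, labels = NULL,
                           config = lo_config(), fitness_folds = 5, seed = 1,
                           fitness = NULL) {
  if (is.null(fitness)) {
    x <- as.matrix(features)
    fitness <- function(C, g) {
      cv_accuracy(x, labels, svm_params(C, g), folds = fitness_folds,
                  seed = seed)
    }
  }
  sweep_axis <- function(center, halfwidth, step, eval_fn) {
    grid <- center + seq(-halfwidth, halfwidth, by = step)
    grid[which.min(abs(grid - center))] <- center # keep start exactly on grid
    grid <- grid[grid > 0]
    fit <- vapply(grid, eval_fn, 0)
    list(table = tibble(value = grid, fitness = fit),
         best = grid[which.max(fit)],  # first max = smallest value on ties
         best_fit = max(fit))
  }
  c_sweep <- sweep_axis(start$C, config$C_halfwidth, config$C_step,
                        function(C) fitness(C, start$g))
  g_sweep <- sweep_axis(start$g, config$g_halfwidth, config$g_step,
                        function(g) fitness(c_sweep$best, g))
  list(params = svm_params(c_sweep$best, g_sweep$best),
       fitness = g_sweep$best_fit,
       sweeps = list(C = c_sweep$table, g = g_sweep$table))
}

#' Combined PSO + local line-search tuning (CPSO)
#'
#' Runs the swarm, then refines its best point with the coordinate line
#' search using the identical CV fitness. The refinement can only keep or
#' improve the swarm's fitness.
#'
#' @inheritParams pso_optimize
#' @param lo A [lo_config()].
#' @return List with final `params`, `fitness`, and the component results
#'   `pso` and `lo`.
#' @export
cpso_optimize <- function(features, labels, config = pso_config(),
                          lo = lo_config()) {
  ps <- pso_optimize(features, labels, config)
  lr <- local_optimize(ps$params, features, labels, lo,
                       fitness_folds = config$fitness_folds,
                       seed = config$seed)
  list(params = lr$params, fitness = lr$fitness, pso = ps, lo = lr)
}
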