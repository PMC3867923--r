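test_that("train_svm handles reference separable cases", {
  # one point per class: both are support vectors and classified correctly
  x <- rbind(c(0, 0), c(1, 1))
  clf <- train_svm(x, c(1, -1), svm_params(10, 1))
  expect_identical(clf$model$tot.nSV, 2L)
  expect_identical(predict_instances(clf, x), c(1L, -1L))

  # XOR is separable with an RBF kernel
  xor_x <- rbind(c(0, 0), c(1, 1), c(0, 1), c(1, 0))
  xor_y <- c(1, 1, -1, -1)
  clf2 <- train_svm(xor_x, xor_y, svm_params(100, 1))
  expect_identical(predict_instances(clf2, xor_x), as.integer(xor_y))

  expect_error(train_svm(x, c(1, 1), svm_params(1, 1)),
               class = "iomil_configuration_error")
})

test_that("duplicating every training row leaves decision values unchanged", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(40, 2.5, 0.5), 20, 2), matrix(rnorm(40, -2.5, 0.5), 20, 2))
    y <- rep(c(1, -1), each = 20)
    probe <- matrix(rnorm(60), 30, 2)
  })
  # on a common raw scale the dual solution splits evenly across duplicates
  a <- train_svm(x, y, svm_params(5, 0.7), scale = FALSE)
  b <- train_svm(rbind(x, x), c(y, y), svm_params(5, 0.7), scale = FALSE)
  expect_lt(max(abs(decision_values(a, probe) - decision_values(b, probe))), 1e-6)
})

test_that("stored support vectors and weights reproduce the kernel decision function", {
  withr::with_seed(4, {
    x <- rbind(matrix(rnorm(60, 1.5), 30, 2), matrix(rnorm(60, -1.5), 30, 2))
    y <- rep(c(1, -1), each = 30)
    probe <- matrix(rnorm(200), 100, 2)
  })
  clf <- train_svm(x, y, svm_params(8, 0.5))
  manual <- iomil:::svm_decision_manual(clf, probe)
  expect_lt(max(abs(manual - decision_values(clf, probe))), 1e-10)
  expect_identical(predict_instances(clf, probe),
                   ifelse(manual >= 0, 1L, -1L))
  # dual weights live in [0, C]
  expect_true(all(abs(clf$model$coefs) <= 8 + 1e-9))
})

test_that("prediction tie rule and shape errors", {
  x <- rbind(c(-1, 0), c(1, 0))
  clf <- train_svm(x, c(1, -1), svm_params(10, 1), scale = FALSE)
  # midpoint of a symmetric pair has decision value 0 -> +1 by the tie rule
  expect_identical(predict_instances(clf, rbind(c(0, 0))), 1L)
  expect_error(decision_values(clf, matrix(0, 1, 3)),
               class = "iomil_shape_error")
})

test_that("the swarm is deterministic, monotone in trace, and solves a separable set", {
  withr::with_seed(9, {
    x <- rbind(matrix(rnorm(60, 2), 30, 2), matrix(rnorm(60, -2), 30, 2))
  })
  y <- rep(c(1, -1), each = 30)
  cfg <- pso_config(swarm_size = 8, iterations = 10, fitness_folds = 3, seed = 13)
  r1 <- pso_optimize(x, y, cfg)
  r2 <- pso_optimize(x, y, cfg)
  expect_identical(r1$params, r2$params)
  expect_true(all(diff(r1$trace$best_fitness) >= 0))
  expect_equal(r1$fitness, 1)
})

test_that("swarm preconditions are checked", {
  x <- matrix(rnorm(20), 10, 2)
  expect_error(pso_optimize(x, rep(1, 10), pso_config()),
               class = "iomil_configuration_error")
  expect_error(pso_optimize(x, c(1, rep(-1, 9)), pso_config(fitness_folds = 5)),
               class = "iomil_configuration_error")
})

test_that("line search matches an exhaustive 2-D grid oracle on a unimodal ridge", {
  # smooth unimodal surface peaked at (C, g) = (3.2, 1.4)
  ridge <- function(C, g) exp(-((C - 3.2)^2 / 4 + (g - 1.4)^2 / 2))
  lo <- lo_config(C_step = 0.1, g_step = 0.1, C_halfwidth = 1.5, g_halfwidth = 1.0)
  start <- svm_params(2.5, 0.9)
  res <- local_optimize(start, config = lo, fitness = ridge)

  # oracle: exhaustive evaluation over the same 2-D grid
  Cg <- start$C + seq(-1.5, 1.5, by = 0.1)
  gg <- start$g + seq(-1.0, 1.0, by = 0.1)
  grid <- expand.grid(C = Cg[Cg > 0], g = gg[gg > 0])
  best <- grid[which.max(mapply(ridge, grid$C, grid$g)), ]
  expect_lte(abs(res$params$C - best$C), 0.1 + 1e-9)
  expect_lte(abs(res$params$g - best$g), 0.1 + 1e-9)
  expect_gte(res$fitness, ridge(start$C, start$g))

  # fixed point: starting at the grid optimum returns the start
  res2 <- local_optimize(svm_params(best$C, best$g), config = lo, fitness = ridge)
  expect_equal(res2$params$C, best$C, tolerance = 1e-9)
})

test_that("combined tuning never degrades the swarm fitness", {
  ft <- synth_features(n_bags = 8, sep = 4, seed = 6)
  fc <- grep("_mean_d1$", names(ft), value = TRUE)
  x <- as.matrix(ft[, fc])
  res <- cpso_optimize(x, ft$label, fast_pso(seed = 21), fast_lo())
  expect_gte(res$fitness, res$pso$fitness)
  expect_named(res$lo$sweeps, c("C", "g"))
})
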