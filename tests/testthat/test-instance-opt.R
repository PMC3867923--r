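test_that("first optimization removes exactly the uniform background tiles", {
  # construct a bag with 3 constant tiles and 6 textured tiles
  withr::with_seed(10, {
    img <- matrix(sample(10:250, 90 * 90, replace = TRUE), 90, 90)
  })
  img[1:30, 1:30] <- 0L   # tiles (1,1), (1,2), (2,1) constant
  img[1:30, 31:60] <- 0L
  img[31:60, 1:30] <- 0L
  bag <- label_instances(extract_instances(img, 30, "b", -1))
  ft <- featurize_bags(list(bag))
  out <- first_instance_optimization(ft)
  expect_identical(sum(out$reserved), 6L)
  dropped <- out[!out$reserved, c("grid_row", "grid_col")]
  expect_setequal(paste(dropped$grid_row, dropped$grid_col),
                  c("1 1", "1 2", "2 1"))

  # truth table: removed <=> ASM-mean(d=1) >= 1 - tol
  expect_identical(!out$reserved, out$asm_mean_d1 >= 1 - 1e-9)

  # no background: unchanged; all background: nothing reserved
  ft_tex <- ft[ft$asm_mean_d1 < 1, ]
  expect_true(all(first_instance_optimization(ft_tex)$reserved))
  allbg <- featurize_bags(list(label_instances(
    extract_instances(matrix(5L, 60, 60), 20, "bg", -1))))
  expect_identical(sum(first_instance_optimization(allbg)$reserved), 0L)
  expect_error(first_instance_optimization(allbg[, 1:5]),
               class = "iomil_state_error")
})

test_that("scoring partitions by bag, never trains on the scored fold, and is deterministic", {
  ft <- synth_features(n_bags = 12, sep = 4, seed = 2)
  sc <- score_instances(ft, fast_pso(), fast_lo(),
                        io_config(selection_folds = 3), seed = 8)
  expect_identical(nrow(sc$bag_accuracy), 12L)
  # all instances of a bag share a fold
  per_bag_folds <- tapply(sc$instances$fold, sc$instances$bag_id,
                          function(f) length(unique(f)))
  expect_true(all(per_bag_folds == 1))
  # separable features: every bag is scored perfectly
  expect_true(all(sc$bag_accuracy$accuracy == 1))

  sc2 <- score_instances(ft, fast_pso(), fast_lo(),
                         io_config(selection_folds = 3), seed = 8)
  expect_identical(sc$instances$predicted, sc2$instances$predicted)
})

test_that("scoring on label-shuffled bags sits near chance", {
  accs <- vapply(1:3, function(s) {
    ft <- synth_features(n_bags = 20, sep = 0, seed = 100 + s)
    sc <- score_instances(ft, pso_config(swarm_size = 4, iterations = 3,
                                         fitness_folds = 3, seed = s),
                          lo_config(C_step = 1, g_step = 1,
                                    C_halfwidth = 1, g_halfwidth = 1),
                          io_config(selection_folds = 4), seed = s)
    mean(sc$bag_accuracy$accuracy)
  }, 0)
  expect_lt(abs(mean(accs) - 0.5), 0.15)
})

test_that("scoring preconditions: single bag and single class fail", {
  ft <- synth_features(n_bags = 2, seed = 3)
  expect_error(score_instances(ft[ft$bag_id == "bag01", ], fast_pso(),
                               fast_lo(), io_config()),
               class = "iomil_configuration_error")
  ft_one <- synth_features(n_bags = 12, seed = 3)
  ft_one$bag_label <- 1L; ft_one$label <- 1L
  expect_error(score_instances(ft_one, fast_pso(), fast_lo(),
                               io_config(selection_folds = 3)),
               class = "iomil_configuration_error")
})

test_that("second optimization keeps correct instances of high-accuracy bags", {
  ft <- synth_features(n_bags = 12, sep = 4, seed = 2)
  sc <- score_instances(ft, fast_pso(), fast_lo(),
                        io_config(selection_folds = 3), seed = 8)
  # separable: every bag at accuracy 1, so the key set is all scored instances
  key <- second_instance_optimization(sc, io_config())
  expect_identical(nrow(key$instances), nrow(sc$instances))
  expect_true(all(key$instances$correct))
  expect_identical(unique(key$instances$a_j[key$instances$bag_label == 1]), 1L)
  expect_identical(unique(key$instances$a_j[key$instances$bag_label == -1]), 0L)
  # labels agree with origin-bag labels
  expect_identical(key$instances$label, as.integer(key$instances$bag_label))

  # quantile 1.0 restricted to the top bag(s)
  sc_mixed <- sc
  sc_mixed$bag_accuracy$accuracy[1:6] <- seq(0.1, 0.6, by = 0.1)
  key_top <- second_instance_optimization(sc_mixed, io_config(excellent_bag_quantile = 1))
  top_bags <- sc_mixed$bag_accuracy$bag_id[sc_mixed$bag_accuracy$accuracy == 1]
  expect_setequal(unique(key_top$instances$bag_id), top_bags)
})

test_that("raising the excellent-bag quantile never enlarges the key set", {
  ft <- synth_features(n_bags = 14, sep = 2, seed = 5)
  sc <- score_instances(ft, fast_pso(), fast_lo(),
                        io_config(selection_folds = 3), seed = 4)
  sizes <- vapply(c(0.25, 0.5, 0.75, 1), function(q) {
    nrow(second_instance_optimization(sc, io_config(excellent_bag_quantile = q))$instances)
  }, 0)
  expect_true(all(diff(sizes) <= 0))
})

test_that("classifier construction is reproducible and consistent on phantoms", {
  clf <- fx_classifier()
  ki <- clf$key_instances$instances
  expect_gt(nrow(ki), 0)
  expect_true(all(ki$reserved))
  expect_true(all(ki$asm_mean_d1 < 1 - 1e-9)) # subset of first-IO survivors
  expect_gt(clf$params$C, 0); expect_gt(clf$params$g, 0)

  clf2 <- build_classifier(fx_phantom_features(), pso = fast_pso(),
                           lo = fast_lo(), io = io_config(selection_folds = 3),
                           seed = 3)
  expect_identical(clf$params, clf2$params)
  expect_identical(ki$instance_id, clf2$key_instances$instances$instance_id)

  g <- glance(clf)
  expect_identical(nrow(g), 1L)
  expect_identical(g$n_key_instances, nrow(ki))
  td <- tidy(clf)
  expect_true(all(td$a_j[td$bag_label == 1] == 1))
})
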