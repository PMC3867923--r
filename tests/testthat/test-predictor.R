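test_that("threshold configuration enforces the valid range of P", {
  expect_error(predictor_config(P = 0.4), class = "iomil_parameter_error")
  expect_error(predictor_config(P = 1.01), class = "iomil_parameter_error")
  expect_identical(predictor_config(P = 0.5)$P, 0.5)
})

test_that("negative-ratio rule follows the strict-threshold arithmetic", {
  # stub classifier whose instance predictions we control through features:
  # train a trivially separable SVM so prediction equals the sign of one column
  x <- matrix(c(seq(-1, -0.1, length.out = 10), seq(0.1, 1, length.out = 10)),
              ncol = 1, dimnames = list(NULL, "ent_mean_d1"))
  svm <- train_svm(x, c(rep(-1, 10), rep(1, 10)), svm_params(100, 2))
  clf <- structure(list(svm = svm, feature_cols = "ent_mean_d1",
                        predictor = predictor_config(P = 0.86)),
                   class = "iomil_classifier")
  mk_bag <- function(n_neg, n_pos) {
    tibble::tibble(bag_id = "t", bag_label = 1L,
                   asm_mean_d1 = 0.5,
                   ent_mean_d1 = c(rep(-0.6, n_neg), rep(0.6, n_pos)))
  }
  # 8 of 9 predicted negative: r = 8/9 > 0.86 -> negative bag
  p1 <- predict_bag(clf, mk_bag(8, 1))
  expect_identical(as.integer(p1), -1L)
  expect_equal(attr(p1, "neg_ratio"), 8 / 9)
  # 7 of 9: r = 7/9 <= 0.86 -> positive bag
  expect_identical(as.integer(predict_bag(clf, mk_bag(7, 2))), 1L)
  # r exactly P is not "larger than": predicted positive
  p3 <- predict_bag(clf, mk_bag(3, 1), predictor_config(P = 0.75))
  expect_equal(attr(p3, "neg_ratio"), 0.75)
  expect_identical(as.integer(p3), 1L)
  # an all-background bag cannot be predicted
  bg <- mk_bag(4, 4); bg$asm_mean_d1 <- 1
  expect_error(predict_bag(clf, bg), class = "iomil_prediction_error")
})

test_that("evaluation reproduces the confusion-ratio definitions", {
  r <- evaluate_predictions(c(rep(1, 40), rep(-1, 60)),
                            c(rep(1, 40), rep(-1, 60)))
  expect_equal(unlist(r[c("ACC", "SEN", "SPE")]), c(ACC = 1, SEN = 1, SPE = 1))

  r2 <- evaluate_predictions(rep(-1, 100), c(rep(1, 40), rep(-1, 60)))
  expect_equal(unlist(r2[c("ACC", "SEN", "SPE")]), c(ACC = 0.6, SEN = 0, SPE = 1))

  r3 <- evaluate_predictions(c(1, -1, 1), c(1, 1, 1))
  expect_true(is.na(r3$SPE))
  expect_equal(r3$SEN, 2 / 3)

  expect_error(evaluate_predictions(c(1, 0), c(1, -1)),
               class = "iomil_parameter_error")
  expect_error(evaluate_predictions(c(1), c(1, -1)),
               class = "iomil_parameter_error")

  # permutation invariance and the class-weighted ACC identity
  withr::with_seed(11, {
    pred <- sample(c(1, -1), 50, replace = TRUE)
    truth <- sample(c(1, -1), 50, replace = TRUE)
    perm <- sample(50)
  })
  expect_identical(evaluate_predictions(pred, truth),
                   evaluate_predictions(pred[perm], truth[perm]))
  r4 <- evaluate_predictions(pred, truth)
  npos <- sum(truth == 1); nneg <- sum(truth == -1)
  expect_equal(r4$ACC, (npos * r4$SEN + nneg * r4$SPE) / (npos + nneg))
})

test_that("the count of negative predictions is non-increasing in P", {
  clf <- fx_classifier()
  ft <- fx_phantom_features()
  grid <- seq(0.5, 1, by = 0.01)
  n_neg <- vapply(grid, function(p) {
    cfg <- predictor_config(P = p)
    sum(predict_bags(clf, ft, cfg)$prediction == -1)
  }, 0)
  expect_true(all(diff(n_neg) <= 0))
})

test_that("five-group validation is stratified, averaged and deterministic", {
  ft <- fx_phantom_features()
  rep1 <- five_group_validation(ft, pso = fast_pso(), lo = fast_lo(),
                                io = io_config(selection_folds = 3), seed = 17)
  expect_identical(nrow(rep1$groups), 5L)
  expect_identical(sum(rep1$groups$n_bags), 12L) # test half of 24 bags
  expect_equal(rep1$summary$ACC, mean(rep1$groups$ACC, na.rm = TRUE))
  expect_true(all(table(rep1$split$split) == 12))

  rep2 <- five_group_validation(ft, pso = fast_pso(), lo = fast_lo(),
                                io = io_config(selection_folds = 3), seed = 17)
  expect_identical(rep1$groups, rep2$groups)
  expect_identical(rep1$predictions, rep2$predictions)

  expect_error(five_group_validation(ft[ft$class == "cancer", ],
                                     pso = fast_pso(), lo = fast_lo()),
               class = "iomil_configuration_error")

  g <- glance(rep1)
  expect_identical(g$n_test_bags, 12L)
  expect_s3_class(tidy(rep1), "tbl_df")
})
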