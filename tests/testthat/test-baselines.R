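test_that("minimum Hausdorff distance matches the exhaustive pair minimum", {
  withr::with_seed(5, {
    for (i in 1:5) {
      A <- matrix(rnorm(12), 3, 4)
      B <- matrix(rnorm(16), 4, 4)
      oracle <- min(apply(A, 1, function(a) {
        apply(B, 1, function(b) sqrt(sum((a - b)^2)))
      }))
      expect_equal(min_hausdorff_distance(A, B), oracle, tolerance = 1e-12)
      expect_equal(min_hausdorff_distance(A, B), min_hausdorff_distance(B, A))
    }
  })
  A <- matrix(rnorm(8), 2, 4)
  expect_equal(min_hausdorff_distance(A, A), 0)
  expect_equal(min_hausdorff_distance(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_error(min_hausdorff_distance(A[0, , drop = FALSE], A),
               class = "iomil_value_error")
})

# helper: bags of single instances in 1-D feature space as a tidy table
bags_1d <- function(xs, labels) {
  dplyr::bind_rows(lapply(seq_along(xs), function(i) {
    tibble::tibble(bag_id = sprintf("b%d", i), bag_label = labels[i],
                   ent_mean_d1 = xs[i])
  }))
}

test_that("citation-kNN vote matches a hand-enumerated 1-D configuration", {
  # train bags at 0, 1, 2, 10, 11, 12; labels -1 -1 -1 +1 +1 +1; query at 3.
  tr <- bags_1d(c(0, 1, 2, 10, 11, 12), c(-1, -1, -1, 1, 1, 1))
  te <- tibble::tibble(bag_id = "q", bag_label = NA, ent_mean_d1 = 3)
  # references (R = 2): bags at 2 and 1 (distances 1, 2)  -> votes -1, -1
  # citers (C_cite = 2): neighbourhoods of each train bag among the rest + q:
  #   bag 0: neighbours 1, 2 (d = 1, 2) vs q at 3 -> rank 3, not a citer
  #   bag 1: 0 and 2 at d = 1 -> q (d = 2) rank 3, not a citer
  #   bag 2: 1 at d = 1, q at d = 1 -> rank <= 2, citer (-1)
  #   bags 10, 11, 12: q at d = 7..9 vs neighbours at d = 1, 2 -> not citers
  # votes: {-1, -1, -1} -> -1
  expect_identical(as.integer(citation_knn_predict(tr, te, citation_config(R = 2, C_cite = 2))),
                   -1L)

  # query at 9: references 10, 11 (+1, +1); citers: 10 (q at d = 1) -> +1
  te2 <- tibble::tibble(bag_id = "q", bag_label = NA, ent_mean_d1 = 9)
  expect_identical(as.integer(citation_knn_predict(tr, te2, citation_config(R = 2, C_cite = 2))),
                   1L)
})

test_that("citation-kNN degenerate cases", {
  tr_pos <- bags_1d(c(0, 5, 9), c(1, 1, 1))
  te <- tibble::tibble(bag_id = "q", bag_label = NA, ent_mean_d1 = 100)
  expect_identical(as.integer(citation_knn_predict(tr_pos, te, citation_config(R = 3))),
                   1L)
  one <- bags_1d(4, -1)
  expect_identical(as.integer(citation_knn_predict(one, te, citation_config(R = 1, C_cite = 1))),
                   -1L)
  expect_error(citation_knn_predict(one, te, citation_config(R = 2)),
               class = "iomil_configuration_error")
  # R = all bags: the reference vote alone is the global majority
  tr_mix <- bags_1d(c(0, 1, 2, 3, 50), c(-1, -1, -1, -1, 1))
  te3 <- tibble::tibble(bag_id = "q", bag_label = NA, ent_mean_d1 = 200)
  expect_identical(as.integer(citation_knn_predict(tr_mix, te3, citation_config(R = 5, C_cite = 1))),
                   -1L)
})

test_that("bag-dissolution SVM averages decision values with the tie rule", {
  ft <- synth_features(n_bags = 10, sep = 4, seed = 12)
  clf <- wemisvm_train(ft, fast_pso(), fast_lo())
  fc <- clf$feature_names
  for (id in c("bag01", "bag02")) {
    bf <- ft[ft$bag_id == id, ]
    p <- wemisvm_predict(clf, bf)
    expect_identical(as.integer(p),
                     if (mean(decision_values(clf, as.matrix(bf[, fc]))) >= 0) 1L else -1L)
  }
  # all decision values positive -> +1
  pos_bag <- ft[ft$bag_label == 1, ][1:5, ]
  dv <- decision_values(clf, as.matrix(pos_bag[, fc]))
  expect_true(all(dv > 0))
  expect_identical(as.integer(wemisvm_predict(clf, pos_bag)), 1L)
  expect_error(wemisvm_predict(clf, ft[0, ]), class = "iomil_prediction_error")
})

test_that("single-instance baseline runs the shared protocol deterministically", {
  ds <- cached_fixture("baseline_dataset", function() {
    generate_dataset(c(cancer = 10, normal = 14),
                     config_overrides = high_contrast, master_seed = 11)
  })
  imf <- cached_fixture("baseline_imf", function() whole_image_features(ds))
  expect_identical(nrow(imf), 24L)
  expect_identical(length(iomil:::feature_cols(imf)), 16L)
  r1 <- single_instance_svm_baseline(imf, fast_pso(), fast_lo(), seed = 19)
  r2 <- single_instance_svm_baseline(imf, fast_pso(), fast_lo(), seed = 19)
  expect_identical(r1$summary, r2$summary)
  expect_identical(nrow(r1$groups), 5L)
  expect_true(r1$summary$ACC >= 0 && r1$summary$ACC <= 1)
})
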