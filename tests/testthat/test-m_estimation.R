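test_that("metabolic rate constants and the weighted sum are exact", {
  expect_equal(estimate_m("Sit")$m, 72.5)
  expect_equal(estimate_m("Stand", activity_probabilities(0, 0, 1))$m, 174)
  expect_equal(estimate_m("Stand", activity_probabilities(1, 0, 0))$m, 75)
  expect_equal(estimate_m("Stand", activity_probabilities(0.2, 0.5, 0.3))$m,
               129.7)
  # sitting ignores probabilities entirely
  expect_equal(estimate_m("Sit", activity_probabilities(0, 0, 1))$m, 72.5)
  cfg <- pipeline_config(m_levels = c(low = 70, moderate = 120, high = 180))
  expect_equal(estimate_m("Stand", activity_probabilities(0.5, 0, 0.5),
                          cfg)$m, 125)
})

test_that("invalid posture or probabilities are rejected", {
  expect_error(estimate_m("Lying"), "Sit or Stand")
  expect_error(estimate_m("Stand"), "requires activity probabilities")
  expect_error(activity_probabilities(0.5, 0.4, 0.3), "sum to 1")
  expect_error(activity_probabilities(-0.1, 0.6, 0.5), "\\[0, 1\\]")
})

test_that("the weighted sum is a convex combination of the level boundaries", {
  set.seed(61)
  cfg <- pipeline_config()
  for (rep in 1:50) {
    p <- runif(3)
    p <- p / sum(p)
    m <- estimate_m("Stand", activity_probabilities(p[1], p[2], p[3]), cfg)$m
    expect_gte(m, 75)
    expect_lte(m, 174)
  }
})

sep_training <- function(n = 8, seed = 62) {
  set.seed(seed)
  data.frame(
    center_spread = c(runif(n, 0, 0.5), runif(n, 2, 6), runif(n, 20, 60)),
    scale_spread = c(runif(n, 0, 0.01), runif(n, 0.05, 0.2),
                     runif(n, 0.5, 2)),
    flow_intensity = c(runif(n, 0, 2), runif(n, 5, 12), runif(n, 20, 50)),
    label = rep(c("low", "moderate", "high"), each = n),
    stringsAsFactors = FALSE)
}

test_that("the classifier memorizes a single duplicated point per class", {
  tr <- data.frame(center_spread = c(0.1, 3, 40),
                   scale_spread = c(0.001, 0.1, 1),
                   flow_intensity = c(1, 8, 30),
                   label = c("low", "moderate", "high"))
  tr <- tr[rep(1:3, each = 5), ]
  for (kind in c("random_forest", "knn", "svm")) {
    clf <- fit_activity_classifier(tr, model_kind = kind, seed = 0)
    for (i in c(1, 6, 11)) {
      p <- predict_probabilities(clf, tr[i, 1:3])
      top <- c("low", "moderate", "high")[max.col(as.matrix(p))]
      expect_equal(top, tr$label[i], info = kind)
    }
  }
})

test_that("training is deterministic and invariant to row order", {
  tr <- sep_training()
  probe <- sep_training(n = 4, seed = 63)[, 1:3]
  c1 <- fit_activity_classifier(tr, seed = 7)
  c2 <- fit_activity_classifier(tr, seed = 7)
  set.seed(999)  # prediction must not consume RNG state dependently
  p1 <- predict_probabilities(c1, probe)
  p2 <- predict_probabilities(c2, probe)
  expect_identical(p1, p2)
  c3 <- fit_activity_classifier(tr[sample(nrow(tr)), ], seed = 7)
  p3 <- predict_probabilities(c3, probe)
  expect_identical(p1, p3)
})

test_that("missing classes and ambiguous labels are handled", {
  tr <- sep_training()
  expect_error(fit_activity_classifier(tr[tr$label != "high", ]),
               "high")
  with_amb <- rbind(tr, data.frame(center_spread = 1, scale_spread = 0.05,
                                   flow_intensity = 4, label = "ambiguous"))
  expect_silent(clf <- fit_activity_classifier(with_amb, seed = 1))
})

test_that("predicted probabilities live on the simplex in fixed order", {
  clf <- fit_activity_classifier(sep_training(), seed = 2)
  set.seed(64)
  probe <- data.frame(center_spread = runif(200, 0, 80),
                      scale_spread = runif(200, 0, 3),
                      flow_intensity = runif(200, 0, 60))
  p <- predict_probabilities(clf, probe)
  expect_equal(names(p), c("p_low", "p_moderate", "p_high"))
  expect_true(all(abs(rowSums(as.matrix(p)) - 1) < 1e-9))
  expect_true(all(as.matrix(p) >= 0 & as.matrix(p) <= 1))
  single <- predict_probabilities(clf, structure(
    list(center_spread = 0.1, scale_spread = 0.001, flow_intensity = 0.5,
         window_frames = 210L), class = "activity_features"))
  expect_s3_class(single, "activity_probabilities")
  expect_equal(single$low + single$moderate + single$high, 1,
               tolerance = 1e-9)
})

test_that("classifiers persist with their provenance and restore identically", {
  clf <- fit_activity_classifier(sep_training(), seed = 3,
                                 hyperparameters = list(num_trees = 50))
  path <- withr::local_tempfile(fileext = ".rds")
  save_classifier(clf, path)
  back <- load_classifier(path)
  expect_equal(back$hyperparameters, list(num_trees = 50))
  expect_equal(back$seed, 3L)
  probe <- sep_training(n = 3, seed = 65)[, 1:3]
  expect_identical(predict_probabilities(clf, probe),
                   predict_probabilities(back, probe))
  saveRDS(list(), path)
  expect_error(load_classifier(path), "activity classifier")
})
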