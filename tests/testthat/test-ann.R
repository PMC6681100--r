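test_that("architecture grid has exactly 24 configurations with the stated sizes", {
  grid <- enumerate_grid(12)
  expect_length(grid, 24)
  one_layer <- Filter(function(g) g$n_hidden_layers == 1, grid)
  expect_equal(sort(unique(vapply(one_layer, function(g) g$hidden_sizes[1],
                                  0L))), c(8L, 12L, 16L))
  # a 12-node first layer yields second-layer sizes 8, 12, 16
  expect_equal(net_config("rectifier", 1, 2 / 3)$hidden_sizes, c(12L, 8L))
  expect_equal(net_config("rectifier", 1, 1)$hidden_sizes, c(12L, 12L))
  expect_equal(net_config("rectifier", 1, 4 / 3)$hidden_sizes, c(12L, 16L))
  # all four activations, no duplicated configuration
  acts <- vapply(grid, `[[`, "", "activation")
  expect_equal(sort(unique(acts)),
               sort(c("rectifier", "rectifier_dropout", "maxout",
                      "maxout_dropout")))
  ids <- vapply(grid, function(g) paste(g$activation,
                                        paste(g$hidden_sizes, collapse = "x")),
                "")
  expect_equal(anyDuplicated(ids), 0L)
  # maxout carries two linear pieces
  expect_gt(n_params(net_config("maxout", 1)),
            n_params(net_config("rectifier", 1)))
})

test_that("training pairs are balanced, disjoint and seed-deterministic", {
  pens <- rbind(toy_pens(15))
  # pens 1..5 are event pens; 10 controls available in the same cell
  events <- toy_events(pens$pen_id[1:5], days = c(10, 20, 30, 15, 25))
  pr <- make_training_pairs(pens, events, seed = 3)
  expect_equal(nrow(pr$set1), 5)
  expect_equal(nrow(pr$set2), 5)
  # disjoint controls across the two sets, none of them event pens
  expect_length(intersect(pr$set1$control_pen, pr$set2$control_pen), 0)
  expect_length(intersect(c(pr$set1$control_pen, pr$set2$control_pen),
                          pens$pen_id[1:5]), 0)
  # 50/50 by construction: one control per event pen
  expect_equal(anyDuplicated(pr$set1$control_pen), 0L)
  # deterministic under the same seed
  pr2 <- make_training_pairs(pens, events, seed = 3)
  expect_identical(pr, pr2)
  # single eligible control is reused in both sets, with a message
  pens3 <- toy_pens(2)
  ev3 <- toy_events(pens3$pen_id[1], 10)
  expect_message(pr3 <- make_training_pairs(pens3, ev3, seed = 1),
                 "single eligible control")
  expect_equal(pr3$set1$control_pen, pr3$set2$control_pen)
  # no eligible control: dropped with a warning, empty pairing
  pens4 <- toy_pens(1)
  ev4 <- toy_events(pens4$pen_id, 10)
  expect_warning(pr4 <- make_training_pairs(pens4, ev4, seed = 1),
                 "no eligible control")
  expect_null(pr4$set1)
})

test_that("pen probability is the maximum over included days", {
  expect_equal(pen_probability(c(0.2, 0.9, 0.4)), 0.9)
  expect_equal(pen_probability(0.3), 0.3)
  expect_equal(pen_probability(c(0.4, 0.9, 0.2)),
               pen_probability(c(0.9, 0.2, 0.4)))
  expect_error(pen_probability(NA_real_), "no daily predictions")
})

test_that("alarm types include the stated day windows", {
  expect_equal(alarm_days("UNTIMED"), c(-3L, -2L, -1L))
  expect_equal(alarm_days("BEFORE"), c(-3L, -2L))
  expect_equal(alarm_days("ON"), -1L)
})

test_that("training is seed-reproducible and separates separable data", {
  wf <- toy_window_features(6, shift = 4, seed = 10)
  cols <- predictor_columns()
  std <- standardize_features(wf)
  X <- as.matrix(std[cols])
  net1 <- mlp_train(X, wf$label, net_config("rectifier", 1), seed = 5)
  net2 <- mlp_train(X, wf$label, net_config("rectifier", 1), seed = 5)
  expect_identical(mlp_predict(net1, X), mlp_predict(net2, X))
  p <- mlp_predict(net1, X)
  expect_true(all(p[wf$label == 1] > 0.5))
  expect_true(all(p[wf$label == 0] < 0.5))
  # maxout and dropout variants train too
  for (act in c("maxout", "rectifier_dropout", "maxout_dropout")) {
    net <- mlp_train(X, wf$label, net_config(act, 2 / 3), seed = 5,
                     epochs = 150)
    expect_true(all(is.finite(mlp_predict(net, X))))
  }
})

test_that("leave-one-pair-out search partitions pairs and finds separable structure", {
  wf <- toy_window_features(5, shift = 4, seed = 21)
  grid <- list(net_config("rectifier", 2 / 3), net_config("rectifier", 1))
  res <- cv_optimize(wf, grid, seed = 9, epochs = 150)
  expect_equal(nrow(res$metrics), 2)
  # separable features give perfect cross-validated accuracy
  expect_equal(max(res$metrics$accuracy), 1)
  # ties break to the configuration with fewer parameters
  if (res$metrics$accuracy[1] == res$metrics$accuracy[2]) {
    expect_equal(res$best_index, which.min(res$metrics$n_params))
  }
  # every pair is a fold: removing one pair leaves the others intact
  expect_equal(sort(unique(wf$pair_id)), 1:5)
  expect_error(cv_optimize(toy_window_features(2), grid, seed = 1),
               "at least 3 pairs")
})

test_that("label-shuffled features yield chance-level cross-validation", {
  wf <- toy_window_features(10, shift = 0, seed = 33)  # no signal at all
  res <- cv_optimize(wf, list(net_config("rectifier", 1)), seed = 2,
                     epochs = 150)
  expect_lt(abs(res$metrics$accuracy - 0.5), 0.3)
})

test_that("final training selects a threshold on the 100-value grid", {
  wf1 <- toy_window_features(5, shift = 4, seed = 40)
  wf2 <- toy_window_features(5, shift = 4, seed = 41)
  model <- train_final_and_threshold(wf1, wf2, net_config("rectifier", 1),
                                     net_config("rectifier", 1), seed = 6)
  grid <- seq(0.01, 1, by = 0.01)
  expect_length(grid, 100)
  expect_true(model$models[[1]]$threshold %in% grid)
  expect_true(model$threshold >= 0.01 && model$threshold <= 1)
  # on separable data the chosen threshold reaches accuracy 1 per set
  expect_equal(model$models[[1]]$sensitivity, 1)
  expect_equal(model$models[[1]]$specificity, 1)
  # test-time combination is the mean of the two networks' probabilities
  feats <- wf1[c("pen_id", "day_rel")]
  feats$day_index <- feats$day_rel + 10
  feats <- cbind(feats, wf1[predictor_columns()])
  daily <- predict_daily_probabilities(model, feats)
  cols <- predictor_columns()
  p_each <- sapply(model$models, function(m) {
    mlp_predict(m$net,
                as.matrix(standardize_features(feats, m$stats)[cols]))
  })
  expect_equal(daily$prob, rowMeans(p_each), tolerance = 1e-12)
})
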