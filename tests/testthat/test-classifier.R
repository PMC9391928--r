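test_that("stratified split honours the fraction and the seed", {
  labels <- rep(c("starch", "other"), c(100, 10))
  sp <- split_train_validation(labels, 0.9, seed = 1)
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_setequal(c(sp$train, sp$validation), seq_along(labels))
  expect_equal(sum(labels[sp$train] == "starch"), 90)
  expect_equal(sum(labels[sp$validation] == "starch"), 10)
  expect_equal(sum(labels[sp$train] == "other"), 9)

  sp2 <- split_train_validation(labels, 0.9, seed = 1)
  expect_identical(sp, sp2)
  sp3 <- split_train_validation(labels, 0.9, seed = 2)
  expect_false(identical(sp$train, sp3$train))

  tiny <- split_train_validation(c("a", "a"), 0.5, seed = 1)
  expect_length(tiny$train, 1)
  expect_length(tiny$validation, 1)

  expect_error(split_train_validation(c("a", "a", "b"), 0.9, 1), "'b'")
  expect_error(split_train_validation(c("a", NA), 0.9, 1), "labelled")
})

test_that("model construction is seeded and shape-aware", {
  cfg26 <- classifier_config(c(paste0("p", 1:24), "starch", "other"),
                             seed = 3)
  m26 <- build_model(cfg26, tiny_dims())
  expect_equal(ncol(m26$par$head_W2), 26)

  m26b <- build_model(cfg26, tiny_dims())
  expect_identical(m26$par, m26b$par)
  expect_true(is.finite(m26$n_params) && m26$n_params > 0)

  # untrained model already emits normalized probabilities
  b <- tiny_batch()
  cfg <- classifier_config(tiny_config()$classes, seed = 1)
  m <- build_model(cfg, tiny_dims())
  p <- predict(m, b[1:7])
  expect_equal(rowSums(p$prob), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p$prob >= 0 & p$prob <= 1))

  expect_error(build_model(classifier_config(c("a", "b"), kernel = 30),
                           tiny_dims()), "kernel")
})

test_that("training reduces the loss and reports a coherent split", {
  tr <- tiny_trained()
  losses <- tr$report$epoch_losses
  expect_length(losses, 8)
  expect_lte(losses[length(losses)], losses[1])
  expect_setequal(c(tr$report$train_idx, tr$report$validation_idx),
                  seq_len(length(tiny_batch())))
  expect_true(tr$report$accuracy >= 0 && tr$report$accuracy <= 1)
  expect_equal(sum(tr$report$confusion),
               length(tr$report$validation_idx))

  # single-epoch bookkeeping
  cfg1 <- classifier_config(tiny_config()$classes, epochs = 1,
                            learning_rate = 1e-6, seed = 2)
  tr1 <- train_classifier(build_model(cfg1, tiny_dims()), tiny_batch())
  expect_length(tr1$report$epoch_losses, 1)
})

test_that("training is deterministic in the seed", {
  cfg <- classifier_config(tiny_config()$classes, epochs = 2, seed = 42)
  b <- tiny_batch()
  r1 <- train_classifier(build_model(cfg, tiny_dims()), b)
  r2 <- train_classifier(build_model(cfg, tiny_dims()), b)
  expect_identical(r1$model$par, r2$model$par)
  expect_identical(r1$report$epoch_losses, r2$report$epoch_losses)
})

test_that("zero-noise classes are learned perfectly", {
  cfg0 <- tiny_config(noise_sd = 0)
  b0 <- generate_particle_events(cfg0, tiny_templates(), n_per_class = 40)
  ccfg <- classifier_config(cfg0$classes, epochs = 20, seed = 7)
  tr <- train_classifier(build_model(ccfg, tiny_dims()), b0)
  expect_equal(tr$report$accuracy, 1.0)
})

test_that("confusion matrix and accuracies follow the hand-counted oracle", {
  # 20 outcomes enumerated by hand: [[8,2],[1,9]]
  truth <- rep(c("a", "b"), c(10, 10))
  pred <- c(rep("a", 8), rep("b", 2), rep("a", 1), rep("b", 9))
  ev <- evaluate(truth, pred, c("a", "b"))
  expect_equal(unname(ev$confusion), matrix(c(8, 1, 2, 9), 2))
  expect_equal(ev$overall_accuracy, 0.85)
  expect_equal(unname(ev$per_class_accuracy), c(0.80, 0.90))

  # perfect predictions: identity pattern
  evp <- evaluate(truth, truth, c("a", "b"))
  expect_equal(evp$overall_accuracy, 1.0)
  expect_equal(sum(diag(evp$confusion)), 20)

  # permutation invariance
  set.seed(1)
  ord <- sample(20)
  evs <- evaluate(truth[ord], pred[ord], c("a", "b"))
  expect_identical(evs$confusion, ev$confusion)

  expect_error(evaluate(character(0), character(0), "a"), "empty")
  expect_error(evaluate("a", "c", c("a", "b")), "outside")
})

test_that("predictions agree with evaluate bookkeeping", {
  tr <- tiny_trained()
  b <- tiny_batch()
  va <- tr$report$validation_idx
  p <- predict(tr$model, b[va])
  expect_equal(rowSums(p$prob), rep(1, length(va)), tolerance = 1e-6)
  ev <- evaluate(b$labels[va], p$labels, tr$model$class_names)
  expect_equal(ev$overall_accuracy, tr$report$accuracy)

  wrong <- b[1:2]
  wrong$signals$spectrum <- wrong$signals$spectrum[, 1:5, , drop = FALSE]
  expect_error(predict(tr$model, wrong), "shape")
})

test_that("validation accuracy degrades with signal noise", {
  # 3 noise levels x 5 seeds; mean accuracy non-increasing from the
  # lowest to the highest noise level
  noise_levels <- c(0.1, 1.5, 4)
  mean_acc <- vapply(noise_levels, function(ns) {
    accs <- vapply(1:5, function(s) {
      cfg <- tiny_config(noise_sd = ns, master_seed = 100 + s)
      b <- generate_particle_events(cfg, tiny_templates(), n_per_class = 30)
      ccfg <- classifier_config(cfg$classes, epochs = 5, seed = s)
      train_classifier(build_model(ccfg, tiny_dims()), b)$report$accuracy
    }, 1)
    mean(accs)
  }, 1)
  expect_gte(mean_acc[1], mean_acc[3])
})
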