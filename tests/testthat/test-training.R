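test_that("multilevel_loss matches a direct re-evaluation and its worked cases", {
  w <- level_weights()
  expect_equal(unname(unclass(w)), c(0.1, 0.3, 0.5, 1.0))

  # unit per-level cross-entropies: craft logits with CE exactly 1 per level
  # CE([a, 0], y = 0) = 1  <=>  a = -log(exp(1) - 1)
  a <- -log(exp(1) - 1)
  z_unit <- list(c(a, 0), c(a, 0), c(a, 0), c(a, 0))
  expect_equal(multilevel_loss(z_unit, c(0L, 0L, 0L, 0L), w), 1.9,
               tolerance = 1e-9)

  # perfect one-hot agreement drives the loss to ~0
  z_hot <- lapply(1:4, function(l) c(1000, 0, 0))
  expect_equal(multilevel_loss(z_hot, c(0L, 0L, 0L, 0L), w), 0)

  # random case against an independently scripted sum of -log softmax probs
  set.seed(77)
  for (rep in 1:10) {
    zs <- lapply(c(3, 5, 7, 11), function(k) rnorm(k))
    y <- vapply(c(3, 5, 7, 11), function(k) sample(0:(k - 1), 1), integer(1))
    direct <- sum(vapply(1:4, function(l) {
      p <- exp(zs[[l]]) / sum(exp(zs[[l]]))
      unclass(w)[l] * -log(p[y[l] + 1])
    }, numeric(1)))
    expect_equal(multilevel_loss(zs, y, w), direct, tolerance = 1e-6)
    # linearity in each weight, holding the CE terms fixed
    w2 <- level_weights(0.2, 0.6, 1.0, 2.0)
    expect_equal(multilevel_loss(zs, y, w2),
                 2 * multilevel_loss(zs, y, level_weights(0.1, 0.3, 0.5, 1)),
                 tolerance = 1e-9)
  }
  expect_error(multilevel_loss(list(1:2, 1:2, 1:2, 1:2), c(0L, 0L, 0L, 5L)),
               "out of range")
  expect_error(level_weights(1, 0.5, 0.3, 0.1), "descending")
  expect_error(level_weights(0, 0, 0, 0), "lambda4")
  expect_s3_class(level_weights(1, 0, 0, 0, check = FALSE), "level_weights")
})

test_that("the 80/20 split has exact counts and seed-stable membership", {
  labels <- rep(0:3, c(10, 25, 7, 58))
  tr <- train_test_split(labels, seed = 123)
  expect_identical(tr, train_test_split(labels, seed = 123))
  for (cl in 0:3) {
    n <- sum(labels == cl)
    expect_equal(sum(tr & labels == cl), floor(0.8 * n))
  }
  flat <- train_test_split(labels, seed = 9, stratify = FALSE)
  expect_equal(sum(flat), floor(0.8 * length(labels)))
  expect_error(train_test_split(c(1, 2, 2), seed = 1), "fewer than 2")
})

test_that("classification metrics match a hand-computed confusion matrix", {
  # perfect and constant predictors
  perfect <- classification_report(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perfect$accuracy, 1)
  expect_equal(perfect$f1, 1)
  constant <- classification_report(c(0, 1, 0, 1), rep(0, 4))
  expect_equal(constant$accuracy, 0.5)
  expect_equal(constant$precision, mean(c(0.5, 0)))  # class 1 never predicted

  # 3-class confusion: truth/pred counts worked out by hand
  truth <- rep(c(0, 1, 2), c(4, 3, 3))
  pred <- c(0, 0, 1, 2, 1, 1, 0, 2, 2, 2)
  # class 0: TP 2, FP 1, FN 2;  class 1: TP 2, FP 1, FN 1;
  # class 2: TP 3, FP 1, FN 0;  7 of 10 correct
  r <- classification_report(truth, pred)
  p <- c(2 / 3, 2 / 3, 3 / 4)
  rc <- c(2 / 4, 2 / 3, 1)
  expect_equal(r$per_class$precision, p)
  expect_equal(r$per_class$recall, rc)
  expect_equal(r$accuracy, 7 / 10)
  expect_equal(r$f1, mean(2 * p * rc / (p + rc)))
})

test_that("training separates a tiny 2-class set and is seed-reproducible", {
  specs <- default_class_specs(2)
  ds <- generate_dataset(specs, images_per_variant = 5, size = 32, seed = 7)
  expect_length(ds$images, 20)
  cfg <- train_config(epochs = 30, seed = 3)
  fit <- train_slm(build_gated_cnn(tiny_cfg(2, 32), seed = 3),
                   ds$images, ds$labels, cfg)
  expect_equal(nrow(fit$history), 30)
  # the learning-rate schedule multiplies by the drop factor at each piece
  expect_equal(unique(fit$history$lr), 3e-2 * 0.2^(0:2))
  expect_equal(fit$history$lr[11] / fit$history$lr[10], 0.2)
  # separable data: training accuracy reaches 1.0
  rep <- evaluate_classification(fit$model, ds$images, ds$labels)
  expect_equal(rep$accuracy, 1.0)
  # determinism: identical seed, identical loss history
  fit2 <- train_slm(build_gated_cnn(tiny_cfg(2, 32), seed = 3),
                    ds$images, ds$labels, cfg)
  expect_identical(fit$history, fit2$history)
  expect_error(train_slm(build_gated_cnn(tiny_cfg(2, 32), seed = 1),
                         list(), integer(0), cfg), "empty training set")
})

test_that("multi-level training reduces every level's loss on separable data", {
  specs <- default_class_specs(4)
  ds <- generate_dataset(specs, images_per_variant = 5, size = 32, seed = 19)
  set.seed(19)
  tax <- random_taxonomy(c1 = 2, c2 = 2, c3 = 3, c4 = 4)
  hier <- do.call(rbind, lapply(ds$labels, function(l)
    as.integer(lift_label(tax, l))))
  cfg <- train_config(epochs = 8, seed = 5)
  fit <- train_mlm(build_multilevel_gcnn(tiny_cfg(1, 32), tax, seed = 5),
                   ds$images, hier, cfg)
  expect_equal(nrow(fit$history), 8)
  for (col in paste0("loss_l", 1:4))
    expect_lt(tail(fit$history[[col]], 1), fit$history[[col]][1])
  # isolating the top level still trains it (diagnostic weight setting)
  fit1 <- train_mlm(build_multilevel_gcnn(tiny_cfg(1, 32), tax, seed = 5),
                    ds$images, hier, cfg,
                    w = level_weights(1, 0, 0, 0, check = FALSE))
  expect_lt(tail(fit1$history$loss_l1, 1), fit1$history$loss_l1[1])
})
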