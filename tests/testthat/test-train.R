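test_that("split_train_test is a disjoint, exhaustive, seeded partition", {
  ds <- tiny_dataset(c(10, 7, 5), image_size = 16L)
  sp <- split_train_test(ds, 0.8, seed = 3)
  expect_equal(n_items(sp$train), floor(0.8 * 22))
  expect_equal(n_items(sp$train) + n_items(sp$test), 22L)
  # reconstructible and disjoint: label multiset is preserved
  expect_equal(sort(c(sp$train$labels, sp$test$labels)), sort(ds$labels))
  sp2 <- split_train_test(ds, 0.8, seed = 3)
  expect_identical(sp$train$images, sp2$train$images)
  sp3 <- split_train_test(ds, 0.8, seed = 4)
  expect_false(identical(sp$train$labels, sp3$train$labels) &&
                 identical(sp$train$images, sp3$train$images))
  expect_error(split_train_test(ds, 1.2), "in \\(0, 1\\)")
})

test_that("compute_metrics matches hand-worked examples", {
  perfect <- compute_metrics(c(1, 2, 3, 1), c(1, 2, 3, 1), 3)
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$precision, 100)
  expect_equal(perfect$recall, 100)
  expect_equal(perfect$f1, 100)
  # confusion [[3,1],[1,3]]: accuracy 75, weighted F1 75
  truth <- c(rep(1, 4), rep(2, 4))
  pred <- c(1, 1, 1, 2, 2, 2, 2, 1)
  m <- compute_metrics(truth, pred, 2)
  expect_equal(unname(m$confusion), matrix(c(3, 1, 1, 3), 2, 2))
  expect_equal(m$accuracy, 75)
  expect_equal(m$f1, 75)
  expect_equal(sum(m$confusion), 8L)
  expect_error(compute_metrics(integer(0), integer(0), 2), "empty")
  expect_error(compute_metrics(1:3, 1:2, 3), "differ in length")
})

test_that("weighted recall equals accuracy and metrics stay in [0, 100]", {
  set.seed(17)
  for (i in 1:10) {
    truth <- sample(1:4, 30, replace = TRUE)
    pred <- sample(1:4, 30, replace = TRUE)
    m <- compute_metrics(truth, pred, 4)
    expect_equal(m$recall, m$accuracy)
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) >= 0))
    expect_true(all(unlist(m[c("accuracy", "precision", "recall", "f1")]) <= 100))
    expect_equal(sum(m$confusion), 30L)
  }
})

test_that("a flat validation loss triggers LR reduction and early stop", {
  ds <- tiny_dataset(c(8, 8), image_size = 16L, seed = 20)
  g <- tiny_graph(input_size = 16L, channels = 3L, n_classes = 2L)
  m <- init_model(g, seed = 1)
  # negligible learning rate: validation loss is flat to within the
  # improvement threshold, so the plateau/early-stop callbacks must fire
  cfg <- train_config(learning_rate = 1e-12, batch_size = 8, max_epochs = 12,
                      early_stop_patience = 6, lr_reduce_patience = 3,
                      seed = 2)
  fit <- train_model(m, ds, cfg)
  expect_lte(fit$epochs_run, cfg$max_epochs)
  expect_equal(fit$epochs_run, 7L)          # 1 best epoch + patience 6
  expect_equal(fit$stopped_epoch, 1L)
  expect_lt(min(fit$history$lr), cfg$learning_rate)  # reduced at least once
  expect_true(all(diff(fit$history$lr) <= 0))
  expect_named(fit$history, c("epoch", "train_loss", "val_loss",
                              "train_acc", "val_acc", "lr"))
  # best weights restored; they moved only negligibly from initialisation
  expect_equal(fit$model$weights$conv1$W, m$weights$conv1$W,
               tolerance = 1e-8)
})

test_that("training on separable two-class data beats chance", {
  # nv vs vasc differ strongly in lesion colour; batch norm is needed for
  # the tiny network to pick the small colour signal out of the background
  ds <- generate_dataset(synthetic_spec(c(nv = 20, vasc = 20),
                                        image_size = 16L, seed = 30))
  g <- tiny_graph(input_size = 16L, channels = 3L, n_classes = 2L, bn = TRUE)
  fit <- train_model(init_model(g, seed = 6), ds,
                     train_config(max_epochs = 8, batch_size = 8, seed = 6))
  acc <- tail(fit$history$train_acc, 1)
  expect_gt(acc, 0.6)
  # history improves overall: final training loss below the first epoch's
  expect_lt(tail(fit$history$train_loss, 1), fit$history$train_loss[1])
  # predictions are a valid probability simplex
  p <- predict(fit$model, ds)
  expect_equal(dim(p), c(40L, 2L))
  expect_equal(rowSums(p), rep(1, 40), tolerance = 1e-9)
  m <- evaluate_model(fit$model, ds)
  expect_s3_class(m, "metrics_report")
})

test_that("train_config validates patience and split fractions", {
  expect_error(train_config(validation_fraction = 0), "in \\(0, 1\\)")
  expect_error(train_config(early_stop_patience = 0), ">= 1")
})
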