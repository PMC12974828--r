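test_that("target_counts implements the four strategies exactly", {
  cnt <- table2_train_counts()
  maxc <- 5331L
  expect_equal(target_counts(cnt, imbalance_strategy("minority")),
               c(nv = 5331L, mel = 908L, bkl = 872L, bcc = 420L,
                 akiec = 272L, vasc = 114L, df = 5331L))
  expect_equal(target_counts(cnt, imbalance_strategy("not_minority")),
               c(nv = 5331L, mel = 5331L, bkl = 5331L, bcc = 5331L,
                 akiec = 5331L, vasc = 5331L, df = 95L))
  expect_equal(target_counts(cnt, imbalance_strategy("not_majority")),
               setNames(rep(maxc, 7L), names(cnt)))
  expect_equal(target_counts(cnt, imbalance_strategy("multiplier", k = 2)),
               c(nv = 5331L, mel = 1816L, bkl = 1744L, bcc = 840L,
                 akiec = 544L, vasc = 228L, df = 190L))
  expect_equal(target_counts(cnt, imbalance_strategy("multiplier", k = 3)),
               c(nv = 5331L, mel = 2724L, bkl = 2616L, bcc = 1260L,
                 akiec = 816L, vasc = 342L, df = 285L))
  # 4x caps at the majority count
  expect_equal(target_counts(cnt, imbalance_strategy("multiplier", k = 4)),
               c(nv = 5331L, mel = 3632L, bkl = 3488L, bcc = 1680L,
                 akiec = 1088L, vasc = 456L, df = 380L))
})

test_that("target_counts requires tie_break on tied extremes", {
  cnt <- c(a = 10L, b = 10L, c = 3L)
  expect_error(target_counts(cnt, imbalance_strategy("not_majority")),
               "tie")
  got <- target_counts(cnt, imbalance_strategy("not_majority"), tie_break = 1L)
  expect_equal(got, c(a = 10L, b = 10L, c = 10L))
  expect_error(target_counts(cnt, imbalance_strategy("not_majority"),
                             tie_break = 3L),
               "tied")
  expect_error(target_counts(c(a = 5L), imbalance_strategy("minority")),
               "two classes")
  expect_error(imbalance_strategy("multiplier"), "requires integer k")
  expect_error(imbalance_strategy("minority", k = 2), "only meaningful")
})

test_that("smote_interpolate is an elementwise convex combination", {
  a <- array(c(0, 10, 4, 8), dim = c(2, 2))
  b <- array(c(10, 0, 4, 0), dim = c(2, 2))
  expect_equal(smote_interpolate(a, b, 0), as.numeric(a) + 0 * a)
  expect_equal(as.vector(smote_interpolate(a, b, 1)), as.vector(b))
  expect_equal(as.vector(smote_interpolate(a, b, 0.25)), c(2.5, 7.5, 4, 6))
  expect_error(smote_interpolate(a, 1:3, 0.5), "different shapes")
  expect_error(smote_interpolate(a, b, 1.5), "lambda")
})

test_that("nearest_neighbors matches a brute-force oracle", {
  set.seed(21)
  m <- matrix(rnorm(9 * 4), 9, 4)
  nn <- nearest_neighbors(m, 3)
  for (i in 1:9) {
    d <- apply(m, 1, function(r) sqrt(sum((r - m[i, ])^2)))
    d[i] <- Inf
    expect_setequal(nn[[i]], order(d)[1:3])
  }
  expect_warning(nearest_neighbors(m[1:3, ], 5), "clamped")
  expect_error(nearest_neighbors(m[1, , drop = FALSE], 1), "at least 2")
})

test_that("nearest_neighbors breaks distance ties by ascending index", {
  m <- matrix(c(0, 1, 1, 5), ncol = 1)  # rows 2 and 3 equidistant from row 1
  nn <- nearest_neighbors(m, 1)
  expect_identical(nn[[1]], 2L)
})

test_that("resample hits targets exactly, preserves originals, is convex", {
  ds <- tiny_dataset(c(12, 6, 4), image_size = 16L, seed = 9)
  strat <- imbalance_strategy("not_majority")
  rs <- resample(ds, strat, smote_config(seed = 31))
  expect_equal(unname(class_counts(rs)), c(12L, 12L, 12L))
  # originals first, bitwise unchanged
  expect_identical(rs$images[, , , seq_len(n_items(ds))], ds$images)
  expect_identical(rs$provenance[seq_len(n_items(ds))], ds$provenance)
  synth_idx <- which(rs$provenance == "synthetic")
  expect_length(synth_idx, 14L)
  # every synthetic sample lies in the coordinate-wise hull of its class
  for (i in synth_idx) {
    cls <- rs$labels[i]
    orig <- ds$images[, , , ds$labels == cls, drop = FALSE]
    lo <- apply(orig, 1:3, min); hi <- apply(orig, 1:3, max)
    img <- rs$images[, , , i]
    expect_true(all(img >= lo - 1e-9 & img <= hi + 1e-9))
  }
  # determinism
  rs2 <- resample(ds, strat, smote_config(seed = 31))
  expect_identical(rs$images, rs2$images)
  # no deficit -> unchanged object
  expect_identical(resample(ds, imbalance_strategy("multiplier", k = 1),
                            smote_config()), ds)
})

test_that("resample refuses singleton classes and wrong spaces", {
  ds <- tiny_dataset(c(6, 4), image_size = 16L)
  one <- subset_items(ds, c(which(ds$labels == 1L), which(ds$labels == 2L)[1]))
  expect_error(resample(one, imbalance_strategy("not_majority"),
                        smote_config()),
               "at least 2")
  expect_error(resample(ds, imbalance_strategy("not_majority"),
                        smote_config(space = "feature")),
               "feature-space")
})

test_that("extract_features pools spatial outputs into (N, F) matrices", {
  ds <- tiny_dataset(c(5, 4), image_size = 16L)
  g <- tiny_graph(input_size = 16L, channels = 3L, n_classes = 2L)
  backbone <- truncate_at(init_model(g, seed = 2), "relu2")
  fs <- extract_features(backbone, ds)
  expect_true(is.matrix(fs$images))
  expect_equal(nrow(fs$images), n_items(ds))
  expect_equal(ncol(fs$images), 6L)  # conv2 filters
  # oracle: GAP of the truncated model's spatial output for one image
  y <- model_forward(backbone, ds$images[, , , 1, drop = FALSE] / 255)$out
  expect_equal(fs$images[1, ], apply(y[, , , 1], 3, mean), tolerance = 1e-10)
  # feature-space SMOTE runs on the result
  rs <- resample(fs, imbalance_strategy("not_majority"),
                 smote_config(seed = 4, space = "feature", k_neighbors = 2))
  expect_equal(unname(class_counts(rs)), c(5L, 5L))
})
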