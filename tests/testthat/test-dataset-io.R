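test_that("labeled_image_set validates labels and provenance", {
  imgs <- array(0, c(4, 4, 3, 2))
  expect_error(labeled_image_set(imgs, c(1L, 3L), c("a", "b")),
               "out of range")
  expect_error(labeled_image_set(imgs, 1L, c("a", "b")),
               "labels length")
  expect_error(labeled_image_set(imgs, c(1L, 2L), c("a", "b"),
                                 provenance = c("original", "weird")),
               "unknown provenance")
  expect_error(labeled_image_set(array(0, c(4, 4, 3)), 1L, "a"),
               "array or an")
})

test_that("subset and bind preserve items and classes", {
  ds <- tiny_dataset(c(5, 3), image_size = 16L)
  sub <- subset_items(ds, c(2, 7))
  expect_equal(n_items(sub), 2L)
  expect_identical(sub$images[, , , 1], ds$images[, , , 2])
  both <- bind_items(sub, subset_items(ds, 1))
  expect_equal(n_items(both), 3L)
  expect_identical(both$images[, , , 3], ds$images[, , , 1])
  other <- labeled_image_set(array(0, c(16, 16, 3, 1)), 1L, c("x", "y"))
  expect_error(bind_items(ds, other), "class_names differ")
})

test_that("write-then-read round-trips images, labels and provenance", {
  ds <- tiny_dataset(c(8, 6, 4), image_size = 16L, seed = 55)
  ds$provenance[3] <- "synthetic"
  dir <- tempfile("roundtrip_")
  write_labeled_set(ds, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_image_directory(dir, class_names = ds$class_names)
  expect_identical(back$images, ds$images)   # 8-bit values survive PNG
  expect_identical(back$labels, ds$labels)
  expect_identical(back$provenance, ds$provenance)
  expect_identical(manifest(back), manifest(ds))
  unlink(dir, recursive = TRUE)
})

test_that("directory reading validates layout and warns when empty", {
  empty <- tempfile("empty_")
  dir.create(empty)
  expect_warning(got <- read_image_directory(empty), "no images")
  expect_equal(n_items(got), 0L)
  expect_error(read_image_directory(tempfile("nope_")), "no such directory")
  # manifest label absent from supplied class_names
  ds <- tiny_dataset(c(3, 2), image_size = 16L)
  dir <- tempfile("bad_")
  write_labeled_set(ds, dir)
  expect_error(read_image_directory(dir, class_names = "nv"),
               "absent from class_names")
  # stray class directory not covered by the manifest
  dir.create(file.path(dir, "stray"))
  expect_error(read_image_directory(dir), "not in manifest")
  unlink(dir, recursive = TRUE); unlink(empty, recursive = TRUE)
})

test_that("stage_seed is deterministic and stage-distinct", {
  expect_identical(stage_seed(1L, "resample"), stage_seed(1L, "resample"))
  expect_false(stage_seed(1L, "resample") == stage_seed(1L, "augment"))
  expect_false(stage_seed(1L, "resample") == stage_seed(2L, "resample"))
  s <- vapply(c("split", "train_baseline", "profile_batch", "train_pruned",
                "resample", "augment", "train_final"),
              function(st) stage_seed(7L, st), integer(1))
  expect_false(anyDuplicated(s) > 0)
  expect_true(all(s >= 0))
})

test_that("pipeline config validates and round-trips through YAML", {
  expect_error(pipeline_config(data = list()), "exactly one")
  expect_error(pipeline_config(data = list(directory = "x",
                                           synthetic = synthetic_spec(c(nv = 1)))),
               "exactly one")
  yml <- tempfile(fileext = ".yaml")
  writeLines(c(
    "data:",
    "  synthetic:",
    "    class_counts: {nv: 10, mel: 5}",
    "    image_size: 16",
    "    seed: 3",
    "model: {input_size: 32, n_classes: 2, width_multiplier: 0.125, middle_blocks: 1}",
    "strategy: {mode: multiplier, k: 2}",
    "train: {max_epochs: 1, seed: 5}",
    "stages: {augment: no}",
    "seed: 42"
  ), yml)
  cfg <- read_pipeline_config(yml)
  expect_s3_class(cfg, "pipeline_config")
  expect_equal(cfg$seed, 42L)
  expect_false(cfg$stages$augment)
  expect_true(cfg$stages$prune)
  expect_equal(cfg$data$synthetic$class_counts, c(nv = 10L, mel = 5L))
  expect_equal(cfg$strategy$k, 2L)
})

test_that("artifact JSON validation flags missing fields", {
  good <- tempfile(fileext = ".json")
  jsonlite::write_json(list(accuracy = 1, precision = 1, recall = 1,
                            f1 = 1, confusion = matrix(0, 2, 2)),
                       good, auto_unbox = TRUE)
  expect_true(validate_artifact_json(good, "metrics"))
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(list(accuracy = 1), bad, auto_unbox = TRUE)
  expect_error(validate_artifact_json(bad, "metrics"), "missing")
  expect_error(validate_artifact_json(good, "nonexistent_schema"),
               "unknown schema")
})
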