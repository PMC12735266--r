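# Tiny, fast fixtures: small scenes, few epochs.  The full benchmark
# regime lives in the acceptance tests.
tiny_scene <- function(n_objects = 1, labeled = 1, noise = 0)
  scene_config(height = 40, width = 40, n_objects = n_objects,
               object_radius = 3, noise_sd = noise,
               labeled_count = labeled, min_separation = 9)

tiny_cfg <- function(...)
  train_config(kernel = count_map_config(5), epochs_stage1 = 3,
               epochs_stage2 = 2, eval_delay = 0, val_threshold = 3,
               seed = 1, ...)

test_that("batches hold n positives, n augmented copies and 2n unlabeled", {
  ds <- generate_dataset(5, tiny_scene(n_objects = 4, labeled = 3),
                         seed = 2)
  b <- make_batch(ds, ds, n = 1, seed = 3, keep_fraction = 2 / 3)
  expect_length(b, 4)
  expect_equal(vapply(b, `[[`, "", "role"),
               c("positive", "augmented", "unlabeled", "unlabeled"))
  expect_equal(nrow(b[[1]]$points), 2)   # ceil(2/3 * 3)
  expect_null(b[[3]]$points)
  # recycling from a length-1 pool
  b2 <- make_batch(ds[1], ds[1], n = 2, seed = 4)
  expect_length(b2, 8)
  # without augmentation the copy is verbatim
  b3 <- make_batch(ds, ds, n = 1, seed = 5, augment = FALSE)
  expect_identical(b3[[2]]$image, b3[[1]]$image)
})

test_that("rotations and flips carry annotations with the image", {
  sc <- generate_scene(tiny_scene(noise = 0), seed = 6)
  for (k in 0:3) for (fl in c(FALSE, TRUE)) {
    tr <- transform_scene(sc$image, sc$centers, k, fl)
    # transformed annotation still sits on the transformed disk's plateau
    v <- tr$image[cbind(tr$points$row + 1, tr$points$col + 1)]
    expect_equal(v, max(tr$image))
  }
  # identity transform
  tr0 <- transform_scene(sc$image, sc$centers, 0, FALSE)
  expect_identical(tr0$image, sc$image)
  expect_identical(tr0$points, sc$centers)
})

test_that("stage-1 PU training learns easy zero-noise scenes to F1 = 1", {
  train <- generate_dataset(8, tiny_scene(n_objects = 4, labeled = 4),
                            seed = 7)
  val <- generate_dataset(3, tiny_scene(n_objects = 4, labeled = 0),
                          seed = 8)
  cfg <- train_config(kernel = count_map_config(5), epochs_stage1 = 40,
                      eval_delay = 10, val_threshold = 3, seed = 7,
                      scale_lr_small_batch = FALSE)
  ck <- train_stage1_pu(train, val, cfg)
  expect_equal(ck$val_f1, 1.0)
  expect_equal(ck$stage, "stage1")
  # risk at the end is below the starting risk (optimization sanity)
  risks <- ck$history$risk
  expect_lt(mean(tail(risks, 5)), mean(head(risks, 5)))
  # checkpoint selection: best epoch matches the history maximum
  evald <- ck$history[!is.na(ck$history$val_f1), ]
  expect_equal(ck$val_f1, max(evald$val_f1))
  expect_equal(ck$best_epoch, evald$epoch[which.max(evald$val_f1)])
  # and selection never happens inside the evaluation delay
  expect_gt(ck$best_epoch, cfg$eval_delay)
  expect_true(all(is.na(ck$history$val_f1[seq_len(cfg$eval_delay)])))
})

test_that("training traces are deterministic in the master seed", {
  train <- generate_dataset(3, tiny_scene(), seed = 9)
  val <- generate_dataset(2, tiny_scene(labeled = 0), seed = 10)
  a <- train_stage1_pu(train, val, tiny_cfg())
  b <- train_stage1_pu(train, val, tiny_cfg())
  expect_identical(a$history, b$history)
  expect_identical(a$model$weights, b$model$weights)
})

test_that("stage-2 refinement returns at least its initialization", {
  train <- generate_dataset(4, tiny_scene(n_objects = 3, labeled = 1),
                            seed = 11)
  val <- generate_dataset(2, tiny_scene(n_objects = 3, labeled = 0),
                          seed = 12)
  cfg <- train_config(kernel = count_map_config(5), epochs_stage1 = 12,
                      epochs_stage2 = 3, eval_delay = 2,
                      val_threshold = 3, seed = 11)
  s1 <- train_stage1_pu(train, val, cfg)
  s2 <- train_stage2_pseudo(train, val, s1, cfg)
  expect_equal(s2$stage, "stage2")
  expect_gte(s2$val_f1, s2$history$val_f1[1])  # epoch-0 = stage-1 init
  expect_gte(s2$val_f1, max(s2$history$val_f1) - 1e-12)
  # stage-2 learning rate stays 100x below stage 1 by default
  expect_equal(train_config()$lr_stage2 / train_config()$lr_stage1, 0.01)
})

test_that("annotation resampling never empties a label set", {
  for (n in 1:7)
    expect_gte(ceiling(2 / 3 * n), 1)
  pts <- data.frame(row = 1, col = 1)
  expect_equal(nrow(subsample_annotations(pts, 2 / 3)), 1)
})

test_that("divergent configurations are rejected up front", {
  expect_error(train_config(lr_stage1 = 0), "lr_stage1")
  expect_error(train_config(eval_delay = 100, epochs_stage1 = 50))
  train <- generate_dataset(2, tiny_scene(labeled = 0), seed = 13)
  val <- generate_dataset(1, tiny_scene(labeled = 0), seed = 14)
  expect_error(train_stage1_pu(train, val, tiny_cfg()), "annotation")
})
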