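# Training loop contracts: loss structure, determinism, checkpointing.

test_that("hyperparameter defaults follow the published recipe", {
  hp <- hyperparams()
  expect_equal(hp$lr0, 0.001)
  expect_equal(hp$momentum, 0.937)
  expect_equal(hp$weight_decay, 0.0005)
  expect_equal(hp$batch, 16L)
  expect_equal(hp$img, 640L)
  expect_equal(hp$save_period, 10L)
  expect_error(hyperparams(optimizer = "adam"), "sgd")
  expect_error(hyperparams(epochs = -1L))
})

test_that("a batch without ground truth has exactly zero box and dfl loss", {
  m <- tiny_model()
  fr <- forward_model(m, rand_map(2, 3, 64, 64), train = TRUE)
  empty <- data.frame(class_id = integer(), x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric())
  ls <- compute_loss(fr$levels, list(empty, empty), 16L, m$strides)
  expect_identical(ls$box, 0)
  expect_identical(ls$dfl, 0)
  expect_gt(ls$cls, 0)
  expect_true(is.finite(ls$total))
  expect_error(compute_loss(fr$levels, list(), 16L, m$strides), "empty batch")
})

test_that("loss is finite at random initialization with dense targets", {
  m <- tiny_model()
  fr <- forward_model(m, rand_map(1, 3, 64, 64), train = TRUE)
  gt <- data.frame(class_id = c(0L, 1L, 2L),
                   x1 = c(2, 20, 40), y1 = c(2, 20, 40),
                   x2 = c(18, 38, 60), y2 = c(18, 38, 60))
  ls <- compute_loss(fr$levels, list(gt), 16L, m$strides)
  expect_true(is.finite(ls$total))
  expect_gte(ls$total, 0)
  expect_gt(ls$box, 0)
})

test_that("zero epochs leave the weights untouched with an empty history", {
  m <- tiny_model()
  ds <- list(generate_scene(scene_spec(width = 64L, height = 64L,
                                       counts = c(flower = 0L, green_fruit = 1L,
                                                  orange_fruit = 1L),
                                       object_scale = 0.15, seed = 2L)))
  r <- train(m, ds, hyperparams(epochs = 0L, img = 64L))
  expect_equal(nrow(r$history), 0L)
  expect_identical(r$model$layers[[1]]$m$sub$conv$p$w,
                   m$layers[[1]]$m$sub$conv$p$w)
})

test_that("training is deterministic under a fixed seed", {
  sp <- scene_spec(width = 64L, height = 64L,
                   counts = c(flower = 0L, green_fruit = 1L, orange_fruit = 1L),
                   occlusion_fraction = 0, object_scale = 0.15, seed = 40L)
  ds <- synth_dataset(4, sp)
  hp <- hyperparams(lr0 = 0.01, batch = 2L, img = 64L, epochs = 2L, seed = 5L)
  set.seed(1); m1 <- build_model(model_config("yolov8_rl", num_classes = 3L,
                                              width_multiple = 0.0625,
                                              input_size = 64L))
  r1 <- train(m1, ds, hp)
  set.seed(1); m2 <- build_model(model_config("yolov8_rl", num_classes = 3L,
                                              width_multiple = 0.0625,
                                              input_size = 64L))
  r2 <- train(m2, ds, hp)
  expect_identical(r1$history$loss, r2$history$loss)
  expect_identical(r1$model$head$sub$cls$p$bias, r2$model$head$sub$cls$p$bias)
  expect_error(train(m1, list(), hp), "empty dataset")
})

test_that("an SGD step moves the weights against the gradient", {
  sp <- scene_spec(width = 64L, height = 64L,
                   counts = c(flower = 0L, green_fruit = 1L, orange_fruit = 1L),
                   occlusion_fraction = 0, object_scale = 0.15, seed = 41L)
  ds <- synth_dataset(2, sp)
  m <- tiny_model()
  r <- train(m, ds, hyperparams(lr0 = 0.01, batch = 2L, img = 64L,
                                epochs = 1L, seed = 6L))
  expect_false(identical(r$model$layers[[1]]$m$sub$conv$p$w,
                         m$layers[[1]]$m$sub$conv$p$w))
  expect_equal(nrow(r$history), 1L)
  expect_true(is.finite(r$history$loss))
})

test_that("checkpoint schedule writes periodic weights and a best model", {
  sp <- scene_spec(width = 64L, height = 64L,
                   counts = c(flower = 0L, green_fruit = 1L, orange_fruit = 1L),
                   occlusion_fraction = 0, object_scale = 0.15, seed = 42L)
  ds <- synth_dataset(2, sp)
  rd <- tempfile("run")
  r <- train(tiny_model(), ds, hyperparams(lr0 = 0.01, batch = 2L, img = 64L,
                                           epochs = 2L, seed = 7L,
                                           save_period = 1L),
             val = ds, run_dir = rd)
  expect_true(file.exists(file.path(rd, "epoch001.rds")))
  expect_true(file.exists(file.path(rd, "epoch002.rds")))
  expect_true(file.exists(file.path(rd, "best.rds")))
  expect_true(file.exists(file.path(rd, "history.csv")))
  expect_false(any(is.na(r$history$val_map50)))
  unlink(rd, recursive = TRUE)
})

test_that("counting returns per-class tallies from suppressed detections", {
  m <- tiny_model()
  sc <- generate_scene(scene_spec(width = 64L, height = 64L,
                                  counts = c(flower = 1L, green_fruit = 1L,
                                             orange_fruit = 1L),
                                  object_scale = 0.12, seed = 50L))
  cnt <- count_objects(m, sc$image, class_names = c("flower", "green", "orange"))
  expect_named(cnt, c("flower", "green", "orange"))
  expect_true(all(cnt >= 0))
})
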