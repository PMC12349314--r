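# Synthetic orchard scenes, photometric augmentation, mixup/mosaic,
# dataset splitting, YOLO label IO and tree-level count simulation.

test_that("empty scenes have empty label lists", {
  sc <- generate_scene(scene_spec(width = 64L, height = 64L,
                                  counts = c(flower = 0L, green_fruit = 0L,
                                             orange_fruit = 0L), seed = 1L))
  expect_equal(nrow(sc$labels), 0L)
  expect_equal(dim(sc$image), c(64, 64, 3))
})

test_that("unoccluded fruit scenes label every object with near-square boxes", {
  sc <- generate_scene(scene_spec(width = 320L, height = 320L,
                                  counts = c(flower = 0L, green_fruit = 0L,
                                             orange_fruit = 12L),
                                  occlusion_fraction = 0,
                                  object_scale = 0.05, seed = 7L))
  expect_equal(nrow(sc$labels), 12L)
  expect_true(all(sc$labels$class_id == 2L))
  expect_true(all(sc$labels$cx >= 0 & sc$labels$cx <= 1))
  expect_true(all(sc$labels$cy - sc$labels$h / 2 >= 0))
  expect_true(all(sc$labels$cx + sc$labels$w / 2 <= 1))
  aspect <- (sc$labels$w * 320) / (sc$labels$h * 320)
  expect_true(all(aspect >= 0.8 & aspect <= 1.25))
})

test_that("scene generation is byte-identical under the same seed", {
  sp <- small_scene_spec(seed = 11L)
  a <- generate_scene(sp)
  b <- generate_scene(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$labels, b$labels)
  c <- generate_scene(small_scene_spec(seed = 12L))
  expect_false(identical(a$image, c$image))
})

test_that("generated labels stay in bounds across seeds and occlusion levels", {
  for (seed in 1:6) {
    sp <- small_scene_spec(seed = seed, occlusion_fraction = 0.5)
    sc <- generate_scene(sp)
    lb <- sc$labels
    expect_true(all(lb$cx - lb$w / 2 >= -1e-9 & lb$cx + lb$w / 2 <= 1 + 1e-9))
    expect_true(all(lb$cy - lb$h / 2 >= -1e-9 & lb$cy + lb$h / 2 <= 1 + 1e-9))
    expect_true(all(lb$w * lb$h * 128^2 >= 8))   # minimum visible area
  }
})

test_that("box aspect ratios concentrate near one", {
  sp <- scene_spec(width = 320L, height = 320L,
                   counts = c(flower = 0L, green_fruit = 10L,
                              orange_fruit = 10L),
                   occlusion_fraction = 0.1, object_scale = 0.05, seed = 3L)
  lb <- do.call(rbind, lapply(1:6, function(i) {
    sp$seed <- 3L + i
    generate_scene(sp)$labels
  }))
  med <- median(lb$w / lb$h)
  expect_gte(med, 0.95)
  expect_lte(med, 1.05)
})

test_that("overpacked scenes fail with a packing error", {
  expect_error(generate_scene(scene_spec(width = 64L, height = 64L,
                                         counts = c(flower = 0L,
                                                    green_fruit = 200L,
                                                    orange_fruit = 200L),
                                         object_scale = 0.2, seed = 1L)),
               "packing")
})

test_that("gamma mapping matches the power-law formula", {
  img <- array(128, dim = c(4, 4, 3))
  expect_identical(photometric_augment(img, "gamma", 1), img)
  out <- photometric_augment(img, "gamma", 2)
  expect_true(all(out == 64))       # 255 * (128/255)^2 = 64.25 -> 64
  expect_error(photometric_augment(img, "gamma", 0), "param > 0")
})

test_that("equalization preserves constant images and raises global contrast", {
  flat <- array(77, dim = c(8, 8, 3))
  expect_identical(photometric_augment(flat, "equalize"), flat)
  sc <- generate_scene(small_scene_spec(seed = 4L))
  eq <- photometric_augment(sc$image, "equalize")
  expect_equal(dim(eq), dim(sc$image))
  lum <- function(x) 0.299 * x[, , 1] + 0.587 * x[, , 2] + 0.114 * x[, , 3]
  expect_gte(diff(range(lum(eq))), 0.95 * diff(range(lum(sc$image))))
})

test_that("mixup blends pixels and concatenates labels", {
  a <- generate_scene(small_scene_spec(seed = 5L))
  b <- generate_scene(small_scene_spec(seed = 6L))
  m1 <- mixup(a, b, lam = 1)
  expect_equal(m1$image, a$image)
  expect_equal(nrow(m1$labels), nrow(a$labels) + nrow(b$labels))
  m5 <- mixup(a, b, lam = 0.5)
  expect_equal(m5$image, 0.5 * a$image + 0.5 * b$image)
  ca <- structure(list(image = array(100, dim = c(8, 8, 3)),
                       labels = a$labels[0, ]), class = "crl_scene")
  cb <- structure(list(image = array(200, dim = c(8, 8, 3)),
                       labels = a$labels[0, ]), class = "crl_scene")
  expect_true(all(mixup(ca, cb, 0.5)$image == 150))
  small <- structure(list(image = array(0, dim = c(4, 4, 3)),
                          labels = a$labels[0, ]), class = "crl_scene")
  expect_error(mixup(a, small), "same size")
})

test_that("mosaic with a centred junction shifts labels by the quadrant affine", {
  sc <- generate_scene(small_scene_spec(seed = 8L))   # 128 x 128
  quad <- list(sc, sc, sc, sc)
  mo <- mosaic(quad, canvas_size = 256L, junction = c(128L, 128L))
  expect_equal(dim(mo$image), c(256, 256, 3))
  # inputs keep their size (quadrant = input size): labels are the union of
  # the four shifted copies, none dropped
  expect_equal(nrow(mo$labels), 4L * nrow(sc$labels))
  lb1 <- mo$labels[seq_len(nrow(sc$labels)), ]             # top-left quadrant
  expect_equal(lb1$cx, sc$labels$cx / 2, tolerance = 1e-9)
  expect_equal(lb1$w, sc$labels$w / 2, tolerance = 1e-9)
  lb4 <- mo$labels[3L * nrow(sc$labels) + seq_len(nrow(sc$labels)), ]
  expect_equal(lb4$cx, sc$labels$cx / 2 + 0.5, tolerance = 1e-2)
  # solid-colour inputs collapse to a solid canvas
  solid <- structure(list(image = array(42, dim = c(64, 64, 3)),
                          labels = sc$labels[0, ]), class = "crl_scene")
  ms <- mosaic(list(solid, solid, solid, solid), 128L, seed = 2L)
  expect_true(all(ms$image == 42))
  expect_equal(nrow(ms$labels), 0L)
})

test_that("mosaic labels stay inside the canvas and never multiply", {
  scs <- lapply(1:4, function(i) generate_scene(small_scene_spec(seed = 20L + i)))
  for (seed in 1:5) {
    mo <- mosaic(scs, canvas_size = 192L, seed = seed)
    expect_lte(nrow(mo$labels), sum(vapply(scs, function(s) nrow(s$labels), integer(1))))
    lb <- mo$labels
    expect_true(all(lb$cx - lb$w / 2 >= -1e-9 & lb$cx + lb$w / 2 <= 1 + 1e-9))
    expect_true(all(lb$cy - lb$h / 2 >= -1e-9 & lb$cy + lb$h / 2 <= 1 + 1e-9))
  }
})

test_that("dataset splitting apportions by largest remainder", {
  s <- split_dataset(seq_len(3250), seed = 1L)
  expect_equal(lengths(s), c(train = 2275L, val = 325L, test = 650L))
  s10 <- split_dataset(seq_len(10), seed = 2L)
  expect_equal(lengths(s10), c(train = 7L, val = 1L, test = 2L))
  expect_identical(split_dataset(letters, seed = 9L),
                   split_dataset(letters, seed = 9L))
  expect_false(identical(split_dataset(letters, seed = 9L),
                         split_dataset(letters, seed = 10L)))
  expect_length(intersect(s$train, s$val), 0L)
  expect_setequal(c(s$train, s$val, s$test), seq_len(3250))
  # sizes never deviate from the exact ratios by a full item
  for (n in c(11, 57, 100, 333)) {
    sz <- lengths(split_dataset(seq_len(n)))
    expect_true(all(abs(sz - n * c(0.7, 0.1, 0.2)) < 1))
  }
  expect_error(split_dataset(integer(0)), "empty")
})

test_that("YOLO labels round-trip through the 6-decimal text format", {
  set.seed(31)
  lb <- data.frame(class_id = sample(0:2, 100, TRUE),
                   cx = runif(100), cy = runif(100),
                   w = runif(100, 0, 0.3), h = runif(100, 0, 0.3))
  tf <- tempfile(fileext = ".txt")
  write_yolo_labels(lb, tf)
  back <- read_yolo_labels(tf)
  expect_equal(back$class_id, lb$class_id)
  for (col in c("cx", "cy", "w", "h"))
    expect_lt(max(abs(back[[col]] - lb[[col]])), 1e-6)

  writeLines(character(0), tf)
  expect_equal(nrow(read_yolo_labels(tf)), 0L)
  writeLines("0 0.5 0.5 0.1 0.1", tf)
  one <- read_yolo_labels(tf)
  expect_equal(one$class_id, 0L)
  expect_equal(one$cx, 0.5)
  writeLines(c("0 0.5 0.5 0.1 0.1", "1 0.2 oops 0.1 0.1"), tf)
  expect_error(read_yolo_labels(tf), "line 2")
  unlink(tf)
})

test_that("scenes round-trip through PNG plus label text", {
  sc <- generate_scene(small_scene_spec(seed = 12L))
  tf <- tempfile(fileext = ".png")
  save_scene(sc, tf)
  back <- load_scene(tf)
  expect_equal(back$image, sc$image, tolerance = 1e-8)
  expect_equal(back$labels$class_id, sc$labels$class_id)
  expect_lt(max(abs(back$labels$cx - sc$labels$cx)), 1e-6)
  unlink(c(tf, sub("\\.png$", ".txt", tf)))
})

test_that("tree-view simulation respects the visibility contract", {
  tv <- generate_tree_views(30, visibility = 1, sigma = 0, seed = 4L)
  expect_true(all(tv$detect == tv$actual))
  tv2 <- generate_tree_views(50, alpha = 1.44, beta = 1, sigma = 5, seed = 4L)
  expect_true(all(tv2$detect <= tv2$actual))
  expect_true(all(tv2$detect >= 40 & tv2$detect <= 90))
  expect_identical(tv2, generate_tree_views(50, alpha = 1.44, beta = 1,
                                            sigma = 5, seed = 4L))
  expect_error(generate_tree_views(10, visibility = 1.4), "visibility")
})
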