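# LSCD head behaviour, anchor-free decoding and non-maximum suppression.

test_that("lscd head emits the contracted channel counts and weight sharing", {
  set.seed(2)
  head <- citrusRL:::lscd_head(nc = 3L, ch = c(8L, 8L, 8L), reg_max = 16L,
                               h = 8L, t1 = 8L, t2 = 8L)
  x <- rand_map(1, 8, 4, 4)
  out <- lscd_forward(list(x, x, x), head)
  expect_length(out, 3L)
  expect_equal(dim(out[[1]]$reg), c(1, 64, 4, 4))
  expect_equal(dim(out[[1]]$cls), c(1, 3, 4, 4))
  # identical inputs through identical per-level widths with unit scales:
  # the shared trunk must produce identical outputs across levels, up to the
  # per-level (independently initialized) unify convs - so share the unify too
  head$sub$u2 <- head$sub$u1
  head$sub$u3 <- head$sub$u1
  out2 <- lscd_forward(list(x, x, x), head)
  expect_equal(out2[[1]]$reg, out2[[2]]$reg, tolerance = 1e-12)
  expect_equal(out2[[1]]$cls, out2[[3]]$cls, tolerance = 1e-12)
})

test_that("a zero level scale nulls that level's regression output only", {
  set.seed(3)
  head <- citrusRL:::lscd_head(nc = 2L, ch = c(8L, 8L, 8L), h = 8L,
                               t1 = 8L, t2 = 8L)
  head$sub$s2$p$s <- 0
  out <- lscd_forward(list(rand_map(1, 8, 4, 4), rand_map(1, 8, 2, 2),
                           rand_map(1, 8, 1, 1)), head)
  expect_true(all(out[[2]]$reg == 0))
  expect_false(all(out[[1]]$reg == 0))
  expect_false(all(out[[2]]$cls == 0))
})

test_that("head parameters are dominated by the shared trunk, not the levels", {
  # weight sharing: tripling the number of levels must not triple parameters
  h1 <- citrusRL:::lscd_head(nc = 3L, ch = c(16L), strides = c(8L),
                             h = 16L, t1 = 16L, t2 = 16L)
  h3 <- citrusRL:::lscd_head(nc = 3L, ch = c(16L, 16L, 16L),
                             h = 16L, t1 = 16L, t2 = 16L)
  p1 <- citrusRL:::module_param_count(h1)
  p3 <- citrusRL:::module_param_count(h3)
  expect_lt(p3, 1.5 * p1)
})

test_that("box decode follows the expectation decode, hand-checked", {
  reg_max <- 16L
  # one cell at grid (0,0), stride 8; one-hot distance bins at l=t=r=b=0.5
  # expectation over bins {0..15} with all mass between bins 0 and 1
  reg <- array(-30, dim = c(1, 4 * reg_max, 1, 1))
  for (side in 0:3) {
    reg[1, side * reg_max + 1, 1, 1] <- 10 + log(0.5)  # bin 0
    reg[1, side * reg_max + 2, 1, 1] <- 10 + log(0.5)  # bin 1 -> E = 0.5
  }
  cls <- array(5, dim = c(1, 1, 1, 1))
  dets <- decode_boxes(list(list(reg = reg, cls = cls)), reg_max,
                       conf_threshold = 0.25, strides = 8L,
                       img_size = c(8, 8))
  expect_equal(nrow(dets), 1L)
  expect_equal(as.numeric(dets[1, c("x1", "y1", "x2", "y2")]), c(0, 0, 8, 8),
               tolerance = 1e-6)
})

test_that("decode drops everything at impossible confidence", {
  reg_max <- 16L
  reg <- array(rnorm(4 * reg_max * 4), dim = c(1, 4 * reg_max, 2, 2))
  cls <- array(-1e6, dim = c(1, 3, 2, 2))
  out <- decode_boxes(list(list(reg = reg, cls = cls)), reg_max, 0.25,
                      strides = 8L)
  expect_equal(nrow(out), 0L)
  cls2 <- array(3, dim = c(1, 3, 2, 2))
  out2 <- decode_boxes(list(list(reg = reg, cls = cls2)), reg_max, 1.0,
                       strides = 8L)
  expect_equal(nrow(out2), 0L)   # a logistic score never reaches exactly 1
})

test_that("decoded boxes are clipped and scores thresholded", {
  m <- tiny_model()
  fr <- forward_model(m, rand_map(1, 3, 64, 64))
  dets <- decode_boxes(fr$levels, 16L, conf_threshold = 0.01,
                       img_size = c(64, 64))
  if (nrow(dets) > 0) {
    expect_true(all(dets$score >= 0.01))
    expect_true(all(dets$x1 >= 0 & dets$x2 <= 64))
    expect_true(all(dets$y1 >= 0 & dets$y2 <= 64))
    expect_true(all(dets$x1 < dets$x2 & dets$y1 < dets$y2))
  }
  # decoded plus suppressed detections never exceed the raw cell count
  total_cells <- sum(vapply(fr$levels, function(l) prod(dim(l$reg)[3:4]),
                            numeric(1)))
  kept <- nms(dets, 0.45)
  expect_lte(nrow(kept), total_cells * m$head$cfg$nc)
})

test_that("nms keeps hand-checked configurations", {
  one <- data.frame(class_id = 0L, score = 0.9, x1 = 0, y1 = 0, x2 = 10, y2 = 10)
  expect_equal(nrow(nms(one, 0.5)), 1L)

  dup <- rbind(one, transform(one, score = 0.8))
  expect_equal(nrow(nms(dup, 0.5)), 1L)
  expect_equal(nms(dup, 0.5)$score, 0.9)

  # IoU((0,0,10,10), (0,5,10,15)) = 50/150 = 1/3 < 0.5: both survive
  pair <- data.frame(class_id = 0L, score = c(0.9, 0.8),
                     x1 = c(0, 0), y1 = c(0, 5), x2 = c(10, 10), y2 = c(10, 15))
  expect_equal(as.numeric(box_iou(c(0, 0, 10, 10), c(0, 5, 10, 15))), 1 / 3)
  expect_equal(nrow(nms(pair, 0.5)), 2L)
  # ... and exactly at the threshold both are kept (strict suppression)
  expect_equal(nrow(nms(pair, 1 / 3)), 2L)
  expect_equal(nrow(nms(pair, 0.33)), 1L)

  # different classes never suppress each other
  cross <- transform(dup, class_id = c(0L, 1L))
  expect_equal(nrow(nms(cross, 0.5)), 2L)
})

test_that("nms output is invariant to the order of the input detections", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 20L
    base <- data.frame(class_id = sample(0:1, n, TRUE),
                       score = round(runif(n), 2),
                       x1 = runif(n, 0, 50), y1 = runif(n, 0, 50))
    base$x2 <- base$x1 + runif(n, 5, 30)
    base$y2 <- base$y1 + runif(n, 5, 30)
    a <- nms(base, 0.45)
    b <- nms(base[sample(n), ], 0.45)
    key <- function(d) paste(d$class_id, d$score, round(d$x1, 9), round(d$y1, 9),
                             round(d$x2, 9), round(d$y2, 9))
    expect_setequal(key(a), key(b))
  }
})
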