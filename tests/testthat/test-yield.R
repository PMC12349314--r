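# Count-to-yield regression and error-rate accounting against the published
# field-count tables.

test_that("packaged count tables have the published shapes and ranges", {
  tabs <- citrus_count_tables()
  expect_equal(nrow(tabs$green_fit), 10L)
  expect_equal(range(tabs$green_fit$detect), c(38, 86))
  expect_equal(nrow(tabs$ripe_fit), 10L)
  expect_equal(range(tabs$ripe_fit$actual), c(56, 135))
  expect_equal(nrow(tabs$green_valid), 6L)
  expect_equal(nrow(tabs$ripe_valid), 6L)
  expect_true(all(tabs$green_fit$detect <= tabs$green_fit$actual))
})

test_that("an exact linear relation is recovered with unit R2", {
  pairs <- data.frame(detect = 1:5, actual = 2 * (1:5) + 1)
  fit <- fit_polynomial(pairs, 1L)
  expect_equal(fit$coefficients, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$r2_plain, 1)
  expect_error(fit_polynomial(data.frame(detect = rep(3, 5),
                                         actual = 1:5), 1L), "rank")
  expect_error(fit_polynomial(pairs[1:2, ], 1L), "at least")
})

test_that("green-stage linear fit reproduces the published coefficients", {
  fit <- stage_yield_fit("green")
  expect_equal(fit$degree, 1L)
  expect_equal(round(fit$coefficients[2], 5), 1.43885)
  expect_equal(round(fit$coefficients[1], 5), 0.89779)
  expect_equal(round(fit$r2_plain, 5), 0.91992)
})

test_that("ripening-stage quadratic fit reproduces the published coefficients", {
  fit <- stage_yield_fit("ripe")
  expect_equal(fit$degree, 2L)
  expect_equal(round(fit$coefficients[1], 5), 39.22014)
  expect_equal(round(fit$coefficients[2], 5), 0.04029)
  expect_equal(round(fit$coefficients[3], 5), 0.01100)
  # the published determination coefficient for this stage is the adjusted one
  expect_equal(round(fit$r2_adjusted, 5), 0.95639)
  expect_gt(fit$r2_plain, fit$r2_adjusted)
})

test_that("determination coefficient follows both definitions", {
  y <- c(1, 2, 3, 4, 6)
  expect_equal(coefficient_of_determination(y, y, 1), 1)
  yh <- c(1.1, 2.1, 2.8, 4.2, 5.8)
  r2 <- 1 - sum((y - yh)^2) / sum((y - mean(y))^2)
  expect_equal(coefficient_of_determination(y, yh, 1), r2)
  adj <- 1 - (sum((y - yh)^2) / 3) / (sum((y - mean(y))^2) / 4)
  expect_equal(coefficient_of_determination(y, yh, 1, adjusted = TRUE), adj)
  expect_error(coefficient_of_determination(rep(2, 5), rep(2, 5), 1),
               "zero total variance")
})

test_that("degree-1 plain R2 equals the squared sample correlation", {
  set.seed(77)
  for (rep in 1:20) {
    x <- sample(30:90, 12)
    y <- 1.3 * x + rnorm(12, 0, 8)
    fit <- fit_polynomial(data.frame(detect = x, actual = y), 1L)
    expect_equal(fit$r2_plain, cor(x, y)^2, tolerance = 1e-10)
  }
})

test_that("fit residuals are orthogonal to the design columns", {
  set.seed(78)
  tabs <- citrus_count_tables()
  for (deg in 1:2) {
    pairs <- tabs$ripe_fit
    fit <- fit_polynomial(pairs, deg)
    pred <- outer(pairs$detect, 0:deg, "^") %*% fit$coefficients
    res <- pairs$actual - pred
    for (p in 0:deg) {
      col <- pairs$detect^p
      expect_lt(abs(sum(res * col)),
                1e-6 * sqrt(sum(res^2)) * sqrt(sum(col^2)) + 1e-8)
    }
  }
})

test_that("integer predictions reproduce the self-consistent published rows", {
  green <- stage_yield_fit("green")
  ripe <- stage_yield_fit("ripe")
  expect_equal(predict_count(green, 43), 63L)   # 1.43885*43 + 0.89779 = 62.77
  expect_equal(predict_count(green, 42), 61L)
  expect_equal(predict_count(green, 0), 1L)     # round(0.89779)
  expect_equal(predict_count(ripe, c(44, 46, 37, 77, 67)),
               c(62L, 64L, 56L, 108L, 91L))
  # monotone over the observed count range for both stage fits
  for (fit in list(green, ripe))
    expect_true(all(diff(predict_count(fit, 0:150)) >= 0))
})

test_that("error accounting truncates rates as in the published tables", {
  tabs <- citrus_count_tables()
  ev <- evaluate_predictions(tabs$ripe_valid)
  expect_equal(ev$table$E1, c(19, 26, 22, 17, 29, 23))
  expect_equal(ev$table$E2, c(1, 8, 3, 1, 2, 1))
  expect_equal(ev$table$error_rate, c(1.5, 11.1, 5.0, 1.8, 1.8, 1.1))
  expect_equal(ev$mean_error_rate, 3.71)
  # a perfect prediction column zeroes E2 and the mean rate
  perfect <- transform(tabs$ripe_valid, predicted = actual)
  evp <- evaluate_predictions(perfect)
  expect_true(all(evp$table$E2 == 0))
  expect_equal(evp$mean_error_rate, 0)
  expect_error(evaluate_predictions(transform(tabs$ripe_valid,
                                              actual = 0)), "positive")
})

test_that("tree-view simulation supports slope recovery by the linear fit", {
  tv <- generate_tree_views(50, alpha = 1.44, beta = 1, sigma = 5, seed = 123L)
  fit <- fit_polynomial(tv, 1L)
  expect_lt(abs(fit$coefficients[2] - 1.44) / 1.44, 0.1)
  expect_gt(fit$r2_plain, 0.8)
})
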