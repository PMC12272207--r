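test_that("feature selection splits by sign and screens by p-value", {
  set.seed(1)
  n <- 100
  X <- matrix(stats::rnorm(n * 20), n, 20)
  y <- X[, 3] + stats::rnorm(n, 0, 0.2)   # strong positive feature
  X[, 7] <- -y + stats::rnorm(n, 0, 0.2)  # strong negative feature
  X[, 12] <- 5                            # constant: never selected
  masks <- cpm_select_features(X, y)
  expect_true(masks$positive[3])
  expect_true(masks$negative[7])
  expect_false(masks$positive[12] || masks$negative[12])
  expect_equal(masks$n_excluded, 1)
  expect_false(any(masks$positive & masks$negative))
})

test_that("null features are selected at about the nominal rate", {
  set.seed(2)
  rates <- vapply(1:200, function(r) {
    X <- matrix(stats::rnorm(60 * 50), 60, 50)
    y <- stats::rnorm(60)
    m <- cpm_select_features(X, y, p_threshold = 0.01)
    mean(m$positive | m$negative)
  }, numeric(1))
  expect_equal(mean(rates), 0.01, tolerance = 0.005)
})

test_that("summary scores follow the positive-minus-negative convention", {
  X <- cbind(a = c(1, 2, 3), b = c(10, 20, 30), c = c(5, 5, 5))
  masks <- list(positive = c(TRUE, FALSE, FALSE),
                negative = c(FALSE, TRUE, FALSE))
  expect_equal(cpm_summarize(X, masks, "positive"), c(1, 2, 3))
  expect_equal(cpm_summarize(X, masks), c(1, 2, 3) - c(10, 20, 30))
  # equal pos and neg features cancel
  masks2 <- list(positive = c(TRUE, FALSE, FALSE),
                 negative = c(TRUE, FALSE, FALSE))
  X2 <- X; X2[, 2] <- X2[, 1]
  expect_equal(cpm_summarize(X2, list(positive = c(TRUE, FALSE, FALSE),
                                      negative = c(FALSE, TRUE, FALSE))),
               rep(0, 3))
  empty <- list(positive = rep(FALSE, 3), negative = rep(FALSE, 3))
  expect_error(cpm_summarize(X, empty), "no features selected")
})

test_that("fold streams are deterministic and partition the subjects", {
  f1 <- cpm_folds(53, k = 10, n_repeats = 5, seed = 7)
  f2 <- cpm_folds(53, k = 10, n_repeats = 5, seed = 7)
  expect_identical(f1, f2)
  expect_false(identical(f1, cpm_folds(53, 10, 5, seed = 8)))
  for (r in 1:5) {
    expect_setequal(unique(f1[r, ]), 1:10)
    expect_true(all(table(f1[r, ]) >= floor(53 / 10)))
  }
})

test_that("noiseless linear phenotypes are recovered almost perfectly", {
  set.seed(3)
  X <- matrix(stats::rnorm(80 * 10), 80, 10)
  y <- 2 * X[, 4] + 1
  res <- cpm_cross_validate(X, y, k = 10, n_repeats = 3, seed = 1)
  expect_true(all(res$performance > 0.99))
  expect_equal(dim(res$predictions), c(3, 80))
  expect_false(anyNA(res$predictions))
})

test_that("null phenotypes give near-zero mean performance", {
  set.seed(4)
  X <- matrix(stats::rnorm(200 * 40), 200, 40)
  y <- stats::rnorm(200)
  res <- suppressMessages(
    cpm_cross_validate(X, y, k = 10, n_repeats = 30, seed = 2))
  expect_lt(abs(mean(res$performance)), 0.1)
})

test_that("feature selection never leaks the held-out fold", {
  set.seed(5)
  X <- matrix(stats::rnorm(60 * 30), 60, 30)
  y <- X[, 1] + stats::rnorm(60, 0, 0.5)
  folds <- cpm_folds(60, k = 10, n_repeats = 1, seed = 11)
  test_subjects <- which(folds[1, ] == 1)
  y2 <- y
  y2[test_subjects] <- sample(y[test_subjects])  # perturb held-out fold only
  r1 <- suppressMessages(cpm_cross_validate(X, y, 10, 1, seed = 11))
  r2 <- suppressMessages(cpm_cross_validate(X, y2, 10, 1, seed = 11))
  expect_identical(r1$folds, r2$folds)
  expect_equal(r1$predictions[1, test_subjects],
               r2$predictions[1, test_subjects])
})

test_that("replaying a seed reproduces predictions exactly", {
  set.seed(6)
  X <- matrix(stats::rnorm(70 * 25), 70, 25)
  y <- X[, 2] + stats::rnorm(70)
  r1 <- suppressMessages(cpm_cross_validate(X, y, 10, 4, seed = 31))
  r2 <- suppressMessages(cpm_cross_validate(X, y, 10, 4, seed = 31))
  expect_identical(r1$predictions, r2$predictions)
  expect_identical(r1$performance, r2$performance)
})

test_that("paired model comparison counts repeat-wise wins", {
  set.seed(7)
  X <- matrix(stats::rnorm(60 * 10), 60, 10)
  y <- X[, 1] + stats::rnorm(60, 0, 0.3)
  a <- suppressMessages(cpm_cross_validate(X, y, 10, 8, seed = 3))
  b <- suppressMessages(cpm_cross_validate(X, y, 10, 8, seed = 3))
  expect_equal(cpm_compare(a, b), mean(a$performance <= b$performance))
  # identical models tie on every repeat -> p = 1 under <=
  expect_equal(cpm_compare(a, b), 1)

  # dominant model a: compare against noise features
  Xn <- matrix(stats::rnorm(60 * 10), 60, 10)
  d <- suppressMessages(cpm_cross_validate(Xn, y, 10, 8, seed = 3))
  expect_equal(cpm_compare(a, d), mean(a$performance <= d$performance))
  expect_lt(cpm_compare(a, d), 0.5)

  mismatch <- suppressMessages(cpm_cross_validate(X, y, 10, 8, seed = 4))
  expect_error(cpm_compare(a, mismatch), "fold splits differ")
})
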