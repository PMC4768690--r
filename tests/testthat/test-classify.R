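test_that("the 1-D two-class fit recovers means and the midpoint boundary", {
  x <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  g <- c("a", "a", "b", "b")
  fit <- stftda(x, g)
  expect_equal(as.numeric(fit$means), c(0.05, 10.05))
  expect_equal(as.character(predict(fit, matrix(4.9))), "a")
  expect_equal(as.character(predict(fit, matrix(5.2))), "b")
})

test_that("exact score ties resolve to the earlier class in class order", {
  # means -9 and +9: every term of the two scores at x = 0 is the same
  # floating-point number, so the tie is exact
  x <- matrix(c(-10, -8, 8, 10), ncol = 1)
  fit <- stftda(x, c("first", "first", "second", "second"))
  sc <- predict(fit, matrix(0), type = "scores")
  expect_equal(unname(sc[1, 1]), unname(sc[1, 2]))
  expect_equal(as.character(predict(fit, matrix(0))), "first")
  # the spec's asymmetric variant: the midpoint classifies deterministically
  fit2 <- stftda(matrix(c(0, 0.1, 10, 10.1), ncol = 1),
                 c("first", "first", "second", "second"))
  expect_true(as.character(predict(fit2, matrix(5.05))) %in%
                c("first", "second"))
  expect_equal(as.character(predict(fit2, matrix(5.04))), "first")
  expect_equal(as.character(predict(fit2, matrix(5.06))), "second")
})

test_that("discriminant scores match the elimination-based closed-form oracle", {
  set.seed(31)
  for (rep_i in 1:5) {
    x <- matrix(rnorm(30 * 5), 30, 5)
    g <- rep(c("a", "b", "c"), each = 10)
    fit <- stftda(x, g)
    xt <- matrix(rnorm(8 * 5), 8, 5)
    got <- predict(fit, xt, type = "scores")
    want <- oracle_da_scores(xt, fit$means, fit$cov, fit$priors)
    expect_lt(max(abs(got - want)), 1e-9)
    # predictions equal the oracle argmax everywhere
    expect_equal(as.integer(predict(fit, xt)), max.col(want, "first"))
  }
})

test_that("fits agree with an independent LDA implementation on separable data", {
  skip_if_not_installed("MASS")
  set.seed(32)
  x <- rbind(matrix(rnorm(100, 0), 50), matrix(rnorm(100, 2.5), 50))
  g <- rep(c("a", "b"), each = 50)
  fit <- stftda(x, g)
  ref <- MASS::lda(x, grouping = g, prior = c(0.5, 0.5))
  xt <- rbind(matrix(rnorm(60, 0), 30), matrix(rnorm(60, 2.5), 30))
  expect_equal(as.character(predict(fit, xt)),
               as.character(predict(ref, xt)$class))
})

test_that("training-sample order does not change the model", {
  set.seed(33)
  x <- matrix(rnorm(40 * 6), 40, 6)
  g <- rep(c("a", "b"), each = 20)
  fit1 <- stftda(x, g)
  p <- sample(40)
  fit2 <- stftda(x[p, ], g[p])
  expect_equal(fit1$means, fit2$means, tolerance = 1e-12)
  expect_equal(fit1$cov, fit2$cov, tolerance = 1e-12)
})

test_that("predictions are equivariant under invertible affine feature maps", {
  set.seed(34)
  x <- rbind(matrix(rnorm(80, 0), 20), matrix(rnorm(80, 1), 20))
  g <- rep(c("a", "b"), each = 20)
  A <- matrix(rnorm(16), 4, 4) + diag(4)
  b <- rnorm(4)
  xt <- matrix(rnorm(200), 50, 4)
  fit <- stftda(x, g)
  fit2 <- stftda(sweep(x %*% A, 2, b, "+"), g)
  expect_equal(as.character(predict(fit, xt)),
               as.character(predict(fit2, sweep(xt %*% A, 2, b, "+"))))
})

test_that("identical class means give chance-level accuracy", {
  set.seed(35)
  K <- 4
  x <- matrix(rnorm(200 * 3), 200, 3)
  g <- rep(letters[1:K], each = 50)
  fit <- stftda(x, g)
  xt <- matrix(rnorm(2000 * 3), 2000, 3)
  gt <- sample(letters[1:K], 2000, replace = TRUE)
  acc <- mean(as.character(predict(fit, xt)) == gt)
  ci_half <- 2.576 * sqrt(0.25 * 0.75 / 2000)
  expect_lt(abs(acc - 1 / K), ci_half + 0.01)
})

test_that("Gaussian classes are recovered near the analytic Bayes rate", {
  set.seed(36)
  n <- 500
  mu <- c(0, 2)  # 1-D projection separation delta = 2
  x <- rbind(cbind(rnorm(n, mu[1]), rnorm(n)), cbind(rnorm(n, mu[2]), rnorm(n)))
  g <- rep(c("a", "b"), each = n)
  fit <- stftda(x, g)
  se <- 1 / sqrt(n)
  expect_lt(max(abs(fit$means[, 1] - mu)), 3 * se)
  xt <- rbind(cbind(rnorm(1000, mu[1]), rnorm(1000)),
              cbind(rnorm(1000, mu[2]), rnorm(1000)))
  gt <- rep(c("a", "b"), each = 1000)
  acc <- mean(as.character(predict(fit, xt)) == gt)
  bayes <- pnorm((mu[2] - mu[1]) / 2)  # Phi(delta/2) for equal priors
  expect_lt(abs(acc - bayes), 0.02 + 2.576 * sqrt(bayes * (1 - bayes) / 2000))
})

test_that("priors and formula interface behave as documented", {
  set.seed(37)
  df <- data.frame(f1 = c(rnorm(30), rnorm(10, 4)),
                   species = rep(c("a", "b"), c(30, 10)))
  fit_u <- stftda(species ~ ., df)
  expect_equal(fit_u$priors, c(0.5, 0.5))
  fit_e <- stftda(species ~ ., df, prior = "empirical")
  expect_equal(fit_e$priors, c(0.75, 0.25))
  expect_equal(fit_u$d, 1L)
})

test_that("degenerate training sets produce the documented errors", {
  expect_error(stftda(matrix(rnorm(6), 3), c("a", "a", "b")),
               "insufficient data")
  expect_error(stftda(matrix(rnorm(8), 4), rep("a", 4)), "2 classes")
  # zero within-class variance -> singular pooled covariance
  x <- matrix(rep(c(0, 0, 1, 1), 3), 4, 3)
  g <- c("a", "a", "b", "b")
  expect_error(stftda(x, g), "singular")
  fit <- stftda(x, g, ridge = 1e-6)
  expect_gt(fit$ridge, 0)
  expect_equal(as.character(predict(fit, matrix(1, 1, 3))), "b")
})

test_that("prediction validates the feature dimension", {
  fit <- stftda(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  expect_error(predict(fit, matrix(rnorm(9), 3, 3)), "dimension mismatch")
})

test_that("confusion matrices conserve row sums and report accuracies", {
  set.seed(38)
  truth <- sample(c("a", "b", "c"), 60, replace = TRUE)
  pred <- sample(c("a", "b", "c"), 60, replace = TRUE)
  cm <- confusion_matrix(truth, pred, classes = c("a", "b", "c"))
  expect_equal(rowSums(cm), table(factor(truth, c("a", "b", "c"))),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 60)
  all_right <- confusion_matrix(truth, truth, classes = c("a", "b", "c"))
  expect_equal(overall_accuracy(all_right), 1)
  expect_true(all(diag(as.matrix(all_right)) == rowSums(all_right)))
  expect_error(confusion_matrix(c("a", "z"), c("a", "a"), classes = c("a")),
               "outside")
})

test_that("evaluate rejects labels unknown to the model", {
  fit <- stftda(matrix(rnorm(20), 10, 2), rep(c("a", "b"), 5))
  expect_error(evaluate(fit, matrix(rnorm(4), 2, 2), c("a", "zz")),
               "unknown class")
})

test_that("JSON persistence round-trips models and predictions", {
  set.seed(39)
  x <- matrix(rnorm(60 * 4), 60, 4)
  g <- rep(c("a", "b", "c"), each = 20)
  fit <- stftda(x, g)
  path <- tempfile(fileext = ".json")
  write_stftda(fit, path, config = list(window = "gaussian"))
  fit2 <- read_stftda(path)
  expect_equal(fit2$classes, fit$classes)
  expect_equal(unname(fit2$means), unname(fit$means), tolerance = 1e-12)
  xt <- matrix(rnorm(40), 10, 4)
  expect_equal(predict(fit2, xt, type = "scores"),
               predict(fit, xt, type = "scores"), tolerance = 1e-10)
  unlink(path)
})

test_that("the seeded splitter is deterministic with disjoint balanced splits", {
  labels <- rep(c("a", "b", "c"), each = 30)
  s1 <- train_test_split(labels, 18, 10, seed = 4)
  s2 <- train_test_split(labels, 18, 10, seed = 4)
  expect_identical(s1, s2)
  expect_length(s1$train, 54)
  expect_length(s1$test, 30)
  expect_length(intersect(s1$train, s1$test), 0)
  expect_equal(as.numeric(table(labels[s1$test])), rep(10, 3))
  expect_error(train_test_split(labels, 25, 10, seed = 1), "need")
})
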