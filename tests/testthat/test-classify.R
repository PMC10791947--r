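test_that("max-correlation decision values equal brute-force Pearson correlations", {
  set.seed(5)
  y <- rep(c("w", "x", "y", "z"), each = 6)
  train <- matrix(rnorm(24 * 8), nrow = 24)
  test <- matrix(rnorm(5 * 8), nrow = 5)
  rec <- max_correlation_predict(train, y, test)
  # oracle: prototypes and cor() from the definition
  for (cls in c("w", "x", "y", "z")) {
    proto <- colMeans(train[y == cls, , drop = FALSE])
    for (i in 1:5) {
      expect_equal(rec[[paste0("dv.", cls)]][i], cor(test[i, ], proto),
                   tolerance = 1e-12)
    }
  }
  # predicted class attains the max decision value
  dvm <- as.matrix(rec[grep("^dv\\.", names(rec))])
  expect_equal(rec$predicted_class,
               sub("^dv\\.", "", colnames(dvm)[max.col(dvm, "first")]))
})

test_that("max-correlation is invariant to positive affine maps of the test vector", {
  set.seed(6)
  y <- rep(c("a", "b", "c"), each = 5)
  train <- matrix(rnorm(15 * 6), nrow = 15)
  test <- matrix(rnorm(4 * 6), nrow = 4)
  r1 <- max_correlation_predict(train, y, test)
  r2 <- max_correlation_predict(train, y, test * 3.7 + 11)
  expect_equal(r1$predicted_class, r2$predicted_class)
  expect_equal(as.matrix(r1[grep("^dv", names(r1))]),
               as.matrix(r2[grep("^dv", names(r2))]), tolerance = 1e-12)

  # a test vector equal to a (non-constant) prototype gets dv exactly 1
  proto_a <- colMeans(train[y == "a", ])
  r3 <- max_correlation_predict(train, y, rbind(proto_a))
  expect_equal(r3[["dv.a"]], 1, tolerance = 1e-12)
  expect_equal(r3$predicted_class, "a")

  expect_error(max_correlation_predict(train[, 1, drop = FALSE], y,
                                       test[, 1, drop = FALSE]), "2 features")
})

test_that("Poisson naive Bayes scores equal direct log-pmf sums", {
  set.seed(7)
  y <- rep(c("p", "q"), each = 6)
  train <- matrix(rpois(12 * 4, lambda = 3), nrow = 12)
  test <- matrix(rpois(3 * 4, lambda = 3), nrow = 3)
  smoothing <- 0.5
  rec <- poisson_nb_predict(train, y, test, smoothing = smoothing)
  for (cls in c("p", "q")) {
    n_c <- sum(y == cls)
    lam <- (colSums(train[y == cls, , drop = FALSE]) + smoothing) / n_c
    for (i in 1:3) {
      oracle <- sum(dpois(test[i, ], lam, log = TRUE))
      expect_equal(rec[[paste0("dv.", cls)]][i], oracle, tolerance = 1e-9)
    }
  }
})

test_that("Poisson NB degenerate cases behave as documented", {
  # 2 classes, 1 feature, lambda-hat {1, 3}: a zero count favors the smaller rate
  train <- matrix(c(1, 1, 3, 3), ncol = 1)
  y <- c("lo", "lo", "hi", "hi")
  rec <- poisson_nb_predict(train, y, matrix(0), smoothing = 0)
  expect_equal(rec$predicted_class, "lo")
  expect_equal(rec$dv.lo, dpois(0, 1, log = TRUE))   # brute-force both pmfs
  expect_equal(rec$dv.hi, dpois(0, 3, log = TRUE))

  # a feature with identical rates across classes never changes the decision
  set.seed(8)
  y2 <- rep(c("a", "b"), each = 5)
  tr <- matrix(rpois(10 * 3, 4), nrow = 10)
  te <- matrix(rpois(6 * 3, 4), nrow = 6)
  r1 <- poisson_nb_predict(tr, y2, te)
  tr2 <- cbind(tr, 3)   # constant training counts -> identical lambda
  te2 <- cbind(te, rpois(6, 3))
  r2 <- poisson_nb_predict(tr2, y2, te2)
  expect_equal(r1$predicted_class, r2$predicted_class)

  expect_error(poisson_nb_predict(-train, y, matrix(0)), "negative")
  expect_error(poisson_nb_predict(train + 0.25, y, matrix(0)), "non-integer")
  expect_silent(poisson_nb_predict(train + 0.25, y, matrix(0),
                                   allow_rounding = TRUE))
  zero_class <- matrix(c(0, 0, 1, 2), ncol = 1)
  expect_error(poisson_nb_predict(zero_class, y, matrix(1), smoothing = 0),
               "smoothing")
})

test_that("classifier invariances: training order, duplication, separability", {
  set.seed(9)
  y <- rep(c("a", "b"), each = 6)
  train <- matrix(rpois(12 * 5, 3), nrow = 12)
  test <- matrix(rpois(4 * 5, 3), nrow = 4)
  perm <- sample(12)
  for (fn in list(max_correlation_predict, poisson_nb_predict)) {
    r1 <- fn(train, y, test)
    r2 <- fn(train[perm, ], y[perm], test)
    dv1 <- as.matrix(r1[grep("^dv", names(r1))])
    dv2 <- as.matrix(r2[grep("^dv", names(r2))])
    expect_equal(dv1[, sort(colnames(dv1))], dv2[, sort(colnames(dv2))],
                 tolerance = 1e-12)
  }
  # duplicating every training point leaves prototypes unchanged
  r1 <- max_correlation_predict(train, y, test)
  r2 <- max_correlation_predict(rbind(train, train), c(y, y), test)
  expect_equal(as.matrix(r1[grep("^dv", names(r1))]),
               as.matrix(r2[grep("^dv", names(r2))]), tolerance = 1e-12)

  # linearly separated 2-feature fixture: both classifiers are perfect on train
  sep_train <- rbind(matrix(c(8, 1), 6, 2, byrow = TRUE),
                     matrix(c(1, 8), 6, 2, byrow = TRUE)) +
    matrix(rpois(24, 1), 12, 2)
  ys <- rep(c("hi", "lo"), each = 6)
  expect_equal(max_correlation_predict(sep_train, ys, sep_train)$predicted_class, ys)
  expect_equal(poisson_nb_predict(sep_train, ys, sep_train)$predicted_class, ys)
})

test_that("tie-breaking is uniform over the argmax set and flagged", {
  # all-zero features: every class ties; uniform choice keeps chance at 1/C
  train <- matrix(0, 12, 3)
  y <- rep(c("a", "b", "c", "d"), each = 3)
  set.seed(10)
  rec <- max_correlation_predict(train, y, matrix(0, 2000, 3))
  expect_true(all(rec$tie_flag))
  frac <- table(rec$predicted_class) / nrow(rec)
  expect_true(all(abs(frac - 0.25) < 3 * sqrt(0.25 * 0.75 / 2000)))
})
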