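#' Classifiers
#'
#' Classifiers learn from a labeled training set and emit, for every
#' test point, one real-valued decision value per training class (higher
#' = more confident); the predicted class attains the maximum decision
#' value.  Ties among equal maxima are broken by a uniform random draw
#' from the tied set (flagged in the output): deterministic first-index
#' tie-breaking would bias accuracy away from the 1/C chance level on
#' degenerate bins (e.g. all-silent baseline activity), which the
#' chance-level diagnostics rely on.
#'
#' * `cl_max_correlation()` — maximum correlation coefficient
#'   classifier: each class's prototype is the mean of its training
#'   vectors, and the decision value is the Pearson correlation between
#'   the test vector and the prototype across features.  Pairs where
#'   either vector has zero variance get decision value 0.  Requires at
#'   least 2 features.
#' * `cl_poisson_naive_bayes(smoothing)` — models each feature of each
#'   class as an independent Poisson spike count with rate
#'   `lambda_cf = (sum of class c's training counts of feature f +
#'   smoothing) / n_c`; the decision value is the total log likelihood
#'   `sum_f x_f log(lambda_cf) - lambda_cf - log(x_f!)` under equal
#'   class priors.  Requires nonnegative integer counts (bin with
#'   `aggregate = "sum"`); set `allow_rounding = TRUE` to acknowledge
#'   rounding of non-integer input.  The default `smoothing = 0.5`
#'   keeps every rate positive for silent neurons.
#' * `cl_svm()` — optional thin adapter around \pkg{e1071}'s support
#'   vector machine with one-vs-rest decision values; available only
#'   when \pkg{e1071} is installed.
#'
#' @param x reserved for pipe-style construction; leave unset when
#'   building the object directly.
#' @param smoothing additive smoothing constant for Poisson rates
#'   (default 0.5; must be > 0 unless every class x feature has spikes).
#' @param allow_rounding accept non-integer counts by rounding them.
#' @param ... for `cl_svm`, options passed to `e1071::svm()`.
#' @return a `decoding_classifier` object.
#' @name classifiers
NULL

#' @rdname classifiers
#' @export
cl_max_correlation <- function(x = NULL) {
  cl <- structure(list(type = "max_correlation"),
                  class = c("cl_max_correlation", "decoding_classifier"))
  maybe_pipe(x, cl)
}

#' @rdname classifiers
#' @export
cl_poisson_naive_bayes <- function(x = NULL, smoothing = 0.5, allow_rounding = FALSE) {
  stopifnot(smoothing >= 0)
  cl <- structure(list(type = "poisson_naive_bayes", smoothing = smoothing,
                       allow_rounding = allow_rounding),
                  class = c("cl_poisson_naive_bayes", "decoding_classifier"))
  maybe_pipe(x, cl)
}

#' @rdname classifiers
#' @export
cl_svm <- function(x = NULL, ...) {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop_pd("cl_svm requires the e1071 package, which is not installed; ",
            "use cl_max_correlation() or cl_poisson_naive_bayes() instead")
  }
  cl <- structure(list(type = "svm", options = list(...)),
                  class = c("cl_svm", "decoding_classifier"))
  maybe_pipe(x, cl)
}

cl_train <- function(cl, train, labels) UseMethod("cl_train")

#' @export
cl_train.cl_max_correlation <- function(cl, train, labels) {
  if (ncol(train) < 2) {
    stop_pd("cl_max_correlation needs at least 2 features: Pearson correlation ",
            "across features is undefined for a single feature")
  }
  labels <- as.character(labels)
  classes <- unique(labels)
  fac <- factor(labels, levels = classes)
  protos <- rowsum(train, fac) / as.vector(table(fac))
  structure(list(classes = classes, prototypes = protos),
            class = "model_max_correlation")
}

#' @export
cl_train.cl_poisson_naive_bayes <- function(cl, train, labels) {
  train <- check_counts(train, cl$allow_rounding, "training")
  labels <- as.character(labels)
  classes <- unique(labels)
  fac <- factor(labels, levels = classes)
  n_c <- as.vector(table(fac))
  lambda <- (rowsum(train, fac) + cl$smoothing) / n_c
  if (any(lambda <= 0)) {
    stop_pd("cl_poisson_naive_bayes: a class has an all-zero training count with ",
            "smoothing = 0; use smoothing > 0")
  }
  structure(list(classes = classes, lambda = lambda,
                 allow_rounding = cl$allow_rounding),
            class = "model_poisson_nb")
}

#' @export
cl_train.cl_svm <- function(cl, train, labels) {
  fit <- do.call(e1071::svm,
                 c(list(x = train, y = factor(as.character(labels))), cl$options))
  structure(list(classes = levels(fit$fitted), fit = fit), class = "model_svm")
}

cl_decision_values <- function(model, test) UseMethod("cl_decision_values")

#' @export
cl_decision_values.model_max_correlation <- function(model, test) {
  a <- test - rowMeans(test)
  b <- model$prototypes - rowMeans(model$prototypes)
  num <- a %*% t(b)
  den <- outer(sqrt(rowSums(a^2)), sqrt(rowSums(b^2)))
  dv <- num / den
  dv[!is.finite(dv)] <- 0          # zero-variance test vector or prototype
  colnames(dv) <- model$classes
  dv
}

#' @export
cl_decision_values.model_poisson_nb <- function(model, test) {
  test <- check_counts(test, model$allow_rounding, "test")
  # dv[i, c] = sum_f x_if log(lambda_cf) - lambda_cf - log(x_if !)
  dv <- test %*% t(log(model$lambda))
  dv <- sweep(dv, 2, rowSums(model$lambda), "-")
  dv <- dv - rowSums(lgamma(test + 1))
  colnames(dv) <- model$classes
  dv
}

#' @export
cl_decision_values.model_svm <- function(model, test) {
  pred <- stats::predict(model$fit, test, decision.values = TRUE)
  one_vs_rest_from_pairwise(attr(pred, "decision.values"), model$classes)
}

# aggregate libsvm's pairwise decision values into one-vs-rest scores
one_vs_rest_from_pairwise <- function(pairwise, classes) {
  dv <- matrix(0, nrow = nrow(pairwise), ncol = length(classes),
               dimnames = list(NULL, classes))
  pairs <- strsplit(colnames(pairwise), "/", fixed = TRUE)
  for (j in seq_along(pairs)) {
    dv[, pairs[[j]][1]] <- dv[, pairs[[j]][1]] + pairwise[, j]
    dv[, pairs[[j]][2]] <- dv[, pairs[[j]][2]] - pairwise[, j]
  }
  dv
}

check_counts <- function(x, allow_rounding, what) {
  if (any(x < 0)) stop_pd("cl_poisson_naive_bayes: negative ", what, " counts")
  if (!is_wholenumber(x)) {
    if (!allow_rounding) {
      stop_pd("cl_poisson_naive_bayes models integer spike counts but the ", what,
              " data is non-integer; bin with aggregate = \"sum\" or set ",
              "allow_rounding = TRUE to acknowledge rounding")
    }
    x <- round(x)
  }
  x
}

# Turn a decision-value matrix into prediction records.  Ties among the
# maximal decision values are broken uniformly at random with the
# caller's RNG state (the cross-validator seeds a substream per
# evaluation cell, so tie-breaking is reproducible and
# scheduling-independent).
predictions_from_dv <- function(dv, actual = NULL) {
  n <- nrow(dv)
  predicted <- integer(n)
  tie <- logical(n)
  for (i in seq_len(n)) {
    mx <- max(dv[i, ])
    amax <- which(dv[i, ] == mx)
    if (length(amax) > 1) {
      tie[i] <- TRUE
      predicted[i] <- sample_exactly(amax, 1)
    } else {
      predicted[i] <- amax
    }
  }
  list(predicted = predicted, tie_flag = tie,
       actual = if (!is.null(actual)) match(as.character(actual), colnames(dv)))
}

#' One-shot classifier predictions
#'
#' Functional forms of the classifiers: train and predict in one call,
#' returning one prediction record per test row.
#'
#' @param train labeled training feature matrix (`poisson_nb_predict`:
#'   nonnegative counts).
#' @param train_labels class label per training row.
#' @param test test feature matrix (same features).
#' @param test_labels optional actual classes of the test rows.
#' @param smoothing,allow_rounding see [cl_poisson_naive_bayes()].
#' @return a data frame with columns `actual_class` (NA when
#'   `test_labels` is missing), `predicted_class`, `tie_flag`, and one
#'   decision-value column per class named `dv.<class>`.
#' @export
max_correlation_predict <- function(train, train_labels, test, test_labels = NULL) {
  model <- cl_train(cl_max_correlation(), train, train_labels)
  records_from_model(model, test, test_labels)
}

#' @rdname max_correlation_predict
#' @export
poisson_nb_predict <- function(train, train_labels, test, test_labels = NULL,
                               smoothing = 0.5, allow_rounding = FALSE) {
  model <- cl_train(cl_poisson_naive_bayes(smoothing = smoothing,
                                           allow_rounding = allow_rounding),
                    train, train_labels)
  records_from_model(model, test, test_labels)
}

records_from_model <- function(model, test, test_labels) {
  dv <- cl_decision_values(model, test)
  p <- predictions_from_dv(dv, test_labels)
  out <- data.frame(
    actual_class = if (is.null(p$actual)) NA_character_ else colnames(dv)[p$actual],
    predicted_class = colnames(dv)[p$predicted],
    tie_flag = p$tie_flag,
    stringsAsFactors = FALSE)
  dvdf <- as.data.frame(dv)
  names(dvdf) <- paste0("dv.", colnames(dv))
  cbind(out, dvdf)
}
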