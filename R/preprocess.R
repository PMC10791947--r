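#' Feature preprocessors
#'
#' Preprocessors estimate statistics on the training set only and apply
#' the resulting transformation to both the training and the test set,
#' so no information leaks from test to train.  They are supplied to the
#' cross-validator as a list and compose left-to-right in list order.
#'
#' * `fp_zscore()` — per-feature z-score normalization.  Mean and
#'   standard deviation (sample, n-1 denominator) are estimated on the
#'   training set; features with zero training sd map to 0 in both sets.
#'   This keeps high-rate neurons from dominating the population vector.
#' * `fp_select_k_features(k)` — keeps the `k` features with the largest
#'   one-way ANOVA F statistic of feature value against class label on
#'   the training set ("most selective" features), dropping all others
#'   from both sets.  Ties are broken toward the lower feature index;
#'   the surviving features keep their original relative order.
#'   Degenerate features are ranked deterministically: zero within-class
#'   variance with nonzero between-class variance scores `Inf`
#'   (perfectly selective), an all-constant feature scores 0.
#'
#' @param x reserved for pipe-style construction (see
#'   [cv_standard()]); leave unset when building the object directly.
#' @param k number of features to keep.
#' @return a `feature_preprocessor` object.
#' @name feature_preprocessors
NULL

#' @rdname feature_preprocessors
#' @export
fp_zscore <- function(x = NULL) {
  fp <- structure(list(type = "zscore"),
                  class = c("fp_zscore", "feature_preprocessor"))
  maybe_pipe(x, fp)
}

#' @rdname feature_preprocessors
#' @export
fp_select_k_features <- function(x = NULL, k) {
  if (!is.null(x) && is.numeric(x) && missing(k)) { # fp_select_k_features(50)
    k <- x
    x <- NULL
  }
  stopifnot(length(k) == 1, k >= 1)
  fp <- structure(list(type = "select_k_features", k = as.integer(k)),
                  class = c("fp_select_k_features", "feature_preprocessor"))
  maybe_pipe(x, fp)
}

fp_fit <- function(fp, train, labels) UseMethod("fp_fit")

#' @export
fp_fit.fp_zscore <- function(fp, train, labels) {
  m <- colMeans(train)
  s <- apply(train, 2, stats::sd)
  s[is.na(s)] <- 0
  structure(list(mean = m, sd = s), class = "fp_state_zscore")
}

#' @export
fp_fit.fp_select_k_features <- function(fp, train, labels) {
  if (fp$k > ncol(train)) {
    stop_pd("fp_select_k_features: k = ", fp$k, " exceeds the ",
            ncol(train), " available features")
  }
  f <- anova_f_scores(train, labels)
  ord <- order(-f, seq_along(f))       # largest F first, ties to lower index
  kept <- sort(ord[seq_len(fp$k)])     # original feature order preserved
  structure(list(k = fp$k, scores = f, kept = kept), class = "fp_state_select_k")
}

fp_apply <- function(state, x) UseMethod("fp_apply")

#' @export
fp_apply.fp_state_zscore <- function(state, x) {
  if (ncol(x) != length(state$mean)) stop_pd("feature-set mismatch between fit and apply")
  out <- sweep(x, 2, state$mean, "-")
  nz <- state$sd > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2, state$sd[nz], "/")
  out[, !nz] <- 0
  out
}

#' @export
fp_apply.fp_state_select_k <- function(state, x) {
  if (ncol(x) != length(state$scores)) stop_pd("feature-set mismatch between fit and apply")
  x[, state$kept, drop = FALSE]
}

#' Z-score train and test features with training-set statistics
#'
#' Functional form of [fp_zscore()]: `x' = (x - mean) / sd` with mean
#' and sd (sample denominator) estimated on `train` only and applied to
#' both sets; features with training sd 0 become 0 everywhere.
#'
#' @param train,test numeric matrices with identical feature columns.
#' @return list with `train`, `test`, and `state` (per-feature `mean`
#'   and `sd`).
#' @export
zscore_fit_apply <- function(train, test) {
  if (ncol(train) != ncol(test)) stop_pd("train and test have different feature sets")
  st <- fp_fit(fp_zscore(), train, labels = NULL)
  list(train = fp_apply(st, train), test = fp_apply(st, test), state = st)
}

#' Keep the k most selective features (one-way ANOVA F)
#'
#' Functional form of [fp_select_k_features()].
#'
#' @param train training feature matrix.
#' @param labels training class labels (>= 2 classes).
#' @param test test feature matrix with the same feature columns.
#' @param k number of features to keep (1..n_features).
#' @return list with `train`, `test` (restricted to the kept features,
#'   original order) and `state` (`scores`, `kept`).
#' @export
select_k_features_fit_apply <- function(train, labels, test, k) {
  if (ncol(train) != ncol(test)) stop_pd("train and test have different feature sets")
  st <- fp_fit(fp_select_k_features(k = k), train, labels)
  list(train = fp_apply(st, train), test = fp_apply(st, test), state = st)
}

#' One-way ANOVA F statistic for every feature
#'
#' F = (between-class SS / (G - 1)) / (within-class SS / (N - G)),
#' computed column-wise.  Degenerate cases: within-SS ~ 0 with
#' between-SS > 0 gives `Inf`; both ~ 0 gives 0.
#'
#' @param x observations x features matrix.
#' @param labels class label per observation; at least 2 classes, and
#'   N must exceed the number of classes.
#' @return numeric vector of F statistics, one per feature.
#' @export
anova_f_scores <- function(x, labels) {
  labels <- as.character(labels)
  g <- unique(labels)
  G <- length(g)
  N <- nrow(x)
  if (G < 2) stop_pd("feature selection needs at least 2 classes in the training set")
  if (N <= G) stop_pd("cannot compute F: no within-class degrees of freedom (N <= #classes)")
  fac <- factor(labels, levels = g)
  n_g <- as.vector(table(fac))
  grp_means <- rowsum(x, fac) / n_g
  grand <- colMeans(x)
  ssb <- colSums(n_g * sweep(grp_means, 2, grand, "-")^2)
  ssw <- colSums((x - grp_means[as.integer(fac), , drop = FALSE])^2)
  msb <- ssb / (G - 1)
  msw <- ssw / (N - G)
  # tolerance scaled to the data so exact-arithmetic zeros are detected
  tol <- 1e-12 * pmax(colMeans(x^2), 1)
  f <- msb / msw
  f[ssw <= tol & ssb > tol] <- Inf
  f[ssw <= tol & ssb <= tol] <- 0
  unname(f)
}
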