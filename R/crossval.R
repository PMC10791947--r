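# ---- pipe-style construction -------------------------------------------
# "binned.csv" |> ds_basic(...) |> fp_zscore() |> cl_max_correlation() |>
#   rm_main_results() |> cv_standard() |> run_decoding()
# Each component constructor accepts the accumulating pipeline as its
# first argument; maybe_pipe() appends the freshly built component in
# the required order datasource -> preprocessors -> classifier ->
# result metrics -> cross-validator.

new_pipeline <- function(ds) {
  structure(list(ds = ds, fps = list(), cl = NULL, rms = list()),
            class = "ndr_pipeline")
}

maybe_pipe <- function(x, component) {
  if (is.null(x)) return(component)
  if (inherits(x, "decoding_datasource")) x <- new_pipeline(x)
  if (!inherits(x, "ndr_pipeline")) {
    stop_pd("cannot pipe a ", class(component)[1], " onto an object of class ",
            class(x)[1], "; pipelines start from a datasource")
  }
  if (inherits(component, "feature_preprocessor")) {
    if (!is.null(x$cl)) {
      stop_pd("pipeline out of order: feature preprocessors must come before ",
              "the classifier")
    }
    x$fps <- c(x$fps, list(component))
  } else if (inherits(component, "decoding_classifier")) {
    if (!is.null(x$cl)) stop_pd("pipeline already has a classifier")
    if (length(x$rms) > 0) {
      stop_pd("pipeline out of order: the classifier must come before result metrics")
    }
    x$cl <- component
  } else if (inherits(component, "result_metric")) {
    if (is.null(x$cl)) {
      stop_pd("pipeline out of order: add a classifier before result metrics")
    }
    x$rms <- c(x$rms, list(component))
  } else {
    stop_pd("cannot pipe an object of class ", class(component)[1])
  }
  x
}

#' Standard cross-validator
#'
#' Orchestrates the full decoding analysis: for each of
#' `num_resample_runs` resample runs, the datasource builds fresh
#' pseudo-population split data; for each of the k cross-validation
#' folds, feature preprocessors are fitted on that fold's training data
#' at each training time bin and applied to both sets; the classifier is
#' trained at each training bin and evaluated at every test bin when
#' `run_TCD = TRUE` (a temporal cross-decoding analysis), or only at the
#' matching bin when `FALSE`.  Metrics are aggregated as fold means
#' within each run and then averaged across runs; per-run values are
#' retained for dispersion estimates.
#'
#' Parallelism is across resample runs only (each run is internally
#' sequential), and every random draw comes from a per-(seed, run)
#' substream, so results are bit-identical for any worker count.
#'
#' @param datasource a datasource ([ds_basic()]/[ds_generalization()]),
#'   or a pipeline built with the native pipe (see Examples in the
#'   README).
#' @param classifier a classifier object (see [classifiers]).
#' @param feature_preprocessors list of [feature_preprocessors], applied
#'   left-to-right (may be empty).
#' @param result_metrics list of result-metric requests; defaults to
#'   `list(rm_main_results(), rm_confusion_matrix())`.
#' @param num_resample_runs number of resample runs (default 50).
#' @param run_TCD evaluate every (train bin, test bin) pair (default
#'   `TRUE`); `FALSE` restricts to train bin == test bin.
#' @param num_parallel_workers forked workers for the run loop; default
#'   half the logical processors (1 where forking is unavailable).
#' @param seed master seed governing all sampling and tie-breaking; if
#'   `NULL` one is drawn from the session RNG (and recorded in the
#'   results so the analysis is re-derivable).
#' @param keep_predictions retain the raw per-record prediction set in
#'   the returned object (memory-hungry for large TCD grids; default
#'   `FALSE`).
#' @return a `cv_standard` specification; pass it to [run_decoding()].
#' @export
cv_standard <- function(datasource = NULL, classifier = NULL,
                        feature_preprocessors = list(),
                        result_metrics = NULL,
                        num_resample_runs = 50, run_TCD = TRUE,
                        num_parallel_workers = NULL, seed = NULL,
                        keep_predictions = FALSE) {
  if (inherits(datasource, "ndr_pipeline")) {
    pipe <- datasource
    datasource <- pipe$ds
    classifier <- classifier %||% pipe$cl
    if (length(feature_preprocessors) == 0) feature_preprocessors <- pipe$fps
    result_metrics <- result_metrics %||% pipe$rms
  }
  if (is.null(datasource) || !inherits(datasource, "decoding_datasource")) {
    stop_pd("cv_standard needs a datasource (ds_basic or ds_generalization)")
  }
  if (is.null(classifier) || !inherits(classifier, "decoding_classifier")) {
    stop_pd("cv_standard needs a classifier")
  }
  result_metrics <- result_metrics %||% list(rm_main_results(), rm_confusion_matrix())
  if (length(result_metrics) == 0) {
    stop_pd("cv_standard needs at least one result metric")
  }
  stopifnot(num_resample_runs >= 1)
  structure(list(
    datasource = datasource, classifier = classifier,
    feature_preprocessors = feature_preprocessors,
    result_metrics = result_metrics,
    num_resample_runs = as.integer(num_resample_runs),
    run_TCD = isTRUE(run_TCD),
    num_parallel_workers = num_parallel_workers,
    seed = seed, keep_predictions = isTRUE(keep_predictions)
  ), class = "cv_standard")
}

default_workers <- function() {
  if (.Platform$OS.type != "unix") return(1L)
  max(1L, as.integer(floor(parallel::detectCores(logical = TRUE) / 2)))
}

#' Run a decoding analysis
#'
#' Executes the cross-validator and compiles the requested result
#' metrics.
#'
#' @param cv a `cv_standard` specification.
#' @return a `decoding_results` list holding one entry per requested
#'   metric (`rm_main_results`, `rm_confusion_matrix`), the raw
#'   prediction set when requested, and `cross_validation_parameters`
#'   (the complete flattened parameter record, including the master
#'   seed).
#' @export
run_decoding <- function(cv) {
  if (inherits(cv, "ndr_pipeline")) {
    stop_pd("the pipeline must end with cv_standard() before run_decoding()")
  }
  stopifnot(inherits(cv, "cv_standard"))
  ds <- cv$datasource
  seed <- cv$seed %||% ds$seed %||% sample.int(2147483647L, 1)
  if (inherits(cv$classifier, "cl_poisson_naive_bayes") &&
      !isTRUE(cv$classifier$allow_rounding) && !is_wholenumber(ds$data_matrix)) {
    stop_pd("configuration error: cl_poisson_naive_bayes requires integer spike ",
            "counts but the binned data is non-integer (mean-aggregated?); ",
            "re-bin with aggregate = \"sum\" or set allow_rounding = TRUE")
  }
  workers <- as.integer(cv$num_parallel_workers %||% default_workers())
  runs <- seq_len(cv$num_resample_runs)
  run_one <- function(run) decode_one_run(cv, ds, run, seed)
  res_list <- if (workers > 1 && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(runs, run_one, mc.cores = workers,
                              mc.preschedule = TRUE)
    errs <- vapply(out, inherits, logical(1), "try-error")
    if (any(errs)) stop_pd("decoding failed: ", out[[which(errs)[1]]])
    out
  } else {
    lapply(runs, run_one)
  }
  preds <- data.table::rbindlist(res_list)
  data.table::setDF(preds)
  attr(preds, "classes") <- ds$classes
  attr(preds, "bin_info") <- ds$time_info
  attr(preds, "num_cv_splits") <- ds$num_cv_splits
  attr(preds, "num_resample_runs") <- cv$num_resample_runs
  attr(preds, "run_TCD") <- cv$run_TCD
  class(preds) <- c("raw_predictions", "data.frame")

  results <- list()
  for (rm in cv$result_metrics) {
    if (inherits(rm, "rm_main_results")) {
      results$rm_main_results <- compute_main_results(preds)
    } else if (inherits(rm, "rm_confusion_matrix")) {
      results$rm_confusion_matrix <- compute_confusion_matrix_set(preds)
    } else {
      stop_pd("unknown result metric of class ", class(rm)[1])
    }
  }
  if (cv$keep_predictions) results$raw_predictions <- preds
  results$cross_validation_parameters <- cv_parameters(cv, seed)
  class(results) <- "decoding_results"
  results
}

# one resample run: returns a data.table of prediction records
decode_one_run <- function(cv, ds, run, seed) {
  sd_run <- get_split_data(ds, run, master_seed = seed)
  k <- sd_run$num_cv_splits
  B <- nrow(sd_run$time_info)
  tcd <- cv$run_TCD
  cells <- vector("list", k * B * (if (tcd) B else 1))
  ci <- 0
  for (fold in seq_len(k)) {
    tr_rows <- sd_run$train$meta$split != fold
    te_rows <- sd_run$test$meta$split == fold
    y_tr <- sd_run$train$meta$class_label[tr_rows]
    y_te <- sd_run$test$meta$class_label[te_rows]
    for (tb in seq_len(B)) {
      x_tr <- sd_run$train$data[tr_rows, , tb, drop = TRUE]
      if (is.null(dim(x_tr))) x_tr <- matrix(x_tr, ncol = 1)
      states <- list()
      for (fp in cv$feature_preprocessors) {
        st <- fp_fit(fp, x_tr, y_tr)
        x_tr <- fp_apply(st, x_tr)
        states <- c(states, list(st))
      }
      model <- cl_train(cv$classifier, x_tr, y_tr)
      for (tt in (if (tcd) seq_len(B) else tb)) {
        x_te <- sd_run$test$data[te_rows, , tt, drop = TRUE]
        if (is.null(dim(x_te))) x_te <- matrix(x_te, ncol = 1)
        for (st in states) x_te <- fp_apply(st, x_te)
        dv <- cl_decision_values(model, x_te)
        p <- with_substream(substream_seed(seed, run, "tie", fold, tb, tt),
                            predictions_from_dv(dv, y_te))
        dvt <- data.table::as.data.table(dv)
        data.table::setnames(dvt, paste0("dv_", seq_len(ncol(dv))))
        cells[[ci <- ci + 1]] <- data.table::data.table(
          run = run, fold = fold, train_bin = tb, test_bin = tt,
          actual = p$actual, predicted = p$predicted, tie_flag = p$tie_flag,
          dvt)
      }
    }
  }
  data.table::rbindlist(cells)
}

cv_parameters <- function(cv, seed) {
  ds <- cv$datasource
  flat <- c(
    list(
      "datasource.type" = ds$type,
      "datasource.labels" = ds$label,
      "datasource.num_cv_splits" = ds$num_cv_splits,
      "datasource.num_label_repeats_per_cv_split" = ds$num_label_repeats_per_cv_split,
      "datasource.num_sites" = length(ds$site_ids),
      "datasource.site_IDs_to_use" = paste(ds$site_ids, collapse = ";"),
      "datasource.label_levels" = paste(ds$train_levels, collapse = ";")
    ),
    if (!is.null(ds$test_levels)) {
      list("datasource.test_label_levels" = paste(ds$test_levels, collapse = ";"))
    },
    list("classifier.type" = cv$classifier$type),
    if (!is.null(cv$classifier$smoothing)) {
      list("classifier.smoothing" = cv$classifier$smoothing)
    },
    local({
      fps <- cv$feature_preprocessors
      out <- list()
      for (i in seq_along(fps)) {
        out[[sprintf("preprocessors.%d.type", i)]] <- fps[[i]]$type
        if (!is.null(fps[[i]]$k)) out[[sprintf("preprocessors.%d.k", i)]] <- fps[[i]]$k
      }
      out
    }),
    list(
      "result_metrics" = paste(vapply(cv$result_metrics, function(r) class(r)[1],
                                      character(1)), collapse = ";"),
      "cross_validator.num_resample_runs" = cv$num_resample_runs,
      "cross_validator.run_TCD" = cv$run_TCD,
      "seed" = as.integer(seed)
    )
  )
  list(parameter_df = as.data.frame(flat, check.names = FALSE, optional = TRUE),
       seed = as.integer(seed))
}

#' @export
print.decoding_results <- function(x, ...) {
  cat("decoding_results with components:",
      paste(setdiff(names(x), "cross_validation_parameters"), collapse = ", "), "\n")
  if (!is.null(x$rm_main_results)) {
    acc <- diag_series(x$rm_main_results$accuracy)
    cat(sprintf("  same-time zero-one accuracy: mean %.3f, max %.3f (chance %.3f)\n",
                mean(acc), max(acc), 1 / length(x$rm_main_results$classes)))
  }
  invisible(x)
}
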