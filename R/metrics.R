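#' Result-metric requests
#'
#' Marker objects passed to [cv_standard()] selecting which summaries
#' [run_decoding()] compiles from the raw prediction records:
#' `rm_main_results()` requests the three decoding-accuracy time
#' courses (zero-one loss, normalized rank, correct-class decision
#' value), `rm_confusion_matrix()` requests per-time-bin confusion
#' matrices (at train time == test time).
#'
#' @param x reserved for pipe-style construction.
#' @return a `result_metric` object.
#' @name result_metrics
NULL

#' @rdname result_metrics
#' @export
rm_main_results <- function(x = NULL) {
  maybe_pipe(x, structure(list(type = "main_results"),
                          class = c("rm_main_results", "result_metric")))
}

#' @rdname result_metrics
#' @export
rm_confusion_matrix <- function(x = NULL) {
  maybe_pipe(x, structure(list(type = "confusion_matrix"),
                          class = c("rm_confusion_matrix", "result_metric")))
}

diag_series <- function(m) m[cbind(seq_len(nrow(m)), seq_len(ncol(m)))]

pred_dv_matrix <- function(preds) {
  as.matrix(as.data.frame(preds)[, grep("^dv_", names(preds)), drop = FALSE])
}

#' Compile the main decoding-accuracy results
#'
#' From a raw prediction set, computes three measures per (train bin,
#' test bin) cell:
#' * zero-one accuracy — fraction of records whose predicted class
#'   equals the actual class;
#' * mean normalized rank — per record `(C - r) / (C - 1)` where `r` is
#'   the rank (1 = highest, ties by average rank) of the actual class's
#'   decision value among the C classes; 1 is best, 0 worst, 0.5 the
#'   chance expectation;
#' * mean decision value of the actual class.
#'
#' Records are aggregated as fold means within each resample run, then
#' averaged across runs (identical to pooling for balanced folds);
#' per-run values are retained in `$per_run`.
#'
#' @param preds a `raw_predictions` object (see [run_decoding()] with
#'   `keep_predictions = TRUE` for how to obtain one directly).
#' @return a `main_results` object: train-bins x test-bins matrices
#'   `accuracy`, `normalized_rank`, `decision_values` (NA at cells not
#'   evaluated, e.g. off-diagonal when `run_TCD = FALSE`), per-run
#'   table, and metadata (`bin_info`, `classes`, `run_TCD`).
#' @export
compute_main_results <- function(preds) {
  classes <- attr(preds, "classes")
  bin_info <- attr(preds, "bin_info")
  C <- length(classes)
  if (C < 2) stop_pd("main results need at least 2 classes")
  dvm <- pred_dv_matrix(preds)
  n <- nrow(preds)
  a_idx <- cbind(seq_len(n), preds$actual)
  dv_actual <- dvm[a_idx]
  greater <- rowSums(dvm > dv_actual)
  equal <- rowSums(dvm == dv_actual)
  r <- greater + (equal + 1) / 2
  dt <- data.table::data.table(
    run = preds$run, fold = preds$fold,
    train_bin = preds$train_bin, test_bin = preds$test_bin,
    correct = as.numeric(preds$predicted == preds$actual),
    nrank = (C - r) / (C - 1),
    dvc = dv_actual)
  by_fold <- dt[, list(accuracy = mean(correct), normalized_rank = mean(nrank),
                       decision_value = mean(dvc)),
                by = c("run", "fold", "train_bin", "test_bin")]
  per_run <- by_fold[, list(accuracy = mean(accuracy),
                            normalized_rank = mean(normalized_rank),
                            decision_value = mean(decision_value)),
                     by = c("run", "train_bin", "test_bin")]
  grand <- per_run[, list(accuracy = mean(accuracy),
                          normalized_rank = mean(normalized_rank),
                          decision_value = mean(decision_value)),
                   by = c("train_bin", "test_bin")]
  B <- nrow(bin_info)
  mk <- function(col) {
    m <- matrix(NA_real_, B, B, dimnames = list(bin_info$name, bin_info$name))
    m[cbind(grand$train_bin, grand$test_bin)] <- grand[[col]]
    m
  }
  structure(list(
    accuracy = mk("accuracy"),
    normalized_rank = mk("normalized_rank"),
    decision_values = mk("decision_value"),
    per_run = data.table::setDF(per_run),
    bin_info = bin_info, classes = classes,
    run_TCD = isTRUE(attr(preds, "run_TCD")),
    num_cv_splits = attr(preds, "num_cv_splits"),
    num_resample_runs = attr(preds, "num_resample_runs")
  ), class = "main_results")
}

resolve_bin <- function(bin_info, bin, populated = NULL) {
  avail <- populated %||% seq_len(nrow(bin_info))
  if (is.character(bin)) {
    idx <- match(bin, bin_info$name)
  } else if (bin %in% bin_info$start) {
    idx <- match(bin, bin_info$start)     # a bin start time
  } else if (is_wholenumber(bin) && bin >= 1 && bin <= nrow(bin_info)) {
    idx <- as.integer(bin)                # a bin index
  } else {
    idx <- NA_integer_
  }
  if (is.na(idx) || !(idx %in% avail)) {
    stop_pd("time bin ", bin, " is not populated; available bins: ",
            paste(bin_info$name[avail], collapse = ", "))
  }
  idx
}

#' Confusion matrix at one training time
#'
#' Counts, pooled over resample runs and cross-validation folds at
#' (train bin, test bin = train bin), how often trials of actual class i
#' were predicted as class j.  The diagonal sum divided by the total
#' equals the zero-one accuracy at that cell exactly.
#'
#' @param preds a `raw_predictions` object.
#' @param train_time the training bin: a bin name (`"time.1_31"`), a bin
#'   start time, or a bin index.
#' @return a `confusion_matrix`: list with `counts` (C x C, rows =
#'   actual, columns = predicted), `proportions` (rows normalized to
#'   sum to 1), and `train_bin` (the resolved bin name).
#' @export
compute_confusion_matrix <- function(preds, train_time) {
  classes <- attr(preds, "classes")
  bin_info <- attr(preds, "bin_info")
  populated <- sort(unique(preds$train_bin[preds$train_bin == preds$test_bin]))
  idx <- resolve_bin(bin_info, train_time, populated)
  sel <- preds$train_bin == idx & preds$test_bin == idx
  counts <- table(factor(preds$actual[sel], levels = seq_along(classes)),
                  factor(preds$predicted[sel], levels = seq_along(classes)))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  structure(list(counts = counts, proportions = props,
                 train_bin = bin_info$name[idx]),
            class = "confusion_matrix")
}

# all populated same-time bins at once (what rm_confusion_matrix stores)
compute_confusion_matrix_set <- function(preds) {
  bin_info <- attr(preds, "bin_info")
  populated <- sort(unique(preds$train_bin[preds$train_bin == preds$test_bin]))
  mats <- lapply(populated, function(b) compute_confusion_matrix(preds, bin_info$name[b]))
  names(mats) <- bin_info$name[populated]
  structure(list(matrices = mats, bin_info = bin_info,
                 classes = attr(preds, "classes")),
            class = "confusion_matrix_set")
}

#' Tidy tables (and plots) of decoding results
#'
#' Three views:
#' * `"line"` — the same-time (diagonal) series of each requested
#'   metric against test-bin start time (`results_to_show = "all"` for
#'   zero-one accuracy, normalized rank and decision values;
#'   `"accuracy"` for accuracy only);
#' * `"TCD"` — the full train x test zero-one accuracy matrix in long
#'   form (requires a run with `run_TCD = TRUE`);
#' * `"matrix"` — one confusion matrix in long form, taken at the
#'   earliest bin starting at or after `train_time` (the bin that
#'   "starts around" the requested time), so e.g. requesting 200 with
#'   bins starting ..., 196, 206, ... selects the bin starting at 206;
#'   if no bin starts that late, the last bin is used.
#'
#' Time-bin axis labels use the bin start time.
#'
#' @param results a `main_results` (line/TCD) or `confusion_matrix_set`
#'   (matrix view) object.
#' @param view one of `"line"`, `"TCD"`, `"matrix"`.
#' @param results_to_show `"all"` or `"accuracy"` (line view).
#' @param train_time requested training time for the matrix view (ms).
#' @param file optional image path; the plot is saved there with
#'   [ggplot2::ggsave()].
#' @return list with `table` (tidy data frame; line tables carry a
#'   `chance` attribute of 1/C) and `plot` (ggplot object).
#' @export
results_to_plot_tables <- function(results, view = c("line", "TCD", "matrix"),
                                   results_to_show = "all", train_time = NULL,
                                   file = NULL) {
  view <- match.arg(view)
  out <- switch(view,
    line = {
      stopifnot(inherits(results, "main_results"))
      starts <- results$bin_info$start
      metrics <- if (identical(results_to_show, "accuracy")) "accuracy"
                 else c("accuracy", "normalized_rank", "decision_values")
      tab <- do.call(rbind, lapply(metrics, function(mn) {
        data.frame(test_time = starts, metric = mn,
                   value = diag_series(results[[mn]]))
      }))
      tab <- tab[!is.na(tab$value), , drop = FALSE]
      attr(tab, "chance") <- 1 / length(results$classes)
      p <- ggplot(tab, aes(x = test_time, y = value, color = metric)) +
        geom_line() +
        geom_hline(yintercept = 1 / length(results$classes), linetype = "dashed") +
        labs(x = "Time (ms)", y = "Value") + theme_classic()
      list(table = tab, plot = p)
    },
    TCD = {
      stopifnot(inherits(results, "main_results"))
      if (!results$run_TCD) {
        stop_pd("TCD view requires results computed with run_TCD = TRUE ",
                "(only same-time cells are populated)")
      }
      starts <- results$bin_info$start
      tab <- expand.grid(train_time = starts, test_time = starts)
      tab$accuracy <- as.vector(results$accuracy)  # column-major: train varies fastest
      # accuracy is [train, test]; expand.grid varies train_time fastest: match
      p <- ggplot(tab, aes(x = test_time, y = train_time, fill = accuracy)) +
        geom_tile() + scale_fill_viridis_c() +
        labs(x = "Test time (ms)", y = "Train time (ms)") + theme_classic()
      list(table = tab, plot = p)
    },
    matrix = {
      stopifnot(inherits(results, "confusion_matrix_set"))
      avail <- names(results$matrices)
      starts <- results$bin_info$start[match(avail, results$bin_info$name)]
      if (is.null(train_time)) train_time <- starts[1]
      at_or_after <- which(starts >= train_time)
      pick <- if (length(at_or_after)) avail[at_or_after[1]] else avail[length(avail)]
      cm <- results$matrices[[pick]]
      tab <- as.data.frame(as.table(cm$counts), stringsAsFactors = FALSE)
      names(tab) <- c("actual", "predicted", "count")
      tab$proportion <- as.vector(cm$proportions)
      p <- ggplot(tab, aes(x = predicted, y = actual, fill = proportion)) +
        geom_tile() + scale_fill_viridis_c() +
        labs(title = paste("Confusion matrix at", pick)) + theme_classic() +
        theme(axis.text.x = element_text(angle = 90, vjust = 0.5, hjust = 1))
      attr(tab, "train_bin") <- pick
      list(table = tab, plot = p)
    })
  if (!is.null(file)) ggsave(file, out$plot, width = 7, height = 5)
  out
}

#' @export
plot.main_results <- function(x, type = c("line", "TCD"),
                              results_to_show = "accuracy", ...) {
  type <- match.arg(type)
  results_to_plot_tables(x, view = type, results_to_show = results_to_show)$plot
}

#' @export
plot.confusion_matrix_set <- function(x, plot_only_one_train_time = NULL, ...) {
  results_to_plot_tables(x, view = "matrix",
                         train_time = plot_only_one_train_time)$plot
}

#' Compare saved decoding results
#'
#' Loads named results from a results log and overlays their same-time
#' zero-one accuracy series.
#'
#' @param results_dir_name directory managed by [log_save_results()].
#' @param result_names character vector of saved result names.
#' @return list with `table` (result_name, test_time, accuracy; one row
#'   per result per time bin) and `plot` (ggplot with one series per
#'   result).
#' @export
plot_main_results <- function(results_dir_name, result_names) {
  tabs <- lapply(result_names, function(nm) {
    res <- log_load_results_from_result_name(nm, results_dir_name)
    if (is.null(res$rm_main_results)) {
      stop_pd("saved result ", shQuote(nm), " has no rm_main_results component")
    }
    tab <- results_to_plot_tables(res$rm_main_results, "line",
                                  results_to_show = "accuracy")$table
    data.frame(result_name = nm, test_time = tab$test_time,
               accuracy = tab$value, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, tabs)
  p <- ggplot(tab, aes(x = test_time, y = accuracy, color = result_name)) +
    geom_line() + labs(x = "Time (ms)", y = "Zero-one accuracy") +
    theme_classic()
  list(table = tab, plot = p)
}
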