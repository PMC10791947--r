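# hand-built prediction sets with known answers
dv_row <- function(C, actual_rank) {
  # decision values C, C-1, ..., 1 placed so the actual class has the
  # requested rank; actual class is index 1
  dv <- rev(seq_len(C))
  out <- numeric(C)
  out[1] <- dv[actual_rank]
  out[-1] <- dv[-actual_rank]
  out
}

test_that("normalized rank hits its endpoints and midpoint for C = 25", {
  C <- 25
  rows <- lapply(c(1, 13, 25), function(rk) dv_row(C, rk))
  df <- data.frame(run = 1, fold = 1, train_bin = 1, test_bin = 1,
                   actual = 1L, predicted = c(1L, 2L, 2L), tie_flag = FALSE)
  dvm <- do.call(rbind, rows)
  colnames(dvm) <- paste0("dv_", 1:C)
  preds <- make_preds(cbind(df, dvm), classes = paste0("cl", 1:C))
  mr <- compute_main_results(preds)
  # records average within the single cell: (1.0 + 0.5 + 0.0) / 3
  expect_equal(mr$normalized_rank[1, 1], 0.5)
  # and record-by-record via single-record sets
  for (pair in list(c(1, 1), c(13, 0.5), c(25, 0))) {
    single <- make_preds(cbind(df[1, ], rbind(dv_row(C, pair[1]))[, , drop = FALSE] |>
                                 `colnames<-`(paste0("dv_", 1:C))),
                         classes = paste0("cl", 1:C))
    expect_equal(compute_main_results(single)$normalized_rank[1, 1], pair[2])
  }
})

test_that("all-correct predictions give accuracy 1 and errors need 2+ classes", {
  C <- 4
  n <- 12
  dvm <- matrix(rnorm(n * C), n, C)
  actual <- max.col(dvm)
  df <- cbind(data.frame(run = rep(1:2, each = 6), fold = rep(1:2, 6),
                         train_bin = 1, test_bin = 1,
                         actual = actual, predicted = actual, tie_flag = FALSE),
              `colnames<-`(dvm, paste0("dv_", 1:C)))
  preds <- make_preds(df, classes = paste0("c", 1:C))
  expect_equal(compute_main_results(preds)$accuracy[1, 1], 1.0)

  one_class <- make_preds(df[, c(1:7, 8)], classes = "c1")
  expect_error(compute_main_results(one_class), "2 classes")
})

test_that("metrics match an independent record replay on a random fixture", {
  set.seed(12)
  C <- 5; n <- 400
  dvm <- matrix(rnorm(n * C), n, C)
  actual <- sample(C, n, replace = TRUE)
  predicted <- max.col(dvm)
  df <- cbind(data.frame(run = sample(1:2, n, TRUE), fold = sample(1:2, n, TRUE),
                         train_bin = 1, test_bin = 1, actual = actual,
                         predicted = predicted, tie_flag = FALSE),
              `colnames<-`(dvm, paste0("dv_", 1:C)))
  preds <- make_preds(df, classes = paste0("c", 1:C))
  mr <- compute_main_results(preds)
  # oracle: loop over records, fold means within run, then run means
  accs <- ranks <- dvs <- c()
  for (rr in 1:2) {
    fa <- fr <- fd <- c()
    for (ff in 1:2) {
      sel <- which(df$run == rr & df$fold == ff)
      fa <- c(fa, mean(predicted[sel] == actual[sel]))
      rks <- vapply(sel, function(i) {
        r <- rank(-dvm[i, ], ties.method = "average")[actual[i]]
        (C - r) / (C - 1)
      }, numeric(1))
      fr <- c(fr, mean(rks))
      fd <- c(fd, mean(dvm[cbind(sel, actual[sel])]))
    }
    accs <- c(accs, mean(fa)); ranks <- c(ranks, mean(fr)); dvs <- c(dvs, mean(fd))
  }
  expect_equal(mr$accuracy[1, 1], mean(accs), tolerance = 1e-12)
  expect_equal(mr$normalized_rank[1, 1], mean(ranks), tolerance = 1e-12)
  expect_equal(mr$decision_values[1, 1], mean(dvs), tolerance = 1e-12)

  # random decision values: mean normalized rank ~ 0.5, accuracy ~ 1/C
  expect_lt(abs(mr$normalized_rank[1, 1] - 0.5), 3 * sqrt(1 / 12 / n) + 0.01)
  expect_lt(abs(mean(predicted == actual) - 1 / C),
            3 * sqrt((1 / C) * (1 - 1 / C) / n))
})

test_that("confusion matrices tally records and tie out with accuracy", {
  # C = 2 fixture with 8 hand-enumerable records
  actual <-    c(1, 1, 1, 1, 2, 2, 2, 2)
  predicted <- c(1, 1, 2, 1, 2, 2, 1, 2)
  dvm <- cbind(ifelse(predicted == 1, 1, 0), ifelse(predicted == 2, 1, 0))
  df <- cbind(data.frame(run = 1, fold = rep(1:2, 4), train_bin = 1,
                         test_bin = 1, actual = actual, predicted = predicted,
                         tie_flag = FALSE),
              `colnames<-`(dvm, c("dv_1", "dv_2")))
  preds <- make_preds(df, classes = c("A", "B"))
  cm <- compute_confusion_matrix(preds, "time.0_10")
  expect_equal(unname(cm$counts), matrix(c(3, 1, 1, 3), 2))  # hand tally
  expect_equal(rowSums(cm$proportions), c(actual = 1, actual = 1),
               ignore_attr = TRUE)
  expect_equal(sum(diag(cm$counts)) / sum(cm$counts),
               compute_main_results(preds)$accuracy[1, 1])
  expect_error(compute_confusion_matrix(preds, 999), "available")

  # a perfect classifier gives a diagonal matrix
  df2 <- df; df2$predicted <- df2$actual
  cm2 <- compute_confusion_matrix(make_preds(df2, classes = c("A", "B")), 1)
  expect_equal(unname(cm2$counts), diag(c(4L, 4L)))
})

test_that("plot tables implement the documented views and bin selection", {
  binned <- make_signal_binned(n_sites = 4, n_bins = 2)
  ds <- ds_basic(binned, "cond", num_cv_splits = 3)
  res <- run_decoding(cv_standard(ds, cl_max_correlation(),
                                  result_metrics = list(rm_main_results(),
                                                        rm_confusion_matrix()),
                                  num_resample_runs = 2, seed = 1,
                                  num_parallel_workers = 1))
  line <- results_to_plot_tables(res$rm_main_results, "line",
                                 results_to_show = "all")
  expect_equal(nrow(line$table), 2 * 3)           # bins x metrics
  expect_equal(attr(line$table, "chance"), 1 / 3)
  acc_only <- results_to_plot_tables(res$rm_main_results, "line",
                                     results_to_show = "accuracy")
  expect_equal(nrow(acc_only$table), 2)
  tcd <- results_to_plot_tables(res$rm_main_results, "TCD")
  expect_equal(nrow(tcd$table), 4)
  expect_equal(tcd$table$accuracy[tcd$table$train_time == 0 &
                                    tcd$table$test_time == 10],
               res$rm_main_results$accuracy[1, 2])

  # diagonal-only results refuse the TCD view
  res_d <- run_decoding(cv_standard(ds, cl_max_correlation(),
                                    result_metrics = list(rm_main_results()),
                                    num_resample_runs = 1, run_TCD = FALSE,
                                    seed = 1, num_parallel_workers = 1))
  expect_error(results_to_plot_tables(res_d$rm_main_results, "TCD"), "run_TCD")

  # 1-bin result -> single-row line table
  b1 <- binned[, !startsWith(names(binned), "time.1")]
  res1 <- run_decoding(cv_standard(ds_basic(read_binned_data(b1), "cond", 3),
                                   cl_max_correlation(),
                                   result_metrics = list(rm_main_results()),
                                   num_resample_runs = 1, seed = 1,
                                   num_parallel_workers = 1))
  expect_equal(nrow(results_to_plot_tables(res1$rm_main_results, "line",
                                           results_to_show = "accuracy")$table), 1)
})

test_that("confusion view picks the earliest bin starting at or after the request", {
  classes <- c("A", "B")
  mk_cm_set <- function(starts) {
    bin_info <- data.frame(name = sprintf("time.%d_%d", starts, starts + 30),
                           start = starts, end = starts + 30)
    mats <- lapply(seq_along(starts), function(i) {
      structure(list(counts = matrix(c(2L, 0L, 0L, 2L), 2,
                                     dimnames = list(actual = classes,
                                                     predicted = classes)),
                     proportions = diag(2), train_bin = bin_info$name[i]),
                class = "confusion_matrix")
    })
    names(mats) <- bin_info$name
    structure(list(matrices = mats, bin_info = bin_info, classes = classes),
              class = "confusion_matrix_set")
  }
  cms <- mk_cm_set(c(186, 196, 206, 216))
  got <- results_to_plot_tables(cms, "matrix", train_time = 200)
  expect_equal(attr(got$table, "train_bin"), "time.206_236")
  got_last <- results_to_plot_tables(cms, "matrix", train_time = 400)
  expect_equal(attr(got_last$table, "train_bin"), "time.216_246")
})

test_that("plot_main_results overlays saved series", {
  dir <- file.path(tempdir(), "pmr_results")
  unlink(dir, recursive = TRUE)
  binned <- make_signal_binned(n_sites = 4, n_bins = 3)
  ds <- ds_basic(binned, "cond", num_cv_splits = 3)
  res <- run_decoding(cv_standard(ds, cl_max_correlation(),
                                  result_metrics = list(rm_main_results()),
                                  num_resample_runs = 2, run_TCD = FALSE,
                                  seed = 5, num_parallel_workers = 1))
  for (nm in c("one", "two", "three")) log_save_results(res, dir, nm)
  out <- plot_main_results(dir, c("one", "two", "three"))
  expect_equal(nrow(out$table), 3 * 3)            # results x bins
  # one name -> identical to its own line view
  solo <- plot_main_results(dir, "one")
  line <- results_to_plot_tables(res$rm_main_results, "line", "accuracy")$table
  expect_equal(solo$table$accuracy, line$value, tolerance = 1e-12)
  # two identical saved results -> coincident series
  wide <- split(out$table$accuracy, out$table$result_name)
  expect_equal(wide$one, wide$two)
  expect_error(plot_main_results(dir, "nope"), "one|available|mean")
})
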