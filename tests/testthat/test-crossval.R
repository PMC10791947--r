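quick_cv <- function(binned, label = "cond", k = 3, classes = NULL, runs = 2,
                     tcd = TRUE, cl = cl_max_correlation(), fps = list(),
                     seed = 42, keep = FALSE, workers = 1) {
  ds <- ds_basic(binned, label, num_cv_splits = k, label_levels = classes)
  cv_standard(ds, cl, fps, list(rm_main_results(), rm_confusion_matrix()),
              num_resample_runs = runs, run_TCD = tcd,
              num_parallel_workers = workers, seed = seed,
              keep_predictions = keep)
}

test_that("the evaluation grid matches run_TCD and each cell holds C test records", {
  binned <- make_signal_binned(n_sites = 4, classes = paste0("c", 1:3),
                               reps = 6, n_bins = 3)
  res <- run_decoding(quick_cv(binned, runs = 1, tcd = TRUE, keep = TRUE))
  preds <- res$raw_predictions
  cells <- unique(preds[c("fold", "train_bin", "test_bin")])
  expect_equal(nrow(cells), 3 * 3 * 3)      # folds x B^2
  counts <- table(preds$train_bin, preds$test_bin, preds$fold)
  expect_true(all(counts == 3))             # C test records per cell (r = 1)

  res_d <- run_decoding(quick_cv(binned, runs = 1, tcd = FALSE, keep = TRUE))
  cells_d <- unique(res_d$raw_predictions[c("fold", "train_bin", "test_bin")])
  expect_equal(nrow(cells_d), 3 * 3)        # folds x B, diagonal only
  expect_true(all(cells_d$train_bin == cells_d$test_bin))
  acc <- res_d$rm_main_results$accuracy
  expect_true(all(is.na(acc[upper.tri(acc)])) && all(is.na(acc[lower.tri(acc)])))
})

test_that("worker count never changes the results (bit-identical)", {
  binned <- make_signal_binned(n_sites = 5, classes = paste0("c", 1:3), reps = 8)
  r1 <- run_decoding(quick_cv(binned, runs = 4, seed = 17, workers = 1))
  r2 <- run_decoding(quick_cv(binned, runs = 4, seed = 17, workers = 4))
  expect_identical(r1$rm_main_results$accuracy, r2$rm_main_results$accuracy)
  expect_identical(r1$rm_main_results$per_run, r2$rm_main_results$per_run)
  expect_identical(lapply(r1$rm_confusion_matrix$matrices, `[[`, "counts"),
                   lapply(r2$rm_confusion_matrix$matrices, `[[`, "counts"))
})

test_that("metrics equal an independent replay of the stored records", {
  binned <- make_signal_binned(n_sites = 4, classes = paste0("c", 1:3),
                               reps = 6, noise = 1.5)
  res <- run_decoding(quick_cv(binned, runs = 3, keep = TRUE))
  preds <- res$raw_predictions
  C <- length(attr(preds, "classes"))
  # replay: plain loops, fold means within run then run means
  for (cell in list(c(1, 1), c(2, 1), c(2, 2))) {
    per_run <- sapply(sort(unique(preds$run)), function(rr) {
      mean(sapply(sort(unique(preds$fold)), function(ff) {
        sel <- preds$run == rr & preds$fold == ff &
          preds$train_bin == cell[1] & preds$test_bin == cell[2]
        mean(preds$predicted[sel] == preds$actual[sel])
      }))
    })
    expect_equal(res$rm_main_results$accuracy[cell[1], cell[2]], mean(per_run),
                 tolerance = 1e-12)
  }
  # confusion diagonal fraction == zero-one accuracy, exactly
  for (bn in names(res$rm_confusion_matrix$matrices)) {
    cm <- res$rm_confusion_matrix$matrices[[bn]]$counts
    b <- match(bn, res$rm_main_results$bin_info$name)
    expect_equal(sum(diag(cm)) / sum(cm), res$rm_main_results$accuracy[b, b])
  }
})

test_that("decoding a two-class separable fixture is perfect; shuffled labels sit at chance", {
  fx <- generate_worked_fixture("two-class-separable")
  res <- run_decoding(quick_cv(fx$binned, label = fx$label, runs = 3,
                               fps = list(fp_zscore())))
  expect_equal(unname(diag(res$rm_main_results$accuracy)),
               rep(fx$expected$accuracy, 2))

  tie <- generate_worked_fixture("tie-degenerate")
  res_t <- run_decoding(quick_cv(tie$binned, label = tie$label, runs = 20,
                                 tcd = FALSE, seed = 99))
  accs <- res_t$rm_main_results$per_run$accuracy
  # all-zero data: every prediction is an independent uniform tie-break,
  # so the record-level binomial SE applies (20 runs x 3 folds x 2 bins x 5)
  n_rec <- 20 * 3 * 2 * 5
  expect_lt(abs(mean(accs) - tie$expected$chance),
            3 * sqrt(0.2 * 0.8 / n_rec))
})

test_that("poisson classifier rejects mean-aggregated (non-integer) data", {
  binned <- make_signal_binned()
  expect_error(run_decoding(quick_cv(binned, cl = cl_poisson_naive_bayes())),
               "aggregate")
  # integer data runs fine
  ints <- binned
  tc <- startsWith(names(ints), "time.")
  ints[tc] <- lapply(ints[tc], function(v) round(pmax(v, 0)))
  expect_s3_class(run_decoding(quick_cv(read_binned_data(ints), runs = 1,
                                        cl = cl_poisson_naive_bayes())),
                  "decoding_results")
})

test_that("pipe-built analyses equal explicitly built ones", {
  binned <- make_signal_binned(n_sites = 4)
  dir <- file.path(tempdir(), "pipe_results")
  unlink(dir, recursive = TRUE)

  cv_explicit <- cv_standard(
    datasource = ds_basic(binned, "cond", num_cv_splits = 3),
    classifier = cl_max_correlation(),
    feature_preprocessors = list(fp_zscore()),
    result_metrics = list(rm_main_results()),
    num_resample_runs = 2, run_TCD = FALSE, num_parallel_workers = 1, seed = 8)
  res_explicit <- run_decoding(cv_explicit)
  log_save_results(res_explicit, dir, "explicit")

  piped <- binned |>
    ds_basic("cond", num_cv_splits = 3) |>
    fp_zscore() |>
    cl_max_correlation() |>
    rm_main_results() |>
    cv_standard(num_resample_runs = 2, run_TCD = FALSE,
                num_parallel_workers = 1, seed = 8)
  expect_equal(piped$classifier, cv_explicit$classifier)
  expect_equal(piped$feature_preprocessors, cv_explicit$feature_preprocessors)
  expect_equal(piped$num_resample_runs, cv_explicit$num_resample_runs)
  res_piped <- run_decoding(piped)
  log_save_results(res_piped, dir, "piped")

  # the two saved archives are byte-identical where it matters
  f1 <- file.path(dir, "explicit", "main_results_mean.csv")
  f2 <- file.path(dir, "piped", "main_results_mean.csv")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("pipeline construction errors name the offending stage", {
  binned <- make_signal_binned(n_sites = 4)
  start <- ds_basic(binned, "cond", num_cv_splits = 3)
  expect_error(start |> cl_max_correlation() |> fp_zscore(), "before")
  expect_error(start |> cl_max_correlation() |> cl_max_correlation(), "already")
  expect_error(start |> fp_zscore() |> rm_main_results(), "classifier")
  expect_error(cv_standard(classifier = cl_max_correlation()), "datasource")
  expect_error(run_decoding(start |> cl_max_correlation() |> rm_main_results()),
               "cv_standard")
})
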