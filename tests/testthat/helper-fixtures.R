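# fixtures are built in code at test time; nothing is read from disk
# except files the tests themselves write to tempdir()

# random binary raster as a raster_data object
make_test_raster <- function(n_trials = 10, n_time = 40, start = 0, seed = 1,
                             p = 0.2, labels = NULL) {
  set.seed(seed)
  m <- matrix(as.integer(runif(n_trials * n_time) < p), nrow = n_trials)
  colnames(m) <- sprintf("time.%d_%d", start + seq_len(n_time) - 1,
                         start + seq_len(n_time))
  df <- data.frame(
    "site_info.monkey" = "m1",
    "labels.stim" = labels %||% rep_len(c("A", "B"), n_trials),
    check.names = FALSE, stringsAsFactors = FALSE)
  as_raster_data(cbind(df, as.data.frame(m, check.names = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# binned table where every trial's value encodes (site, level, repetition)
# uniquely -- lets tests reconstruct exactly which raw trials a
# pseudo-population sampled
make_coded_binned <- function(n_sites = 3, levels = c("A", "B", "C"),
                              reps = 5, n_bins = 2) {
  rows <- list()
  for (s in seq_len(n_sites)) {
    for (li in seq_along(levels)) {
      for (rp in seq_len(reps)) {
        code <- s * 10000 + li * 100 + rp
        vals <- as.list(rep(code, n_bins))
        names(vals) <- sprintf("time.%d_%d", (seq_len(n_bins) - 1) * 10,
                               seq_len(n_bins) * 10)
        rows[[length(rows) + 1]] <- data.frame(
          siteID = s, "labels.cond" = levels[li], vals,
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  read_binned_data(do.call(rbind, rows))
}

# minimal decodable binned table: class-dependent means + small noise
make_signal_binned <- function(n_sites = 6, classes = c("c1", "c2", "c3"),
                               reps = 6, n_bins = 2, sep = 4, noise = 0.3,
                               seed = 5) {
  set.seed(seed)
  rows <- list()
  for (s in seq_len(n_sites)) {
    site_pref <- (s %% length(classes)) + 1
    for (ci in seq_along(classes)) {
      mu <- if (ci == site_pref) sep else 0
      for (rp in seq_len(reps)) {
        vals <- as.list(mu + rnorm(n_bins, sd = noise))
        names(vals) <- sprintf("time.%d_%d", (seq_len(n_bins) - 1) * 10,
                               seq_len(n_bins) * 10)
        rows[[length(rows) + 1]] <- data.frame(
          siteID = s, "labels.cond" = classes[ci], vals,
          check.names = FALSE, stringsAsFactors = FALSE)
      }
    }
  }
  read_binned_data(do.call(rbind, rows))
}

# build a raw_predictions object by hand (for metric unit tests)
make_preds <- function(df, classes, bin_info = NULL, run_TCD = FALSE,
                       num_cv_splits = 2, num_resample_runs = 1) {
  bin_info <- bin_info %||% data.frame(name = "time.0_10", start = 0, end = 10)
  attr(df, "classes") <- classes
  attr(df, "bin_info") <- bin_info
  attr(df, "num_cv_splits") <- num_cv_splits
  attr(df, "num_resample_runs") <- num_resample_runs
  attr(df, "run_TCD") <- run_TCD
  class(df) <- c("raw_predictions", "data.frame")
  df
}
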