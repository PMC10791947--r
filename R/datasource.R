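#' Basic pseudo-population datasource
#'
#' Builds, for each resample run, pseudo-population training and test
#' sets for k-fold cross-validation.  Sites need not have been recorded
#' simultaneously: for each site independently, `num_cv_splits *
#' num_label_repeats_per_cv_split` trials of every label level are drawn
#' uniformly without replacement and dealt into the k splits; the
#' pseudo-trial feature vector for a given (class, split, repeat-slot)
#' concatenates sites in ascending siteID order.  Surplus trials of a
#' site are simply unused that run — a fresh sample is drawn on each
#' run, which is what makes repeated resample runs informative.
#'
#' Sampling uses a counter-based per-(seed, run, site) random substream,
#' so results are bit-identical regardless of how runs are scheduled
#' across parallel workers.
#'
#' @param binned_data binned-format path or data frame.
#' @param labels label variable to decode (with or without the
#'   `labels.` prefix).
#' @param num_cv_splits number of cross-validation splits k (>= 2).
#' @param label_levels levels to decode; defaults to all levels present.
#'   Level i defines class i.
#' @param site_IDs_to_use sites to include; defaults to every site in
#'   the binned data.  Every included site must have at least
#'   `num_cv_splits * num_label_repeats_per_cv_split` trials of every
#'   required level (see [get_siteIDs_with_k_label_repetitions()]).
#' @param num_label_repeats_per_cv_split pseudo-trials per class per
#'   split (default 1).
#' @param seed optional datasource-level RNG seed; usually left `NULL`
#'   so the cross-validator's master seed governs all sampling.
#' @return a `ds_basic` datasource object.
#' @seealso [ds_generalization()], [get_split_data()]
#' @export
ds_basic <- function(binned_data, labels, num_cv_splits,
                     label_levels = NULL, site_IDs_to_use = NULL,
                     num_label_repeats_per_cv_split = 1, seed = NULL) {
  new_datasource("ds_basic", binned_data, labels, num_cv_splits,
                 train_levels = label_levels, test_levels = NULL,
                 site_IDs_to_use = site_IDs_to_use,
                 r = num_label_repeats_per_cv_split, seed = seed)
}

#' Generalization datasource: train on one level set, test on another
#'
#' Class i is trained on pseudo-trials drawn from `train_label_levels[i]`
#' and tested on pseudo-trials drawn from `test_label_levels[i]` — e.g.
#' train on `"left profile 1".."left profile 25"` and test on
#' `"right profile 1".."right profile 25"` to ask whether identity
#' coding is invariant to head orientation.  Train-level and test-level
#' trials are sampled independently (so if a level appears in both
#' lists, the test set is a fresh resample, not the held-out split of
#' the training sample).
#'
#' @inheritParams ds_basic
#' @param train_label_levels,test_label_levels equal-length character
#'   vectors; index i of each defines class i (named by the train
#'   level).
#' @return a `ds_generalization` datasource object.
#' @export
ds_generalization <- function(binned_data, labels, num_cv_splits,
                              train_label_levels, test_label_levels,
                              site_IDs_to_use = NULL,
                              num_label_repeats_per_cv_split = 1, seed = NULL) {
  if (length(train_label_levels) != length(test_label_levels)) {
    stop_pd("train_label_levels (", length(train_label_levels),
            ") and test_label_levels (", length(test_label_levels),
            ") must have equal length: index i of each defines class i")
  }
  new_datasource("ds_generalization", binned_data, labels, num_cv_splits,
                 train_levels = train_label_levels,
                 test_levels = test_label_levels,
                 site_IDs_to_use = site_IDs_to_use,
                 r = num_label_repeats_per_cv_split, seed = seed)
}

new_datasource <- function(type, binned_data, labels, num_cv_splits,
                           train_levels, test_levels, site_IDs_to_use, r, seed) {
  binned <- read_binned_data(binned_data)
  stopifnot(num_cv_splits >= 2, r >= 1)
  cn <- binned_label_column(binned, labels)
  lv <- as.character(binned[[cn]])
  train_levels <- as.character(train_levels %||% sort(unique(lv)))
  required <- unique(c(train_levels, test_levels))
  site_ids <- sort(as.integer(site_IDs_to_use %||% unique(binned$siteID)))
  missing_sites <- setdiff(site_ids, unique(binned$siteID))
  if (length(missing_sites)) {
    stop_pd("site_IDs_to_use not present in the binned data: ",
            paste(missing_sites, collapse = ", "))
  }
  need <- num_cv_splits * r
  # feasibility check up front: every used site must have >= k*r trials
  # of every required level
  info <- get_num_label_repetitions(binned, labels, required)
  cc <- info$counts[info$counts$siteID %in% site_ids, , drop = FALSE]
  short <- cc[cc$n_trials < need, , drop = FALSE]
  if (nrow(short) > 0) {
    ex <- short[1, ]
    stop_pd("datasource infeasible: ", nrow(short), " (site, level) pair(s) have ",
            "fewer than num_cv_splits * num_label_repeats_per_cv_split = ", need,
            " trials (e.g. site ", ex$siteID, ", level ", shQuote(ex$level),
            ": ", ex$n_trials, " trials). ",
            "Use get_siteIDs_with_k_label_repetitions() to pick usable sites.")
  }
  # per (site, level) binned row indices, precomputed once
  rows_by_site_level <- lapply(site_ids, function(s) {
    in_site <- binned$siteID == s
    lapply(setNames(required, required), function(l) which(in_site & lv == l))
  })
  names(rows_by_site_level) <- as.character(site_ids)
  structure(list(
    type = type, binned = binned, label = sub("^labels\\.", "", cn),
    label_col = cn, num_cv_splits = as.integer(num_cv_splits),
    num_label_repeats_per_cv_split = as.integer(r),
    train_levels = train_levels, test_levels = test_levels,
    classes = train_levels, site_ids = site_ids,
    rows_by_site_level = rows_by_site_level,
    time_info = binned_time_info(binned),
    data_matrix = binned_data_matrix(binned),
    seed = seed
  ), class = c(type, "decoding_datasource"))
}

#' @export
print.decoding_datasource <- function(x, ...) {
  cat(sprintf("%s: %d classes, %d sites, %d CV splits, %d repeat(s) per split, %d time bins\n",
              x$type, length(x$classes), length(x$site_ids), x$num_cv_splits,
              x$num_label_repeats_per_cv_split, nrow(x$time_info)))
  invisible(x)
}

#' Build one resample run's pseudo-population split data
#'
#' @param ds a datasource created by [ds_basic()] or
#'   [ds_generalization()].
#' @param run_index 1-based resample-run counter; different runs with
#'   the same seed draw different trial samples.
#' @param master_seed seed used when the datasource has none of its own
#'   (this is how [run_decoding()] passes its master seed down).
#' @return a `split_data` object: list with `train` and `test`, each
#'   holding `meta` (data frame class_idx, class_label, split, slot) and
#'   `data` (pseudo-trials x sites x time-bins array), plus `classes`,
#'   `site_ids`, `time_info`, `num_cv_splits`, and
#'   `num_label_repeats_per_cv_split`.  For `ds_basic` the test
#'   component is the training component itself: fold j tests on split
#'   j's pseudo-trials and trains on the others.
#' @export
get_split_data <- function(ds, run_index, master_seed = NULL) {
  UseMethod("get_split_data")
}

#' @export
get_split_data.ds_basic <- function(ds, run_index, master_seed = NULL) {
  seed <- ds$seed %||% master_seed
  if (is.null(seed)) stop_pd("no seed: set seed= on the datasource or pass master_seed")
  train <- sample_pseudo_population(ds, ds$train_levels, seed, run_index, role = 1L)
  structure(list(train = train, test = train, classes = ds$classes,
                 site_ids = ds$site_ids, time_info = ds$time_info,
                 num_cv_splits = ds$num_cv_splits,
                 num_label_repeats_per_cv_split = ds$num_label_repeats_per_cv_split,
                 run_index = run_index),
            class = "split_data")
}

#' @export
get_split_data.ds_generalization <- function(ds, run_index, master_seed = NULL) {
  seed <- ds$seed %||% master_seed
  if (is.null(seed)) stop_pd("no seed: set seed= on the datasource or pass master_seed")
  train <- sample_pseudo_population(ds, ds$train_levels, seed, run_index, role = 1L)
  test <- sample_pseudo_population(ds, ds$test_levels, seed, run_index, role = 2L)
  structure(list(train = train, test = test, classes = ds$classes,
                 site_ids = ds$site_ids, time_info = ds$time_info,
                 num_cv_splits = ds$num_cv_splits,
                 num_label_repeats_per_cv_split = ds$num_label_repeats_per_cv_split,
                 run_index = run_index),
            class = "split_data")
}

# Core sampler.  For each site independently (its own substream), draw
# k*r trial rows per level without replacement and deal them into the k
# splits (first r rows -> split 1, next r -> split 2, ...).  Returns
# meta + a pseudo-trials x sites x bins array in class-major,
# split-major, slot order.
sample_pseudo_population <- function(ds, levels, seed, run_index, role) {
  k <- ds$num_cv_splits
  r <- ds$num_label_repeats_per_cv_split
  C <- length(levels)
  S <- length(ds$site_ids)
  B <- nrow(ds$time_info)
  n <- C * k * r
  meta <- data.frame(
    class_idx = rep(seq_len(C), each = k * r),
    class_label = rep(ds$classes, each = k * r),
    split = rep(rep(seq_len(k), each = r), times = C),
    slot = rep(seq_len(r), times = C * k))
  arr <- array(NA_real_, dim = c(n, S, B))
  for (si in seq_len(S)) {
    site <- ds$site_ids[si]
    rows_by_level <- ds$rows_by_site_level[[as.character(site)]]
    picked <- with_substream(substream_seed(seed, run_index, site, role), {
      unlist(lapply(levels, function(l) {
        sample_exactly(rows_by_level[[l]], k * r)
      }), use.names = FALSE)
    })
    arr[, si, ] <- ds$data_matrix[picked, , drop = FALSE]
  }
  list(meta = meta, data = arr)
}
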