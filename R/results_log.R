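#' Save decoding results with a managed manifest
#'
#' Serializes a [run_decoding()] result to one plain-text archive
#' directory under `save_directory_name` (metric tables as CSV plus a
#' `parameters.json` record) and appends a row to the directory's
#' `manifest.csv`.  The manifest row carries the result name, a
#' timestamp, the archive path and the full flattened parameter map
#' (dotted keys, e.g. `datasource.num_cv_splits`), including the master
#' seed, so every saved result is re-derivable and searchable.
#'
#' Result names are unique keys (duplicates error); saving the same
#' *parameters* twice under different names is allowed but flagged in
#' the returned entry.  The manifest is written to a temporary file and
#' renamed, so a crashed save never leaves a partial row.
#'
#' @param results a `decoding_results` object.
#' @param save_directory_name directory for the log (created if needed).
#' @param result_name unique name for this result; default
#'   `"result_<n+1>"`.
#' @return invisibly, a `manifest_entry` list (`result_name`,
#'   `timestamp`, `file_path`, `parameters`,
#'   `duplicate_parameters` flag).
#' @export
log_save_results <- function(results, save_directory_name, result_name = NULL) {
  stopifnot(inherits(results, "decoding_results"))
  dir.create(save_directory_name, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(save_directory_name, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    data.table::fread(manifest_path, data.table = FALSE, colClasses = "character")
  }
  result_name <- result_name %||% sprintf("result_%d", nrow(manifest) %||% 0 + 1)
  if (!is.null(manifest) && result_name %in% manifest$result_name) {
    stop_pd("result_name ", shQuote(result_name), " already exists in the log; ",
            "result names are unique keys")
  }
  slug <- gsub("[^A-Za-z0-9._-]+", "_", result_name)
  archive <- file.path(save_directory_name, slug)
  if (dir.exists(archive)) stop_pd("archive directory already exists: ", archive)
  dir.create(archive)

  params <- results$cross_validation_parameters$parameter_df
  jsonlite::write_json(as.list(params), file.path(archive, "parameters.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(result_name, file.path(archive, "result_name.txt"))
  mr <- results$rm_main_results
  if (!is.null(mr)) {
    long <- main_results_to_long(mr)
    data.table::fwrite(long, file.path(archive, "main_results_mean.csv"))
    data.table::fwrite(mr$per_run, file.path(archive, "main_results_per_run.csv"))
    data.table::fwrite(mr$bin_info, file.path(archive, "bin_info.csv"))
    writeLines(mr$classes, file.path(archive, "classes.txt"))
    jsonlite::write_json(
      list(run_TCD = mr$run_TCD, num_cv_splits = mr$num_cv_splits,
           num_resample_runs = mr$num_resample_runs),
      file.path(archive, "main_results_meta.json"), auto_unbox = TRUE)
  }
  cm <- results$rm_confusion_matrix
  if (!is.null(cm)) {
    rows <- lapply(names(cm$matrices), function(bn) {
      tab <- as.data.frame(as.table(cm$matrices[[bn]]$counts),
                           stringsAsFactors = FALSE)
      names(tab) <- c("actual", "predicted", "count")
      cbind(train_bin = bn, tab)
    })
    data.table::fwrite(data.table::rbindlist(rows),
                       file.path(archive, "confusion_matrices.csv"))
  }

  flat <- vapply(as.list(params), function(v) as.character(v), character(1))
  dup <- FALSE
  if (!is.null(manifest) && nrow(manifest) > 0) {
    keys <- setdiff(names(manifest), c("result_name", "timestamp", "file_path"))
    for (i in seq_len(nrow(manifest))) {
      old <- unlist(manifest[i, keys, drop = FALSE])
      old <- old[!is.na(old) & old != ""]   # keys absent from that row's spec
      if (identical(sort(names(old)), sort(names(flat))) &&
          all(old[names(flat)] == flat)) { dup <- TRUE; break }
    }
  }
  entry <- data.frame(result_name = result_name,
                      timestamp = format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                      file_path = archive, t(flat),
                      check.names = FALSE, stringsAsFactors = FALSE)
  combined <- if (is.null(manifest)) entry else
    data.table::rbindlist(list(manifest, entry), use.names = TRUE, fill = TRUE)
  tmp <- paste0(manifest_path, ".tmp")
  data.table::fwrite(combined, tmp)
  file.rename(tmp, manifest_path)

  invisible(structure(list(result_name = result_name,
                           timestamp = entry$timestamp,
                           file_path = archive,
                           parameters = as.list(params),
                           duplicate_parameters = dup),
                      class = "manifest_entry"))
}

main_results_to_long <- function(mr) {
  grids <- which(!is.na(mr$accuracy), arr.ind = TRUE)
  data.frame(train_bin = grids[, 1], test_bin = grids[, 2],
             train_time = mr$bin_info$start[grids[, 1]],
             test_time = mr$bin_info$start[grids[, 2]],
             accuracy = mr$accuracy[grids],
             normalized_rank = mr$normalized_rank[grids],
             decision_value = mr$decision_values[grids])
}

read_manifest <- function(results_dir) {
  manifest_path <- file.path(results_dir, "manifest.csv")
  if (!file.exists(manifest_path)) {
    stop_pd("no manifest.csv in ", results_dir,
            " (is it a results directory created by log_save_results?)")
  }
  data.table::fread(manifest_path, data.table = FALSE, colClasses = "character")
}

#' Load saved decoding results by name
#'
#' @param result_name exact name used at save time (unknown names error
#'   with close matches listed).
#' @param results_dir directory managed by [log_save_results()].
#' @return a `decoding_results` object reconstructed from the archive.
#' @export
log_load_results_from_result_name <- function(result_name, results_dir) {
  manifest <- read_manifest(results_dir)
  i <- match(result_name, manifest$result_name)
  if (is.na(i)) {
    near <- agrep(result_name, manifest$result_name, value = TRUE,
                  max.distance = 0.3)
    stop_pd("no saved result named ", shQuote(result_name),
            if (length(near)) paste0("; did you mean: ",
                                     paste(shQuote(near), collapse = ", "), "?")
            else paste0("; available: ",
                        paste(shQuote(manifest$result_name), collapse = ", ")))
  }
  load_result_archive(manifest$file_path[i])
}

load_result_archive <- function(archive) {
  if (!dir.exists(archive)) stop_pd("result archive missing: ", archive)
  out <- list()
  mm <- file.path(archive, "main_results_mean.csv")
  if (file.exists(mm)) {
    long <- data.table::fread(mm, data.table = FALSE)
    bin_info <- data.table::fread(file.path(archive, "bin_info.csv"),
                                  data.table = FALSE)
    classes <- readLines(file.path(archive, "classes.txt"))
    meta <- jsonlite::read_json(file.path(archive, "main_results_meta.json"),
                                simplifyVector = TRUE)
    B <- nrow(bin_info)
    mk <- function(col) {
      m <- matrix(NA_real_, B, B, dimnames = list(bin_info$name, bin_info$name))
      m[cbind(long$train_bin, long$test_bin)] <- long[[col]]
      m
    }
    out$rm_main_results <- structure(list(
      accuracy = mk("accuracy"), normalized_rank = mk("normalized_rank"),
      decision_values = mk("decision_value"),
      per_run = data.table::fread(file.path(archive, "main_results_per_run.csv"),
                                  data.table = FALSE),
      bin_info = bin_info, classes = classes,
      run_TCD = isTRUE(meta$run_TCD), num_cv_splits = meta$num_cv_splits,
      num_resample_runs = meta$num_resample_runs), class = "main_results")
  }
  cmf <- file.path(archive, "confusion_matrices.csv")
  if (file.exists(cmf)) {
    long <- data.table::fread(cmf, data.table = FALSE,
                              colClasses = list(character = c("actual", "predicted")))
    bin_info <- data.table::fread(file.path(archive, "bin_info.csv"),
                                  data.table = FALSE)
    classes <- readLines(file.path(archive, "classes.txt"))
    mats <- lapply(split(long, long$train_bin), function(d) {
      counts <- matrix(0L, length(classes), length(classes),
                       dimnames = list(actual = classes, predicted = classes))
      counts[cbind(match(d$actual, classes), match(d$predicted, classes))] <- d$count
      rs <- rowSums(counts)
      structure(list(counts = counts,
                     proportions = counts / ifelse(rs == 0, 1, rs),
                     train_bin = d$train_bin[1]), class = "confusion_matrix")
    })
    mats <- mats[intersect(bin_info$name, names(mats))]
    out$rm_confusion_matrix <- structure(
      list(matrices = mats, bin_info = bin_info, classes = classes),
      class = "confusion_matrix_set")
  }
  params <- jsonlite::read_json(file.path(archive, "parameters.json"),
                                simplifyVector = TRUE)
  out$cross_validation_parameters <- list(
    parameter_df = as.data.frame(params, check.names = FALSE, optional = TRUE),
    seed = as.integer(params$seed))
  class(out) <- "decoding_results"
  out
}

#' Load saved decoding results by parameter values
#'
#' Filters the manifest for rows matching every supplied `key = value`
#' pair (dotted keys as stored in the manifest, e.g.
#' `datasource.num_cv_splits = 3`).  Exactly one row must match.
#'
#' @param param_subset named list of manifest key/value pairs; values
#'   are compared as character.
#' @param results_dir directory managed by [log_save_results()].
#' @return the matching `decoding_results` object.
#' @export
log_load_results_from_params <- function(param_subset, results_dir) {
  manifest <- read_manifest(results_dir)
  bad <- setdiff(names(param_subset), names(manifest))
  if (length(bad)) {
    stop_pd("unknown manifest key(s): ", paste(shQuote(bad), collapse = ", "),
            "; schema: ", paste(names(manifest), collapse = ", "))
  }
  keep <- rep(TRUE, nrow(manifest))
  for (k in names(param_subset)) {
    keep <- keep & manifest[[k]] == as.character(param_subset[[k]])
  }
  hits <- manifest$result_name[keep]
  if (length(hits) == 0) stop_pd("no saved result matches the given parameters")
  if (length(hits) > 1) {
    stop_pd("parameters match ", length(hits), " results: ",
            paste(shQuote(hits), collapse = ", "),
            "; add keys or use log_load_results_from_result_name()")
  }
  log_load_results_from_result_name(hits, results_dir)
}

#' Rebuild a manifest by scanning result archives
#'
#' Reconstructs `manifest.csv` from the `parameters.json` files of every
#' archive directory under `results_dir` (e.g. after a manifest is lost
#' or corrupted).  Timestamps are taken from the archive's modification
#' time.
#'
#' @param results_dir the results directory.
#' @return invisibly, the rebuilt manifest data frame.
#' @export
log_rebuild_manifest <- function(results_dir) {
  dirs <- list.dirs(results_dir, recursive = FALSE)
  rows <- list()
  for (d in dirs) {
    pj <- file.path(d, "parameters.json")
    if (!file.exists(pj)) next
    params <- jsonlite::read_json(pj, simplifyVector = TRUE)
    nm_file <- file.path(d, "result_name.txt")
    nm <- if (file.exists(nm_file)) readLines(nm_file)[1] else basename(d)
    rows[[length(rows) + 1]] <- data.frame(
      result_name = nm,
      timestamp = format(file.mtime(d), "%Y-%m-%d %H:%M:%S"),
      file_path = d,
      t(vapply(params, as.character, character(1))),
      check.names = FALSE, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop_pd("no result archives found under ", results_dir)
  manifest <- data.table::rbindlist(rows, use.names = TRUE, fill = TRUE)
  tmp <- file.path(results_dir, "manifest.csv.tmp")
  data.table::fwrite(manifest, tmp)
  file.rename(tmp, file.path(results_dir, "manifest.csv"))
  invisible(data.table::setDF(manifest))
}
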