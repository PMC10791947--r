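#' Read a raster-format file
#'
#' Raster format holds one recording site's data as a delimited table with
#' one row per trial.  Every column name must carry exactly one of three
#' prefixes: `site_info.` (site metadata, constant across trials),
#' `labels.` (per-trial experimental conditions), or `time.` (activity in
#' a half-open time window `time.<start>_<end>`, typically a 0/1 spike
#' indicator at 1 ms resolution).
#'
#' Time columns are returned sorted by window start; trial order is the
#' file's row order (trials are identified by 1-based row index, no trial
#' id column is required).
#'
#' @param path path to a CSV raster file with a header row.
#' @param strict if `TRUE` (default), error-severity validation issues
#'   (non-constant `site_info.` columns, gaps or overlaps between time
#'   windows, missing values) abort the read; with `strict = FALSE` the
#'   object is returned so it can be inspected with [validate_raster()].
#' @return a `raster_data` object (a `data.frame` subclass).
#' @seealso [validate_raster()], [raster_event_table()], [write_raster_data()]
#' @export
read_raster_data <- function(path, strict = TRUE) {
  if (!file.exists(path)) stop_pd("raster file not found: ", path)
  df <- tryCatch(
    data.table::fread(path, header = TRUE, check.names = FALSE, data.table = FALSE),
    error = function(e) stop_pd("could not parse raster file ", path, ": ", conditionMessage(e))
  )
  if (ncol(df) == 0 || any(!nzchar(names(df))) || any(grepl("^V[0-9]+$", names(df)))) {
    bad <- names(df)[!nzchar(names(df)) | grepl("^V[0-9]+$", names(df))]
    stop_pd("raster file ", path, " has a missing or garbled header",
            if (length(bad)) paste0(" (column(s): ", paste(shQuote(bad), collapse = ", "), ")"))
  }
  r <- as_raster_data(df, source = path)
  if (strict) {
    rep <- validate_raster(r)
    errs <- rep$issues[rep$issues$severity == "error", , drop = FALSE]
    if (nrow(errs) > 0) {
      stop_pd("invalid raster data in ", path, ":\n",
              paste(sprintf("  [%s] %s: %s", errs$severity, errs$column, errs$message),
                    collapse = "\n"))
    }
  }
  r
}

#' Construct a raster_data object from a data frame
#'
#' Checks the column-name grammar (a structural requirement) and sorts
#' time columns by window start.  Invariants beyond the grammar are the
#' business of [validate_raster()].
#'
#' @param df a data frame whose columns all start with `site_info.`,
#'   `labels.` or `time.`.
#' @param source optional provenance string (e.g. file path).
#' @return a `raster_data` object.
#' @export
as_raster_data <- function(df, source = NULL) {
  stopifnot(is.data.frame(df))
  nms <- names(df)
  bad <- nms[!grepl(PREFIX_RE, nms)]
  if (length(bad) > 0) {
    stop_pd("column(s) without a site_info./labels./time. prefix: ",
            paste(shQuote(bad), collapse = ", "))
  }
  tn <- nms[startsWith(nms, "time.")]
  tinfo <- parse_time_names(tn)
  ord <- order(tinfo$start)
  other <- nms[!startsWith(nms, "time.")]
  df <- df[, c(other[startsWith(other, "site_info.")],
               other[startsWith(other, "labels.")],
               tn[ord]), drop = FALSE]
  attr(df, "source") <- source
  class(df) <- c("raster_data", "data.frame")
  df
}

#' @export
print.raster_data <- function(x, ...) {
  ti <- raster_time_info(x)
  cat(sprintf("raster_data: %d trials x %d time windows [%d, %d) ms\n",
              nrow(x), nrow(ti), min(ti$start), max(ti$end)))
  si <- raster_site_info(x)
  if (length(si)) cat("  site_info:", paste(names(si), unlist(si), sep = "=", collapse = ", "), "\n")
  ln <- names(raster_labels(x))
  if (length(ln)) cat("  labels:", paste(ln, collapse = ", "), "\n")
  invisible(x)
}

#' Time-window table of a raster
#' @param raster a `raster_data` object.
#' @return data frame with columns `name`, `start`, `end` (ms, half-open
#'   windows, sorted by start).
#' @export
raster_time_info <- function(raster) {
  parse_time_names(names(raster)[startsWith(names(raster), "time.")])
}

#' @rdname raster_time_info
#' @return `raster_site_info()`: named list of the constant per-site values.
#' @export
raster_site_info <- function(raster) {
  cols <- names(raster)[startsWith(names(raster), "site_info.")]
  out <- lapply(cols, function(cn) raster[[cn]][1])
  names(out) <- sub("^site_info\\.", "", cols)
  out
}

#' @rdname raster_time_info
#' @return `raster_labels()`: data frame of the per-trial label columns
#'   (names stripped of the `labels.` prefix).
#' @export
raster_labels <- function(raster) {
  cols <- names(raster)[startsWith(names(raster), "labels.")]
  out <- as.data.frame(raster, check.names = FALSE)[, cols, drop = FALSE]
  names(out) <- sub("^labels\\.", "", cols)
  out
}

#' @rdname raster_time_info
#' @return `raster_data_matrix()`: the trials x time-windows activity matrix.
#' @export
raster_data_matrix <- function(raster) {
  cols <- names(raster)[startsWith(names(raster), "time.")]
  as.matrix(as.data.frame(raster, check.names = FALSE)[, cols, drop = FALSE])
}

#' Validate a raster table against the format invariants
#'
#' Pure function: all problems are reported, none raised.  Checked
#' invariants: column-name grammar; time windows ordered, non-overlapping
#' and contiguous at native resolution (a uniform stride larger than the
#' window width — a down-sampled raster — is reported as a warning, any
#' other gap or an overlap as an error); `site_info.` columns constant
#' across trials; at least one trial; no missing values.
#'
#' @param raster a `raster_data` object or plain data frame.
#' @return a `raster_validation` list with elements `ok` (no
#'   error-severity issues) and `issues` (data frame `severity`,
#'   `column`, `message`).
#' @export
validate_raster <- function(raster) {
  issues <- list()
  add <- function(severity, column, message) {
    issues[[length(issues) + 1]] <<- data.frame(
      severity = severity, column = column, message = message,
      stringsAsFactors = FALSE)
  }
  nms <- names(raster)
  bad <- nms[!grepl(PREFIX_RE, nms)]
  for (b in bad) add("error", b, "column name lacks a site_info./labels./time. prefix")

  tn <- nms[startsWith(nms, "time.")]
  tinfo <- tryCatch(parse_time_names(tn), error = function(e) NULL)
  if (is.null(tinfo)) {
    add("error", "time.*", "time column name(s) do not parse as time.<start>_<end>")
  } else if (nrow(tinfo) >= 1) {
    tinfo <- tinfo[order(tinfo$start), , drop = FALSE]
    if (any(tinfo$end <= tinfo$start)) {
      for (i in which(tinfo$end <= tinfo$start))
        add("error", tinfo$name[i], "window end must exceed window start")
    }
    if (nrow(tinfo) >= 2) {
      gaps <- tinfo$start[-1] - tinfo$end[-nrow(tinfo)]
      if (any(gaps < 0)) {
        for (i in which(gaps < 0))
          add("error", tinfo$name[i + 1], sprintf(
            "window overlaps the previous one (%s)", tinfo$name[i]))
      }
      if (any(gaps > 0)) {
        # a uniform-stride pattern needs at least two equal inter-window
        # gaps; a single gap is always a contiguity error
        if (length(gaps) >= 2 && all(gaps > 0) && length(unique(gaps)) == 1 &&
            length(unique(tinfo$end - tinfo$start)) == 1) {
          add("warning", "time.*", sprintf(
            "uniform stride of %d ms between windows: raster appears down-sampled, not contiguous",
            unique(gaps) + unique(tinfo$end - tinfo$start)))
        } else {
          for (i in which(gaps > 0))
            add("error", tinfo$name[i + 1], sprintf(
              "gap of %d ms after %s breaks contiguity", gaps[i], tinfo$name[i]))
        }
      }
    }
  }

  if (nrow(raster) < 1) add("error", "(table)", "raster must contain at least one trial")
  for (cn in nms[startsWith(nms, "site_info.")]) {
    if (nrow(raster) > 0 && length(unique(raster[[cn]])) > 1)
      add("error", cn, "site_info. column is not constant across trials")
  }
  na_cols <- nms[vapply(raster, function(col) anyNA(col), logical(1))]
  for (cn in na_cols) add("error", cn, "missing values are not allowed")

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), column = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "raster_validation")
}

#' @export
print.raster_validation <- function(x, ...) {
  cat(if (x$ok) "OK" else "INVALID", "-", nrow(x$issues), "issue(s)\n")
  if (nrow(x$issues) > 0) {
    cat(paste(sprintf("  [%s] %s: %s", x$issues$severity, x$issues$column,
                      x$issues$message), collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Spike-event table of a binary raster
#'
#' Converts a 0/1 spike-indicator raster into a long table with one row
#' per action potential, the representation behind the classic raster
#' plot (trials on the y axis, time on the x axis, one tick per spike).
#'
#' @param raster a `raster_data` object with 0/1 entries.
#' @return data frame with columns `trial_index` (1-based row order) and
#'   `event_time_ms` (the start of the window containing the spike).
#' @export
raster_event_table <- function(raster) {
  m <- raster_data_matrix(raster)
  if (!all(m %in% c(0, 1))) {
    stop_pd("event plots require spike-indicator (0/1) data; ",
            "this raster contains other values")
  }
  ti <- raster_time_info(raster)
  idx <- which(m == 1, arr.ind = TRUE)
  out <- data.frame(trial_index = as.integer(idx[, 1]),
                    event_time_ms = ti$start[idx[, 2]])
  out <- out[order(out$trial_index, out$event_time_ms), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Plot a raster as spike ticks
#'
#' @param x a `raster_data` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.raster_data <- function(x, ...) {
  ev <- raster_event_table(x)
  ggplot(ev, aes(x = .data$event_time_ms, y = .data$trial_index)) +
    geom_point(shape = "|", size = 2) +
    labs(x = "Time (ms)", y = "Trial") +
    theme_classic()
}

#' Write a raster table to CSV
#'
#' The written file round-trips through [read_raster_data()]: values,
#' column order within each prefix group and trial order are preserved
#' exactly.
#'
#' @param raster a `raster_data` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_raster_data <- function(raster, path) {
  data.table::fwrite(as.data.frame(raster, check.names = FALSE), path)
  invisible(path)
}
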