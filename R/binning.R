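#' Bin one site's raster into sliding time windows
#'
#' Averages (or sums) raw activity in windows of `bin_width` ms placed
#' every `sampling_interval` ms.  Bins start at the raster's first window
#' start (or `start_time`) and advance by `sampling_interval`; a bin
#' keeps every native window fully inside `[start, start + bin_width)`.
#' Trailing bins that would overrun the raster (or `end_time`) are
#' dropped, never padded, so every bin aggregates exactly
#' `bin_width / native_width` samples.  Bin columns are named
#' `time.<start>_<start + bin_width>`: a millisecond raster starting at
#' 1 ms binned with width 30 and interval 10 yields `time.1_31`,
#' `time.11_41`, `time.21_51`, ...
#'
#' @param raster a `raster_data` object.
#' @param bin_width window width in ms (>= 1).
#' @param sampling_interval step between successive bin starts in ms (>= 1).
#' @param start_time,end_time optional bounds (ms) on the binned range;
#'   `start_time` must not precede the raster start, `end_time` must not
#'   exceed the raster end.
#' @param aggregate `"mean"` (default; firing-rate semantics) or `"sum"`
#'   (spike counts, as the Poisson naive Bayes classifier requires).
#' @return a data frame with the raster's `site_info.` and `labels.`
#'   columns plus one `time.` column per bin.
#' @export
bin_site <- function(raster, bin_width, sampling_interval,
                     start_time = NULL, end_time = NULL,
                     aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  stopifnot(bin_width >= 1, sampling_interval >= 1)
  ti <- raster_time_info(raster)
  r_start <- min(ti$start)
  r_end <- max(ti$end)
  t0 <- start_time %||% r_start
  t_max <- end_time %||% r_end
  if (t0 < r_start) {
    stop_pd("start_time (", t0, ") precedes the raster start (", r_start, ")")
  }
  if (t_max > r_end) {
    stop_pd("end_time (", t_max, ") exceeds the raster end (", r_end, ")")
  }
  starts <- seq(from = t0, by = sampling_interval,
                length.out = max(0, floor((t_max - bin_width - t0) / sampling_interval) + 1))
  if (length(starts) == 0) {
    stop_pd("bin_width (", bin_width, ") is longer than the available raster span [",
            t0, ", ", t_max, ")")
  }
  m <- raster_data_matrix(raster)
  # native window j contributes to bin b iff fully inside the bin
  agg <- matrix(0, nrow = nrow(m), ncol = length(starts))
  for (b in seq_along(starts)) {
    inside <- ti$start >= starts[b] & ti$end <= starts[b] + bin_width
    v <- m[, inside, drop = FALSE]
    agg[, b] <- if (aggregate == "mean") rowMeans(v) else rowSums(v)
  }
  colnames(agg) <- time_col_name(as.integer(starts), as.integer(starts + bin_width))
  keep <- names(raster)[!startsWith(names(raster), "time.")]
  out <- cbind(as.data.frame(raster, check.names = FALSE)[, keep, drop = FALSE],
               as.data.frame(agg, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Bin a directory of raster files into one binned-format table
#'
#' Reads every `.csv` raster in `raster_dir` (lexicographically sorted
#' file names are assigned `siteID` 1..N), bins each site with
#' [bin_site()], stacks the results, and writes a single binned-format
#' CSV named `<save_prefix>_<bin_width>bins_<sampling_interval>sampled.csv`
#' plus a sidecar sites manifest
#' `<save_prefix>_<bin_width>bins_<sampling_interval>sampled_sites.csv`
#' recording (siteID, file, site_info columns).
#'
#' @inheritParams bin_site
#' @param raster_dir directory containing >= 1 raster CSV file.
#' @param save_prefix path prefix for the output file (may include a
#'   directory).
#' @return the path of the written binned-format CSV.
#' @export
create_binned_data <- function(raster_dir, save_prefix, bin_width, sampling_interval,
                               start_time = NULL, end_time = NULL,
                               aggregate = c("mean", "sum")) {
  aggregate <- match.arg(aggregate)
  files <- sort(list.files(raster_dir, pattern = "\\.csv$", full.names = FALSE))
  if (length(files) == 0) stop_pd("no raster .csv files found in ", raster_dir)
  pieces <- vector("list", length(files))
  manifests <- vector("list", length(files))
  bin_cols <- NULL
  for (i in seq_along(files)) {
    r <- read_raster_data(file.path(raster_dir, files[i]))
    b <- tryCatch(
      bin_site(r, bin_width, sampling_interval, start_time, end_time, aggregate),
      error = function(e) stop_pd("binning failed for ", files[i], ": ",
                                  conditionMessage(e)))
    these <- names(b)[startsWith(names(b), "time.")]
    if (is.null(bin_cols)) {
      bin_cols <- these
    } else if (!identical(bin_cols, these)) {
      stop_pd("raster files have incompatible time ranges: ", files[1],
              " vs ", files[i], " produce different bin columns")
    }
    pieces[[i]] <- cbind(siteID = i, b)
    si <- raster_site_info(r)
    manifests[[i]] <- cbind(data.frame(siteID = i, file = files[i],
                                       stringsAsFactors = FALSE),
                            as.data.frame(si, check.names = FALSE))
  }
  binned <- data.table::rbindlist(pieces, use.names = TRUE, fill = TRUE)
  base <- sprintf("%s_%dbins_%dsampled", save_prefix, bin_width, sampling_interval)
  out_path <- paste0(base, ".csv")
  data.table::fwrite(binned, out_path)
  data.table::fwrite(data.table::rbindlist(manifests, use.names = TRUE, fill = TRUE),
                     paste0(base, "_sites.csv"))
  out_path
}

#' Read a binned-format table
#'
#' Binned format stacks all recording sites as rows: a `siteID` column,
#' the carried-over `site_info.` and `labels.` columns, and one `time.`
#' column per bin.
#'
#' @param binned a path to a binned CSV, or an already-loaded data frame
#'   (returned unchanged apart from the class tag).
#' @return a `binned_data` object (a `data.frame` subclass).
#' @export
read_binned_data <- function(binned) {
  if (is.character(binned)) {
    if (!file.exists(binned)) stop_pd("binned file not found: ", binned)
    binned <- data.table::fread(binned, header = TRUE, check.names = FALSE,
                                data.table = FALSE)
  }
  stopifnot(is.data.frame(binned))
  if (!"siteID" %in% names(binned)) stop_pd("binned data must contain a siteID column")
  class(binned) <- c("binned_data", "data.frame")
  binned
}

binned_time_info <- function(binned) {
  parse_time_names(names(binned)[startsWith(names(binned), "time.")])
}

binned_label_column <- function(binned, label) {
  cn <- if (startsWith(label, "labels.")) label else paste0("labels.", label)
  if (!cn %in% names(binned)) {
    stop_pd("label ", shQuote(label), " not found; available: ",
            paste(sub("^labels\\.", "", names(binned)[startsWith(names(binned), "labels.")]),
                  collapse = ", "))
  }
  cn
}

binned_data_matrix <- function(binned) {
  cols <- names(binned)[startsWith(names(binned), "time.")]
  as.matrix(as.data.frame(binned, check.names = FALSE)[, cols, drop = FALSE])
}
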