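#' Count per-site label repetitions
#'
#' For pseudo-population decoding with k cross-validation splits, every
#' site used must have at least k (times the repeats-per-split factor)
#' trials of every label level.  This function tallies, for every site
#' and level, how many trials were recorded, the first step in choosing
#' k and the usable sites.
#'
#' When `label_levels` is supplied, all other levels are ignored; a site
#' lacking one of the requested levels gets a count of 0 for it (and
#' hence a per-site minimum of 0) rather than being dropped silently.
#'
#' @param binned_data a binned-format path or data frame.
#' @param labels name of the label variable (with or without the
#'   `labels.` prefix).
#' @param label_levels optional character vector restricting the levels
#'   considered; defaults to every level present in the data.
#' @return a `label_repetitions` object: list with `counts` (data frame
#'   siteID, level, n_trials), `min_reps` (siteID, min_reps = minimum
#'   over levels), `levels`, and `label`.
#' @export
get_num_label_repetitions <- function(binned_data, labels, label_levels = NULL) {
  binned <- read_binned_data(binned_data)
  cn <- binned_label_column(binned, labels)
  lv <- as.character(binned[[cn]])
  levels_all <- sort(unique(lv))
  if (is.null(label_levels)) {
    label_levels <- levels_all
  } else {
    missing_lv <- setdiff(label_levels, levels_all)
    if (length(missing_lv) == length(label_levels)) {
      stop_pd("none of the requested levels occur in the data: ",
              paste(shQuote(missing_lv), collapse = ", "))
    }
  }
  sites <- sort(unique(binned$siteID))
  keep <- lv %in% label_levels
  tab <- table(factor(binned$siteID[keep], levels = sites),
               factor(lv[keep], levels = label_levels))
  counts <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(counts) <- c("siteID", "level", "n_trials")
  counts$siteID <- as.integer(as.character(counts$siteID))
  counts <- counts[order(counts$siteID, counts$level), , drop = FALSE]
  rownames(counts) <- NULL
  mins <- apply(tab, 1, min)
  min_reps <- data.frame(siteID = sites, min_reps = as.integer(mins))
  rownames(min_reps) <- NULL
  structure(list(counts = counts, min_reps = min_reps,
                 levels = label_levels, label = sub("^labels\\.", "", cn)),
            class = "label_repetitions")
}

#' @export
print.label_repetitions <- function(x, ...) {
  cat(sprintf("label_repetitions for %s: %d sites x %d levels; per-site min %d..%d\n",
              shQuote(x$label), nrow(x$min_reps), length(x$levels),
              min(x$min_reps$min_reps), max(x$min_reps$min_reps)))
  invisible(x)
}

#' Sites with at least k repetitions of every level
#'
#' @param info a `label_repetitions` object.
#' @param k minimum number of repetitions required (>= 1).
#' @return ascending integer vector of qualifying siteIDs.
#' @export
sites_with_k_repetitions <- function(info, k) {
  stopifnot(inherits(info, "label_repetitions"), k >= 1)
  sort(info$min_reps$siteID[info$min_reps$min_reps >= k])
}

#' @describeIn sites_with_k_repetitions convenience wrapper that tallies
#'   and filters in one call.
#' @inheritParams get_num_label_repetitions
#' @export
get_siteIDs_with_k_label_repetitions <- function(binned_data, labels, k,
                                                 label_levels = NULL) {
  sites_with_k_repetitions(
    get_num_label_repetitions(binned_data, labels, label_levels), k)
}

#' Sites-available-versus-k trade-off curve
#'
#' For each k, counts how many sites have at least k repetitions of each
#' individual level, and — the `"ALL"` rows — of every level at once.
#' The ALL curve is the one used to choose the number of cross-validation
#' splits: with k splits, only sites on or above the ALL curve at k can
#' enter the analysis.
#'
#' @param info a `label_repetitions` object.
#' @param max_k largest k tabulated; defaults to one past the largest
#'   observed count so every curve reaches zero.
#' @return data frame (k, level, n_sites) where `level` is a level name
#'   or `"ALL"`; `n_sites` is non-increasing in k within each level, and
#'   the ALL value never exceeds any per-level value at the same k.
#' @export
repetition_curve <- function(info, max_k = NULL) {
  stopifnot(inherits(info, "label_repetitions"))
  max_k <- max_k %||% (max(info$counts$n_trials) + 1L)
  ks <- seq_len(max_k)
  per_level <- do.call(rbind, lapply(ks, function(kk) {
    n_by_level <- vapply(split(info$counts$n_trials >= kk, info$counts$level),
                         sum, integer(1))
    data.frame(k = kk, level = names(n_by_level),
               n_sites = as.integer(n_by_level), stringsAsFactors = FALSE)
  }))
  all_rows <- data.frame(
    k = ks, level = "ALL",
    n_sites = vapply(ks, function(kk) sum(info$min_reps$min_reps >= kk), integer(1)))
  out <- rbind(all_rows, per_level)
  rownames(out) <- NULL
  out
}

#' Plot the repetition trade-off curve
#'
#' One colored line per label level plus a black dashed line for the
#' ALL-levels curve.
#'
#' @param x a `label_repetitions` object.
#' @param show_legend show the per-level color legend (off by default;
#'   with hundreds of levels it swamps the plot).
#' @param ... unused.
#' @return a ggplot object.
#' @export
plot.label_repetitions <- function(x, show_legend = FALSE, ...) {
  curve <- repetition_curve(x)
  lv <- curve[curve$level != "ALL", , drop = FALSE]
  all_c <- curve[curve$level == "ALL", , drop = FALSE]
  p <- ggplot(lv, aes(x = k, y = n_sites, color = level)) +
    geom_line() +
    geom_line(data = all_c, aes(x = k, y = n_sites),
              color = "black", linetype = "dashed", linewidth = 1,
              inherit.aes = FALSE) +
    labs(x = "Number of repetitions (k)", y = "Number of sites with >= k repetitions") +
    theme_classic()
  if (!show_legend) p <- p + theme(legend.position = "none")
  p
}
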