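ORIENTATION_NAMES <- c("left profile", "left three quarter", "frontal",
                       "right three quarter", "right profile",
                       "head up", "head down", "back")

#' Describe a synthetic tuned-neuron experiment
#'
#' The generator emulates a face-views-style design: a randomized
#' sequence of images of `n_people` individuals seen from
#' `n_orientations` head orientations, shown for `stimulus_on_ms` with
#' an `isi_ms` inter-stimulus interval, recorded as millisecond spike
#' rasters from independently tuned Poisson-spiking sites with a
#' response latency.  Each site has a preferred (orientation, person)
#' pair; its firing rate is `baseline_rate_hz` before the response
#' latency, jumps during the response window to `baseline +
#' (peak - baseline) * similarity` (Gaussian similarity in circular
#' person/orientation index distance with the given tuning widths), and
#' decays exponentially (`decay_tau_ms`) back to baseline after the
#' stimulus turns off.  With `orientation_invariant = TRUE` the tuning
#' ignores orientation entirely, the ground truth for a generalization
#' analysis across orientations.
#'
#' Setting `peak_rate_hz = baseline_rate_hz` removes all stimulus
#' signal: downstream decoding must then sit at chance.
#'
#' @param n_sites number of recording sites (one raster file each).
#' @param n_orientations,n_people stimulus grid (defaults 8 x 25, i.e.
#'   200 combined orientation x person label levels).
#' @param trials_per_stimulus a single count, or a length-2 range
#'   `c(lo, hi)` from which each (site, stimulus) count is drawn
#'   uniformly — emulating the unequal repetitions of sites recorded in
#'   different sessions.
#' @param trial_length_ms raster length per trial (default 800 ms: a
#'   200 ms stimulus + 200 ms ISI cycle with room to see the next
#'   stimulus' response).
#' @param stimulus_on_ms,isi_ms,latency_ms stimulus timing (defaults
#'   200/200/150 ms).
#' @param baseline_rate_hz,peak_rate_hz firing rates (defaults 5/50 Hz).
#' @param person_tuning_width,orientation_tuning_width Gaussian tuning
#'   widths in index units (default 1.5).
#' @param orientation_invariant tuning ignores orientation.
#' @param decay_tau_ms post-stimulus decay constant (default 100 ms).
#' @param seed master seed; generation is deterministic given the
#'   design.
#' @return a `synthetic_design` list.
#' @export
synthetic_design <- function(n_sites = 20, n_orientations = 8, n_people = 25,
                             trials_per_stimulus = 3, trial_length_ms = 800,
                             stimulus_on_ms = 200, isi_ms = 200,
                             latency_ms = 150, baseline_rate_hz = 5,
                             peak_rate_hz = 50, person_tuning_width = 1.5,
                             orientation_tuning_width = 1.5,
                             orientation_invariant = FALSE,
                             decay_tau_ms = 100, seed = 1) {
  stopifnot(n_sites >= 1, n_orientations >= 1, n_people >= 1,
            baseline_rate_hz >= 0, peak_rate_hz >= 0,
            latency_ms < trial_length_ms,
            length(trials_per_stimulus) %in% c(1, 2),
            all(trials_per_stimulus >= 1))
  if (max(baseline_rate_hz, peak_rate_hz) / 1000 >= 1) {
    stop_pd("rate * 1 ms >= 1: the Bernoulli-per-ms spike approximation needs ",
            "rates below 1000 Hz")
  }
  orientations <- if (n_orientations <= length(ORIENTATION_NAMES)) {
    ORIENTATION_NAMES[seq_len(n_orientations)]
  } else {
    c(ORIENTATION_NAMES, paste("orientation", seq_len(n_orientations -
                                                        length(ORIENTATION_NAMES)) +
                                 length(ORIENTATION_NAMES)))
  }
  structure(list(
    n_sites = n_sites, n_orientations = n_orientations, n_people = n_people,
    orientations = orientations,
    trials_per_stimulus = trials_per_stimulus,
    trial_length_ms = trial_length_ms, stimulus_on_ms = stimulus_on_ms,
    isi_ms = isi_ms, latency_ms = latency_ms,
    baseline_rate_hz = baseline_rate_hz, peak_rate_hz = peak_rate_hz,
    person_tuning_width = person_tuning_width,
    orientation_tuning_width = orientation_tuning_width,
    orientation_invariant = orientation_invariant,
    decay_tau_ms = decay_tau_ms, seed = seed
  ), class = "synthetic_design")
}

circ_dist <- function(i, j, n) pmin(abs(i - j), n - abs(i - j))

# firing-rate profile (Hz) over the trial for one stimulus at one site
site_rate_profile <- function(design, pref_orient, pref_person, orient, person) {
  d <- design
  sim_p <- exp(-circ_dist(person, pref_person, d$n_people)^2 /
                 (2 * d$person_tuning_width^2))
  sim_o <- if (d$orientation_invariant) 1 else
    exp(-circ_dist(orient, pref_orient, d$n_orientations)^2 /
          (2 * d$orientation_tuning_width^2))
  resp <- d$baseline_rate_hz + (d$peak_rate_hz - d$baseline_rate_hz) * sim_p * sim_o
  t <- seq_len(d$trial_length_ms) - 1
  off <- d$latency_ms + d$stimulus_on_ms
  rate <- rep(d$baseline_rate_hz, d$trial_length_ms)
  rate[t >= d$latency_ms & t < off] <- resp
  after <- t >= off
  rate[after] <- d$baseline_rate_hz +
    (resp - d$baseline_rate_hz) * exp(-(t[after] - off) / d$decay_tau_ms)
  rate
}

#' Generate a directory of synthetic raster files
#'
#' Writes one raster CSV per site at 1 ms resolution (time columns
#' `time.0_1` ... so stimulus onset is t = 0).  Spikes are drawn from an
#' inhomogeneous Bernoulli-per-millisecond approximation of a Poisson
#' process (valid while rate x 1 ms << 1), which keeps rasters binary as
#' the format expects.  Every site draws from its own (seed, site)
#' substream, so the output is deterministic given the design,
#' regardless of evaluation order.
#'
#' @param design a [synthetic_design()].
#' @param out_dir output directory (created if needed).
#' @return character vector of the written file paths (sorted, the
#'   order in which [create_binned_data()] will assign siteIDs).
#' @export
generate_raster_dir <- function(design, out_dir) {
  stopifnot(inherits(design, "synthetic_design"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  d <- design
  stims <- expand.grid(person = seq_len(d$n_people),
                       orient = seq_len(d$n_orientations))
  time_cols <- time_col_name(seq_len(d$trial_length_ms) - 1L,
                             seq_len(d$trial_length_ms))
  paths <- character(d$n_sites)
  for (site in seq_len(d$n_sites)) {
    path <- file.path(out_dir, sprintf("raster_synthetic_site_%04d.csv", site))
    with_substream(substream_seed(d$seed, "site", site), {
      pref_person <- sample.int(d$n_people, 1)
      pref_orient <- sample.int(d$n_orientations, 1)
      reps <- if (length(d$trials_per_stimulus) == 1) {
        rep(d$trials_per_stimulus, nrow(stims))
      } else {
        sample(seq(d$trials_per_stimulus[1], d$trials_per_stimulus[2]),
               nrow(stims), replace = TRUE)
      }
      trial_stim <- rep(seq_len(nrow(stims)), times = reps)
      trial_stim <- sample_exactly(trial_stim, length(trial_stim)) # randomized order
      spikes <- matrix(0L, nrow = length(trial_stim), ncol = d$trial_length_ms)
      probs <- lapply(seq_len(nrow(stims)), function(si) {
        site_rate_profile(d, pref_orient, pref_person,
                          stims$orient[si], stims$person[si]) / 1000
      })
      for (i in seq_along(trial_stim)) {
        spikes[i, ] <- as.integer(stats::runif(d$trial_length_ms) <
                                    probs[[trial_stim[i]]])
      }
      orient_name <- d$orientations[stims$orient[trial_stim]]
      person_idx <- stims$person[trial_stim]
      df <- data.frame(
        "site_info.monkey" = "synthetic_m1",
        "site_info.region" = "synthetic_AM",
        "site_info.site_id" = sprintf("site_%04d", site),
        "labels.orientation" = orient_name,
        "labels.person" = paste("person", person_idx),
        "labels.orient_person_combo" = paste(orient_name, person_idx),
        check.names = FALSE, stringsAsFactors = FALSE)
      df <- cbind(df, as.data.frame(`colnames<-`(spikes, time_cols),
                                    check.names = FALSE))
      data.table::fwrite(df, path)
    })
    paths[site] <- path
  }
  sort(paths)
}

#' Shuffle a label column independently within each site
#'
#' Destroys any relationship between neural activity and the label while
#' preserving every site's label counts, so downstream decoding of that
#' label must sit at the 1/C chance level.  Deterministic per-(seed,
#' site) substreams.
#'
#' @param binned_data binned-format path or data frame.
#' @param labels the label variable to shuffle.
#' @param seed RNG seed.
#' @return the `binned_data` object with the label column permuted
#'   within each site.
#' @export
shuffle_binned_labels <- function(binned_data, labels, seed) {
  binned <- read_binned_data(binned_data)
  cn <- binned_label_column(binned, labels)
  for (s in unique(binned$siteID)) {
    rows <- which(binned$siteID == s)
    perm <- with_substream(substream_seed(seed, "shuffle", s),
                           sample.int(length(rows)))
    binned[[cn]][rows] <- binned[[cn]][rows][perm]
  }
  binned
}

#' Small fixtures with hand-computed ground truth
#'
#' A catalog of tiny in-memory datasets paired with the answers a
#' correct pipeline must produce, used by the unit tests:
#'
#' * `"two-class-separable"` — 4 sites, 2 linearly separated classes, 2
#'   time bins; expected same-time zero-one accuracy 1.0.
#' * `"tie-degenerate"` — all-zero features, 5 classes; every decision
#'   is a tie, so expected accuracy is chance 1/5.
#' * `"three-split-counts"` — 5 sites x 3 levels with hand-chosen
#'   repetition counts; expected qualifying sites for each k were
#'   tallied by an independent loop at construction.
#'
#' @param name fixture name from the catalog above.
#' @return list with `binned` (a `binned_data` data frame), `label`,
#'   and `expected` (fixture-specific ground truth).
#' @export
generate_worked_fixture <- function(name) {
  switch(name,
    "two-class-separable" = {
      n_sites <- 4; reps <- 6
      rows <- list()
      with_substream(90210, {
        for (s in seq_len(n_sites)) {
          for (cls in c("A", "B")) {
            # alternate each site's preferred class so the two class
            # *patterns* differ (a uniform offset would be invisible to
            # the correlation classifier, which is affine-invariant)
            base <- if (xor(cls == "A", s %% 2 == 0)) 5 else 1
            for (i in seq_len(reps)) {
              rows[[length(rows) + 1]] <- data.frame(
                siteID = s, "labels.stim" = cls,
                "time.0_10" = base + stats::runif(1, -0.5, 0.5),
                "time.10_20" = base + stats::runif(1, -0.5, 0.5),
                check.names = FALSE, stringsAsFactors = FALSE)
            }
          }
        }
      })
      list(binned = read_binned_data(do.call(rbind, rows)), label = "stim",
           expected = list(accuracy = 1.0, num_cv_splits = 3, chance = 0.5))
    },
    "tie-degenerate" = {
      classes <- paste("person", 1:5)
      grid <- expand.grid(siteID = 1:4, "labels.person" = classes,
                          rep = 1:6, stringsAsFactors = FALSE)
      binned <- data.frame(siteID = grid$siteID,
                           "labels.person" = grid[["labels.person"]],
                           "time.0_10" = 0, "time.10_20" = 0,
                           check.names = FALSE, stringsAsFactors = FALSE)
      list(binned = read_binned_data(binned), label = "person",
           expected = list(chance = 1 / 5, num_cv_splits = 3))
    },
    "three-split-counts" = {
      # counts[site, level]: repetitions of each level at each site
      counts <- matrix(c(3, 3, 3,
                         4, 5, 3,
                         2, 6, 6,
                         1, 1, 1,
                         5, 4, 4), nrow = 5, byrow = TRUE)
      levels <- c("alpha", "beta", "gamma")
      rows <- list()
      for (s in 1:5) for (l in 1:3) {
        n <- counts[s, l]
        if (n > 0) rows[[length(rows) + 1]] <- data.frame(
          siteID = s, "labels.cond" = levels[l],
          "time.0_5" = seq_len(n) * 0.1, check.names = FALSE,
          stringsAsFactors = FALSE)
      }
      # independent brute-force tally of the expected answers
      expected_sites <- lapply(1:6, function(kk) {
        out <- integer(0)
        for (s in 1:5) {
          ok <- TRUE
          for (l in 1:3) if (counts[s, l] < kk) ok <- FALSE
          if (ok) out <- c(out, s)
        }
        out
      })
      list(binned = read_binned_data(do.call(rbind, rows)), label = "cond",
           expected = list(counts = counts, levels = levels,
                           sites_with_k = expected_sites))
    },
    stop_pd("unknown fixture ", shQuote(name), "; catalog: two-class-separable, ",
            "tie-degenerate, three-split-counts"))
}
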