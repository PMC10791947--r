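`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic 32-bit substream seed derived from a master seed and an
# arbitrary sequence of integer or character ids.  Used so that every
# random draw in the package (trial sampling, tie-breaking, synthetic
# spikes) depends only on (master seed, logical position), never on
# worker scheduling or evaluation order.  Constants: multiplier from the
# classic 69069 LCG, modulus 2147483563 (< 2^31, products stay exact in
# doubles).
substream_seed <- function(master, ...) {
  ids <- list(master, ...)
  s <- 0
  for (x in ids) {
    if (is.character(x)) x <- sum(utf8ToInt(paste(x, collapse = ""))) else x <- as.numeric(x)
    for (xi in x) s <- (s * 69069 + (abs(xi) %% 2147483563) + 1) %% 2147483563
  }
  as.integer(s %% 2147483562 + 1)
}

# Evaluate `code` with the global RNG temporarily seeded by `seed`,
# restoring the caller's RNG state afterwards.
with_substream <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# sample() that never triggers base R's length-1 surprise
sample_exactly <- function(x, n) x[sample.int(length(x), n)]

stop_pd <- function(..., call. = FALSE) stop(..., call. = call.)

is_wholenumber <- function(x, tol = 1e-8) {
  is.numeric(x) && all(is.finite(x)) && all(abs(x - round(x)) < tol)
}

# column-name grammar shared by raster and binned tables
PREFIX_RE <- "^(site_info|labels|time)\\."
TIME_RE <- "^time\\.(-?[0-9]+)_(-?[0-9]+)$"

parse_time_names <- function(nms) {
  ok <- grepl(TIME_RE, nms)
  if (!all(ok)) {
    stop_pd("malformed time column name(s): ", paste(nms[!ok], collapse = ", "),
            " (expected time.<start>_<end> with integer bounds)")
  }
  start <- as.integer(sub(TIME_RE, "\\1", nms))
  end <- as.integer(sub(TIME_RE, "\\2", nms))
  data.frame(name = nms, start = start, end = end, stringsAsFactors = FALSE)
}

time_col_name <- function(start, end) sprintf("time.%d_%d", start, end)
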