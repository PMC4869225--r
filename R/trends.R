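# Daily keyword-mention series per channel, max-normalization, spike
# detection and cross-channel spike matching. This replaces a visual
# comparison of two trend lines with an explicit, deterministic procedure.

#' Construct a daily mention series
#'
#' @param channel Channel label (for example `"twitter"`, `"newspapers"`).
#' @param dates Strictly increasing, gap-free sequence of calendar days.
#' @param counts Non-negative integer mention count per day.
#' @param normalized Optional normalized values (filled by
#'   [normalize_series()]).
#' @return A `mention_series`: list with `channel`, `dates`, `counts`,
#'   `normalized` (NA until normalized).
#' @export
mention_series <- function(channel, dates, counts, normalized = NULL) {
  dates <- as.Date(dates)
  if (length(dates) != length(counts)) {
    stop("dates and counts must have equal length", call. = FALSE)
  }
  if (length(dates) > 1 && any(diff(dates) != 1)) {
    stop("dates must be strictly increasing and gap-free", call. = FALSE)
  }
  if (any(!is_count(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  structure(list(channel = channel, dates = dates,
                 counts = as.numeric(counts),
                 normalized = if (is.null(normalized))
                   rep(NA_real_, length(counts)) else normalized),
            class = "mention_series")
}

#' @export
print.mention_series <- function(x, ...) {
  cat(sprintf("Mention series '%s': %d days (%s to %s), %g mentions\n",
              x$channel, length(x$dates),
              format(min(x$dates)), format(max(x$dates)), sum(x$counts)))
  invisible(x)
}

#' Count keyword mentions per day over a window
#'
#' Bins dated keyword-bearing items into one count per calendar day across
#' the whole window; days with no items count 0. Items outside the window
#' are excluded with a message. When `texts` and `keywords` are given, only
#' items with at least one keyword match are counted.
#'
#' @param timestamps Item date-times (ISO-8601 strings, dates, or
#'   date-times); compared at day granularity.
#' @param window_start,window_end First and last day of the window
#'   (inclusive).
#' @param channel Channel label for the series.
#' @param texts Optional item texts for keyword filtering.
#' @param keywords Optional tracked keyword set.
#' @return A [mention_series()] covering every day of the window.
#' @export
daily_mention_counts <- function(timestamps, window_start, window_end,
                                 channel = "channel",
                                 texts = NULL, keywords = NULL) {
  window_start <- as.Date(window_start)
  window_end <- as.Date(window_end)
  if (window_end < window_start) stop("empty window", call. = FALSE)
  days <- seq(window_start, window_end, by = "day")
  d <- as.Date(substr(as.character(timestamps), 1, 10))
  keep <- rep(TRUE, length(d))
  if (!is.null(keywords)) {
    if (is.null(texts)) stop("texts required for keyword filtering",
                             call. = FALSE)
    keep <- vapply(match_keywords(texts, keywords), length, integer(1)) > 0
  }
  outside <- keep & (d < window_start | d > window_end)
  if (any(outside)) {
    message(sum(outside), " item(s) outside the window were excluded")
  }
  keep <- keep & !outside
  counts <- tabulate(match(d[keep], days), nbins = length(days))
  mention_series(channel, days, counts)
}

#' Max-normalize a mention series
#'
#' Divides every daily count by the series maximum, mapping the busiest day
#' to 1 and making channels of very different volumes comparable on one
#' plot. An all-zero series stays all zero, with a warning.
#'
#' @param s A [mention_series()].
#' @return The series with `normalized` filled (values in `[0, 1]`).
#' @export
normalize_series <- function(s) {
  stopifnot(inherits(s, "mention_series"))
  m <- max(s$counts)
  if (m == 0) {
    warning("all-zero series '", s$channel, "': normalized values are 0")
    s$normalized <- rep(0, length(s$counts))
  } else {
    s$normalized <- s$counts / m
  }
  s
}

#' Detect spikes in a normalized mention series
#'
#' A spike is a local maximum -- at least as large as both neighbours and
#' strictly larger than one of them (so a constant series has none; at the
#' series ends only the inner neighbour is compared) -- whose normalized
#' value reaches `height`. A flat-topped peak is reported once, at its first
#' day. Candidate spikes closer together than `min_separation` days are
#' resolved by keeping the taller (ties: the earlier day).
#'
#' @param s A normalized [mention_series()].
#' @param height Minimum normalized value of a spike, in `(0, 1]`;
#'   default 0.3.
#' @param min_separation Minimum days between reported spikes; default 2.
#' @return Sorted integer vector of spike day indices (1-based).
#' @export
detect_spikes <- function(s, height = 0.3, min_separation = 2) {
  stopifnot(inherits(s, "mention_series"))
  if (anyNA(s$normalized)) stop("series not normalized", call. = FALSE)
  if (!is.numeric(height) || length(height) != 1 || is.na(height) ||
      height <= 0 || height > 1) {
    stop("height must be in (0, 1]", call. = FALSE)
  }
  v <- s$normalized
  n <- length(v)
  if (n == 0) return(integer(0))
  left <- c(-Inf, v[-n])
  right <- c(v[-1], -Inf)
  # strictly above a real neighbour somewhere, so constants are spike-free
  strict <- v > c(Inf, v[-n]) | v > c(v[-1], Inf)
  cand <- which(v >= left & v >= right & strict & v >= height)
  # flat-topped runs: keep only the first index of each constant run
  if (length(cand) > 1) {
    run_dup <- c(FALSE, diff(cand) == 1 & diff(v[cand]) == 0)
    cand <- cand[!run_dup]
  }
  # enforce separation, keeping the taller spike on conflict
  keep <- logical(length(cand))
  for (i in order(-v[cand], cand)) {
    if (!any(keep & abs(cand - cand[i]) < min_separation)) keep[i] <- TRUE
  }
  sort(cand[keep])
}

#' Match spikes across two channels
#'
#' Greedy one-to-one matching of spike days: candidate pairs within
#' `window_days` of each other are matched nearest-first (ties broken by the
#' earlier pair), and each spike participates in at most one match. The
#' number of matches is the package's reproducible counterpart of counting
#' "similar spikes" on a plotted pair of trend lines.
#'
#' @param spikes_a,spikes_b Sorted spike index vectors (days, comparable
#'   across series).
#' @param window_days Maximum day offset for a match; default 1.
#' @return A `spike_match_report`: list with `spikes_a`, `spikes_b`,
#'   `matches` (two-column matrix of indices into the day axis),
#'   `window_days`, `n_matched`.
#' @export
match_spikes <- function(spikes_a, spikes_b, window_days = 1) {
  if (!is.numeric(window_days) || length(window_days) != 1 ||
      is.na(window_days) || window_days < 0) {
    stop("window_days must be a non-negative number", call. = FALSE)
  }
  spikes_a <- sort(spikes_a)
  spikes_b <- sort(spikes_b)
  pairs <- expand.grid(i = seq_along(spikes_a), j = seq_along(spikes_b))
  if (nrow(pairs) > 0) {
    pairs$dist <- abs(spikes_a[pairs$i] - spikes_b[pairs$j])
    pairs <- pairs[pairs$dist <= window_days, , drop = FALSE]
    pairs <- pairs[order(pairs$dist, pairs$i, pairs$j), , drop = FALSE]
  }
  used_a <- logical(length(spikes_a))
  used_b <- logical(length(spikes_b))
  matches <- matrix(numeric(0), ncol = 2,
                    dimnames = list(NULL, c("index_a", "index_b")))
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE
      used_b[j] <- TRUE
      matches <- rbind(matches, c(spikes_a[i], spikes_b[j]))
    }
  }
  structure(list(spikes_a = spikes_a, spikes_b = spikes_b,
                 matches = matches, window_days = window_days,
                 n_matched = nrow(matches)),
            class = "spike_match_report")
}

#' @export
print.spike_match_report <- function(x, ...) {
  cat(sprintf("Spike match: %d of (%d, %d) spikes matched within %g day(s)\n",
              x$n_matched, length(x$spikes_a), length(x$spikes_b),
              x$window_days))
  invisible(x)
}
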