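series <- function(counts, channel = "x",
                   start = as.Date("2014-01-01")) {
  mention_series(channel, seq(start, by = "day",
                              length.out = length(counts)), counts)
}

test_that("mention series enforce gap-free windows and count binning", {
  expect_error(mention_series("x", as.Date(c("2014-01-01", "2014-01-03")),
                              c(1, 2)), "gap-free")
  expect_error(series(c(1, -1)), "non-negative")

  ts <- c(rep("2014-01-02", 3), "2014-01-05")
  s <- daily_mention_counts(ts, "2014-01-01", "2014-01-07")
  expect_equal(s$counts, c(0, 3, 0, 0, 1, 0, 0))
  expect_equal(daily_mention_counts(character(0), "2014-01-01",
                                    "2014-01-03")$counts, c(0, 0, 0))
  expect_message(
    out <- daily_mention_counts(c("2013-12-25", "2014-01-02"),
                                "2014-01-01", "2014-01-03"),
    "outside the window")
  expect_equal(sum(out$counts), 1)

  # keyword filtering: only matching items are counted
  s_kw <- daily_mention_counts(
    c("2014-01-01", "2014-01-01"), "2014-01-01", "2014-01-02",
    texts = c("about road accidents", "about cats"),
    keywords = "road accidents")
  expect_equal(s_kw$counts, c(1, 0))
})

test_that("max-normalization maps the peak to 1 and is scale-invariant", {
  s <- normalize_series(series(c(2, 4, 8)))
  expect_equal(s$normalized, c(0.25, 0.5, 1))
  expect_equal(normalize_series(series(c(5, 5, 5)))$normalized, c(1, 1, 1))
  expect_warning(z <- normalize_series(series(c(0, 0))), "all-zero")
  expect_equal(z$normalized, c(0, 0))

  set.seed(13)
  counts <- rpois(90, 20)
  n1 <- normalize_series(series(counts))$normalized
  n7 <- normalize_series(series(counts * 7))$normalized
  expect_equal(n7, n1) # scale invariance
  expect_equal(n1[which.max(counts)], 1)
  expect_equal(order(n1), order(counts, seq_along(counts)))
  # idempotent on the normalized channel
  expect_equal(normalize_series(normalize_series(series(counts)))$normalized,
               n1)
})

test_that("spike detection finds planted local maxima above threshold", {
  tri <- normalize_series(series(c(1, 2, 6, 2, 1)))
  expect_equal(detect_spikes(tri), 3)
  expect_equal(detect_spikes(normalize_series(series(rep(3, 10)))),
               integer(0)) # flat series has no spikes
  expect_error(detect_spikes(tri, height = 0), "\\(0, 1\\]")
  expect_error(detect_spikes(series(c(1, 2))), "not normalized")

  # sub-threshold local maxima are ignored
  s <- normalize_series(series(c(1, 3, 1, 1, 20, 1)))
  expect_equal(detect_spikes(s, height = 0.3), 5)

  # min_separation keeps the taller of two close spikes
  s2 <- normalize_series(series(c(0, 8, 0, 10, 0, 0, 7, 0)))
  expect_equal(detect_spikes(s2, height = 0.3, min_separation = 3),
               c(4, 7))

  # generator ground truth: 13 planted spikes recovered exactly
  cfg <- sim_config(seed = 21)
  tr <- simulate_paired_trends(cfg)
  sp <- detect_spikes(normalize_series(tr$social))
  expect_equal(sp, cfg$shared_spike_days)
})

test_that("flat-topped peaks are reported once, at their first day", {
  plateau <- normalize_series(series(c(1, 5, 5, 1)))
  expect_equal(detect_spikes(plateau), 2)
})

test_that("spike matching is greedy, one-to-one, and window-monotone", {
  r <- match_spikes(c(3, 10, 20), c(3, 10, 20), 1)
  expect_equal(r$n_matched, 3)
  expect_equal(match_spikes(c(1, 2), c(50, 60), 1)$n_matched, 0)
  expect_error(match_spikes(1, 1, -1), "non-negative")

  # each spike used at most once; cap by the smaller list
  r2 <- match_spikes(c(5, 6), c(5), 1)
  expect_equal(r2$n_matched, 1)
  expect_equal(r2$matches[1, ], c(index_a = 5, index_b = 5))

  set.seed(14)
  for (i in 1:20) {
    a <- sort(sample(1:90, 10))
    b <- sort(sample(1:90, 8))
    n_prev <- -1
    for (w in 0:4) {
      n <- match_spikes(a, b, w)$n_matched
      expect_lte(n, min(length(a), length(b)))
      expect_gte(n, n_prev) # widening never decreases
      n_prev <- n
    }
    r <- match_spikes(a, b, 1)
    expect_true(all(abs(r$matches[, 1] - r$matches[, 2]) <= 1))
    expect_equal(anyDuplicated(r$matches[, 1]), 0)
    expect_equal(anyDuplicated(r$matches[, 2]), 0)
  }
})
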