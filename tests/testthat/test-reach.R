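test_that("amplification multiplier follows the spread formula", {
  expect_equal(amplification_multiplier(100, 220), 2.2)
  expect_equal(amplification_multiplier(50, 50), 1.0)
  # oracle: total exposure assembled by summing retweeter follower counts
  followers <- c(30, 70)
  expect_equal(amplification_multiplier(200, 200 + sum(followers)), 1.5)
  expect_error(amplification_multiplier(0, 10), "undefined")
  expect_error(amplification_multiplier(10, 5), "inconsistent")

  # identity amp(x, x) = 1 and formula agreement on random inputs
  set.seed(1)
  imp <- sample(1:10000, 200, replace = TRUE)
  expect_equal(amplification_multiplier(imp, imp), rep(1, 200))
  extra <- rpois(200, 500)
  expect_equal(amplification_multiplier(imp, imp + extra),
               (imp + extra - imp) / imp + 1)
})

test_that("compute_reach matches brute-force summation and is additive", {
  tw <- make_tweets(make_tweet("t1", deliveries = 10, retweet_count = 0,
                               retweet_impressions = 0),
                    make_tweet("t2", deliveries = 10, retweet_count = 0,
                               retweet_impressions = 0))
  ev0 <- retweet_events(character(0), character(0), numeric(0))
  out <- compute_reach(tw, ev0)
  expect_equal(out$retweet_impressions, c(0, 0))
  expect_equal(out$total_impressions, c(10, 10))

  ev <- retweet_events(c("t1", "t1"), c("u1", "u2"), c(5, 5))
  out <- compute_reach(tw, ev)
  expect_equal(out$retweet_count, c(2, 0))
  expect_equal(out$retweet_impressions, c(10, 0))
  expect_equal(out$total_impressions, c(20, 10))

  # 50 random events vs nested-loop oracle
  set.seed(2)
  ids <- c("t1", "t2")
  ev50 <- retweet_events(sample(ids, 50, TRUE), sprintf("u%02d", 1:50),
                         rpois(50, 40))
  out <- compute_reach(tw, ev50)
  for (i in seq_along(ids)) {
    expect_equal(out$retweet_impressions[i],
                 sum(ev50$retweeter_followers[
                   ev50$original_tweet_id == ids[i]]))
    expect_equal(out$total_impressions[i],
                 tw$deliveries[i] + out$retweet_impressions[i])
  }
  # additivity: appending events never decreases counters
  out2 <- compute_reach(out, rbind(ev50, ev))
  expect_true(all(out2$retweet_impressions >= out$retweet_impressions))
  expect_true(all(out2$total_impressions >= out$total_impressions))

  expect_error(compute_reach(tw, retweet_events("t9", "u1", 5)),
               "not in the working set")
})

test_that("regular-tweet selection keeps keyword-bearing originals only", {
  tw <- make_tweets(
    make_tweet("t1", kind = "original"),
    make_tweet("t2", kind = "reply"),
    make_tweet("t3", kind = "retweet", retweeted_tweet_id = "t1"),
    make_tweet("t4", kind = "original", text = "off topic"))
  tw$matched_keywords <- match_keywords(tw$text, "road accidents")
  expect_equal(select_regular_tweets(tw)$tweet_id, "t1")
  # without the derived column, all originals pass
  expect_equal(select_regular_tweets(tw[tweet_columns()])$tweet_id,
               c("t1", "t4"))
})

test_that("zero-retweet drop and best-tweet selection are deterministic", {
  tw <- make_tweets(
    make_tweet("t1", "A", retweet_count = 0, retweet_impressions = 0),
    make_tweet("t2", "A", retweet_count = 1, retweet_impressions = 10),
    make_tweet("t3", "A", retweet_count = 2, retweet_impressions = 40),
    make_tweet("t4", "B", retweet_count = 1, retweet_impressions = 7))
  kept <- drop_zero_retweet(tw)
  expect_setequal(kept$tweet_id, c("t2", "t3", "t4"))
  expect_identical(drop_zero_retweet(kept), kept) # idempotent

  best <- best_tweet_per_user(kept)
  expect_equal(best$tweet_id[best$author_id == "A"], "t3")
  expect_equal(best$tweet_id[best$author_id == "B"], "t4")

  # tie-break: earliest timestamp then smallest tweet id, vs brute force
  ties <- make_tweets(
    make_tweet("t9", "C", timestamp = "2014-02-01", retweet_impressions = 5),
    make_tweet("t8", "C", timestamp = "2014-01-15", retweet_impressions = 5),
    make_tweet("t7", "C", timestamp = "2014-01-15", retweet_impressions = 5))
  expect_equal(best_tweet_per_user(ties)$tweet_id, "t7")

  # brute-force max oracle over a random stream
  tw_r <- drop_zero_retweet(random_tweets(200, seed = 5))
  best_r <- best_tweet_per_user(tw_r)
  expect_equal(anyDuplicated(best_r$author_id), 0)
  for (a in unique(tw_r$author_id)) {
    expect_equal(best_r$retweet_impressions[best_r$author_id == a],
                 max(tw_r$retweet_impressions[tw_r$author_id == a]))
  }
})

test_that("amplification and deliveries filters apply the stated cut-offs", {
  contrib <- data.frame(account_id = c("a", "b", "c"),
                        amplification_multiplier = c(1.0, 1.2, 1.5))
  kept <- filter_min_amplification(contrib)
  expect_equal(kept$account_id, c("b", "c")) # boundary 1.2 kept
  expect_equal(nrow(filter_min_amplification(
    data.frame(amplification_multiplier = c(1.0, 1.1)))), 0)
  expect_error(filter_min_amplification(contrib, -1), "non-negative")
  expect_identical(filter_min_amplification(kept), kept) # idempotent

  x <- data.frame(deliveries = c(1, 2, 3, 6)) # mean 3, strict >
  expect_equal(filter_above_average_deliveries(x)$deliveries, 6)
  expect_equal(nrow(filter_above_average_deliveries(
    data.frame(deliveries = rep(4, 5)))), 0)
  expect_warning(filter_above_average_deliveries(x[0, , drop = FALSE]),
                 "empty")

  # predicate oracle on random values
  set.seed(6)
  r <- data.frame(deliveries = rpois(100, 30))
  expect_equal(filter_above_average_deliveries(r)$deliveries,
               r$deliveries[r$deliveries > mean(r$deliveries)])
})
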