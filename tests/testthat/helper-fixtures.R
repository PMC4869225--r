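# In-code fixture builders shared across the suite.

# A valid tweet row with overridable fields; counters are consistent by
# construction (total = deliveries + retweet_impressions).
make_tweet <- function(tweet_id = "t1", author_id = "a1",
                       timestamp = "2014-01-01T10:00:00",
                       kind = "original", text = "about road accidents",
                       deliveries = 10, retweet_count = 1,
                       retweet_impressions = 5,
                       retweeted_tweet_id = "") {
  data.frame(tweet_id = tweet_id, author_id = author_id,
             timestamp = timestamp, kind = kind, text = text,
             deliveries = deliveries, retweet_count = retweet_count,
             retweet_impressions = retweet_impressions,
             total_impressions = deliveries + retweet_impressions,
             retweeted_tweet_id = retweeted_tweet_id,
             stringsAsFactors = FALSE)
}

make_tweets <- function(...) do.call(rbind, list(...))

make_accounts <- function(ids, types, followers = 100, in_scope = TRUE) {
  data.frame(account_id = ids, account_type = types,
             follower_count = rep_len(followers, length(ids)),
             in_scope = rep_len(in_scope, length(ids)),
             stringsAsFactors = FALSE)
}

# Random valid tweet table for round-trip / property tests.
random_tweets <- function(n, seed = 42) {
  set.seed(seed)
  kind <- sample(c("original", "reply", "retweet"), n, replace = TRUE)
  deliveries <- rpois(n, 50)
  rt_count <- rpois(n, 2)
  rt_impr <- ifelse(rt_count == 0, 0, rpois(n, 100))
  data.frame(
    tweet_id = sprintf("t%04d", seq_len(n)),
    author_id = sprintf("a%03d", sample.int(max(2, n %/% 3), n,
                                            replace = TRUE)),
    timestamp = format(as.Date("2014-01-01") + sample.int(90, n, TRUE) - 1),
    kind = kind,
    text = ifelse(runif(n) < 0.8, "tracked road accidents text", "other"),
    deliveries = deliveries,
    retweet_count = rt_count,
    retweet_impressions = rt_impr,
    total_impressions = deliveries + rt_impr,
    retweeted_tweet_id = ifelse(kind == "retweet", "t0001", ""),
    stringsAsFactors = FALSE)
}

# The case-study 4x4 interaction counts (source rows, target columns).
case_counts <- function() {
  matrix(c(672, 125, 267, 48,
           132,  68,  18, 17,
             8,   2,   9,  1,
             8,   5,   0,  2),
         nrow = 4, byrow = TRUE,
         dimnames = list(account_types(), account_types()))
}
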