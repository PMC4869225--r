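# Reach measures and the filter cascades used to isolate influential tweets
# and contributors.

#' Amplification multiplier
#'
#' The rate at which retweeting spread a contributor's content beyond direct
#' delivery: `((total_exposure - impressions) / impressions) + 1`.
#' `impressions` is the number of timelines that received the contributor's
#' tweets directly; `total_exposure` additionally counts timelines reached
#' through retweets. The multiplier is 1 exactly when nothing spread beyond
#' direct delivery.
#'
#' @param impressions Direct timeline deliveries; must be >= 1 (the metric is
#'   undefined at 0).
#' @param total_exposure Total timelines reached; must be >= `impressions`.
#' @return The amplification multiplier, a ratio >= 1.
#' @export
#' @examples
#' amplification_multiplier(100, 220) # 2.2
#' amplification_multiplier(50, 50)   # 1: no amplification
amplification_multiplier <- function(impressions, total_exposure) {
  if (any(is.na(impressions)) || any(impressions < 1)) {
    stop("amplification multiplier undefined for impressions < 1",
         call. = FALSE)
  }
  if (any(total_exposure < impressions)) {
    stop("inconsistent input: total_exposure < impressions", call. = FALSE)
  }
  (total_exposure - impressions) / impressions + 1
}

#' Construct retweet events
#'
#' One row per retweet of a tracked tweet, with the retweeter's follower
#' count frozen at event time (so that retweet impressions are well defined
#' even though real follower counts drift).
#'
#' @param original_tweet_id Id of the tweet that was retweeted.
#' @param retweeter_id Id of the account that retweeted.
#' @param retweeter_followers Retweeter's follower count at event time
#'   (non-negative integer).
#' @param timestamp Event time (ISO-8601 string or date).
#' @return Data frame of retweet events.
#' @export
retweet_events <- function(original_tweet_id, retweeter_id,
                           retweeter_followers,
                           timestamp = NA_character_) {
  if (length(retweeter_followers) > 0 && any(!is_count(retweeter_followers))) {
    stop("retweeter_followers must be non-negative integers", call. = FALSE)
  }
  data.frame(original_tweet_id = as.character(original_tweet_id),
             retweeter_id = as.character(retweeter_id),
             retweeter_followers = as.numeric(retweeter_followers),
             timestamp = rep_len(as.character(timestamp),
                                 length(original_tweet_id)),
             stringsAsFactors = FALSE)
}

#' Fill reach counters from retweet events
#'
#' For every tweet, sets `retweet_count` to the number of its retweet events,
#' `retweet_impressions` to the sum of its retweeters' follower counts, and
#' `total_impressions` to `deliveries + retweet_impressions`. Reply events,
#' if the caller chooses to count replies toward impressions, can simply be
#' included in `events` -- they are accounted identically.
#'
#' @param tweets Tweet data frame (counters are overwritten).
#' @param events Retweet-event data frame as from [retweet_events()]; every
#'   event must reference a tweet present in `tweets`.
#' @return `tweets` with `retweet_count`, `retweet_impressions` and
#'   `total_impressions` filled.
#' @export
compute_reach <- function(tweets, events) {
  unknown <- setdiff(unique(events$original_tweet_id), tweets$tweet_id)
  if (length(unknown) > 0) {
    stop("event(s) reference tweet id(s) not in the working set: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  idx <- factor(events$original_tweet_id, levels = tweets$tweet_id)
  tweets$retweet_count <- as.numeric(tabulate(idx, nbins = nrow(tweets)))
  imp <- vapply(split(events$retweeter_followers, idx), sum, numeric(1))
  tweets$retweet_impressions <- as.numeric(imp)
  tweets$total_impressions <- tweets$deliveries + tweets$retweet_impressions
  tweets
}

#' Keep regular keyword-bearing tweets
#'
#' Regular tweets are original posts (not retweets or replies); the tracked
#' corpus additionally requires a keyword match. Tweets whose
#' `matched_keywords` entry is empty are dropped; if the column is absent,
#' all originals are treated as keyword-bearing (pre-filtered input).
#'
#' @param tweets Tweet data frame, optionally with a `matched_keywords`
#'   list-column.
#' @return The subset of regular keyword-bearing tweets.
#' @export
select_regular_tweets <- function(tweets) {
  keep <- tweets$kind == "original"
  if ("matched_keywords" %in% names(tweets)) {
    keep <- keep & vapply(tweets$matched_keywords, length, integer(1)) > 0
  }
  tweets[keep, , drop = FALSE]
}

#' Drop tweets that attracted no retweets
#'
#' Isolates influential tweets by excluding those with `retweet_count == 0`.
#' Reach counters must be filled first (see [compute_reach()]).
#'
#' @param tweets Tweet data frame with reach counters filled.
#' @return The subset with `retweet_count >= 1`.
#' @export
drop_zero_retweet <- function(tweets) {
  tweets[tweets$retweet_count >= 1, , drop = FALSE]
}

#' Best tweet per author
#'
#' For authors with more than one tweet, keeps the tweet with the highest
#' retweet impressions. Ties are broken deterministically: earliest
#' timestamp, then lexicographically smallest tweet id.
#'
#' @param tweets Tweet data frame with reach counters filled.
#' @return One tweet per distinct author.
#' @export
best_tweet_per_user <- function(tweets) {
  if (nrow(tweets) == 0) return(tweets)
  ord <- order(tweets$author_id, -tweets$retweet_impressions,
               tweets$timestamp, tweets$tweet_id)
  sorted <- tweets[ord, , drop = FALSE]
  sorted[!duplicated(sorted$author_id), , drop = FALSE]
}

#' Keep contributors at or above an amplification threshold
#'
#' Contributors with amplification multipliers below the threshold are
#' filtered out; the boundary is kept (a multiplier of exactly 1.2x counts
#' as spreading conversation well). The 1.2 default follows the platform
#' analytics convention for a well-amplified contributor.
#'
#' @param contributors Contributor data frame with
#'   `amplification_multiplier` present.
#' @param threshold Minimum multiplier kept; default 1.2.
#' @return The subset with `amplification_multiplier >= threshold`.
#' @export
filter_min_amplification <- function(contributors, threshold = 1.2) {
  if (!is.numeric(threshold) || length(threshold) != 1 || is.na(threshold) ||
      threshold < 0) {
    stop("amplification threshold must be a single non-negative number",
         call. = FALSE)
  }
  contributors[contributors$amplification_multiplier >= threshold, ,
               drop = FALSE]
}

#' Keep rows whose deliveries exceed the sample mean
#'
#' Strictly-above-average filter on a deliveries column: a row is kept iff
#' its deliveries are greater than the arithmetic mean of deliveries over
#' the input. Used to restrict retweet events to the widely delivered ones
#' before interaction analysis. With all values equal, nothing survives.
#'
#' @param x Data frame with a deliveries column.
#' @param col Name of the deliveries column; default `"deliveries"`.
#' @return The subset with `x[[col]] > mean(x[[col]])`.
#' @export
filter_above_average_deliveries <- function(x, col = "deliveries") {
  if (!col %in% names(x)) {
    stop("column '", col, "' not found", call. = FALSE)
  }
  if (nrow(x) == 0) {
    warning("empty input to above-average-deliveries filter")
    return(x)
  }
  x[x[[col]] > mean(x[[col]]), , drop = FALSE]
}
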