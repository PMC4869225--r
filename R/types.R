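#' Canonical account types
#'
#' The four-way account typology used throughout the package: `individual`
#' (accounts owned by one person), `organizational` (group- or
#' organization-owned accounts other than media or policy bodies), `media`
#' (news and media program/organization accounts), and `policy`
#' (non-individual accounts created for policy purposes or owned by political
#' organizations). Any other label is rejected at parse time.
#'
#' @return Character vector of the four valid account-type labels, in
#'   canonical order.
#' @export
#' @examples
#' account_types()
account_types <- function() {
  c("individual", "organizational", "media", "policy")
}

#' Round half away from zero
#'
#' Percentage shares are presented rounded half-up (5 rounds away from zero),
#' matching how summary tables are conventionally printed, rather than R's
#' default round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return `x` rounded half-up to `digits` places.
#' @export
#' @examples
#' round_half_up(2.345, 2) # 2.35, where round() gives 2.34
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

tweet_kinds <- function() c("original", "reply", "retweet")

# Required columns of the on-disk tweet schema, in canonical write order.
tweet_columns <- function() {
  c("tweet_id", "author_id", "timestamp", "kind", "text", "deliveries",
    "retweet_count", "retweet_impressions", "total_impressions",
    "retweeted_tweet_id")
}

account_columns <- function() {
  c("account_id", "account_type", "follower_count", "in_scope")
}

contributor_columns <- function() {
  c("account_id", "n_retweets_made", "impressions", "total_exposure",
    "amplification_multiplier")
}

is_count <- function(x) {
  is.numeric(x) & !is.na(x) & x >= 0 & x == floor(x)
}

#' Validate a tweet table
#'
#' Checks every row of a tweet data frame against the record invariants:
#' counts are non-negative integers, `kind` is one of original/reply/retweet,
#' `total_impressions >= deliveries`, a tweet with `retweet_count == 0` has
#' `retweet_impressions == 0`, and `retweeted_tweet_id` is present exactly
#' when `kind == "retweet"`. Invalid rows are reported with their row numbers
#' and offending fields; nothing is silently coerced.
#'
#' @param tweets Data frame with the columns of [tweet_columns()]
#'   (`matched_keywords` list-column optional).
#' @return The validated data frame, invisibly unchanged.
#' @export
validate_tweets <- function(tweets) {
  missing <- setdiff(tweet_columns(), names(tweets))
  if (length(missing) > 0) {
    stop("tweet table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(tweets) == 0) return(invisible(tweets))

  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(bad), collapse = ","), ": ", what))
    }
  }
  has_rt_ref <- !is.na(tweets$retweeted_tweet_id) &
    nzchar(as.character(tweets$retweeted_tweet_id))

  note(is.na(tweets$tweet_id) | !nzchar(as.character(tweets$tweet_id)),
       "empty tweet_id")
  note(duplicated(tweets$tweet_id), "duplicate tweet_id")
  note(!(tweets$kind %in% tweet_kinds()), "invalid kind")
  for (col in c("deliveries", "retweet_count", "retweet_impressions",
                "total_impressions")) {
    note(!is_count(tweets[[col]]), paste0(col, " not a non-negative integer"))
  }
  ok_counts <- is_count(tweets$deliveries) & is_count(tweets$retweet_count) &
    is_count(tweets$retweet_impressions) & is_count(tweets$total_impressions)
  note(ok_counts & tweets$total_impressions < tweets$deliveries,
       "total_impressions < deliveries")
  note(ok_counts & tweets$retweet_count == 0 & tweets$retweet_impressions > 0,
       "retweet_impressions > 0 with retweet_count = 0")
  note(tweets$kind == "retweet" & !has_rt_ref,
       "kind = retweet without retweeted_tweet_id")
  note(tweets$kind != "retweet" & has_rt_ref,
       "retweeted_tweet_id present on non-retweet")

  if (length(problems) > 0) {
    stop("invalid tweet record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(tweets)
}

#' Validate an account table
#'
#' @param accounts Data frame with columns `account_id`, `account_type`,
#'   `follower_count`, `in_scope`. `account_type` must be one of the four
#'   canonical labels or `"unknown"`; `follower_count` must be a non-negative
#'   integer; `account_id` must be unique.
#' @return The validated data frame, invisibly.
#' @export
validate_accounts <- function(accounts) {
  missing <- setdiff(account_columns(), names(accounts))
  if (length(missing) > 0) {
    stop("account table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(accounts) == 0) return(invisible(accounts))
  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(bad), collapse = ","), ": ", what))
    }
  }
  note(duplicated(accounts$account_id), "duplicate account_id")
  note(!(accounts$account_type %in% c(account_types(), "unknown")),
       "invalid account_type")
  note(!is_count(accounts$follower_count),
       "follower_count not a non-negative integer")
  note(is.na(accounts$in_scope), "missing in_scope flag")
  if (length(problems) > 0) {
    stop("invalid account record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(accounts)
}

#' Validate a contributor table
#'
#' Beyond count checks, enforces the amplification identity: when
#' `impressions > 0`, `amplification_multiplier` must equal
#' `((total_exposure - impressions) / impressions) + 1` to within 1e-9.
#'
#' @param contributors Data frame with columns `account_id`,
#'   `n_retweets_made`, `impressions`, `total_exposure`,
#'   `amplification_multiplier`.
#' @return The validated data frame, invisibly.
#' @export
validate_contributors <- function(contributors) {
  missing <- setdiff(contributor_columns(), names(contributors))
  if (length(missing) > 0) {
    stop("contributor table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(contributors) == 0) return(invisible(contributors))
  problems <- character(0)
  note <- function(bad, what) {
    if (any(bad)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(bad), collapse = ","), ": ", what))
    }
  }
  note(duplicated(contributors$account_id), "duplicate account_id")
  for (col in c("n_retweets_made", "impressions", "total_exposure")) {
    note(!is_count(contributors[[col]]),
         paste0(col, " not a non-negative integer"))
  }
  pos <- is_count(contributors$impressions) & contributors$impressions > 0
  expected <- (contributors$total_exposure - contributors$impressions) /
    contributors$impressions + 1
  note(pos & abs(contributors$amplification_multiplier - expected) > 1e-9,
       "amplification_multiplier inconsistent with impressions/total_exposure")
  if (length(problems) > 0) {
    stop("invalid contributor record(s):\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  }
  invisible(contributors)
}

#' Match tracked keywords in message texts
#'
#' Literal, case-sensitive substring matching with no Unicode normalization:
#' the tracked keywords are fixed strings and callers wanting looser matching
#' should pre-normalize both texts and keywords. Matching is monotone --
#' adding a keyword to the set never removes an existing match.
#'
#' @param text Character vector of message texts (may contain empty strings).
#' @param keywords Non-empty character vector of tracked keyword strings.
#' @return A list, one element per text, each the character vector of
#'   keywords found in that text (in `keywords` order; empty if none).
#' @export
#' @examples
#' match_keywords("road accidents rise", c("road accidents"))
match_keywords <- function(text, keywords) {
  if (length(keywords) == 0 || all(!nzchar(keywords))) {
    stop("keyword set must be non-empty", call. = FALSE)
  }
  text <- as.character(text)
  hits <- vapply(keywords, function(k) grepl(k, text, fixed = TRUE),
                 logical(length(text)))
  if (length(text) == 1) hits <- matrix(hits, nrow = 1)
  lapply(seq_along(text), function(i) keywords[hits[i, ]])
}
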