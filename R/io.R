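# Readers/writers for the tabular interchange formats. All files are UTF-8
# CSV with a header row; ids are read as character (never factors or
# numerics), counts as numeric, and the canonical column order is enforced on
# write so that write -> read is the identity on validated tables.

read_table_checked <- function(path, required, col_classes) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = col_classes, encoding = "UTF-8")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("schema error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df[required]
}

#' Read a tweet table from CSV
#'
#' @param path Path to a CSV file with the columns of [tweet_columns()].
#' @param keywords Optional character vector of tracked keywords; when given,
#'   a `matched_keywords` list-column is filled by [match_keywords()] on the
#'   `text` column.
#' @return A validated tweet data frame.
#' @seealso [write_tweets()], [validate_tweets()]
#' @export
read_tweets <- function(path, keywords = NULL) {
  df <- read_table_checked(path, tweet_columns(), c(
    tweet_id = "character", author_id = "character", timestamp = "character",
    kind = "character", text = "character", deliveries = "numeric",
    retweet_count = "numeric", retweet_impressions = "numeric",
    total_impressions = "numeric", retweeted_tweet_id = "character"))
  df$retweeted_tweet_id[is.na(df$retweeted_tweet_id)] <- ""
  validate_tweets(df)
  if (!is.null(keywords)) df$matched_keywords <- match_keywords(df$text, keywords)
  df
}

#' Write a tweet table to CSV
#'
#' Columns are emitted in the canonical order of [tweet_columns()];
#' `matched_keywords` (a derived list-column) is never written. An empty
#' record list yields a header-only file.
#'
#' @param tweets Validated tweet data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tweets <- function(tweets, path) {
  validate_tweets(tweets)
  utils::write.csv(tweets[tweet_columns()], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an account table from CSV
#'
#' @param path Path to a CSV with columns `account_id`, `account_type`,
#'   `follower_count`, `in_scope`.
#' @return A validated account data frame.
#' @export
read_accounts <- function(path) {
  df <- read_table_checked(path, account_columns(), c(
    account_id = "character", account_type = "character",
    follower_count = "numeric", in_scope = "logical"))
  validate_accounts(df)
  df
}

#' Write an account table to CSV
#' @param accounts Validated account data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_accounts <- function(accounts, path) {
  validate_accounts(accounts)
  utils::write.csv(accounts[account_columns()], path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a contributor table from CSV
#'
#' Ratios are expected in plain decimal notation; the amplification identity
#' is checked to within 1e-9, so writers should keep at least nine
#' significant digits (as [write_contributors()] does).
#'
#' @param path Path to a CSV with the columns of `contributor` records.
#' @return A validated contributor data frame.
#' @export
read_contributors <- function(path) {
  df <- read_table_checked(path, contributor_columns(), c(
    account_id = "character", n_retweets_made = "numeric",
    impressions = "numeric", total_exposure = "numeric",
    amplification_multiplier = "numeric"))
  validate_contributors(df)
  df
}

#' Write a contributor table to CSV
#' @param contributors Validated contributor data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contributors <- function(contributors, path) {
  validate_contributors(contributors)
  # write.csv serializes doubles at full precision (15 significant digits),
  # comfortably beyond the 1e-9 identity tolerance checked on re-read
  utils::write.csv(contributors[contributor_columns()], path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a coding sheet
#'
#' A coding sheet is one rater's assignment of account types, as a
#' two-column CSV (`account_id`, `account_type`). Labels outside the four
#' canonical types are rejected; duplicate assignments for one account are an
#' error.
#'
#' @param path Path to the CSV.
#' @param rater_id Label for the rater; defaults to the file name.
#' @return Data frame with columns `account_id`, `account_type` and a
#'   `rater_id` attribute.
#' @export
read_coding_sheet <- function(path, rater_id = basename(path)) {
  df <- read_table_checked(path, c("account_id", "account_type"),
                           c(account_id = "character",
                             account_type = "character"))
  coding_sheet(df$account_id, df$account_type, rater_id = rater_id)
}

#' Construct a coding sheet in memory
#'
#' @param account_id Character vector of account ids (unique).
#' @param account_type One of the four canonical type labels per account.
#' @param rater_id Label identifying the rater.
#' @return Data frame with columns `account_id`, `account_type` and a
#'   `rater_id` attribute.
#' @export
coding_sheet <- function(account_id, account_type, rater_id = "rater") {
  if (anyDuplicated(account_id)) {
    stop("coding sheet assigns more than one type to an account",
         call. = FALSE)
  }
  bad <- !(account_type %in% account_types())
  if (any(bad)) {
    stop("coding sheet has invalid account_type label(s): ",
         paste(unique(account_type[bad]), collapse = ", "), call. = FALSE)
  }
  out <- data.frame(account_id = as.character(account_id),
                    account_type = as.character(account_type),
                    stringsAsFactors = FALSE)
  attr(out, "rater_id") <- rater_id
  out
}

#' Read a pre-counted daily mention series
#'
#' Channels whose mentions are tallied externally (for example newspaper
#' archive searches) are ingested as a per-day CSV with columns `date`
#' (ISO-8601) and `count`.
#'
#' @param path Path to the CSV.
#' @param channel Channel label for the resulting series.
#' @return A [mention_series()].
#' @export
read_daily_counts <- function(path, channel = basename(path)) {
  df <- read_table_checked(path, c("date", "count"),
                           c(date = "character", count = "numeric"))
  mention_series(channel, as.Date(df$date), df$count)
}
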