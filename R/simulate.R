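# Seeded synthetic tweet-cascade generator. Emits accounts, a keyword-bearing
# activity stream (originals, replies, retweets) with exact reach counters
# derived from the simulated retweet events, contributor summaries, and
# paired cross-channel mention trends with planted shared spikes -- all with
# machine-checkable ground truth, so every pipeline stage is testable without
# platform access.

#' Simulation configuration
#'
#' Defaults emulate the structure of a 90-day keyword-tracked public-health
#' topic stream: about 38,000 contributing accounts with an
#' individual-dominant type mixture, heavy-tailed (log-normal) follower
#' counts with median about 200, a posting intensity that (with the planted
#' spike regime) totals roughly 19,000 posts attracting roughly 40,000
#' retweets over the window, about 15% of posts being replies, and per-type
#' retweet propensities that make individual accounts the strongest
#' attractors of retweets. Thirteen shared spike days, boosted tenfold, are
#' planted in the 90-day window for cross-channel trend comparison.
#'
#' @param n_accounts Number of accounts in the pool.
#' @param type_mixture Probabilities over the four account types (canonical
#'   order; must sum to 1).
#' @param follower_log_mean,follower_log_sd Log-normal parameters for
#'   follower counts.
#' @param days Window length in days.
#' @param start_date First day of the window.
#' @param base_daily_tweets Poisson intensity of posts per ordinary day.
#' @param keyword_rate Probability a post carries the tracked keyword.
#' @param retweet_propensity Named per-type mean retweets attracted per 100
#'   followers of the author.
#' @param reply_rate Probability a post is a reply rather than an original.
#' @param shared_spike_days Day indices (1-based) with boosted activity in
#'   both channels. `NULL` (the default) plants a spike every 7th day
#'   starting on day 5 -- 13 spikes over a 90-day window.
#' @param spike_boost Intensity multiplier on spike days.
#' @param trend_base_secondary Poisson intensity of the secondary
#'   (newspaper-like) channel per ordinary day.
#' @param keyword Literal keyword string planted in keyword-bearing texts.
#' @param seed Integer seed fixing the whole stream.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_accounts = 38066,
                       type_mixture = c(individual = 0.70,
                                        organizational = 0.15,
                                        media = 0.10,
                                        policy = 0.05),
                       follower_log_mean = log(200),
                       follower_log_sd = 1.4,
                       days = 90,
                       start_date = as.Date("2014-01-01"),
                       base_daily_tweets = 90,
                       keyword_rate = 0.85,
                       retweet_propensity = c(individual = 0.6,
                                              organizational = 0.25,
                                              media = 0.2,
                                              policy = 0.15),
                       reply_rate = 0.15,
                       shared_spike_days = NULL,
                       spike_boost = 10,
                       trend_base_secondary = 5.8,
                       keyword = "road accidents",
                       seed = 1L) {
  if (!setequal(names(type_mixture), account_types()) ||
      any(type_mixture < 0) || any(type_mixture > 1) ||
      abs(sum(type_mixture) - 1) > 1e-9) {
    stop("type_mixture must be probabilities over the four account types ",
         "summing to 1", call. = FALSE)
  }
  if (!setequal(names(retweet_propensity), account_types()) ||
      any(retweet_propensity < 0)) {
    stop("retweet_propensity must be non-negative and named by the four ",
         "account types", call. = FALSE)
  }
  if (is.null(shared_spike_days)) {
    shared_spike_days <- if (days >= 6) seq(5, days - 1, by = 7)
                         else integer(0)
  }
  stopifnot(n_accounts >= 0, days >= 1, base_daily_tweets >= 0,
            keyword_rate >= 0, keyword_rate <= 1,
            reply_rate >= 0, reply_rate <= 1,
            spike_boost >= 0, trend_base_secondary >= 0,
            all(shared_spike_days >= 1), all(shared_spike_days <= days))
  cfg <- list(n_accounts = as.integer(n_accounts),
              type_mixture = type_mixture[account_types()],
              follower_log_mean = follower_log_mean,
              follower_log_sd = follower_log_sd,
              days = as.integer(days),
              start_date = as.Date(start_date),
              base_daily_tweets = base_daily_tweets,
              keyword_rate = keyword_rate,
              retweet_propensity = retweet_propensity[account_types()],
              reply_rate = reply_rate,
              shared_spike_days = as.integer(shared_spike_days),
              spike_boost = spike_boost,
              trend_base_secondary = trend_base_secondary,
              keyword = keyword,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate the account pool
#'
#' Account types are drawn from the configured mixture and follower counts
#' from the configured log-normal, rounded to integers. The draw is fixed by
#' `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return Account data frame with ground-truth `account_type` filled and
#'   `in_scope = TRUE`.
#' @export
simulate_accounts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_accounts
  if (n == 0) {
    return(data.frame(account_id = character(0),
                      account_type = character(0),
                      follower_count = numeric(0), in_scope = logical(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(
    account_id = sprintf("acct%06d", seq_len(n)),
    account_type = sample(account_types(), n, replace = TRUE,
                          prob = cfg$type_mixture),
    follower_count = pmax(0, round(stats::rlnorm(
      n, cfg$follower_log_mean, cfg$follower_log_sd))),
    in_scope = TRUE,
    stringsAsFactors = FALSE)
}

#' Simulate the keyword activity stream
#'
#' Per day, a Poisson number of posts (intensity boosted on planted spike
#' days) by uniformly sampled authors; each post is a reply with probability
#' `reply_rate` and carries the tracked keyword with probability
#' `keyword_rate`. Each keyword-bearing post attracts a Poisson number of
#' retweets with mean `retweet_propensity[author type] * followers / 100`;
#' retweeters are sampled without replacement from the pool (no follow graph
#' is modelled) and their follower counts are frozen per event. Retweets are
#' emitted both as events and as retweet-kind records, and all reach
#' counters are derivable exactly from the events.
#'
#' @param accounts Account pool from [simulate_accounts()].
#' @param cfg A [sim_config()].
#' @return List with `tweets` (posts plus retweet records, counters filled),
#'   `events` (retweet events), `contributors` (per-account summaries),
#'   `daily_counts` (a [mention_series()] of all keyword-bearing activity),
#'   and `truth` (ground-truth sidecar: coding sheet of true types, planted
#'   spike days, stream composition).
#' @export
simulate_stream <- function(accounts, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  force(accounts) # must be evaluated before the stream's seed is set
  set.seed(cfg$seed + 1L)
  n_acc <- nrow(accounts)
  lambda <- rep(cfg$base_daily_tweets, cfg$days)
  lambda[cfg$shared_spike_days] <- lambda[cfg$shared_spike_days] *
    cfg$spike_boost
  n_per_day <- if (n_acc == 0) rep(0L, cfg$days) else stats::rpois(cfg$days, lambda)
  n_posts <- sum(n_per_day)
  day <- rep(seq_len(cfg$days), n_per_day)
  author_idx <- if (n_posts > 0) sample.int(n_acc, n_posts, replace = TRUE)
                else integer(0)
  is_reply <- stats::runif(n_posts) < cfg$reply_rate
  has_kw <- stats::runif(n_posts) < cfg$keyword_rate
  post_id <- sprintf("tw%07d", seq_len(n_posts))
  text <- ifelse(has_kw,
                 paste0("post ", post_id, " about ", cfg$keyword),
                 paste0("post ", post_id, " off topic"))
  deliveries <- accounts$follower_count[author_idx]
  a_type <- accounts$account_type[author_idx]

  # retweets: only keyword-bearing posts are part of the tracked cascade
  lam_rt <- ifelse(has_kw,
                   cfg$retweet_propensity[a_type] * deliveries / 100, 0)
  n_rt <- if (n_posts > 0) stats::rpois(n_posts, lam_rt) else integer(0)
  n_rt <- pmin(n_rt, max(0L, n_acc - 1L))
  ev_list <- vector("list", n_posts)
  for (i in which(n_rt > 0)) {
    rtw <- sample.int(n_acc, n_rt[i] + 1L)
    rtw <- setdiff(rtw, author_idx[i])[seq_len(n_rt[i])]
    ev_list[[i]] <- data.frame(post = i, retweeter = rtw)
  }
  ev <- do.call(rbind, ev_list)
  if (is.null(ev)) ev <- data.frame(post = integer(0),
                                    retweeter = integer(0))
  events <- retweet_events(
    original_tweet_id = post_id[ev$post],
    retweeter_id = accounts$account_id[ev$retweeter],
    retweeter_followers = accounts$follower_count[ev$retweeter],
    timestamp = format(cfg$start_date + day[ev$post] - 1))

  # internal exact counters (independent of compute_reach)
  rt_count <- tabulate(ev$post, nbins = n_posts)
  rt_impr <- rep(0, n_posts)
  if (nrow(ev) > 0) {
    agg <- rowsum(accounts$follower_count[ev$retweeter], group = ev$post)
    rt_impr[as.integer(rownames(agg))] <- agg[, 1]
  }
  posts <- data.frame(
    tweet_id = post_id,
    author_id = accounts$account_id[author_idx],
    timestamp = format(cfg$start_date + day - 1),
    kind = ifelse(is_reply, "reply", "original"),
    text = text,
    deliveries = as.numeric(deliveries),
    retweet_count = as.numeric(rt_count),
    retweet_impressions = as.numeric(rt_impr),
    total_impressions = as.numeric(deliveries + rt_impr),
    retweeted_tweet_id = rep("", n_posts),
    stringsAsFactors = FALSE)

  rt_records <- data.frame(
    tweet_id = sprintf("rt%07d", seq_len(nrow(ev))),
    author_id = events$retweeter_id,
    timestamp = events$timestamp,
    kind = rep("retweet", nrow(ev)),
    text = text[ev$post],
    deliveries = events$retweeter_followers,
    retweet_count = rep(0, nrow(ev)),
    retweet_impressions = rep(0, nrow(ev)),
    total_impressions = events$retweeter_followers,
    retweeted_tweet_id = events$original_tweet_id,
    stringsAsFactors = FALSE)
  tweets <- rbind(posts, rt_records)
  tweets$matched_keywords <- match_keywords(tweets$text, cfg$keyword)

  contributors <- build_contributors(tweets, events)

  kw_day <- as.Date(substr(tweets$timestamp[
    vapply(tweets$matched_keywords, length, integer(1)) > 0], 1, 10))
  all_days <- seq(cfg$start_date, by = "day", length.out = cfg$days)
  daily_counts <- mention_series(
    "simulated-social", all_days,
    tabulate(match(kw_day, all_days), nbins = cfg$days))

  truth <- list(
    coding = coding_sheet(accounts$account_id, accounts$account_type,
                          rater_id = "ground-truth"),
    type_mixture = cfg$type_mixture,
    shared_spike_days = cfg$shared_spike_days,
    composition = c(originals = sum(!is_reply), replies = sum(is_reply),
                    retweets = nrow(ev),
                    keyword_posts = sum(has_kw)))
  list(tweets = tweets, events = events, contributors = contributors,
       daily_counts = daily_counts, truth = truth)
}

#' Summarize contributors from a stream
#'
#' Per-account accumulation over all authored activity: `impressions` sums
#' the deliveries of everything the account posted (originals, replies, and
#' its own retweets), `total_exposure` adds the retweet impressions its
#' posts attracted, and the amplification multiplier follows from the two
#' (1 when the account delivered nothing).
#'
#' @param tweets Tweet data frame with reach counters filled.
#' @param events Retweet events.
#' @return Validated contributor data frame, one row per active account.
#' @export
build_contributors <- function(tweets, events) {
  ids <- sort(unique(tweets$author_id))
  f <- factor(tweets$author_id, levels = ids)
  impressions <- vapply(split(tweets$deliveries, f), sum, numeric(1))
  gained <- vapply(split(tweets$retweet_impressions, f), sum, numeric(1))
  n_rt_made <- table(factor(events$retweeter_id, levels = ids))
  amp <- ifelse(impressions > 0,
                (impressions + gained - impressions) / impressions + 1, 1)
  out <- data.frame(account_id = ids,
                    n_retweets_made = as.numeric(n_rt_made),
                    impressions = as.numeric(impressions),
                    total_exposure = as.numeric(impressions + gained),
                    amplification_multiplier = as.numeric(amp),
                    stringsAsFactors = FALSE)
  validate_contributors(out)
  out
}

#' Simulate paired cross-channel mention trends
#'
#' Two daily mention series -- a high-volume social channel and a low-volume
#' newspaper-like channel -- sharing elevated Poisson intensity (multiplied
#' by `spike_boost`) on the planted `shared_spike_days`, with independent
#' Poisson noise elsewhere.
#'
#' @param cfg A [sim_config()]; the social channel uses
#'   `base_daily_tweets` as its base intensity and the secondary channel
#'   `trend_base_secondary`.
#' @return List of two [mention_series()]: `social` and `newspaper`.
#' @export
simulate_paired_trends <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  boost <- rep(1, cfg$days)
  boost[cfg$shared_spike_days] <- cfg$spike_boost
  all_days <- seq(cfg$start_date, by = "day", length.out = cfg$days)
  social <- mention_series("simulated-social", all_days,
                           stats::rpois(cfg$days,
                                        cfg$base_daily_tweets * boost))
  paper <- mention_series("simulated-newspaper", all_days,
                          stats::rpois(cfg$days,
                                       cfg$trend_base_secondary * boost))
  list(social = social, newspaper = paper)
}

#' Corrupt a coding sheet with independent errors
#'
#' Each assignment is independently replaced, with probability `error_rate`,
#' by one of the other three account types chosen uniformly. Used to
#' exercise the kappa reliability machinery at a known error level.
#'
#' @param truth A ground-truth coding sheet.
#' @param error_rate Probability in `[0, 1]` of corrupting each assignment.
#' @param seed Integer seed.
#' @return A corrupted coding sheet (rater id `"corrupted"`).
#' @export
corrupt_coding_sheet <- function(truth, error_rate, seed = 1L) {
  if (error_rate < 0 || error_rate > 1) {
    stop("error_rate must be in [0, 1]", call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(truth)
  flip <- stats::runif(n) < error_rate
  new_type <- truth$account_type
  if (any(flip)) {
    new_type[flip] <- vapply(truth$account_type[flip], function(t) {
      sample(setdiff(account_types(), t), 1)
    }, character(1))
  }
  coding_sheet(truth$account_id, new_type, rater_id = "corrupted")
}
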