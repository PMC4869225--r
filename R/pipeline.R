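# End-to-end orchestration of the three study pipelines, with stage-count
# logging (so attrition through each filter cascade is auditable) and a
# reproducibility manifest per run.

#' Pipeline configuration
#'
#' @param amplification_threshold Minimum contributor amplification
#'   multiplier kept; default 1.2.
#' @param spike_height Minimum normalized spike height in `(0, 1]`;
#'   default 0.3.
#' @param spike_min_separation Minimum days between spikes; default 2.
#' @param spike_window_days Match window for cross-channel spikes;
#'   default 1.
#' @param dp Decimal places for presented percentages; default 2.
#' @param outdir Optional output directory; when set, pipelines write their
#'   CSV/JSON products and a manifest there.
#' @param seed Seed for any sampling a pipeline performs.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(amplification_threshold = 1.2,
                            spike_height = 0.3,
                            spike_min_separation = 2,
                            spike_window_days = 1,
                            dp = 2,
                            outdir = NULL,
                            seed = 1L) {
  stopifnot(amplification_threshold >= 0,
            spike_height > 0, spike_height <= 1,
            spike_min_separation >= 1, spike_window_days >= 0, dp >= 0)
  structure(list(amplification_threshold = amplification_threshold,
                 spike_height = spike_height,
                 spike_min_separation = spike_min_separation,
                 spike_window_days = spike_window_days,
                 dp = dp, outdir = outdir, seed = as.integer(seed)),
            class = "pipeline_config")
}

md5_of <- function(x) {
  path <- tempfile()
  on.exit(unlink(path))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, dataframe = "columns"), path)
  unname(tools::md5sum(path))
}

#' Build a run manifest
#'
#' Records everything needed to reproduce a pipeline run: a hash of the
#' configuration, a hash per input table, and the record count entering and
#' leaving every stage.
#'
#' @param config The `pipeline_config` used.
#' @param inputs Named list of input data frames (or file paths).
#' @param stage_counts Named numeric vector of record counts per stage.
#' @return List with `config`, `config_hash`, `input_hashes`,
#'   `stage_counts`.
#' @export
run_manifest <- function(config, inputs, stage_counts) {
  input_hashes <- vapply(inputs, function(x) {
    if (is.character(x) && length(x) == 1 && file.exists(x)) {
      unname(tools::md5sum(x))
    } else md5_of(x)
  }, character(1))
  list(config = unclass(config)[!vapply(config, is.null, logical(1))],
       config_hash = md5_of(unclass(config)),
       input_hashes = as.list(input_hashes),
       stage_counts = as.list(stage_counts))
}

log_stage <- function(stage, n_in, n_out, detail = NULL) {
  message(sprintf("[%s] %d -> %d%s", stage, n_in, n_out,
                  if (is.null(detail)) "" else paste0(" (", detail, ")")))
}

#' Run the tweet-dataset influence pipeline
#'
#' The full cascade used to rank account types by tweet influence:
#' keep regular keyword-bearing tweets, drop tweets with no retweets, keep
#' each author's best tweet (highest retweet impressions), restrict to
#' in-scope accounts, attach account types, then build three per-type share
#' tables -- reverse-rank-scaled retweet impressions, total impressions, and
#' amplification multipliers -- and their cross-measure average.
#'
#' The amplification measure is taken from the contributor dataset when
#' `contributors` is supplied (restricted to multipliers at or above the
#' configured threshold, as in the contributor cascade); otherwise a
#' per-tweet multiplier is derived from each best tweet's deliveries and
#' total impressions (tweets with zero deliveries are then excluded, with a
#' log note).
#'
#' @param tweets Tweet data frame (with `matched_keywords` filled if keyword
#'   filtering is wanted).
#' @param accounts Account data frame; types may be pre-assigned or supplied
#'   via `sheet`.
#' @param contributors Optional contributor data frame for the amplification
#'   measure.
#' @param sheet Optional coding sheet applied with [classify_accounts()]
#'   (non-strict; unknown-typed accounts are dropped with a log note).
#' @param config A [pipeline_config()].
#' @return List with `tables` (three `type_share_table`s), `combined` (named
#'   per-type average share), `cascade` (stage counts), `manifest`.
#' @export
run_tweet_pipeline <- function(tweets, accounts, contributors = NULL,
                               sheet = NULL, config = pipeline_config()) {
  validate_tweets(tweets)
  validate_accounts(accounts)
  if (!is.null(sheet)) accounts <- classify_accounts(accounts, sheet,
                                                     strict = FALSE)
  cascade <- c(input = nrow(tweets))

  regular <- select_regular_tweets(tweets)
  log_stage("regular keyword tweets", nrow(tweets), nrow(regular))
  with_rt <- drop_zero_retweet(regular)
  log_stage("with retweets", nrow(regular), nrow(with_rt))
  best <- best_tweet_per_user(with_rt)
  log_stage("best tweet per user", nrow(with_rt), nrow(best))

  idx <- match(best$author_id, accounts$account_id)
  in_scope <- !is.na(idx) & accounts$in_scope[idx]
  scoped <- best[in_scope, , drop = FALSE]
  log_stage("in-scope accounts", nrow(best), nrow(scoped))
  types <- accounts$account_type[match(scoped$author_id,
                                       accounts$account_id)]
  typed <- types %in% account_types()
  if (any(!typed)) {
    log_stage("typed accounts", nrow(scoped), sum(typed),
              "unknown-typed dropped")
  }
  scoped <- scoped[typed, , drop = FALSE]
  types <- types[typed]
  cascade <- c(cascade, regular = nrow(regular), with_retweets = nrow(with_rt),
               best_per_user = nrow(best), in_scope_typed = nrow(scoped))
  if (nrow(scoped) == 0) {
    warning("no tweets survived the cascade; returning empty result")
    return(list(tables = list(), combined = NULL, cascade = cascade,
                manifest = run_manifest(config,
                                        list(tweets = tweets[tweet_columns()],
                                             accounts = accounts),
                                        cascade)))
  }

  t_rank <- type_share_table(types, rank_scale(scoped$retweet_impressions),
                             "retweet_impressions_rank_scale")
  t_total <- type_share_table(types, scoped$total_impressions,
                              "total_impressions")
  if (!is.null(contributors)) {
    validate_contributors(contributors)
    kept <- filter_min_amplification(contributors,
                                     config$amplification_threshold)
    log_stage("contributors at/above amplification threshold",
              nrow(contributors), nrow(kept),
              paste0("threshold ", config$amplification_threshold))
    cascade <- c(cascade, contributors_kept = nrow(kept))
    ctype <- accounts$account_type[match(kept$account_id,
                                         accounts$account_id)]
    ok <- !is.na(ctype) & ctype %in% account_types()
    t_amp <- type_share_table(ctype[ok], kept$amplification_multiplier[ok],
                              "amplification_multiplier")
  } else {
    pos <- scoped$deliveries > 0
    if (any(!pos)) {
      log_stage("amplification-defined tweets", nrow(scoped), sum(pos),
                "zero-delivery tweets excluded")
    }
    t_amp <- type_share_table(
      types[pos],
      amplification_multiplier(scoped$deliveries[pos],
                               scoped$total_impressions[pos]),
      "amplification_multiplier")
  }
  tables <- list(t_rank, t_total, t_amp)
  combined <- combine_measures(tables)
  manifest <- run_manifest(config,
                           list(tweets = tweets[tweet_columns()],
                                accounts = accounts),
                           cascade)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_share_tables(tables, file.path(config$outdir,
                                         "type_share_table.csv"))
    jsonlite::write_json(manifest,
                         file.path(config$outdir, "tweet_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(tables = tables, combined = combined, cascade = cascade,
       manifest = manifest)
}

#' Run the contributor-interaction pipeline
#'
#' Restricts retweet interactions to those delivered above the sample mean,
#' extracts distinct (source, retweeter) user pairs, tabulates them 4x4 by
#' account type, and derives source/target percentage shares and the
#' type-level influence network edge list.
#'
#' @param events Interaction events (see [interaction_events()] and
#'   [retweets_to_interactions()]).
#' @param accounts Typed account data frame.
#' @param sheet Optional coding sheet applied non-strictly first.
#' @param config A [pipeline_config()].
#' @return List with `matrix` (an `interaction_matrix`), `percentages`,
#'   `edges`, `cascade`, `manifest`.
#' @export
run_interaction_pipeline <- function(events, accounts, sheet = NULL,
                                     config = pipeline_config()) {
  validate_accounts(accounts)
  if (!is.null(sheet)) accounts <- classify_accounts(accounts, sheet,
                                                     strict = FALSE)
  kept <- filter_above_average_deliveries(events)
  log_stage("above-average deliveries", nrow(events), nrow(kept))
  m <- build_interaction_matrix(kept, accounts)
  log_stage("distinct typed user pairs", nrow(kept), m$grand_total)
  pct <- matrix_percentages(m)
  edges <- export_edge_list(m, events = kept)
  cascade <- c(input = nrow(events), above_mean = nrow(kept),
               pairs = m$grand_total, users = m$n_users)
  manifest <- run_manifest(config, list(events = events, accounts = accounts),
                           cascade)
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_interaction_matrix(m, file.path(config$outdir,
                                          "interaction_matrix.csv"))
    utils::write.csv(edges$type_edges,
                     file.path(config$outdir, "type_edges.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest,
                         file.path(config$outdir,
                                   "interaction_manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(matrix = m, percentages = pct, edges = edges, cascade = cascade,
       manifest = manifest)
}

#' Run the cross-channel trends pipeline
#'
#' Max-normalizes both daily mention series, detects spikes in each, and
#' matches them one-to-one within the configured day window.
#'
#' @param series_a,series_b Two [mention_series()] over the same window.
#' @param config A [pipeline_config()].
#' @return List with `series` (both normalized), `report` (a
#'   `spike_match_report`), `manifest`.
#' @export
run_trends_pipeline <- function(series_a, series_b,
                                config = pipeline_config()) {
  a <- normalize_series(series_a)
  b <- normalize_series(series_b)
  sp_a <- detect_spikes(a, config$spike_height, config$spike_min_separation)
  sp_b <- detect_spikes(b, config$spike_height, config$spike_min_separation)
  log_stage(paste0("spikes in ", a$channel), length(a$counts), length(sp_a))
  log_stage(paste0("spikes in ", b$channel), length(b$counts), length(sp_b))
  report <- match_spikes(sp_a, sp_b, config$spike_window_days)
  manifest <- run_manifest(
    config,
    list(series_a = list(channel = a$channel, counts = a$counts),
         series_b = list(channel = b$channel, counts = b$counts)),
    c(spikes_a = length(sp_a), spikes_b = length(sp_b),
      matched = report$n_matched))
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      data.frame(date = format(a$dates),
                 counts_a = a$counts, normalized_a = a$normalized,
                 counts_b = b$counts, normalized_b = b$normalized),
      file.path(config$outdir, "normalized_trends.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(spikes_a = report$spikes_a, spikes_b = report$spikes_b,
           matches = apply(report$matches, 1, function(r)
             list(index_a = r[[1]], index_b = r[[2]])),
           window_days = report$window_days,
           n_matched = report$n_matched, manifest = manifest),
      file.path(config$outdir, "spike_report.json"),
      auto_unbox = TRUE, digits = NA)
  }
  list(series = list(a = a, b = b), report = report, manifest = manifest)
}
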