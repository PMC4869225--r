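# Bundled reference tables from the motivating case study: a 90-day
# keyword-tracked road-traffic-accident topic stream on a microblogging
# platform, with accounts coded into the four-type typology. These are the
# published summary numbers only (the raw stream was never deposited); they
# serve as desk-scale inputs for checking the package's table arithmetic.

#' Case-study interaction counts
#'
#' The 4x4 matrix of distinct retweet-interaction user pairs from the
#' bundled case study, rows = source account type (author of the retweeted
#' message), columns = target type (the retweeter), in canonical order.
#' 1382 interacting user pairs in total.
#'
#' @return An `interaction_matrix` (see [interaction_matrix_from_counts()]).
#' @export
#' @examples
#' matrix_percentages(case_interaction_matrix())$row_shares
case_interaction_matrix <- function() {
  path <- system.file("extdata", "case_interaction_counts.csv",
                      package = "agendareach", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, account_types()])
  rownames(counts) <- df$source_type
  interaction_matrix_from_counts(counts)
}

#' Case-study per-type influence shares
#'
#' Published percentage shares of the three influence measures
#' (reverse-rank-scaled retweet impressions, total impressions,
#' amplification multipliers) for the four account types in the bundled
#' case study, as a list of `type_share_table`s suitable for
#' [combine_measures()].
#'
#' @return Named list of three `type_share_table`s.
#' @export
#' @examples
#' combine_measures(case_measure_shares())
case_measure_shares <- function() {
  path <- system.file("extdata", "case_measure_shares.csv",
                      package = "agendareach", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  measures <- setdiff(names(df), "account_type")
  tabs <- lapply(measures, function(m) {
    share_table_from_shares(stats::setNames(df[[m]], df$account_type), m)
  })
  stats::setNames(tabs, measures)
}
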