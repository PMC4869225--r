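# Source-by-target retweet-interaction matrices and network edge export.
# Rows are the source of influence (the author of the retweeted message),
# columns the target (the account that retweeted it).

#' Construct interaction events
#'
#' One row per retweet interaction: the creator of the retweeted message
#' (source of influence), the account that retweeted it (target), and the
#' deliveries of the retweet (the retweeter's follower count at event time).
#'
#' @param source_author_id Author of the retweeted message.
#' @param retweeter_id Account that retweeted it.
#' @param deliveries Deliveries of the retweet event.
#' @return Data frame of interaction events.
#' @export
interaction_events <- function(source_author_id, retweeter_id, deliveries) {
  data.frame(source_author_id = as.character(source_author_id),
             retweeter_id = as.character(retweeter_id),
             deliveries = as.numeric(deliveries),
             stringsAsFactors = FALSE)
}

#' Derive interaction events from retweet events
#'
#' Maps each retweet event's `original_tweet_id` to the tweet's author, and
#' carries the retweeter's follower count as the event's deliveries.
#'
#' @param events Retweet events as from [retweet_events()].
#' @param tweets Tweet data frame containing every referenced tweet.
#' @return Interaction-event data frame (see [interaction_events()]).
#' @export
retweets_to_interactions <- function(events, tweets) {
  idx <- match(events$original_tweet_id, tweets$tweet_id)
  if (anyNA(idx)) {
    stop("event(s) reference tweet id(s) not in the tweet table",
         call. = FALSE)
  }
  interaction_events(tweets$author_id[idx], events$retweeter_id,
                     events$retweeter_followers)
}

#' Build the 4x4 interaction matrix by account type
#'
#' Cell (s, t) counts interacting user pairs whose source account has type s
#' and whose retweeter has type t. By default each distinct (source,
#' retweeter) pair is counted once regardless of how many retweets link them
#' (interactions between users, not raw events); set
#' `count_unique_pairs = FALSE` to count every event. Self-retweets are
#' excluded in either mode.
#'
#' @param events Interaction events (see [interaction_events()]).
#' @param accounts Account data frame giving a canonical type to every
#'   account referenced by `events`.
#' @param count_unique_pairs Count each (source, retweeter) pair once
#'   (default) or count raw events.
#' @return An `interaction_matrix`: list with `counts` (4x4 matrix, rows =
#'   source type, columns = retweeter type), `row_totals`, `col_totals`,
#'   `grand_total`, and `n_users` (distinct interacting accounts).
#' @export
build_interaction_matrix <- function(events, accounts,
                                     count_unique_pairs = TRUE) {
  events <- events[events$source_author_id != events$retweeter_id, ,
                   drop = FALSE]
  if (count_unique_pairs) {
    events <- events[!duplicated(events[c("source_author_id",
                                          "retweeter_id")]), , drop = FALSE]
  }
  ids <- unique(c(events$source_author_id, events$retweeter_id))
  type_of <- accounts$account_type[match(ids, accounts$account_id)]
  untyped <- ids[is.na(type_of) | !(type_of %in% account_types())]
  if (length(untyped) > 0) {
    stop("untyped account(s) referenced by interaction events: ",
         paste(utils::head(untyped, 10), collapse = ", "),
         if (length(untyped) > 10) ", ...", call. = FALSE)
  }
  s_type <- factor(type_of[match(events$source_author_id, ids)],
                   levels = account_types())
  t_type <- factor(type_of[match(events$retweeter_id, ids)],
                   levels = account_types())
  counts <- unclass(table(source = s_type, target = t_type))
  interaction_matrix_from_counts(counts, n_users = length(ids))
}

#' Wrap a 4x4 count matrix as an interaction matrix
#'
#' Entry point for pre-tabulated interaction counts (for example a published
#' table): rows must be source types, columns target types, both in
#' canonical [account_types()] order.
#'
#' @param counts 4x4 numeric matrix of pair counts.
#' @param n_users Optional number of distinct interacting accounts.
#' @return An `interaction_matrix` (see [build_interaction_matrix()]).
#' @export
interaction_matrix_from_counts <- function(counts, n_users = NA_integer_) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(4, 4)) || any(counts < 0)) {
    stop("counts must be a 4x4 matrix of non-negative counts", call. = FALSE)
  }
  dimnames(counts) <- list(source = account_types(),
                           target = account_types())
  structure(list(counts = counts,
                 row_totals = rowSums(counts),
                 col_totals = colSums(counts),
                 grand_total = sum(counts),
                 n_users = n_users),
            class = "interaction_matrix")
}

#' Row and column percentage shares of an interaction matrix
#'
#' Row shares give each type's share as a source of influence
#' (`row_total / grand_total * 100`); column shares give its share as a
#' target. Both are rounded half-up to 2 decimal places; unrounded values
#' are returned alongside.
#'
#' @param m An `interaction_matrix` with `grand_total >= 1`.
#' @return List with `row_shares`, `col_shares` (named, rounded),
#'   `row_shares_raw`, `col_shares_raw`, and `grand_total`.
#' @export
matrix_percentages <- function(m) {
  if (m$grand_total < 1) {
    stop("shares undefined: interaction matrix is empty", call. = FALSE)
  }
  rr <- m$row_totals / m$grand_total * 100
  cr <- m$col_totals / m$grand_total * 100
  list(row_shares = round_half_up(rr, 2), col_shares = round_half_up(cr, 2),
       row_shares_raw = rr, col_shares_raw = cr,
       grand_total = m$grand_total)
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("Retweet-interaction matrix (rows = source type, cols = target type)\n")
  print(x$counts)
  cat("grand total:", x$grand_total,
      if (!is.na(x$n_users)) paste0("over ", x$n_users, " accounts"), "\n")
  invisible(x)
}

#' Export the type-level influence network as an edge list
#'
#' All 16 directed type-to-type edges, including zero-weight ones (flagged),
#' in a layout consumable by standard graph tools. Optionally also derives
#' user-level directed edges from the raw events.
#'
#' @param m An `interaction_matrix`.
#' @param events Optional interaction events; when given, a `user_edges`
#'   data frame (source id, target id, weight = number of events) is
#'   attached.
#' @return List with `type_edges` (16 rows: `source_type`, `target_type`,
#'   `weight`, `zero_weight`) and optionally `user_edges`.
#' @export
export_edge_list <- function(m, events = NULL) {
  grid <- expand.grid(source_type = account_types(),
                      target_type = account_types(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid$weight <- m$counts[cbind(grid$source_type, grid$target_type)]
  grid$zero_weight <- grid$weight == 0
  out <- list(type_edges = grid)
  if (!is.null(events)) {
    ev <- events[events$source_author_id != events$retweeter_id, ,
                 drop = FALSE]
    agg <- stats::aggregate(list(weight = rep(1, nrow(ev))),
                            by = list(source_id = ev$source_author_id,
                                      target_id = ev$retweeter_id),
                            FUN = sum)
    out$user_edges <- agg[order(agg$source_id, agg$target_id), ,
                          drop = FALSE]
    rownames(out$user_edges) <- NULL
  }
  out
}

#' Write an interaction matrix as CSV in presentation layout
#'
#' Rows are source types plus a column-total and column-share row; columns
#' are target types plus row totals and row shares.
#'
#' @param m An `interaction_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interaction_matrix <- function(m, path) {
  pct <- matrix_percentages(m)
  body <- as.data.frame(m$counts)
  names(body) <- account_types()
  body <- cbind(account_type = account_types(), body,
                total = as.numeric(m$row_totals),
                percentage = as.numeric(pct$row_shares))
  total_row <- data.frame(account_type = "total",
                          t(as.numeric(m$col_totals)),
                          total = m$grand_total, percentage = NA_real_)
  share_row <- data.frame(account_type = "percentage",
                          t(as.numeric(pct$col_shares)),
                          total = NA_real_, percentage = NA_real_)
  names(total_row)[2:5] <- account_types()
  names(share_row)[2:5] <- account_types()
  utils::write.csv(rbind(body, total_row, share_row), path,
                   row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
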