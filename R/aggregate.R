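# Per-type influence summaries: totals, percentage shares, rank scaling,
# cross-measure averages, and the popularity-vs-influence correlations.

#' Per-type share table for one influence measure
#'
#' Sums one non-negative measure (retweet-impression rank scores, total
#' impressions, amplification multipliers, ...) over typed users, and
#' reports, for each of the four account types: the total, its percentage
#' share of the grand total (rounded half-up to 2 decimal places for
#' presentation; the unrounded share is kept in `share_raw`), and the
#' per-user mean. All four canonical types appear even when empty.
#'
#' @param types Character vector of account types, one per user; every user
#'   must carry one of the four canonical labels.
#' @param values Non-negative measure values, same length as `types`.
#' @param measure_name Label for the measure.
#' @return A `type_share_table`: list with `measure_name`, `table` (data
#'   frame with columns `account_type`, `total`, `share`, `share_raw`,
#'   `mean`, `n`), and `grand_total`.
#' @export
type_share_table <- function(types, values, measure_name = "measure") {
  if (length(types) != length(values)) {
    stop("types and values must have equal length", call. = FALSE)
  }
  bad <- !(types %in% account_types())
  if (any(bad)) {
    stop("untyped or invalid account type(s): ",
         paste(unique(types[bad]), collapse = ", "), call. = FALSE)
  }
  if (any(is.na(values) | values < 0)) {
    stop("measure values must be non-negative", call. = FALSE)
  }
  f <- factor(types, levels = account_types())
  total <- vapply(split(values, f), sum, numeric(1))
  n <- as.numeric(table(f))
  grand <- sum(total)
  if (grand == 0) {
    stop("grand total is 0: shares undefined for measure '", measure_name,
         "'", call. = FALSE)
  }
  share_raw <- total / grand * 100
  tab <- data.frame(account_type = account_types(),
                    total = as.numeric(total),
                    share = round_half_up(share_raw, 2),
                    share_raw = as.numeric(share_raw),
                    mean = ifelse(n > 0, total / n, NA_real_),
                    n = n,
                    stringsAsFactors = FALSE)
  structure(list(measure_name = measure_name, table = tab,
                 grand_total = grand),
            class = "type_share_table")
}

#' Build a share table directly from known percentage shares
#'
#' Convenience constructor for entering an already-summarized row of
#' percentage shares (for example a published table) so it can be combined
#' with computed tables by [combine_measures()].
#'
#' @param shares Named numeric vector of percentage shares, names being the
#'   four account types; must sum to 100 within 0.05.
#' @param measure_name Label for the measure.
#' @return A `type_share_table` (totals equal to the shares; means `NA`).
#' @export
share_table_from_shares <- function(shares, measure_name = "measure") {
  if (!setequal(names(shares), account_types())) {
    stop("shares must be named by the four account types", call. = FALSE)
  }
  shares <- shares[account_types()]
  if (abs(sum(shares) - 100) > 0.05) {
    stop("shares must sum to 100 (within rounding)", call. = FALSE)
  }
  tab <- data.frame(account_type = account_types(),
                    total = as.numeric(shares),
                    share = round_half_up(as.numeric(shares), 2),
                    share_raw = as.numeric(shares),
                    mean = NA_real_, n = NA_real_,
                    stringsAsFactors = FALSE)
  structure(list(measure_name = measure_name, table = tab,
                 grand_total = sum(shares)),
            class = "type_share_table")
}

#' @export
print.type_share_table <- function(x, ...) {
  cat("Per-type shares of", x$measure_name,
      sprintf("(grand total %g)\n", x$grand_total))
  print(x$table[c("account_type", "total", "share", "mean", "n")],
        row.names = FALSE)
  invisible(x)
}

#' Reverse-rank scaling
#'
#' Linear rank scaling of a measure: the user ranked `r` of `N` (rank 1 being
#' the largest value) scores `N - r + 1` points, so the largest value scores
#' `N` and the smallest 1. Tied values share the mean of their tied score
#' span, which preserves the total score `N(N+1)/2`. Rank scaling dampens
#' the leverage of extreme outliers before shares are computed.
#'
#' @param values Numeric vector of non-negative measure values.
#' @return Numeric vector of rank scores, same length as `values`.
#' @export
#' @examples
#' rank_scale(c(10, 20, 30)) # 1 2 3
rank_scale <- function(values) {
  if (length(values) == 0) stop("need at least one value", call. = FALSE)
  rank(values, ties.method = "average")
}

#' Average percentage shares across measures
#'
#' Unweighted arithmetic mean of the per-type percentage shares across two or
#' more share tables (rounded half-up to 2 decimal places), giving a single
#' cross-measure influence share per account type.
#'
#' @param tables List of `type_share_table`s with identical type sets.
#' @return Named numeric vector: mean percentage share per account type.
#' @export
combine_measures <- function(tables) {
  if (length(tables) < 2) stop("need at least two tables", call. = FALSE)
  type_sets <- lapply(tables, function(t) t$table$account_type)
  for (ts in type_sets[-1]) {
    if (!identical(ts, type_sets[[1]])) {
      stop("tables have mismatched account-type sets", call. = FALSE)
    }
  }
  shares <- vapply(tables, function(t) t$table$share_raw,
                   numeric(length(type_sets[[1]])))
  out <- round_half_up(rowMeans(shares), 2)
  names(out) <- type_sets[[1]]
  out
}

#' Pearson correlation between two measures
#'
#' Sample product-moment correlation, used to check whether an account's
#' influence tracks its popularity (for example deliveries vs retweet
#' impressions): a near-zero r says widely disseminated tweets need not come
#' from widely followed accounts.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @param pair_name Label for the measure pair.
#' @return A `correlation_result`: list with `r`, `n`, `pair_name`.
#' @export
pearson_r <- function(x, y, pair_name = "x vs y") {
  if (length(x) != length(y) || length(x) < 3) {
    stop("need two equal-length series of at least 3 values", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance in '", pair_name, "'",
         call. = FALSE)
  }
  structure(list(r = stats::cor(x, y), n = length(x), pair_name = pair_name),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f (%s, n = %d)\n", x$r, x$pair_name, x$n))
  invisible(x)
}

#' Write a share table as CSV in presentation layout
#'
#' Rows are account types, columns the measures' percentage shares plus the
#' combined average.
#'
#' @param tables List of `type_share_table`s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_share_tables <- function(tables, path) {
  combined <- combine_measures(tables)
  out <- data.frame(account_type = account_types(),
                    stringsAsFactors = FALSE)
  for (t in tables) out[[t$measure_name]] <- t$table$share
  out$average <- as.numeric(combined)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
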