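# Account-type classification from coding sheets and inter-rater
# reliability of the coding.

#' Attach account types from a coding sheet
#'
#' Sets each account's `account_type` from a rater's coding sheet. In strict
#' mode every in-scope account must be covered; otherwise uncoded accounts
#' are marked `"unknown"` (and are excluded by downstream per-type
#' aggregation, which only tabulates the four canonical types).
#'
#' @param accounts Account data frame.
#' @param sheet Coding sheet from [coding_sheet()] or [read_coding_sheet()].
#' @param strict If `TRUE` (default), an in-scope account missing from the
#'   sheet is a coverage error naming the account ids.
#' @return `accounts` with `account_type` filled.
#' @export
classify_accounts <- function(accounts, sheet, strict = TRUE) {
  idx <- match(accounts$account_id, sheet$account_id)
  uncovered <- accounts$account_id[is.na(idx) & accounts$in_scope]
  if (strict && length(uncovered) > 0) {
    stop("coding sheet does not cover in-scope account(s): ",
         paste(utils::head(uncovered, 10), collapse = ", "),
         if (length(uncovered) > 10) ", ...", call. = FALSE)
  }
  accounts$account_type <- ifelse(is.na(idx), "unknown",
                                  sheet$account_type[idx])
  accounts
}

#' Cohen's kappa between two coding sheets
#'
#' Chance-corrected agreement between two raters over the items they both
#' coded: `kappa = (p_o - p_e) / (1 - p_e)`, where `p_o` is the observed
#' proportion of agreement and `p_e` the chance agreement implied by the two
#' raters' marginal label frequencies. Computed over the four account-type
#' categories (categories used by neither rater contribute nothing).
#'
#' If both raters assign one identical constant label, chance agreement is 1
#' and the ratio is indeterminate; agreement is nonetheless perfect, so kappa
#' is reported as 1 with a note.
#'
#' @param sheet_a,sheet_b Coding sheets; at least two common `account_id`s
#'   are required.
#' @return A `kappa_result`: list with `kappa`, `observed_agreement`,
#'   `expected_agreement`, `n_items`, `benchmark` (see [kappa_benchmark()]),
#'   and an optional `note`.
#' @export
#' @examples
#' a <- coding_sheet(letters[1:4], c("media", "media", "policy", "policy"))
#' b <- coding_sheet(letters[1:4], c("media", "media", "policy", "media"))
#' cohen_kappa(a, b)$kappa
cohen_kappa <- function(sheet_a, sheet_b) {
  common <- intersect(sheet_a$account_id, sheet_b$account_id)
  if (length(common) < 2) {
    stop("need at least 2 items coded by both raters", call. = FALSE)
  }
  lab_a <- sheet_a$account_type[match(common, sheet_a$account_id)]
  lab_b <- sheet_b$account_type[match(common, sheet_b$account_id)]
  n <- length(common)
  tab <- table(factor(lab_a, levels = account_types()),
               factor(lab_b, levels = account_types()))
  po <- sum(diag(tab)) / n
  pe <- sum((rowSums(tab) / n) * (colSums(tab) / n))
  note <- NULL
  if (1 - pe < 1e-12) {
    # both raters constant and equal: agreement is perfect by construction
    kappa <- 1
    note <- "expected agreement is 1 (both raters constant); kappa set to 1"
  } else {
    kappa <- (po - pe) / (1 - pe)
  }
  structure(list(kappa = kappa, observed_agreement = po,
                 expected_agreement = pe, n_items = n,
                 benchmark = kappa_benchmark(kappa), note = note),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa: %.4f (%s) over %d items\n",
              x$kappa, x$benchmark, x$n_items))
  cat(sprintf("  observed agreement %.4f, expected %.4f\n",
              x$observed_agreement, x$expected_agreement))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Benchmark a kappa value
#'
#' Fleiss's strength-of-agreement benchmarks: below 0.40 is `poor`, 0.40 to
#' 0.75 inclusive is `intermediate-good`, above 0.75 is `excellent`.
#'
#' @param kappa A value in `[-1, 1]`.
#' @return One of `"poor"`, `"intermediate-good"`, `"excellent"`.
#' @export
#' @examples
#' kappa_benchmark(0.87) # "excellent"
kappa_benchmark <- function(kappa) {
  if (!is.numeric(kappa) || length(kappa) != 1 || is.na(kappa) ||
      kappa < -1 || kappa > 1) {
    stop("kappa must be a single value in [-1, 1]", call. = FALSE)
  }
  if (kappa < 0.40) "poor"
  else if (kappa <= 0.75) "intermediate-good"
  else "excellent"
}

#' Write a kappa result as JSON
#'
#' @param x A `kappa_result` from [cohen_kappa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kappa_report <- function(x, path) {
  jsonlite::write_json(x[!vapply(x, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
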