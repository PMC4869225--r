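acc4 <- function() make_accounts(c("i1", "i2", "o1", "m1", "p1"),
                                 c("individual", "individual",
                                   "organizational", "media", "policy"))

test_that("interaction matrix counts distinct typed user pairs", {
  ev <- interaction_events("i1", "m1", 100)
  m <- build_interaction_matrix(ev, acc4())
  expect_equal(m$counts["individual", "media"], 1)
  expect_equal(m$grand_total, 1)

  # duplicate pairs count once; duplicating the event list changes nothing
  ev2 <- rbind(ev, ev, interaction_events("i1", "i1", 5)) # self excluded
  m2 <- build_interaction_matrix(ev2, acc4())
  expect_equal(m2$counts, m$counts)
  m3 <- build_interaction_matrix(rbind(ev2, ev2), acc4())
  expect_equal(m3$counts, m$counts)

  # raw-event mode counts every non-self event
  m_raw <- build_interaction_matrix(ev2, acc4(), count_unique_pairs = FALSE)
  expect_equal(m_raw$counts["individual", "media"], 2)

  expect_error(build_interaction_matrix(
    interaction_events("i1", "ghost", 5), acc4()), "ghost")
})

test_that("random events match a nested-loop oracle and conserve totals", {
  set.seed(10)
  ids <- sprintf("u%02d", 1:20)
  acc <- make_accounts(ids, sample(account_types(), 20, TRUE))
  ev <- interaction_events(sample(ids, 300, TRUE), sample(ids, 300, TRUE),
                           rpois(300, 50))
  m <- build_interaction_matrix(ev, acc)

  # oracle: enumerate unique non-self pairs, count by type pair
  pairs <- unique(ev[ev$source_author_id != ev$retweeter_id,
                     c("source_author_id", "retweeter_id")])
  oracle <- matrix(0, 4, 4, dimnames = list(account_types(),
                                            account_types()))
  for (r in seq_len(nrow(pairs))) {
    s <- acc$account_type[acc$account_id == pairs$source_author_id[r]]
    t <- acc$account_type[acc$account_id == pairs$retweeter_id[r]]
    oracle[s, t] <- oracle[s, t] + 1
  }
  expect_equal(unclass(m$counts), oracle, ignore_attr = TRUE)
  expect_equal(sum(m$row_totals), m$grand_total)
  expect_equal(sum(m$col_totals), m$grand_total)

  pct <- matrix_percentages(m)
  expect_equal(sum(pct$row_shares_raw), 100)
  expect_equal(sum(pct$col_shares_raw), 100)
})

test_that("the case-study counts reproduce the published shares", {
  m <- interaction_matrix_from_counts(case_counts())
  expect_equal(m$grand_total, 1382)
  pct <- matrix_percentages(m)
  expect_equal(unname(pct$row_shares), c(80.46, 17.00, 1.45, 1.09))
  # standard rounding of the cell arithmetic is authoritative here:
  # 820/1382 gives 59.33 (the text value; the table's 59.34 is a
  # transcription artifact), 200/1382 gives 14.47
  expect_equal(unname(pct$col_shares), c(59.33, 14.47, 21.27, 4.92))
  expect_error(matrix_percentages(
    interaction_matrix_from_counts(matrix(0, 4, 4))), "empty")
})

test_that("edge export emits all 16 type edges and user-level edges", {
  m <- interaction_matrix_from_counts(case_counts())
  edges <- export_edge_list(m)
  expect_equal(nrow(edges$type_edges), 16)
  ind_ind <- edges$type_edges$weight[
    edges$type_edges$source_type == "individual" &
      edges$type_edges$target_type == "individual"]
  expect_equal(ind_ind, 672)
  zero <- export_edge_list(interaction_matrix_from_counts(matrix(0, 4, 4)))
  expect_equal(nrow(zero$type_edges), 16)
  expect_true(all(zero$type_edges$zero_weight))

  # edge weights equal matrix cells on random events
  set.seed(12)
  ids <- sprintf("u%02d", 1:10)
  acc <- make_accounts(ids, sample(account_types(), 10, TRUE))
  ev <- interaction_events(sample(ids, 100, TRUE), sample(ids, 100, TRUE),
                           rpois(100, 10))
  m_r <- build_interaction_matrix(ev, acc)
  e_r <- export_edge_list(m_r, events = ev)
  expect_equal(
    e_r$type_edges$weight,
    m_r$counts[cbind(e_r$type_edges$source_type,
                     e_r$type_edges$target_type)])
  nonself <- ev[ev$source_author_id != ev$retweeter_id, ]
  expect_equal(sum(e_r$user_edges$weight), nrow(nonself))
})

test_that("interaction matrices write in presentation layout", {
  m <- interaction_matrix_from_counts(case_counts())
  path <- withr::local_tempfile(fileext = ".csv")
  write_interaction_matrix(m, path)
  out <- read.csv(path)
  expect_equal(out$total[1:4], c(1112, 235, 20, 15))
  expect_equal(out$individual[5], 820) # column totals row
  expect_equal(out$percentage[1], 80.46)
})
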