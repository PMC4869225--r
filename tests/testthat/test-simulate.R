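test_that("sim_config validates its stated world", {
  expect_error(sim_config(type_mixture = c(individual = 0.5,
                                           organizational = 0.5,
                                           media = 0.5, policy = -0.5)),
               "type_mixture")
  expect_error(sim_config(keyword_rate = 1.5))
  expect_error(sim_config(shared_spike_days = 100, days = 90))
  cfg <- sim_config()
  expect_equal(sum(cfg$type_mixture), 1)
  expect_equal(length(cfg$shared_spike_days), 13)
  expect_equal(cfg$days, 90L)
})

test_that("simulated accounts follow the configured mixture", {
  all_ind <- sim_config(n_accounts = 50,
                        type_mixture = c(individual = 1, organizational = 0,
                                         media = 0, policy = 0), seed = 3)
  acc <- simulate_accounts(all_ind)
  expect_true(all(acc$account_type == "individual"))
  expect_silent(validate_accounts(acc))

  expect_equal(nrow(simulate_accounts(sim_config(n_accounts = 0))), 0)

  # law of large numbers at fixed seed: fractions within 0.01 of mixture
  cfg <- sim_config(n_accounts = 20000, seed = 4)
  acc <- simulate_accounts(cfg)
  frac <- prop.table(table(factor(acc$account_type,
                                  levels = account_types())))
  expect_true(all(abs(as.numeric(frac) - cfg$type_mixture) < 0.01))
  expect_true(all(acc$follower_count >= 0))
  expect_true(all(acc$follower_count == floor(acc$follower_count)))
})

test_that("the stream honours degenerate configurations", {
  zero_prop <- sim_config(n_accounts = 200, days = 10,
                          base_daily_tweets = 20,
                          retweet_propensity = c(individual = 0,
                                                 organizational = 0,
                                                 media = 0, policy = 0),
                          shared_spike_days = 5, seed = 5)
  st <- simulate_stream(simulate_accounts(zero_prop), zero_prop)
  expect_true(all(st$tweets$retweet_count == 0))
  expect_equal(nrow(st$events), 0)

  silent <- sim_config(n_accounts = 50, days = 10, base_daily_tweets = 0,
                       spike_boost = 1, shared_spike_days = 2, seed = 5)
  st2 <- simulate_stream(simulate_accounts(silent), silent)
  expect_equal(nrow(st2$tweets), 0)
})

test_that("the stream is exact and reproducible", {
  cfg <- sim_config(n_accounts = 800, days = 30, base_daily_tweets = 25,
                    shared_spike_days = c(10, 20), seed = 6)
  acc <- simulate_accounts(cfg)
  st <- simulate_stream(acc, cfg)
  expect_silent(validate_tweets(st$tweets[tweet_columns()]))
  expect_silent(validate_contributors(st$contributors))

  # exactness: compute_reach on the events reproduces internal counters
  posts <- st$tweets[st$tweets$kind != "retweet", ]
  refilled <- compute_reach(posts, st$events)
  expect_identical(refilled$retweet_count, posts$retweet_count)
  expect_identical(refilled$retweet_impressions, posts$retweet_impressions)
  expect_identical(refilled$total_impressions, posts$total_impressions)

  # all randomness flows from the seed: identical runs are identical
  st_again <- simulate_stream(simulate_accounts(cfg), cfg)
  expect_identical(st_again$tweets, st$tweets)
  expect_identical(st_again$events, st$events)
  tr1 <- simulate_paired_trends(cfg)
  tr2 <- simulate_paired_trends(cfg)
  expect_identical(tr1, tr2)

  # ...and a different seed moves it
  cfg2 <- sim_config(n_accounts = 800, days = 30, base_daily_tweets = 25,
                     shared_spike_days = c(10, 20), seed = 7)
  expect_false(identical(
    simulate_stream(simulate_accounts(cfg2), cfg2)$tweets, st$tweets))

  # contributors: per-account accumulation matches a brute-force oracle
  for (id in sample(st$contributors$account_id, 5)) {
    mine <- st$tweets[st$tweets$author_id == id, ]
    row <- st$contributors[st$contributors$account_id == id, ]
    expect_equal(row$impressions, sum(mine$deliveries))
    expect_equal(row$total_exposure,
                 sum(mine$deliveries) + sum(mine$retweet_impressions))
    expect_equal(row$n_retweets_made, sum(st$events$retweeter_id == id))
  }
})

test_that("paired trends plant shared spikes with no structure at boost 1", {
  flat_cfg <- sim_config(spike_boost = 1, seed = 8)
  tr <- simulate_paired_trends(flat_cfg)
  # no planted structure: spike days are not systematically elevated
  expect_lt(mean(tr$social$counts[flat_cfg$shared_spike_days]),
            1.2 * mean(tr$social$counts))

  cfg <- sim_config(seed = 9)
  tr2 <- simulate_paired_trends(cfg)
  expect_true(all(tr2$social$counts[cfg$shared_spike_days] >
                    max(tr2$social$counts[-cfg$shared_spike_days])))
})

test_that("coding-sheet corruption hits the analytic kappa", {
  set.seed(15)
  truth <- coding_sheet(sprintf("u%04d", 1:5000),
                        sample(account_types(), 5000, TRUE,
                               prob = c(0.7, 0.15, 0.1, 0.05)))
  expect_identical(corrupt_coding_sheet(truth, 0, seed = 1)$account_type,
                   truth$account_type)
  expect_equal(cohen_kappa(truth, corrupt_coding_sheet(truth, 0,
                                                       seed = 1))$kappa, 1)

  # full corruption over two categories: agreement below chance
  two <- coding_sheet(sprintf("v%03d", 1:200),
                      sample(c("individual", "media"), 200, TRUE))
  expect_lte(cohen_kappa(two, corrupt_coding_sheet(two, 1,
                                                   seed = 2))$kappa, 0)

  # closed-form kappa under independent corruption at rate e:
  # po = 1 - e; q_k = p_k (1-e) + e (1-p_k)/3; pe = sum p_k q_k
  e <- 0.1
  corrupted <- corrupt_coding_sheet(truth, e, seed = 3)
  p <- prop.table(table(factor(truth$account_type,
                               levels = account_types())))
  q <- p * (1 - e) + e * (1 - p) / 3
  expected_kappa <- ((1 - e) - sum(p * q)) / (1 - sum(p * q))
  expect_equal(cohen_kappa(truth, corrupted)$kappa, expected_kappa,
               tolerance = 0.03)

  expect_error(corrupt_coding_sheet(truth, 1.5), "\\[0, 1\\]")
})
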