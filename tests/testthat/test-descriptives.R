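test_that("descriptives summarize bids, pain and payouts per target", {
  d <- rbind(mini_log(10, target = "Self", outcome = 3, bid = 0),
             mini_log(10, target = "Stranger", outcome = 3, bid = 0,
                      block = 2L))
  desc <- descriptives(d)
  expect_equal(desc$by_target$mean_pain, c(3, 3))
  expect_equal(desc$by_target$sd_pain, c(0, 0))
  # no accepted bids, no misses: full endowment, 22 CHF per block
  expect_equal(desc$payouts$payout_chf, c(22, 22))
  expect_equal(desc$mean_payout_chf, 22)
  expect_error(descriptives(d[0, ]), "non-empty")
})

test_that("per-target mean bids follow the configured intercept ordering", {
  d <- simulate_dataset(default_run_config(), seed = 33)
  bt <- descriptives(d)$by_target
  bids <- setNames(bt$mean_bid, bt$target)
  expect_lt(bids[["Self"]], bids[["Beloved"]])
  expect_lt(bids[["Beloved"]], bids[["Stranger"]])
})

test_that("the pooled one-way F test is zero for identical groups", {
  d <- rbind(mini_log(3, target = "Self", bid = c(1, 2, 3)),
             mini_log(3, target = "Stranger", bid = c(1, 2, 3)))
  res <- oneway_target_test(d, "bid")
  expect_equal(res$F, 0)
  expect_equal(res$df1, 1)
  expect_equal(res$df2, 4)  # N - k
  solo <- mini_log(5, target = "Self")
  expect_error(oneway_target_test(solo, "bid"), "target levels")
})

test_that("the one-way test is calibrated under the null", {
  set.seed(41)
  n_rep <- 400
  pvals <- vapply(seq_len(n_rep), function(i) {
    d <- rbind(mini_log(420, target = "Self", bid = 0),
               mini_log(420, target = "Beloved", bid = 0),
               mini_log(420, target = "Stranger", bid = 0))
    d$bid <- rnorm(nrow(d))  # equal means, unit variance
    oneway_target_test(d, "bid")$p
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # df2 at the full design size
  d <- rbind(mini_log(420, target = "Self"), mini_log(420, target = "Beloved"),
             mini_log(420, target = "Stranger"))
  d$bid <- rnorm(1260)
  expect_equal(oneway_target_test(d, "bid")$df2, 1260 - 3)
})

test_that("gamble proportions exactly linear in EP0 give |r| = 1", {
  # per EP0 level, construct trial counts whose gamble proportion is ep0/3
  ep_levels <- unique(as.vector(outer(c(2, 3), cue_probabilities())))
  rows <- lapply(ep_levels, function(e) {
    n <- 300; k <- round(100 * e)
    d <- mini_log(n, target = "Self", choice = c(rep(1L, k), rep(0L, n - k)))
    d$ep0 <- e
    d
  })
  fit <- gamble_proportion_fit(do.call(rbind, rows))
  expect_equal(fit$r, 1)
  expect_equal(fit$slope, 1 / 3)
  expect_false(fit$degenerate)
})

test_that("constant gamble proportions are flagged degenerate with r = 0", {
  d <- mini_log(20, choice = rep(c(0L, 1L), 10))
  d$ep0 <- rep(c(0.5, 1.5), each = 10)
  d$choice <- rep(c(0L, 1L), 10)  # proportion 0.5 at both levels
  fit <- gamble_proportion_fit(d)
  expect_equal(fit$r, 0)
  expect_equal(fit$slope, 0)
  expect_true(fit$degenerate)
})

test_that("the default generator yields negative gamble-EP0 slopes for all targets", {
  d <- simulate_dataset(default_run_config(), seed = 34)
  fit <- gamble_proportion_fit(d)
  expect_equal(nrow(fit), 3)
  expect_true(all(fit$slope < 0))
  expect_true(all(fit$r < 0))
})
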