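fixed_agent <- function(choice = c(intercept = 0, ep0 = 0, risk0 = 0,
                                   beloved = 0, stranger = 0),
                        bid = c(intercept = 0, ep0 = 0, choice = 0,
                                beloved = 0, stranger = 0),
                        rating = c(intercept = 0, outcome = 0, risk1 = 0,
                                   wtp = 0, beloved = 0, stranger = 0,
                                   beloved_outcome = 0, stranger_outcome = 0,
                                   beloved_risk1 = 0, stranger_risk1 = 0,
                                   beloved_wtp = 0, stranger_wtp = 0),
                        utility = c(curvature = 0, inverse_temperature = 1),
                        noise = c(bid_sd = 0, rating_sd = 0)) {
  list(params = list(choice = choice, bid = bid, rating = rating,
                     utility = utility, noise = noise))
}

test_that("the choice policy saturates and is symmetric at zero", {
  s <- initial_state(cue(3, 0.9))
  # strongly negative EP0 slope with EP0 > 0: sure option almost surely
  hard <- fixed_agent(choice = c(intercept = 0, ep0 = -50, risk0 = 0,
                                 beloved = 0, stranger = 0))
  set.seed(21)
  expect_true(all(replicate(300, simulate_choice(hard, s, "Self")) == "sure"))
  # all coefficients zero: P(gamble) = 1/2
  set.seed(22)
  flat <- replicate(4000, simulate_choice(fixed_agent(), s, "Self"))
  expect_lt(abs(mean(flat == "gamble") - 0.5), 3 * sqrt(0.25 / 4000))
})

test_that("a negative EP0 slope lowers the gamble rate at high expected pain", {
  ag <- fixed_agent(choice = c(intercept = 0, ep0 = -1, risk0 = 0,
                               beloved = 0, stranger = 0))
  hi <- initial_state(cue(3, 0.9))   # EP0 = 2.7
  lo <- initial_state(cue(2, 0.1))   # EP0 = 0.2
  set.seed(23)
  g_hi <- mean(replicate(4000, simulate_choice(ag, hi, "Self")) == "gamble")
  g_lo <- mean(replicate(4000, simulate_choice(ag, lo, "Self")) == "gamble")
  expect_lt(g_hi, g_lo)
  expect_lt(abs(g_hi - plogis(-2.7)), 0.05)
})

test_that("bid policy is deterministic at zero noise and clips at bounds", {
  s <- initial_state(cue(2, 0.5))
  eight <- fixed_agent(bid = c(intercept = 8, ep0 = 0, choice = 0,
                               beloved = 0, stranger = 0))
  expect_equal(simulate_bid(eight, s, "sure", "Self"), 8)
  neg <- fixed_agent(bid = c(intercept = -5, ep0 = 0, choice = 0,
                             beloved = 0, stranger = 0))
  expect_equal(simulate_bid(neg, s, "gamble", "Self"), 0)
  # mean bid increases in EP0 under a positive slope
  ag <- fixed_agent(bid = c(intercept = 5, ep0 = 1.5, choice = 0,
                            beloved = 0, stranger = 0),
                    noise = c(bid_sd = 2, rating_sd = 0))
  set.seed(24)
  states <- lapply(cue_probabilities(), function(p) initial_state(cue(3, p)))
  means <- vapply(states, function(st)
    mean(replicate(2000, simulate_bid(ag, st, "sure", "Self"))), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("rating policy is the clamped linear predictor", {
  s1 <- prospect_state(3, 0.5)
  ag <- fixed_agent(rating = c(intercept = 0, outcome = 2, risk1 = 0,
                               wtp = 0, beloved = 0, stranger = 0,
                               beloved_outcome = 0, stranger_outcome = 0,
                               beloved_risk1 = 0, stranger_risk1 = 0,
                               beloved_wtp = 0, stranger_wtp = 0))
  expect_equal(simulate_rating(ag, 3, s1, 0, "Self"), 6)
  # negative Stranger x Risk1 interaction dampens stranger ratings at high risk
  ag2 <- fixed_agent(rating = c(intercept = 5, outcome = 0, risk1 = 0,
                                wtp = 0, beloved = 0, stranger = 0,
                                beloved_outcome = 0, stranger_outcome = 0,
                                beloved_risk1 = 0, stranger_risk1 = -1,
                                beloved_wtp = 0, stranger_wtp = 0))
  hi_risk <- prospect_state(3, 0.5)    # risk 2.25
  no_risk <- prospect_state(3, 1)      # risk 0
  expect_lt(simulate_rating(ag2, 3, hi_risk, 0, "Stranger"),
            simulate_rating(ag2, 3, no_risk, 0, "Stranger"))
  expect_equal(simulate_rating(ag2, 3, hi_risk, 0, "Self"),
               simulate_rating(ag2, 3, no_risk, 0, "Self"))
  # ratings never leave the 0-10 scale under wild parameter draws
  set.seed(25)
  for (i in 1:300) {
    coefs <- c(intercept = rnorm(1, 0, 10), outcome = rnorm(1, 0, 5),
               risk1 = rnorm(1, 0, 5), wtp = rnorm(1, 0, 2),
               beloved = 0, stranger = 0, beloved_outcome = 0,
               stranger_outcome = 0, beloved_risk1 = 0, stranger_risk1 = 0,
               beloved_wtp = 0, stranger_wtp = 0)
    wild <- fixed_agent(rating = coefs, noise = c(bid_sd = 0, rating_sd = 5))
    r <- simulate_rating(wild, sample(0:3, 1), s1, sample(0:20, 1), "Self")
    expect_true(r >= 0 && r <= 10)
  }
})

test_that("the default dataset has 63 x 20 rows and satisfies all invariants", {
  d <- simulate_dataset(default_run_config(), seed = 31)
  expect_equal(nrow(d), 1260)
  expect_equal(length(unique(d$dyad_id)), 63)
  expect_silent(validate_trial_log(d))
  expect_true(all(d$missed == 0L))
  expect_setequal(unique(d$target), c("Self", "Beloved", "Stranger"))
})

test_that("datasets are reproducible and round-trip through CSV exactly", {
  cfg <- small_config()
  d1 <- simulate_dataset(cfg, seed = 5)
  d2 <- simulate_dataset(cfg, seed = 5)
  expect_identical(d1, d2)
  path <- tempfile(fileext = ".csv")
  write_trial_log(d1, path)
  expect_identical(read_trial_log(path), d1)
})

test_that("a nonzero miss probability produces penalized, response-free trials", {
  cfg <- small_config()
  cfg$cohort$miss_prob <- 0.3
  d <- simulate_dataset(cfg, seed = 6)
  expect_gt(sum(d$missed), 0)
  m <- d[d$missed == 1L, ]
  expect_true(all(is.na(m$choice) & is.na(m$bid) & is.na(m$rating)))
  expect_true(all(m$accepted == 0L))
  expect_true(all(abs(m$ep1 - m$ep0) < 1e-12))
  one_block <- d[d$subject_id == d$subject_id[1] & d$block == 1, ]
  expect_equal(block_payout(one_block),
               220 - sum(one_block$bid[one_block$accepted == 1L]) -
                 2 * sum(one_block$missed))
  expect_silent(validate_trial_log(d))
})

test_that("with all noise off, simulated responses equal the policy values", {
  cfg <- deterministic_config()
  d <- simulate_dataset(cfg, seed = 8)
  g <- cfg$generator
  shift <- function(tgt, prefix, suffix = "") {
    if (tgt == "Self") return(0)
    unname(g[[prefix]]$mean[[paste0(tolower(tgt), suffix)]])
  }
  set.seed(81)
  for (i in sample(nrow(d), 40)) {
    row <- d[i, ]
    bid_mu <- g$bid$mean[["intercept"]] + g$bid$mean[["ep0"]] * row$ep0 +
      g$bid$mean[["choice"]] * row$choice + shift(row$target, "bid")
    expect_equal(row$bid, unname(round_bid(bid_mu)))
    rmu <- g$rating$mean[["intercept"]] +
      g$rating$mean[["outcome"]] * row$outcome +
      g$rating$mean[["risk1"]] * row$risk1 +
      g$rating$mean[["wtp"]] * row$bid +
      shift(row$target, "rating") +
      shift(row$target, "rating", "_outcome") * row$outcome +
      shift(row$target, "rating", "_risk1") * row$risk1 +
      shift(row$target, "rating", "_wtp") * row$bid
    expect_equal(row$rating, round(min(max(unname(rmu), 0), 10), 4))
  }
})

test_that("trial-log validation catches corrupted records", {
  d <- simulate_dataset(small_config(), seed = 9)
  bad <- d; bad$accepted[1] <- 1L - bad$accepted[1]
  expect_error(validate_trial_log(bad), "acceptance")
  bad <- d; bad$probability[3] <- 0.33
  expect_error(validate_trial_log(bad), "probability")
  bad <- d; bad$ep1[2] <- bad$ep1[2] + 1
  expect_error(validate_trial_log(bad), "ep1|prospect")
  bad <- d[, -5]
  expect_error(validate_trial_log(bad), "missing columns")
})
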