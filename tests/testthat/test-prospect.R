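test_that("expected pain is the probability-weighted intensity", {
  expect_equal(expected_pain(3, 0.9), 2.7)
  expect_equal(expected_pain(2, 0), 0)
  expect_equal(expected_pain(3, 0.5), 1.5)
  expect_error(expected_pain(3, 1.5), "probability")
  expect_error(expected_pain(-1, 0.5), "intensity")
})

test_that("pain risk is the variance of the two-outcome lottery", {
  # brute-force variance oracle over the lottery {P w.p. p; 0 otherwise}
  lottery_var <- function(P, p) {
    x <- c(P, 0); w <- c(p, 1 - p)
    sum(w * x^2) - sum(w * x)^2
  }
  expect_equal(pain_risk(3, 0.5), 2.25)
  expect_equal(pain_risk(3, 1.0), 0)
  expect_equal(pain_risk(2, 0.25), lottery_var(2, 0.25))  # 0.75
  expect_equal(pain_risk(2, 0.25), 0.75)
  set.seed(11)
  for (i in 1:50) {
    P <- runif(1, 0, 4); p <- runif(1)
    expect_equal(pain_risk(P, p), lottery_var(P, p))
    expect_equal(pain_risk(P, p), P^2 * p * (1 - p))  # algebraic form
  }
  # zero under certainty, maximal at p = 0.5
  expect_equal(pain_risk(3, 0), 0)
  p_grid <- seq(0.01, 0.99, by = 0.01)
  expect_equal(p_grid[which.max(pain_risk(3, p_grid))], 0.5)
})

test_that("choice updates follow the gamble/sure prospect rules", {
  # medium intensity: both accepted options yield equal expected pain
  for (p in cue_probabilities()) {
    g <- apply_choice(cue(2, p), "gamble", TRUE)
    s <- apply_choice(cue(2, p), "sure", TRUE)
    expect_equal(g$expected_pain, s$expected_pain)
  }
  # high intensity: the gamble is always more advantageous in expectation
  for (p in cue_probabilities()) {
    g <- apply_choice(cue(3, p), "gamble", TRUE)
    s <- apply_choice(cue(3, p), "sure", TRUE)
    expect_lt(g$expected_pain, s$expected_pain)
  }
  # rejection leaves the prospect identical to the initial cue state
  s0 <- initial_state(cue(3, 0.75))
  expect_identical(apply_choice(cue(3, 0.75), "sure", FALSE), s0)
  expect_equal(s0$expected_pain, 2.25)
  # accepted high-probability gamble can increase risk (closed form)
  g <- apply_choice(cue(3, 0.9), "gamble", TRUE)
  expect_equal(g$probability, 0.45)
  expect_equal(g$expected_pain, 1.35)
  expect_equal(g$risk, 9 * 0.45 * 0.55)
  expect_gt(g$risk, pain_risk(3, 0.9))  # 2.2275 > 0.81
})

test_that("risk orderings after choice hold over a dense probability grid", {
  p_grid <- seq(0.001, 0.999, by = 0.001)
  for (P in cue_intensities()) {
    risk0 <- pain_risk(P, p_grid)
    risk_sure <- pain_risk(P - 1, p_grid)
    expect_true(all(risk_sure < risk0))  # sure choices always reduce risk
    risk_gamble <- pain_risk(P, p_grid / 2)
    # gambles increase risk exactly when the initial probability > 2/3
    expect_identical(risk_gamble > risk0, p_grid > 2 / 3)
  }
})

test_that("choice coding maps between labels and the 0/1 model coding", {
  expect_identical(choice_code("gamble"), 1L)
  expect_identical(choice_code("sure"), 0L)
  expect_identical(as_choice(1), "gamble")
  expect_identical(as_choice(0), "sure")
  expect_identical(as_choice(TRUE), "gamble")
  expect_error(as_choice(2), "choice")
  expect_error(as_choice("maybe"), "choice")
})

test_that("cue construction enforces the design grids", {
  expect_error(cue(4, 0.5), "intensity")
  expect_error(cue(3, 0.3), "probability")
  cu <- cue(3, 0.9)
  expect_equal(initial_state(cu)$expected_pain, 2.7)
})
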