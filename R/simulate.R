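target_shift <- function(coefs, target, suffix = "") {
  key <- switch(target, Self = NA_character_,
                Beloved = paste0("beloved", suffix),
                Stranger = paste0("stranger", suffix),
                stop("unknown target: ", target))
  if (is.na(key)) 0 else unname(coefs[[key]])
}

#' Simulate a treatment choice (regression policy)
#'
#' The generative mirror of the choice model: the gamble is drawn as
#' Bernoulli(logistic(eta)) with
#' `eta = intercept + ep0 * EP0 + risk0 * Risk0 + target shift`,
#' where the intercept already contains the agent's random intercept.
#'
#' @param agent An agent from [make_cohort()] (or any list with a `params`
#'   element of the same shape).
#' @param state0 The pre-choice [prospect_state()].
#' @param target `"Self"`, `"Beloved"` or `"Stranger"`.
#' @return `"gamble"` or `"sure"`.
#' @export
simulate_choice <- function(agent, state0, target) {
  b <- agent$params$choice
  eta <- b[["intercept"]] + b[["ep0"]] * state0$expected_pain +
    b[["risk0"]] * state0$risk + target_shift(b, target)
  if (stats::runif(1) < stats::plogis(eta)) "gamble" else "sure"
}

#' Expected-utility difference between the gamble and the sure option
#'
#' Under an exponential (CARA) utility over pain magnitude
#' `u(x) = -(1 - exp(-rho * x)) / rho` (Arrow-Pratt absolute coefficient
#' `rho`; `u(x) = -x` in the `rho -> 0` limit), the gamble keeps intensity
#' `P` with probability `p0/2` and the sure option delivers intensity
#' `P - 1` with probability `p0`. Under the CRRA alternative the utility is
#' `u(x) = -x^(1 + rho)` (risk-averse over a bad for `rho > 0`).
#'
#' @param intensity Cue intensity `P` (vectorized).
#' @param probability Cue probability `p0` (vectorized).
#' @param curvature Arrow-Pratt coefficient `rho` (positive = risk-averse,
#'   negative = risk-seeking).
#' @param family `"cara"` (default) or `"crra"`.
#' @return `EU(gamble) - EU(sure)`, in utility units.
#' @export
utility_gap <- function(intensity, probability, curvature, family = "cara") {
  u <- pain_utility(family, curvature)
  (probability / 2) * u(intensity) - probability * u(intensity - 1)
}

pain_utility <- function(family = c("cara", "crra"), curvature) {
  family <- match.arg(family)
  if (family == "cara") {
    if (abs(curvature) < 1e-8) return(function(x) -x)
    function(x) -(1 - exp(-curvature * x)) / curvature
  } else {
    function(x) -x^(1 + curvature)
  }
}

#' Simulate a treatment choice (utility policy)
#'
#' Softmax choice between the two options' expected utilities under the
#' agent's utility curvature: the gamble is drawn with probability
#' `logistic(beta * (EU_gamble - EU_sure))`. This is the generative
#' counterpart of the risk-aversion estimator (see [risk_aversion()]).
#'
#' @inheritParams simulate_choice
#' @param family Utility family, `"cara"` or `"crra"`.
#' @return `"gamble"` or `"sure"`.
#' @export
simulate_choice_utility <- function(agent, state0, family = "cara") {
  u <- agent$params$utility
  gap <- utility_gap(state0$intensity, state0$probability,
                     u[["curvature"]], family)
  p <- stats::plogis(u[["inverse_temperature"]] * gap)
  if (stats::runif(1) < p) "gamble" else "sure"
}

#' Simulate a bid (willingness to pay)
#'
#' Linear policy plus Gaussian noise, rounded half-up to whole MUs and
#' clipped to `[0, max_bid]`:
#' `intercept + ep0 * EP0 + choice_shift * choice + target shift + noise`.
#'
#' @inheritParams simulate_choice
#' @param choice The selected option (see [as_choice()]).
#' @param max_bid Upper bid bound in MU.
#' @return An integer-valued bid in `[0, max_bid]`.
#' @export
simulate_bid <- function(agent, state0, choice, target, max_bid = 20) {
  b <- agent$params$bid
  mu <- b[["intercept"]] + b[["ep0"]] * state0$expected_pain +
    b[["choice"]] * choice_code(choice) + target_shift(b, target)
  round_bid(mu + stats::rnorm(1, 0, agent$params$noise[["bid_sd"]]), max_bid)
}

#' Simulate a pain rating
#'
#' Linear policy over delivered pain, post-choice risk, the bid (WTP) and
#' target, including the Target x Outcome, Target x Risk and Target x WTP
#' interaction terms, plus Gaussian noise, clamped to the 0--10 analogue
#' scale.
#'
#' @inheritParams simulate_choice
#' @param outcome Delivered pain level in `{0, 1, 2, 3}`.
#' @param state1 The post-auction [prospect_state()] (carries `risk`, the
#'   Risk1 predictor).
#' @param bid The bid (WTP) of the trial, in MU.
#' @return A rating in `[0, 10]`.
#' @export
simulate_rating <- function(agent, outcome, state1, bid, target) {
  if (!outcome %in% 0:3) stop("outcome must be a pain level in {0, 1, 2, 3}")
  b <- agent$params$rating
  mu <- b[["intercept"]] + b[["outcome"]] * outcome +
    b[["risk1"]] * state1$risk + b[["wtp"]] * bid +
    target_shift(b, target) +
    target_shift(b, target, "_outcome") * outcome +
    target_shift(b, target, "_risk1") * state1$risk +
    target_shift(b, target, "_wtp") * bid
  r <- mu + stats::rnorm(1, 0, agent$params$noise[["rating_sd"]])
  # 1e-4 rating-unit resolution: far beyond the physical precision of an
  # analogue scale, and keeps CSV round-trips exact
  round(min(max(r, 0), 10), 4)
}

#' Simulate a full trial-log dataset
#'
#' Composes the cohort generator, trial schedules, choice/bid/rating
#' policies, the sealed-bid auction and stochastic outcome delivery into
#' one trial-log table (one row per trial, the trial-log CSV dialect; see
#' [write_trial_log()]). Fully reproducible from `(config, seed)`.
#'
#' Missed responses (no choice, no bid, a fixed MU penalty, outcome
#' resolved from the initial cue state, no rating) occur independently per
#' trial with probability `cohort$miss_prob` (0 by default).
#'
#' @param config A `"run_config"`.
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A data frame with columns `dyad_id`, `subject_id`, `group`,
#'   `target`, `block`, `trial`, `intensity`, `probability`, `choice`
#'   (0 = sure, 1 = gamble), `bid`, `reserve`, `accepted`, `ep0`, `risk0`,
#'   `ep1`, `risk1`, `outcome`, `rating`, `missed`, `sex_da`, `same_sex`.
#' @examples
#' cfg <- default_run_config()
#' cfg$cohort$n_couples <- 2; cfg$cohort$n_stranger_dyads <- 3
#' d <- simulate_dataset(cfg, seed = 7)
#' nrow(d)  # 5 dyads x 20 trials
#' @export
simulate_dataset <- function(config = default_run_config(),
                             seed = config$seed) {
  validate_run_config(config)
  set.seed(as.integer(seed))
  cohort <- make_cohort(config)
  d <- config$design
  use_utility <- config$generator$choice_policy == "utility"
  rows <- lapply(cohort, function(agent)
    simulate_agent_trials(agent, config, d, use_utility))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

shift_vec <- function(coefs, targets, suffix = "") {
  vapply(targets, function(t) target_shift(coefs, t, suffix), numeric(1),
         USE.NAMES = FALSE)
}

# Vectorized per-agent trial generation: one draw vector per policy
# component instead of a per-trial loop. Policy math is identical to the
# scalar operations simulate_choice()/simulate_bid()/simulate_rating().
simulate_agent_trials <- function(agent, config, d, use_utility) {
  sched <- build_schedule(config, agent$target_other)
  n <- nrow(sched)
  P <- sched$intensity; p0 <- sched$probability; tgt <- sched$target
  # derived EP/Risk columns at 1e-10 resolution so CSV round-trips exactly
  ep0 <- round(expected_pain(P, p0), 10)
  risk0 <- round(pain_risk(P, p0), 10)
  reserve <- as.numeric(draw_reserve(n, d$reserve_continuous))
  missed <- stats::runif(n) < config$cohort$miss_prob
  if (use_utility) {
    u <- agent$params$utility
    gap <- utility_gap(P, p0, u[["curvature"]], config$analysis$utility_family)
    p_gamble <- stats::plogis(u[["inverse_temperature"]] * gap)
  } else {
    b <- agent$params$choice
    p_gamble <- stats::plogis(b[["intercept"]] + b[["ep0"]] * ep0 +
                                b[["risk0"]] * risk0 + shift_vec(b, tgt))
  }
  choice <- as.integer(stats::runif(n) < p_gamble)
  bb <- agent$params$bid
  bid_mu <- bb[["intercept"]] + bb[["ep0"]] * ep0 + bb[["choice"]] * choice +
    shift_vec(bb, tgt)
  bid <- round_bid(bid_mu + stats::rnorm(n, 0, agent$params$noise[["bid_sd"]]),
                   d$max_bid)
  choice[missed] <- NA_integer_
  bid[missed] <- NA_real_
  accepted <- as.integer(!missed & bid >= reserve)
  accepted[is.na(accepted)] <- 0L
  eff_int <- ifelse(accepted == 1L & choice == 0L, P - 1, P)
  eff_p <- ifelse(accepted == 1L & choice == 1L, p0 / 2, p0)
  eff_int[missed] <- P[missed]; eff_p[missed] <- p0[missed]
  ep1 <- round(expected_pain(eff_int, eff_p), 10)
  risk1 <- round(pain_risk(eff_int, eff_p), 10)
  outcome <- stats::rbinom(n, 1L, eff_p) * eff_int
  rb <- agent$params$rating
  rating_mu <- rb[["intercept"]] + rb[["outcome"]] * outcome +
    rb[["risk1"]] * risk1 + rb[["wtp"]] * bid + shift_vec(rb, tgt) +
    shift_vec(rb, tgt, "_outcome") * outcome +
    shift_vec(rb, tgt, "_risk1") * risk1 +
    shift_vec(rb, tgt, "_wtp") * bid
  rating <- round(pmin(pmax(
    rating_mu + stats::rnorm(n, 0, agent$params$noise[["rating_sd"]]), 0), 10), 4)
  rating[missed] <- NA_real_
  data.frame(
    dyad_id = agent$dyad_id, subject_id = agent$subject_id,
    group = agent$group, target = tgt, block = sched$block,
    trial = sched$trial, intensity = P, probability = p0,
    choice = choice, bid = bid, reserve = reserve, accepted = accepted,
    ep0 = ep0, risk0 = risk0, ep1 = ep1, risk1 = risk1,
    outcome = outcome, rating = rating, missed = as.integer(missed),
    sex_da = agent$sex_da, same_sex = agent$same_sex,
    stringsAsFactors = FALSE
  )
}
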