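# Shared fixtures: all data are generated in code at test time.

small_config <- function(n_couples = 3L, n_strangers = 4L, seed = 1L) {
  cfg <- default_run_config()
  cfg$cohort$n_couples <- n_couples
  cfg$cohort$n_stranger_dyads <- n_strangers
  cfg$seed <- seed
  cfg
}

# Noise-free, homogeneous-population configuration: every stochastic policy
# component (bid/rating noise, random intercepts, slope heterogeneity) off.
deterministic_config <- function(...) {
  cfg <- small_config(...)
  cfg$generator$noise$bid_sd <- 0
  cfg$generator$noise$rating_sd <- 0
  cfg$generator$choice$sd[] <- 0
  cfg$generator$bid$sd[] <- 0
  cfg$generator$rating$sd[] <- 0
  cfg$generator$utility$sd[] <- 0
  cfg
}

# Minimal hand-built trial-log rows for descriptives/payout tests.
mini_log <- function(n, target = "Self", bid = 0, accepted = 0L,
                     missed = 0L, outcome = 0, choice = 0L, rating = 0,
                     subject_id = "S001", block = 1L) {
  data.frame(
    dyad_id = 1L, subject_id = subject_id, group = "stranger",
    target = target, block = block, trial = seq_len(n),
    intensity = 3, probability = 0.5,
    choice = rep(as.integer(choice), length.out = n),
    bid = rep(bid, length.out = n), reserve = 20,
    accepted = rep(as.integer(accepted), length.out = n),
    ep0 = 1.5, risk0 = 2.25, ep1 = 1.5, risk1 = 2.25,
    outcome = rep(outcome, length.out = n),
    rating = rep(rating, length.out = n),
    missed = rep(as.integer(missed), length.out = n),
    sex_da = "F", same_sex = 0L, stringsAsFactors = FALSE
  )
}
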