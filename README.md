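# painchoice

Simulation and analysis of probabilistic pain decision-making in dyads.

## The problem

How does uncertainty shape decisions about pain — one's own and someone
else's? In the paradigm this package implements, a *deciding agent* (DA)
faces, on each trial, a cue announcing a pain stimulus of intensity *P*
(2 = medium, 3 = high, on a 0–3 scale) that will occur with probability
*p₀* ∈ {0.1, 0.25, 0.5, 0.75, 0.9}. The agent chooses between two
treatments:

- a **gamble** — a 50% chance of avoiding the pain altogether (effective
  probability *p₀/2*, intensity unchanged), or
- a **sure option** — the intensity is reduced by exactly one level with
  certainty (intensity *P − 1*, probability unchanged),

then bids 0–20 monetary units (MU; 10 MU = 1 CHF) on the chosen treatment
in a sealed-bid auction against a hidden random reserve price (a
Becker–DeGroot–Marschak-style mechanism: bids at or above the reserve are
accepted and the *bid* is deducted from a 220-MU block endowment). The
trial outcome is then delivered stochastically from the post-auction
prospect, and the agent rates the delivered pain on a 0–10 analogue
scale. Each agent plays two 10-trial blocks: one with themselves as the
pain target, one targeting the other member of their dyad (a romantic
partner, "Beloved", or a stranger).

The quantities driving the analysis come from the mean–variance
formalization of the two-outcome pain lottery:

- expected pain  **EP = p·P**
- pain risk  **Risk = p·P² − (p·P)² = P²·p·(1 − p)**

so risk vanishes under certainty and peaks at *p* = 0.5. Accepted sure
options always reduce risk; accepted gambles reduce expected pain but
*increase* risk whenever *p₀ > 2/3*.

The package is for researchers in decision neuroscience and pain
psychophysics who want to (a) simulate this paradigm end to end with a
generative agent population, (b) run its full statistical pipeline on
trial logs, and (c) validate that pipeline by parameter recovery — no
human data are required or included.

## What is inside

- **Task mechanics** — `cue()`, `expected_pain()`, `pain_risk()`,
  `apply_choice()`, `resolve_auction()`, `draw_reserve()`,
  `sample_outcome()`, `block_payout()`.
- **Calibration simulator** — `run_calibration()` /`select_energies()`
  reproduce the laser-energy calibration protocol (1.25–2.5 J, 0.25-J
  grid) that maps energies to low/medium/high pain via mean ratings
  closest to 3, 5 and 7.
- **Synthetic cohort** — `make_cohort()`, `build_schedule()`,
  `simulate_choice()`, `simulate_bid()`, `simulate_rating()`,
  `simulate_dataset()`: 63 dyads by default (20 couples, 43 stranger
  pairs), logistic choice policy, linear bid/rating policies with subject
  random intercepts and Gaussian noise.
- **Statistics** — `descriptives()`, `oneway_target_test()`,
  `gamble_proportion_fit()`, `risk_aversion()` (per-subject Arrow–Pratt
  curvature by maximum likelihood under a CARA softmax choice model, with
  profile-likelihood intervals), `fit_model()` (the three mixed models:
  binomial choice, Gaussian bid and rating, all with a subject random
  intercept, via lme4), and `recovery_report()` (parameter-recovery
  harness).
- **Pipeline & I/O** — `run_pipeline()`, trial-log CSV dialect
  (`write_trial_log()` / `read_trial_log()`), YAML/JSON configuration
  (`load_run_config()`), and a thin CLI at `inst/cli/painchoice`.

## Worked example

```r
library(painchoice)
d <- simulate_dataset(default_run_config(), seed = 2026)
descriptives(d)$by_target
#>     target   n mean_bid   sd_bid mean_pain  sd_pain
#> 1     Self 630 7.779365 3.107592  1.025397 1.207813
#> 2  Beloved 200 9.060000 3.010267  0.975000 1.200659
#> 3 Stranger 430 9.500000 3.162093  1.011628 1.171676
```

Agents bid least on their own pain and most on a stranger's — the
qualitative pattern the default generator is configured to produce — and
the gamble proportion falls roughly linearly with expected pain:

```r
gamble_proportion_fit(d)
#>     target      slope intercept          r n_levels degenerate
#> 1     Self -0.1882148 0.8596699 -0.9537727        9      FALSE
#> 2  Beloved -0.1996846 0.8496145 -0.8927428        9      FALSE
#> 3 Stranger -0.1289024 0.6162037 -0.9055458        9      FALSE
```

The choice model (binomial mixed model, Laplace approximation) recovers
the generating structure — higher expected pain and a stranger target
both push choices toward the sure option:

```r
fit_model(d, 1)
#> Model 1 (binomial, subject random intercept): choice ~ (ep0 + risk0) * target + sex_da + same_sex + (1 | subject_id)
#>   1260 observations, 63 subjects, logLik -777.8
#>            term estimate     se statistic statistic_type        p
#>     (Intercept)   1.8954 0.2821      6.72              z 1.85e-11
#>             ep0  -0.8997 0.1180     -7.63              z 2.41e-14
#>  targetStranger  -1.2516 0.3350     -3.74              z 1.86e-04
#>  ...
```

Per-subject risk attitudes, estimated from choices alone:

```r
risk_aversion(d)
#> Arrow-Pratt risk aversion (CARA utility, softmax choice)
#>   63 subjects fitted; 37 usable (converged, interior)
#>   curvature: mean -0.449, median -0.626, 78% risk-seeking (rho < 0)
```

Negative curvature means risk-seeking in the face of pain, consistent
with the majority-gamble behavior (56.2% gambles in this run).

See `vignette("pain-decisions")` for the model account, generator
defaults, numerical choices and limitations.

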