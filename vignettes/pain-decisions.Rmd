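---
title: "Modeling risky decisions about pain for self and others"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling risky decisions about pain for self and others}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(painchoice)
```

## The paradigm and its mean–variance model

The package simulates and analyzes a dyadic pain-management task. On each
trial a deciding agent sees a cue: a pain intensity $P \in \{2, 3\}$
(medium, high; 0 is no pain on the 0–3 outcome scale) paired with a
probability of occurrence $p_0 \in \{0.1, 0.25, 0.5, 0.75, 0.9\}$. The cue
defines a two-outcome lottery — intensity $P$ with probability $p_0$, no
pain otherwise — summarized by its first two moments:

$$\mathrm{EP}_0 = p_0 P, \qquad
  \mathrm{Risk}_0 = p_0 P^2 - (p_0 P)^2 = P^2 p_0 (1 - p_0).$$

Risk, the lottery's variance, is zero under certainty and maximal at
$p_0 = 0.5$. The agent picks one of two treatments and bids on it in a
sealed-bid auction against a hidden reserve price drawn uniformly on the
integers 0–20 MU. If the bid is at least the reserve, the bid is paid and
the treatment applies:

* **gamble** — a 50% chance of avoiding pain altogether, composed with the
  cue probability as a single Bernoulli draw: the prospect becomes
  $(P,\, p_0/2)$;
* **sure option** — a certain one-level intensity reduction: the prospect
  becomes $(P - 1,\, p_0)$.

A rejected bid leaves the prospect unchanged. These updates have three
properties the implementation treats as invariants, checked exhaustively
in the tests: at medium intensity both accepted options yield the same
expected pain ($2 \cdot p_0/2 = 1 \cdot p_0$); at high intensity the
gamble's expected pain is strictly lower; and while the sure option always
reduces risk, the gamble *raises* it exactly when $p_0 > 2/3$ (from
$P^2 p (1-p)$ algebra). The delivered outcome is then drawn from the
post-auction prospect, and the agent rates it on a continuous 0–10 scale.

Each agent plays two 10-trial blocks from a 220-MU endowment per block —
one block targeting themselves, one targeting the other member of the
dyad — with a 2-MU penalty for missed responses.

## Design choices where the protocol is underspecified

Several mechanism details are not fixed by the protocol; the package
settles them once and exposes the alternatives where sensible:

* **Reserve-price distribution.** Bids are whole MUs, so the reserve is
  discrete uniform on $\{0, \dots, 20\}$, giving bid $b$ an acceptance
  probability of $(b+1)/21$. A continuous-uniform variant is available via
  `design$reserve_continuous` for sensitivity checks. Ties (bid equal to
  reserve) are accepted.
* **Cue schedule.** Ten cue conditions and ten trials per block coincide,
  so each block is assumed to present the full intensity-by-probability
  cross exactly once, shuffled. This balanced schedule is an assumption,
  not a protocol fact; it makes EP/Risk predictors orthogonal to block by
  construction.
* **Missed trials** carry no choice, bid or rating; the outcome resolves
  from the initial cue prospect and the penalty affects only the payout.
  Because their predictors are undefined, missed trials are excluded
  listwise from all three models.
* **Bid granularity.** Continuous bid policies are rounded half-up and
  clipped to $[0, 20]$.

## The calibration simulator

The task's three subjective pain levels are obtained, per participant,
from a laser calibration: after one discarded 2.5-J acclimation pulse,
the five energies 1.25–2.25 J (0.25-J steps) are each rated three times in
random order on the 0–10 scale; the energies whose mean ratings are
closest to 3, 5 and 7 become the low/medium/high stimuli. When two pain
levels select the same energy, 0.25 J is added to the higher level, capped
at 2.5 J. Absolute-deviation ties break toward the lower energy (a
safety-first convention; the protocol is silent). The simulated rater is a
phenomenological linear psychometric profile (`psychometric_profile()`)
with Gaussian rating noise clamped to the scale — it stands in for a
human, not for nociceptive fiber dynamics.

## The synthetic cohort generator

`simulate_dataset()` generates the study conditions: 63 dyads (20 romantic
couples, 43 stranger pairs), each deciding agent playing both blocks. The
"other" target is labeled Beloved for couples and Stranger for stranger
pairs, so each agent contributes the Self level plus exactly one other
level — the partially between-subject target structure the models assume.
Couples are heterosexual by construction; deciding-agent and stranger-
partner sexes are drawn with the cohort's observed frequencies, and the
same-sex-dyad indicator follows.

Choices, bids and ratings come from generative mirrors of the three
analysis models: a logistic policy in EP₀, Risk₀ and target for the
choice; linear policies with Gaussian noise for bid and rating (the rating
policy includes the Target×Outcome, Target×Risk₁ and Target×WTP
interactions). Subject heterogeneity enters as Gaussian random intercepts
(the `sd` entry on each `intercept`); slope heterogeneity is available but
off by default so generating values are well-defined truths for recovery.

Default coefficient magnitudes are this package's own choices and are
**not** estimates from any dataset. Signs follow the qualitative pattern
the simulator is meant to reproduce (sure options become more attractive
as expected pain rises, more so for strangers; higher bids for others and
for higher expected pain; ratings driven by delivered pain, dampened by
risk for stranger targets, mildly amplified by risk for self). Magnitudes
were fixed by design arithmetic before any fitting: linear predictors stay
well inside the bid and rating response ranges across the whole cue grid,
so floor/ceiling clipping is rare and the fitted linear models remain
essentially unbiased; the bid intercept (6 MU) plus the EP₀ slope (1.5
MU per pain unit) also places mean bids in a realistic 8–10 MU band with
the Self < Beloved < Stranger ordering. An alternative utility-based
choice policy (`generator$choice_policy = "utility"`) draws choices from
the softmax-CARA model below, for estimator validation.

What the generator does *not* emulate: habituation or sensitization of
ratings across trials, any communication between dyad members, sequential
effects, response times, and any systematic relation between a subject's
risk attitude and their bid or rating policies. Passing recovery tests
therefore show that the pipeline recovers the generative structure it
assumes — not that real behavior satisfies that structure.

## The statistical pipeline

`descriptives()` reports per-target bid and delivered-pain means/SDs over
delivered trials and per-agent block payouts in CHF (10 MU = 1 CHF).
`oneway_target_test()` is a pooled fixed-effects one-way F across targets
(df₂ = N − k); it ignores the subject dependence and is labeled an
approximation — the mixed models are the dependence-aware analysis.
`gamble_proportion_fit()` computes the grand-mean gamble proportion at
each EP₀ level per target and the Pearson correlation of its OLS fit;
zero-variance proportions are reported as r = 0 with a degenerate flag
rather than NaN.

**The three mixed models** (`fit_model()`), all with a subject random
intercept and two nuisance covariates (deciding-agent sex, same-sex dyad):

| Model | Outcome | Fixed effects | Family |
|---|---|---|---|
| 1 | Choice (0 = sure, 1 = gamble) | EP₀, Risk₀, Target, Target×EP₀, Target×Risk₀ | binomial (Laplace) |
| 2 | WTP (bid, MU) | EP₀, Risk₀, Choice, Target, + Target interactions | Gaussian |
| 3 | Rating (0–10) | Pain outcome, Risk₁, WTP, Target, + Target interactions | Gaussian |

Target is treatment-coded with Self as reference. Inference is Wald
(estimate/SE): z statistics for the binomial model, t for the Gaussian
ones, both against the normal reference — no Satterthwaite or
Kenward–Roger degrees of freedom. The fitted term set is validated against
the specification at fit time; rank-deficient terms (e.g. Stranger
contrasts in a couples-only cohort) are dropped with a warning. On a
convergence failure the fit restarts once from a different optimizer
before erroring with diagnostics.

**Risk aversion.** The protocol calls for an Arrow–Pratt curvature per
subject without fixing a functional form, so the estimator's utility
family is an explicit package choice: exponential (CARA) utility over pain
magnitude, $u(x) = -(1 - e^{-\rho x})/\rho$, whose Arrow–Pratt absolute
coefficient is the constant $\rho$ (negative = risk-seeking), with a CRRA
alternative $u(x) = -x^{1+\rho}$ selectable via `analysis$utility_family`.
Choices follow a softmax on the options' expected utilities with inverse
temperature $\beta$; $(\rho, \log\beta)$ are estimated by maximum
likelihood (L-BFGS-B on $[-5, 5] \times [\log 10^{-2}, \log 10^{2}]$, one
restart from a perturbed start). Because the likelihood is visibly
non-quadratic in $\rho$ at task-sized samples, Wald intervals undercover;
`confint()`/`curvature_ci()` therefore invert the likelihood-ratio test,
profiling out $\beta$. Subjects at the search boundary — including
separation cases such as an agent who always gambles — are flagged and
excluded from group summaries.

## Numerical conventions

* Optimizer tolerance $10^{-6}$ on the relative objective change for the
  risk-aversion MLE; lme4 defaults for the mixed models, with bobyqa as
  the primary optimizer and one Nelder–Mead restart.
* Ratings are stored at $10^{-4}$ resolution and derived EP/Risk columns
  at $10^{-10}$; both are far beyond measurement precision and make the
  trial-log CSV round-trip bit-exact.
* One global seed per run; each pipeline stage draws from a substream
  derived deterministically from it at a fixed stage position, so adding
  a stage never perturbs another stage's draws.
* A degenerate zero-residual-variance response is outside a mixed model's
  domain; exact-recovery checks use epsilon noise instead.

## Validation strategy and problem sizes

The test suite validates the mechanics against independent oracles
(brute-force lottery variance, exhaustive auction enumeration, Monte-Carlo
convergence of outcomes to EP/Risk at $n = 10^5$ with 3-SD bounds) and the
pipeline by simulation at the default cohort size: 50 replicate cohorts
for parameter recovery (requiring the generating sign in at least 80% of
replicates for every nonzero term and Gaussian-model estimates within two
empirical SEs of truth), and 200 replicate cohorts with all choice effects
zeroed for the type-I calibration of the EP₀ Wald test (rejection rate
within 5% ± 3 points). These sizes give binomial standard errors of a few
percent on the monitored rates while keeping the default test run
comfortably fast.

## Limitations

Empirical coefficients from the human study this paradigm mirrors are not
reproducible here — the human dataset is not public — so the package
treats published effect directions only as qualitative targets for the
default generator, never as acceptance values. The pooled one-way F test
is a knowingly rough approximation retained for report compatibility. The
CARA softmax risk-aversion model is one defensible choice among several;
curvature estimates from 20-trial subjects are noisy and are best used at
the group level or with the profile intervals attached.
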