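#' Descriptive summaries of a trial log
#'
#' Per-target means and SDs of the bid (willingness to pay) and the
#' delivered pain outcome, computed over delivered (non-missed) trials, and
#' per-agent block payouts in CHF (10 MU = 1 CHF; missed-trial penalties
#' affect the payout only).
#'
#' @param dataset A trial-log data frame.
#' @param endowment Block endowment in MU.
#' @param penalty Missed-trial penalty in MU.
#' @param mu_per_chf MU per CHF for the payout report.
#' @return A list with `by_target` (data frame: target, n, mean_bid, sd_bid,
#'   mean_pain, sd_pain), `payouts` (data frame: subject_id, block,
#'   payout_mu, payout_chf), `mean_payout_chf`, and `gamble_rate` (the
#'   proportion of gambles over all delivered trials).
#' @export
descriptives <- function(dataset, endowment = 220, penalty = 2,
                         mu_per_chf = 10) {
  if (is.null(dataset) || nrow(dataset) == 0L)
    stop("descriptives need a non-empty trial log")
  delivered <- dataset[dataset$missed == 0L, , drop = FALSE]
  tgt <- factor(delivered$target, levels = c("Self", "Beloved", "Stranger"))
  tgt <- droplevels(tgt)
  by_target <- do.call(rbind, lapply(levels(tgt), function(t) {
    d <- delivered[tgt == t, ]
    data.frame(target = t, n = nrow(d),
               mean_bid = mean(d$bid), sd_bid = stats::sd(d$bid),
               mean_pain = mean(d$outcome), sd_pain = stats::sd(d$outcome))
  }))
  key <- interaction(dataset$subject_id, dataset$block, drop = TRUE)
  payouts <- do.call(rbind, lapply(levels(key), function(k) {
    d <- dataset[key == k, ]
    mu <- block_payout(d, endowment, penalty)
    data.frame(subject_id = d$subject_id[1], block = d$block[1],
               payout_mu = mu, payout_chf = mu / mu_per_chf)
  }))
  list(by_target = by_target, payouts = payouts,
       mean_payout_chf = mean(payouts$payout_chf),
       gamble_rate = mean(delivered$choice == 1L))
}

#' Pooled one-way F test across targets
#'
#' A fixed-effects one-way ANOVA of a trial-level variable (bid or pain
#' outcome) across the three target levels, on pooled delivered trials.
#' This treats trials as independent and is an approximation to the
#' dependence structure of the design (the subject-aware alternative is the
#' mixed model of [fit_model()]).
#'
#' @param dataset A trial-log data frame.
#' @param variable `"bid"` or `"outcome"`.
#' @return A list with `F`, `df1`, `df2` and `p`.
#' @export
oneway_target_test <- function(dataset, variable = c("bid", "outcome")) {
  variable <- match.arg(variable)
  d <- dataset[dataset$missed == 0L, , drop = FALSE]
  tgt <- droplevels(factor(d$target))
  if (nlevels(tgt) < 2L)
    stop("need at least 2 target levels for the one-way test")
  fit <- stats::aov(d[[variable]] ~ tgt)
  tab <- summary(fit)[[1]]
  list(F = tab[["F value"]][1], df1 = tab[["Df"]][1],
       df2 = tab[["Df"]][2], p = tab[["Pr(>F)"]][1])
}

#' Per-target linear fit of gamble proportions against expected pain
#'
#' For each target, computes the grand-mean proportion of gamble choices at
#' each initial expected-pain (EP0) level, fits an ordinary least-squares
#' line through those level means, and reports its slope, intercept and the
#' Pearson correlation of the fit. If the proportions have zero variance
#' across EP0 levels, the correlation is undefined; it is reported as 0
#' with `degenerate = TRUE`.
#'
#' @param dataset A trial-log data frame.
#' @return A data frame with one row per target: `target`, `slope`,
#'   `intercept`, `r`, `n_levels`, `degenerate`.
#' @export
gamble_proportion_fit <- function(dataset) {
  d <- dataset[dataset$missed == 0L, , drop = FALSE]
  targets <- intersect(c("Self", "Beloved", "Stranger"), unique(d$target))
  do.call(rbind, lapply(targets, function(t) {
    dt <- d[d$target == t, ]
    ep <- sort(unique(dt$ep0))
    if (length(ep) < 2L)
      stop("need at least 2 distinct EP0 levels for target ", t)
    prop <- vapply(ep, function(e) mean(dt$choice[dt$ep0 == e] == 1L),
                   numeric(1))
    if (stats::sd(prop) == 0) {
      data.frame(target = t, slope = 0, intercept = prop[1], r = 0,
                 n_levels = length(ep), degenerate = TRUE)
    } else {
      fit <- stats::lm(prop ~ ep)
      data.frame(target = t, slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r = stats::cor(ep, prop),
                 n_levels = length(ep), degenerate = FALSE)
    }
  }))
}
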