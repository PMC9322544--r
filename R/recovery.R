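#' Generating ("true") fixed effects implied by a configuration
#'
#' Maps the generator population means onto the fixed-effect term names of
#' a fitted model, for parameter-recovery checks. Terms the generator does
#' not produce (nuisance covariates, interactions the generative policy
#' lacks) are 0. Only valid when slope population SDs are 0 (the default),
#' so the population mean is the per-agent truth.
#'
#' @param config A `"run_config"`.
#' @param model Model number, 1, 2 or 3.
#' @return A named numeric vector over the model's expected terms.
#' @export
true_fixed_effects <- function(config, model) {
  g <- config$generator
  zero_int <- c("targetBeloved" = 0, "targetStranger" = 0)
  tv <- switch(as.character(model),
    "1" = {
      b <- g$choice$mean
      c("(Intercept)" = unname(b["intercept"]), ep0 = unname(b["ep0"]),
        risk0 = unname(b["risk0"]),
        targetBeloved = unname(b["beloved"]),
        targetStranger = unname(b["stranger"]),
        "ep0:targetBeloved" = 0, "ep0:targetStranger" = 0,
        "risk0:targetBeloved" = 0, "risk0:targetStranger" = 0)
    },
    "2" = {
      b <- g$bid$mean
      c("(Intercept)" = unname(b["intercept"]), ep0 = unname(b["ep0"]),
        risk0 = 0, choice = unname(b["choice"]),
        targetBeloved = unname(b["beloved"]),
        targetStranger = unname(b["stranger"]),
        "ep0:targetBeloved" = 0, "ep0:targetStranger" = 0,
        "risk0:targetBeloved" = 0, "risk0:targetStranger" = 0,
        "choice:targetBeloved" = 0, "choice:targetStranger" = 0)
    },
    "3" = {
      b <- g$rating$mean
      c("(Intercept)" = unname(b["intercept"]),
        outcome = unname(b["outcome"]), risk1 = unname(b["risk1"]),
        wtp = unname(b["wtp"]),
        targetBeloved = unname(b["beloved"]),
        targetStranger = unname(b["stranger"]),
        "outcome:targetBeloved" = unname(b["beloved_outcome"]),
        "outcome:targetStranger" = unname(b["stranger_outcome"]),
        "risk1:targetBeloved" = unname(b["beloved_risk1"]),
        "risk1:targetStranger" = unname(b["stranger_risk1"]),
        "wtp:targetBeloved" = unname(b["beloved_wtp"]),
        "wtp:targetStranger" = unname(b["stranger_wtp"]))
    },
    stop("model must be 1, 2 or 3"))
  c(tv, sex_daM = 0, same_sex = 0)
}

#' Parameter-recovery report
#'
#' Repeatedly simulates datasets from the configuration with known
#' generating coefficients, fits the requested models, and tabulates
#' per-term recovery: bias of the mean estimate, empirical SE (SD of
#' estimates across replicates), mean model SE, sign-recovery rate (for
#' terms with nonzero truth), the rate at which estimates fall within 2
#' model SEs of truth, and nominal-95% Wald interval coverage.
#'
#' @param config A `"run_config"`.
#' @param n_replicates Number of replicate cohorts (>= 1).
#' @param seed Base seed; replicate r uses `seed + r`.
#' @param models Which models to fit (subset of 1:3).
#' @return An object of class `"recovery_report"`: a list with `table`
#'   (one row per model x term), `n_replicates` and `n_failed` (replicates
#'   where a fit errored; excluded from the tabulation).
#' @export
recovery_report <- function(config = default_run_config(),
                            n_replicates = 50L, seed = config$seed,
                            models = config$analysis$models) {
  stopifnot(n_replicates >= 1L)
  draws <- list(); failed <- 0L
  for (r in seq_len(n_replicates)) {
    dat <- simulate_dataset(config, seed = (seed + r) %% .Machine$integer.max)
    fits <- tryCatch(lapply(models, function(m)
      suppressWarnings(fit_model(dat, m))), error = function(e) NULL)
    if (is.null(fits)) { failed <- failed + 1L; next }
    draws[[length(draws) + 1L]] <- fits
  }
  if (!length(draws)) stop("all replicates failed to fit")
  tabs <- lapply(seq_along(models), function(j) {
    m <- models[j]
    truth <- true_fixed_effects(config, m)
    terms <- draws[[1]][[j]]$coefficients$term
    per_term <- lapply(terms, function(tm) {
      est <- vapply(draws, function(f)
        f[[j]]$coefficients$estimate[f[[j]]$coefficients$term == tm],
        numeric(1))
      se <- vapply(draws, function(f)
        f[[j]]$coefficients$se[f[[j]]$coefficients$term == tm], numeric(1))
      tr <- if (tm %in% names(truth)) truth[[tm]] else NA_real_
      data.frame(
        model = m, term = tm, true = tr,
        mean_estimate = mean(est), bias = mean(est) - tr,
        empirical_se = stats::sd(est), mean_se = mean(se),
        sign_rate = if (!is.na(tr) && tr != 0) mean(sign(est) == sign(tr))
                    else NA_real_,
        within_2se_rate = mean(abs(est - tr) <= 2 * se),
        coverage_95 = mean(abs(est - tr) <= stats::qnorm(0.975) * se))
    })
    do.call(rbind, per_term)
  })
  structure(list(table = do.call(rbind, tabs),
                 n_replicates = n_replicates, n_failed = failed),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, digits = 3, ...) {
  cat(sprintf("Parameter recovery over %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a recovery report as CSV
#'
#' @param report A `"recovery_report"`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_recovery_report <- function(report, path) {
  utils::write.csv(report$table, path, row.names = FALSE, na = "")
  invisible(report$table)
}
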