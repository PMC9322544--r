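#' Specification of the three decision models
#'
#' The fixed structure of the three mixed models of the analysis pipeline,
#' all with a subject random intercept and the two nuisance covariates
#' (DA sex, same-sex dyad):
#' \describe{
#'   \item{Model 1 (binomial, Laplace)}{`choice (0 = sure, 1 = gamble) ~
#'     EP0 + Risk0 + Target + Target:EP0 + Target:Risk0`}
#'   \item{Model 2 (Gaussian)}{`wtp (the bid) ~ EP0 + Risk0 + Choice +
#'     Target + Target:EP0 + Target:Risk0 + Target:Choice`}
#'   \item{Model 3 (Gaussian)}{`rating ~ PainOutcome + Risk1 + WTP +
#'     Target + Target:PainOutcome + Target:Risk1 + Target:WTP`}
#' }
#' Target is treatment-coded with Self as the reference level.
#'
#' @param model Model number, 1, 2 or 3.
#' @return A list with `model`, `outcome` (response column), `core` (the
#'   crossed fixed-effect block), `nuisance`, `family` and
#'   `statistic_type` (`"z"` for the binomial model, `"t"` for Gaussian).
#' @export
model_spec <- function(model) {
  if (!(length(model) == 1L && model %in% 1:3))
    stop("model must be 1, 2 or 3")
  switch(as.character(model),
    "1" = list(model = 1L, outcome = "choice",
               core = "(ep0 + risk0) * target",
               nuisance = c("sex_da", "same_sex"),
               family = "binomial", statistic_type = "z"),
    "2" = list(model = 2L, outcome = "wtp",
               core = "(ep0 + risk0 + choice) * target",
               nuisance = c("sex_da", "same_sex"),
               family = "gaussian", statistic_type = "t"),
    "3" = list(model = 3L, outcome = "rating",
               core = "(outcome + risk1 + wtp) * target",
               nuisance = c("sex_da", "same_sex"),
               family = "gaussian", statistic_type = "t")
  )
}

prepare_model_data <- function(dataset, spec) {
  d <- dataset[dataset$missed == 0L, , drop = FALSE]
  d$wtp <- d$bid
  d$target <- factor(d$target,
                     levels = intersect(c("Self", "Beloved", "Stranger"),
                                        unique(d$target)))
  d$sex_da <- factor(d$sex_da, levels = intersect(c("F", "M"),
                                                  unique(d$sex_da)))
  d$subject_id <- factor(d$subject_id)
  vars <- unique(c(spec$outcome, "ep0", "risk0", "risk1", "outcome", "wtp",
                   "choice", "target", "sex_da", "same_sex", "subject_id"))
  d <- d[stats::complete.cases(d[, vars]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no complete trials to fit")
  d
}

model_formula <- function(spec, data) {
  nuis <- spec$nuisance
  dropped <- character(0)
  if ("sex_da" %in% nuis && nlevels(data$sex_da) < 2L) {
    nuis <- setdiff(nuis, "sex_da"); dropped <- c(dropped, "sex_da")
  }
  if ("same_sex" %in% nuis && stats::var(data$same_sex) == 0) {
    nuis <- setdiff(nuis, "same_sex"); dropped <- c(dropped, "same_sex")
  }
  if (length(dropped))
    warning("dropping constant nuisance term(s): ",
            paste(dropped, collapse = ", "))
  rhs <- paste(c(spec$core, nuis, "(1 | subject_id)"), collapse = " + ")
  stats::as.formula(paste(spec$outcome, "~", rhs))
}

is_converged <- function(fit) {
  cc <- fit@optinfo$conv
  opt_ok <- is.null(cc$opt) || cc$opt == 0
  msgs <- unlist(c(cc$lme4$messages,
                   lapply(fit@optinfo$warnings, as.character)))
  warn_ok <- !any(grepl("failed to converge", msgs, ignore.case = TRUE))
  opt_ok && warn_ok
}

#' Fit one of the three decision mixed models
#'
#' Fits the model of [model_spec()] with a subject random intercept:
#' binomial family via Laplace-approximation GLMM ([lme4::glmer()]),
#' Gaussian via [lme4::lmer()]. Missed trials and trials with any missing
#' model variable are excluded listwise. Fixed-effect inference is Wald:
#' the binomial model reports z statistics, the Gaussian models report t
#' statistics (estimate / SE); p-values use the normal reference in both
#' cases (no Satterthwaite or Kenward-Roger machinery).
#'
#' The fitted fixed-effect term set is validated against the specification;
#' inestimable (rank-deficient) terms, e.g. Stranger contrasts in a
#' couples-only cohort, are dropped with a warning. On a convergence
#' failure the fit is retried once from a different optimizer/start point;
#' a fit that still fails raises an error carrying the optimizer
#' diagnostics.
#'
#' @param dataset A trial-log data frame.
#' @param model Model number, 1, 2 or 3.
#' @param reltol Not used directly by lme4's optimizers; kept for the
#'   record in the returned object.
#' @return An object of class `"painchoice_fit"`: a list with
#'   `coefficients` (data frame: `term`, `estimate`, `se`, `statistic`,
#'   `statistic_type`, `p`), `model`, `outcome`, `family`, `formula`,
#'   `n_obs`, `n_groups`, `converged`, `logLik` and `fit` (the underlying
#'   merMod object).
#' @export
fit_model <- function(dataset, model, reltol = 1e-6) {
  spec <- model_spec(model)
  d <- prepare_model_data(dataset, spec)
  form <- model_formula(spec, d)
  fit_once <- function(optimizer) {
    withCallingHandlers({
      if (spec$family == "binomial") {
        lme4::glmer(form, data = d, family = stats::binomial(),
                    nAGQ = 1L,
                    control = lme4::glmerControl(optimizer = optimizer,
                                                 calc.derivs = TRUE))
      } else {
        lme4::lmer(form, data = d,
                   control = lme4::lmerControl(
                     optimizer = optimizer,
                     check.nlev.gtr.1 = "ignore",
                     check.nobs.vs.nlev = "ignore",
                     check.nobs.vs.rankZ = "ignore"))
      }
    }, warning = function(w) invokeRestart("muffleWarning"),
       message = function(m) invokeRestart("muffleMessage"))
  }
  fit <- fit_once("bobyqa")
  if (!is_converged(fit)) {
    fit2 <- tryCatch(fit_once("Nelder_Mead"), error = function(e) NULL)
    if (!is.null(fit2) && is_converged(fit2)) fit <- fit2
  }
  if (!is_converged(fit))
    stop("model ", model, " did not converge after restart; diagnostics: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  validate_fitted_terms(fit, spec, d)
  tab <- as.data.frame(summary(fit)$coefficients)
  est <- tab[, 1]; se <- tab[, 2]; stat <- est / se
  coefs <- data.frame(term = rownames(tab), estimate = est, se = se,
                      statistic = stat, statistic_type = spec$statistic_type,
                      p = 2 * stats::pnorm(-abs(stat)), row.names = NULL)
  structure(list(coefficients = coefs, model = spec$model,
                 outcome = spec$outcome, family = spec$family,
                 formula = form, n_obs = nrow(d),
                 n_groups = nlevels(d$subject_id),
                 converged = TRUE, reltol = reltol,
                 logLik = as.numeric(stats::logLik(fit)), fit = fit),
            class = "painchoice_fit")
}

validate_fitted_terms <- function(fit, spec, data) {
  fixed <- stats::as.formula(paste("~", spec$core))
  # expected design columns given the data's factor levels (before any
  # rank-deficiency drops); nuisance terms are checked by construction
  expected <- colnames(stats::model.matrix(fixed, data))
  fitted_terms <- names(lme4::fixef(fit))
  nuis_ok <- c("sex_daM", "sex_daF", "same_sex")
  core_fitted <- setdiff(fitted_terms, nuis_ok)
  extra <- setdiff(core_fitted, expected)
  if (length(extra))
    stop("fitted design matrix drifted from the model specification; ",
         "unexpected term(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(expected, core_fitted)
  if (length(missing))
    warning("inestimable term(s) dropped from model ", spec$model, ": ",
            paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.painchoice_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Model %d (%s, subject random intercept): %s\n",
              x$model, x$family,
              paste(trimws(deparse(x$formula)), collapse = " ")))
  cat(sprintf("  %d observations, %d subjects, logLik %.1f\n",
              x$n_obs, x$n_groups, x$logLik))
  tab <- x$coefficients
  tab$estimate <- round(tab$estimate, digits)
  tab$se <- round(tab$se, digits)
  tab$statistic <- round(tab$statistic, 2)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.painchoice_fit <- function(object, ...) {
  print(object, ...)
  invisible(object$coefficients)
}

#' @export
coef.painchoice_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Write coefficient tables for one or more fitted models as CSV
#'
#' Columns: `model, term, estimate, se, statistic, statistic_type, p`.
#'
#' @param fits A `"painchoice_fit"` or a list of them.
#' @param path Output CSV path.
#' @return The combined table, invisibly.
#' @export
write_coefficient_table <- function(fits, path) {
  if (inherits(fits, "painchoice_fit")) fits <- list(fits)
  tab <- do.call(rbind, lapply(fits, function(f)
    cbind(model = f$model, f$coefficients)))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
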