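#' Estimate Arrow-Pratt risk aversion from treatment choices
#'
#' Fits, per subject, a softmax choice rule between the expected utilities
#' of the gamble and the sure option under an exponential (CARA) utility
#' over pain magnitude, `u(x) = -(1 - exp(-rho * x)) / rho`, whose
#' Arrow-Pratt absolute coefficient is the constant `rho` (positive =
#' risk-averse, negative = risk-seeking; `u(x) = -x` at `rho = 0`). The
#' probability of choosing the gamble on a trial with cue `(P, p0)` is
#' `logistic(beta * (EU_gamble - EU_sure))` with inverse temperature
#' `beta > 0`; `(rho, log beta)` are estimated by maximum likelihood. A
#' CRRA-style alternative, `u(x) = -x^(1 + rho)`, is available via
#' `family = "crra"`.
#'
#' Estimates at the search boundary (e.g. a subject who always gambles, for
#' whom the likelihood has no interior maximum) are flagged `boundary` and
#' excluded from group summaries, as are non-converged fits (one automatic
#' restart from a perturbed start point is attempted first).
#'
#' @param data A trial-log data frame (see [simulate_dataset()]); missed
#'   trials are excluded.
#' @param family Utility family: `"cara"` (default) or `"crra"`.
#' @param min_choices Minimum number of non-missed choices per subject.
#' @param reltol Relative convergence tolerance of the optimizer.
#' @return An object of class `"risk_aversion"`: a list with `estimates`
#'   (data frame: `subject_id`, `curvature`, `se_curvature`,
#'   `inverse_temperature`, `log_lik`, `n_choices`, `converged`,
#'   `boundary`), `family`, and `call`.
#' @seealso [simulate_choice_utility()] for the generative counterpart.
#' @examples
#' cfg <- default_run_config()
#' cfg$cohort$n_couples <- 0; cfg$cohort$n_stranger_dyads <- 5
#' cfg$generator$choice_policy <- "utility"
#' fit <- risk_aversion(simulate_dataset(cfg, seed = 3))
#' coef(fit)
#' @export
risk_aversion <- function(data, family = c("cara", "crra"),
                          min_choices = 5L, reltol = 1e-6) {
  family <- match.arg(family)
  d <- data[data$missed == 0L & !is.na(data$choice), , drop = FALSE]
  if (nrow(d) == 0L) stop("no non-missed choices in the data")
  ids <- unique(d$subject_id)
  per_subject <- lapply(ids, function(id) {
    di <- d[d$subject_id == id, ]
    list(id = as.character(id), intensity = di$intensity,
         probability = di$probability, choice = di$choice)
  })
  est <- do.call(rbind, lapply(per_subject, function(s)
    fit_subject_risk_aversion(s$intensity, s$probability, s$choice,
                              family, min_choices, reltol, s$id)))
  rownames(est) <- NULL
  structure(list(estimates = est, family = family, data = per_subject,
                 call = match.call()),
            class = "risk_aversion")
}

#' @rdname risk_aversion
#' @param intensity,probability,choice Per-trial cue intensity, cue
#'   probability and choice (0 = sure, 1 = gamble) for one subject.
#' @param subject_id Identifier carried into the result row.
#' @export
estimate_risk_aversion <- function(intensity, probability, choice,
                                   family = c("cara", "crra"),
                                   min_choices = 5L, reltol = 1e-6,
                                   subject_id = "subject") {
  family <- match.arg(family)
  fit_subject_risk_aversion(intensity, probability, choice, family,
                            min_choices, reltol, subject_id)
}

fit_subject_risk_aversion <- function(intensity, probability, choice,
                                      family, min_choices, reltol,
                                      subject_id) {
  ok <- !is.na(choice)
  intensity <- intensity[ok]; probability <- probability[ok]
  choice <- choice[ok]
  n <- length(choice)
  if (n < min_choices)
    stop("subject ", subject_id, " has ", n, " choices; need >= ", min_choices)
  rho_bound <- 5; logb_bound <- log(100)
  negll <- function(par) {
    rho <- par[1]; beta <- exp(par[2])
    gap <- utility_gap(intensity, probability, rho, family)
    eta <- beta * gap
    # log(1 + exp(x)) computed stably
    -sum(choice * eta - log1p(exp(-abs(eta))) - pmax(eta, 0))
  }
  run <- function(start) {
    stats::optim(start, negll, method = "L-BFGS-B",
                 lower = c(-rho_bound, -logb_bound),
                 upper = c(rho_bound, logb_bound),
                 control = list(factr = reltol / .Machine$double.eps),
                 hessian = TRUE)
  }
  opt <- tryCatch(run(c(0, log(1))), error = function(e) NULL)
  if (is.null(opt) || opt$convergence != 0) {
    opt2 <- tryCatch(run(c(0.5, log(2))), error = function(e) NULL)
    if (!is.null(opt2) && (is.null(opt) || opt2$value <= opt$value)) opt <- opt2
  }
  if (is.null(opt)) {
    return(data.frame(subject_id = subject_id, curvature = NA_real_,
                      se_curvature = NA_real_,
                      inverse_temperature = NA_real_, log_lik = NA_real_,
                      n_choices = n, converged = FALSE, boundary = FALSE))
  }
  rho <- opt$par[1]; beta <- exp(opt$par[2])
  boundary <- abs(rho) > rho_bound - 1e-3 ||
    abs(opt$par[2]) > logb_bound - 1e-3 ||
    length(unique(choice)) == 1L
  se <- tryCatch({
    v <- solve(opt$hessian)[1, 1]
    if (is.finite(v) && v > 0) sqrt(v) else NA_real_
  }, error = function(e) NA_real_)
  data.frame(subject_id = subject_id, curvature = rho, se_curvature = se,
             inverse_temperature = beta, log_lik = -opt$value,
             n_choices = n, converged = opt$convergence == 0,
             boundary = boundary)
}

#' Profile-likelihood confidence interval for the curvature
#'
#' Inverts the likelihood-ratio test of `rho = rho0`, profiling out the
#' inverse temperature: the interval contains every `rho0` whose profile
#' deviance lies within the chi-squared(1) quantile of the minimum. Better
#' calibrated than the Wald interval, whose quadratic approximation is poor
#' for this likelihood.
#'
#' @inheritParams estimate_risk_aversion
#' @param level Confidence level.
#' @return A length-2 vector `c(lower, upper)`; endpoints at the +-5 search
#'   bound indicate an unbounded profile (boundary/separation cases).
#' @export
curvature_ci <- function(intensity, probability, choice, level = 0.95,
                         family = c("cara", "crra")) {
  family <- match.arg(family)
  rho_bound <- 5; logb_bound <- log(100)
  profile_nll <- function(rho) {
    negll <- function(lb) {
      beta <- exp(lb)
      eta <- beta * utility_gap(intensity, probability, rho, family)
      -sum(choice * eta - pmax(eta, 0) - log1p(exp(-abs(eta))))
    }
    stats::optimize(negll, c(-logb_bound, logb_bound))$objective
  }
  fit <- fit_subject_risk_aversion(intensity, probability, choice, family,
                                   1L, 1e-8, "ci")
  rho_hat <- fit$curvature
  nll_min <- min(-fit$log_lik, profile_nll(rho_hat))
  cut <- nll_min + stats::qchisq(level, 1) / 2
  lwr <- if (profile_nll(-rho_bound) > cut)
    stats::uniroot(function(r) profile_nll(r) - cut, c(-rho_bound, rho_hat),
                   tol = 1e-4)$root else -rho_bound
  upr <- if (profile_nll(rho_bound) > cut)
    stats::uniroot(function(r) profile_nll(r) - cut, c(rho_hat, rho_bound),
                   tol = 1e-4)$root else rho_bound
  c(lower = lwr, upper = upr)
}

#' @export
confint.risk_aversion <- function(object, parm, level = 0.95, ...) {
  subjects <- vapply(object$data, `[[`, character(1), "id")
  if (!missing(parm)) subjects <- intersect(subjects, parm)
  ci <- t(vapply(object$data[match(subjects,
                                   vapply(object$data, `[[`, character(1), "id"))],
                 function(s) curvature_ci(s$intensity, s$probability,
                                          s$choice, level, object$family),
                 numeric(2)))
  rownames(ci) <- subjects
  colnames(ci) <- c("lower", "upper")
  ci
}

#' @export
print.risk_aversion <- function(x, ...) {
  cat(sprintf("Arrow-Pratt risk aversion (%s utility, softmax choice)\n",
              toupper(x$family)))
  ok <- x$estimates$converged & !x$estimates$boundary
  cat(sprintf("  %d subjects fitted; %d usable (converged, interior)\n",
              nrow(x$estimates), sum(ok)))
  if (any(ok)) {
    rho <- x$estimates$curvature[ok]
    cat(sprintf("  curvature: mean %.3f, median %.3f, %.0f%% risk-seeking (rho < 0)\n",
                mean(rho), stats::median(rho), 100 * mean(rho < 0)))
  }
  invisible(x)
}

#' @export
summary.risk_aversion <- function(object, ...) {
  print(object)
  ok <- object$estimates$converged & !object$estimates$boundary
  if (any(ok)) print(summary(object$estimates$curvature[ok]))
  invisible(object$estimates)
}

#' @export
coef.risk_aversion <- function(object, ...) {
  stats::setNames(object$estimates$curvature, object$estimates$subject_id)
}

#' @export
logLik.risk_aversion <- function(object, ...) {
  ok <- object$estimates$converged
  structure(sum(object$estimates$log_lik[ok]),
            df = 2L * sum(ok), class = "logLik")
}
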