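trial_log_columns <- function() {
  c("dyad_id", "subject_id", "group", "target", "block", "trial",
    "intensity", "probability", "choice", "bid", "reserve", "accepted",
    "ep0", "risk0", "ep1", "risk1", "outcome", "rating", "missed",
    "sex_da", "same_sex")
}

#' Write / read a trial log
#'
#' The trial-log CSV dialect: one row per trial, UTF-8, `.` decimal
#' separator, mandatory header, missing values as empty fields, columns
#' `dyad_id, subject_id, group, target, block, trial, intensity,
#' probability, choice, bid, reserve, accepted, ep0, risk0, ep1, risk1,
#' outcome, rating, missed` plus the two nuisance covariates the analysis
#' models require, `sex_da` and `same_sex`. `choice`, `accepted` and
#' `missed` are coded 0/1 (choice: 0 = sure option, 1 = gamble).
#'
#' @param dataset A trial-log data frame (see [simulate_dataset()]).
#' @param path CSV path.
#' @return `write_trial_log()`: `path`, invisibly. `read_trial_log()`: the
#'   validated trial-log data frame.
#' @export
write_trial_log <- function(dataset, path) {
  dataset <- validate_trial_log(dataset)
  utils::write.csv(dataset[, trial_log_columns()], path,
                   row.names = FALSE, na = "", quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_trial_log
#' @export
read_trial_log <- function(path) {
  cols <- c(dyad_id = "integer", subject_id = "character",
            group = "character", target = "character", block = "integer",
            trial = "integer", intensity = "numeric",
            probability = "numeric", choice = "integer", bid = "numeric",
            reserve = "numeric", accepted = "integer", ep0 = "numeric",
            risk0 = "numeric", ep1 = "numeric", risk1 = "numeric",
            outcome = "numeric", rating = "numeric", missed = "integer",
            sex_da = "character", same_sex = "integer")
  dat <- tryCatch(
    utils::read.csv(path, colClasses = unname(cols), na.strings = "",
                    fileEncoding = "UTF-8", check.names = FALSE),
    error = function(e) stop("failed to parse trial log '", path, "': ",
                             conditionMessage(e)))
  if (!identical(names(dat), names(cols)))
    stop("trial log '", path, "' does not have the expected columns; got: ",
         paste(names(dat), collapse = ", "))
  validate_trial_log(dat)
}

#' Validate a trial-log table
#'
#' Checks the per-trial invariants of the paradigm: cue values on their
#' grids, bids and reserves in range, acceptance consistent with bid vs.
#' reserve, missed trials with missing choice/bid/rating, outcomes bounded
#' by the cue intensity, EP/Risk columns consistent with the recorded
#' choice and acceptance, ratings in `[0, 10]`.
#'
#' @param dataset A trial-log data frame.
#' @return The dataset, invisibly usable, after passing all checks.
#' @export
validate_trial_log <- function(dataset) {
  miss <- setdiff(trial_log_columns(), names(dataset))
  if (length(miss))
    stop("trial log is missing columns: ", paste(miss, collapse = ", "))
  bad_row <- function(cond, what) {
    i <- which(cond)
    if (length(i))
      stop("trial-log invariant violated (", what, ") at row ", i[1])
  }
  m <- dataset$missed == 1L
  bad_row(!dataset$target %in% c("Self", "Beloved", "Stranger"), "target label")
  bad_row(!dataset$group %in% c("couple", "stranger"), "group label")
  bad_row(!dataset$probability %in% cue_probabilities(), "cue probability")
  bad_row(!dataset$intensity %in% cue_intensities(), "cue intensity")
  bad_row(!m & !dataset$choice %in% c(0L, 1L), "choice coding")
  bad_row(m & (!is.na(dataset$choice) | !is.na(dataset$bid) |
                 !is.na(dataset$rating)), "missed trial with responses")
  bad_row(!m & (dataset$bid < 0 | dataset$bid > 20 |
                  dataset$bid != round(dataset$bid)), "bid range")
  bad_row(dataset$reserve < 0 | dataset$reserve > 20, "reserve range")
  bad_row(!m & (dataset$accepted != as.integer(dataset$bid >= dataset$reserve)),
          "acceptance rule")
  bad_row(m & dataset$accepted != 0L, "missed trial accepted")
  bad_row(dataset$outcome > dataset$intensity, "outcome above cue intensity")
  bad_row(!dataset$outcome %in% 0:3, "outcome level")
  tol <- 1e-9
  bad_row(abs(dataset$ep0 - dataset$probability * dataset$intensity) > tol,
          "ep0 formula")
  bad_row(abs(dataset$risk0 - dataset$intensity^2 * dataset$probability *
                (1 - dataset$probability)) > tol, "risk0 formula")
  rejected <- dataset$accepted == 0L
  bad_row(rejected & (abs(dataset$ep1 - dataset$ep0) > tol |
                        abs(dataset$risk1 - dataset$risk0) > tol),
          "rejected trial must keep the initial prospect")
  g <- !m & dataset$accepted == 1L & dataset$choice == 1L
  bad_row(g & abs(dataset$ep1 - dataset$probability / 2 * dataset$intensity) > tol,
          "ep1 after accepted gamble")
  s <- !m & dataset$accepted == 1L & dataset$choice == 0L
  bad_row(s & abs(dataset$ep1 - dataset$probability * (dataset$intensity - 1)) > tol,
          "ep1 after accepted sure option")
  bad_row(s & !(dataset$outcome == 0 | dataset$outcome == dataset$intensity - 1),
          "sure-option outcome level")
  bad_row(!m & (dataset$rating < 0 | dataset$rating > 10), "rating range")
  dataset
}
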