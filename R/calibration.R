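#' Psychometric profile of a simulated rater
#'
#' A phenomenological linear stand-in for a human rater in the pain
#' calibration procedure: the rating of a laser pulse of energy `E` (Joules)
#' is `offset + slope * E` plus Gaussian noise, clamped to the 0--10 rating
#' scale.
#'
#' @param slope Rating units per Joule (> 0: ratings increase with energy).
#' @param offset Rating at zero energy (rating units; typically negative).
#' @param noise_sd Rating noise SD (>= 0).
#' @return An object of class `"psychometric_profile"`.
#' @export
psychometric_profile <- function(slope, offset, noise_sd = 0) {
  if (!(length(slope) == 1L && is.finite(slope) && slope > 0))
    stop("slope must be a single positive number")
  if (!(length(noise_sd) == 1L && is.finite(noise_sd) && noise_sd >= 0))
    stop("noise_sd must be a single non-negative number")
  structure(list(slope = slope, offset = offset, noise_sd = noise_sd),
            class = "psychometric_profile")
}

calibration_grid <- function() seq(1.25, 2.25, by = 0.25)

rate_pulse <- function(profile, energy) {
  r <- profile$offset + profile$slope * energy +
    stats::rnorm(length(energy), 0, profile$noise_sd)
  pmin(pmax(r, 0), 10)
}

#' Simulate one pain-calibration run
#'
#' Mirrors the calibration protocol: one initial acclimation pulse at the
#' highest energy (2.5 J) whose rating is discarded, then the five energies
#' 1.25--2.25 J (0.25 J steps) in random order, three repetitions each
#' (16 stimulations in total, 15 rated). Per-energy mean ratings are then
#' mapped to the three task pain levels with [select_energies()].
#'
#' @param profile A [psychometric_profile()].
#' @return An object of class `"calibration_result"`: list with the selected
#'   `energies` (named low/medium/high, Joules), the per-energy
#'   `mean_ratings`, the full `schedule` (energy, rating, discarded) and a
#'   `collision` flag.
#' @export
run_calibration <- function(profile) {
  stopifnot(inherits(profile, "psychometric_profile"))
  grid <- calibration_grid()
  order <- sample(rep(grid, 3L))
  schedule <- data.frame(
    energy = c(2.5, order),
    rating = c(rate_pulse(profile, 2.5), rate_pulse(profile, order)),
    discarded = c(TRUE, rep(FALSE, length(order)))
  )
  rated <- schedule[!schedule$discarded, ]
  mean_ratings <- tapply(rated$rating, factor(rated$energy, levels = grid), mean)
  res <- select_energies(mean_ratings)
  res$schedule <- schedule
  res
}

#' Map per-energy mean ratings to the three task energies
#'
#' For each target rating 3, 5 and 7 (low, medium, high pain) picks the grid
#' energy whose mean rating is closest; absolute-deviation ties are broken
#' toward the lower energy. If two pain levels select the same energy,
#' 0.25 J is added to the higher pain level, capped at 2.5 J.
#'
#' @param mean_ratings Named numeric vector of mean ratings, names the
#'   energies of the 1.25--2.25 J grid.
#' @return An object of class `"calibration_result"` (see
#'   [run_calibration()]), without the `schedule` element.
#' @export
select_energies <- function(mean_ratings) {
  if (length(mean_ratings) == 0L) stop("mean_ratings must be non-empty")
  energies <- as.numeric(names(mean_ratings))
  if (any(is.na(energies))) stop("mean_ratings must be named by energy")
  ord <- order(energies)
  energies <- energies[ord]
  ratings <- as.numeric(mean_ratings)[ord]
  targets <- c(low = 3, medium = 5, high = 7)
  pick <- vapply(targets, function(t) {
    energies[which.min(abs(ratings - t))]  # first = lowest energy on ties
  }, numeric(1))
  collision <- FALSE
  for (i in 2:3) {
    if (pick[i] <= pick[i - 1]) {
      if (pick[i] == pick[i - 1]) collision <- TRUE
      pick[i] <- min(pick[i - 1] + 0.25, 2.5)
    }
  }
  structure(list(energies = pick,
                 mean_ratings = stats::setNames(ratings, energies),
                 collision = collision),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("Pain calibration: selected energies (J)\n")
  print(x$energies)
  if (x$collision) cat("(collision rule applied: +0.25 J on a higher level)\n")
  invisible(x)
}

#' Write a calibration report as CSV
#'
#' One row per grid energy with its mean rating, plus the selected
#' low/medium/high energies as a `selected` column.
#'
#' @param result A `"calibration_result"`.
#' @param path Output CSV path.
#' @return The report data frame, invisibly.
#' @export
write_calibration_report <- function(result, path) {
  en <- as.numeric(names(result$mean_ratings))
  sel <- vapply(en, function(e) {
    lv <- names(result$energies)[result$energies == e]
    if (length(lv)) paste(lv, collapse = "+") else ""
  }, character(1))
  report <- data.frame(energy = en, mean_rating = as.numeric(result$mean_ratings),
                       selected = sel)
  extra <- setdiff(result$energies, en)  # collision bumps can land on 2.5 J
  if (length(extra)) {
    sel2 <- vapply(extra, function(e)
      paste(names(result$energies)[result$energies == e], collapse = "+"),
      character(1))
    report <- rbind(report, data.frame(energy = extra, mean_rating = NA_real_,
                                       selected = sel2))
  }
  utils::write.csv(report, path, row.names = FALSE, na = "")
  invisible(report)
}
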