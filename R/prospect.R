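#' Probabilistic pain cue
#'
#' A cue shown at the start of a trial: a pain intensity level (2 = medium,
#' 3 = high, on a 0--3 scale where 0 is no pain) together with the probability
#' that the pain occurs at all.
#'
#' @param intensity Pain intensity level, one of 2 or 3.
#' @param probability Probability of pain occurrence, one of
#'   0.1, 0.25, 0.5, 0.75 or 0.9.
#' @return An object of class `"pain_cue"`: a list with elements `intensity`
#'   and `probability`.
#' @examples
#' cue(3, 0.5)
#' @export
cue <- function(intensity, probability) {
  if (!(length(intensity) == 1L && intensity %in% c(2, 3)))
    stop("cue intensity must be 2 (medium) or 3 (high)")
  if (!(length(probability) == 1L && probability %in% cue_probabilities()))
    stop("cue probability must be one of ",
         paste(cue_probabilities(), collapse = ", "))
  structure(list(intensity = as.numeric(intensity),
                 probability = as.numeric(probability)),
            class = "pain_cue")
}

#' @rdname cue
#' @export
cue_probabilities <- function() c(0.1, 0.25, 0.5, 0.75, 0.9)

#' @rdname cue
#' @export
cue_intensities <- function() c(2, 3)

#' Expected pain of a two-outcome pain lottery
#'
#' The probability-weighted pain intensity: the mean of the lottery that
#' delivers intensity `P` with probability `p` and no pain otherwise.
#'
#' @param intensity Pain intensity level (non-negative real, vectorized).
#' @param probability Probability of pain occurrence in `[0, 1]` (vectorized).
#' @return `probability * intensity`, in pain-level units.
#' @examples
#' expected_pain(3, 0.9)  # 2.7
#' @export
expected_pain <- function(intensity, probability) {
  check_lottery_args(intensity, probability)
  probability * intensity
}

#' Pain risk of a two-outcome pain lottery
#'
#' Risk is the variance of the lottery that delivers intensity `P` with
#' probability `p` and no pain (0) otherwise:
#' `p * P^2 - (p * P)^2`, algebraically `P^2 * p * (1 - p)`.
#' It is zero under certainty (`p` 0 or 1) and, for a fixed intensity,
#' maximal at `p = 0.5`.
#'
#' @inheritParams expected_pain
#' @return Variance of the pain lottery, in squared pain-level units.
#' @examples
#' pain_risk(3, 0.5)  # 2.25
#' @export
pain_risk <- function(intensity, probability) {
  check_lottery_args(intensity, probability)
  probability * intensity^2 - (probability * intensity)^2
}

check_lottery_args <- function(intensity, probability) {
  if (any(!is.finite(intensity)) || any(intensity < 0))
    stop("intensity must be a non-negative finite number")
  if (any(!is.finite(probability)) || any(probability < 0) || any(probability > 1))
    stop("probability must lie in [0, 1]")
  invisible(TRUE)
}

#' Prospect state: effective intensity, probability, expected pain and risk
#'
#' Carries the pain lottery in force at a point in the trial (before the
#' choice, or after an accepted treatment has modified it), with its
#' expected pain and risk derived from the effective intensity and
#' probability.
#'
#' @param intensity Effective pain intensity level (non-negative real).
#' @param probability Effective probability of pain occurrence in `[0, 1]`.
#' @return An object of class `"prospect_state"`: a list with elements
#'   `intensity`, `probability`, `expected_pain` and `risk`.
#' @export
prospect_state <- function(intensity, probability) {
  check_lottery_args(intensity, probability)
  structure(list(intensity = as.numeric(intensity),
                 probability = as.numeric(probability),
                 expected_pain = expected_pain(intensity, probability),
                 risk = pain_risk(intensity, probability)),
            class = "prospect_state")
}

#' @export
print.prospect_state <- function(x, ...) {
  cat(sprintf(
    "Pain prospect: intensity %g with probability %g (EP = %g, Risk = %g)\n",
    x$intensity, x$probability, x$expected_pain, x$risk))
  invisible(x)
}

#' Initial prospect state of a cue
#'
#' @param cue A [cue()].
#' @return The pre-choice [prospect_state()] implied by the cue.
#' @export
initial_state <- function(cue) {
  prospect_state(cue$intensity, cue$probability)
}

#' Choice coding
#'
#' The two treatment options, coded as in the choice model: 0 = sure option,
#' 1 = gamble. `as_choice()` normalizes 0/1, `"sure"`/`"gamble"` (any case)
#' or logical (TRUE = gamble) input to the character form.
#'
#' @param choice A choice in any accepted coding.
#' @return `as_choice()`: `"sure"` or `"gamble"`; `choice_code()`: 0 or 1.
#' @export
as_choice <- function(choice) {
  if (length(choice) != 1L || is.na(choice)) stop("choice must be a single non-missing value")
  if (is.logical(choice)) return(if (choice) "gamble" else "sure")
  if (is.numeric(choice)) {
    if (!choice %in% c(0, 1)) stop("numeric choice must be 0 (sure) or 1 (gamble)")
    return(if (choice == 1) "gamble" else "sure")
  }
  ch <- tolower(as.character(choice))
  if (!ch %in% c("sure", "gamble")) stop("choice must be 'sure' or 'gamble'")
  ch
}

#' @rdname as_choice
#' @export
choice_code <- function(choice) {
  if (as_choice(choice) == "gamble") 1L else 0L
}

#' Apply a treatment choice to a cue
#'
#' Returns the prospect state in force after the auction. An accepted gamble
#' halves the probability of pain (a 50% chance of avoiding pain altogether,
#' composed with the cue probability: effective probability `p0 / 2`,
#' intensity unchanged). An accepted sure option reduces the intensity by
#' exactly one level with certainty (intensity `P - 1`, probability
#' unchanged). A rejected bid leaves the prospect identical to the initial
#' cue state.
#'
#' @param cue A [cue()], or any prospect-like list with `intensity` and
#'   `probability` fields (e.g. a [prospect_state()]), which allows applying
#'   the mechanism to probabilities outside the task's cue grid.
#' @param choice The selected option (see [as_choice()]).
#' @param accepted Logical: was the bid accepted by the auction?
#' @return A [prospect_state()].
#' @examples
#' apply_choice(cue(3, 0.9), "gamble", accepted = TRUE)
#' @export
apply_choice <- function(cue, choice, accepted) {
  if (!is.logical(accepted) || length(accepted) != 1L || is.na(accepted))
    stop("accepted must be TRUE or FALSE")
  if (!accepted) return(initial_state(cue))
  ch <- as_choice(choice)
  if (ch == "gamble") {
    prospect_state(cue$intensity, cue$probability / 2)
  } else {
    prospect_state(cue$intensity - 1, cue$probability)
  }
}

#' Resolve a prospect into a delivered pain outcome
#'
#' Draws the trial outcome from the post-auction prospect: pain at the
#' effective intensity with the effective probability, otherwise no pain.
#' The long-run mean of outcomes equals the state's expected pain and the
#' long-run variance equals its risk.
#'
#' @param state A [prospect_state()].
#' @param n Number of independent outcomes to draw.
#' @return Numeric vector of length `n` with values in `{0, intensity}`.
#' @export
sample_outcome <- function(state, n = 1L) {
  stopifnot(inherits(state, "prospect_state"))
  stats::rbinom(n, 1L, state$probability) * state$intensity
}
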