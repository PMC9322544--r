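#' Draw hidden reserve prices
#'
#' The auction's reserve price is hidden and random, between 0 and 20
#' monetary units (MU). Bids are entered in whole MUs, so the default
#' reserve distribution is discrete uniform on the integers 0..20; a
#' continuous uniform on `[0, 20]` is available for sensitivity checks.
#'
#' @param n Number of reserve prices to draw.
#' @param continuous If `TRUE`, draw from continuous uniform `[0, 20]`
#'   instead of the integer grid.
#' @return Numeric vector of length `n` of reserve prices in `[0, 20]`.
#' @export
draw_reserve <- function(n = 1L, continuous = FALSE) {
  if (continuous) stats::runif(n, 0, 20) else sample(0:20, n, replace = TRUE)
}

#' Resolve a sealed bid against a reserve price
#'
#' A bid equal to or higher than the hidden reserve price is accepted, and
#' the bid itself (not the reserve) is deducted from the endowment.
#'
#' @param bid Integer bid in MU, 0--20.
#' @param reserve_price Reserve price in `[0, 20]`.
#' @return An object of class `"auction_result"`: list with `bid`,
#'   `reserve_price` and logical `accepted`.
#' @examples
#' resolve_auction(5, 5)$accepted   # ties are accepted
#' @export
resolve_auction <- function(bid, reserve_price) {
  if (length(bid) != 1L || !is.finite(bid) || bid < 0 || bid > 20)
    stop("bid must lie in [0, 20] MU")
  if (length(reserve_price) != 1L || !is.finite(reserve_price) ||
      reserve_price < 0 || reserve_price > 20)
    stop("reserve_price must lie in [0, 20] MU")
  structure(list(bid = bid, reserve_price = reserve_price,
                 accepted = bid >= reserve_price),
            class = "auction_result")
}

#' Round a continuous bid policy value to the MU grid
#'
#' Half-up rounding (0.5 rounds to 1) then clipping to `[0, max_bid]`;
#' simulated bid policies are continuous but entered bids are whole MUs.
#'
#' @param x Numeric vector of policy values.
#' @param max_bid Upper bid bound in MU.
#' @return Integer-valued numeric vector in `[0, max_bid]`.
#' @export
round_bid <- function(x, max_bid = 20) {
  pmin(pmax(floor(x + 0.5), 0), max_bid)
}

#' Block payout in monetary units
#'
#' Each block starts from a fixed endowment; every accepted bid is deducted,
#' and every missed trial (no response) incurs a fixed penalty.
#'
#' @param trials A data frame of trials from one block, with columns `bid`,
#'   `accepted` and `missed` (trial-log dialect).
#' @param endowment Block endowment in MU.
#' @param penalty Missed-trial penalty in MU.
#' @return The block payout in MU.
#' @export
block_payout <- function(trials, endowment = 220, penalty = 2) {
  missed <- as.logical(trials$missed)
  accepted <- as.logical(trials$accepted) & !missed
  spent <- sum(trials$bid[accepted]) + penalty * sum(missed)
  payout <- endowment - spent
  if (payout < 0)
    stop("negative block payout: spending exceeded the endowment")
  payout
}
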