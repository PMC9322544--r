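#' Generate a synthetic cohort of deciding agents
#'
#' Draws the dyad structure (romantic couples and stranger pairs), sexes,
#' and per-agent generative parameters from the population distributions in
#' the configuration. Each dyad has one deciding agent (DA) and one passive
#' target (PT); the "other" block targets the Beloved for couple dyads and
#' the Stranger for stranger dyads. Couples are heterosexual (PT sex is the
#' opposite of the DA's), so the same-sex-dyad indicator is informative only
#' for stranger pairs.
#'
#' Per-agent coefficients are drawn as independent Gaussians around the
#' population means; the `intercept` SD plays the role of the subject
#' random-intercept SD of each outcome model.
#'
#' @param config A `"run_config"` (see [default_run_config()]).
#' @param seed Optional integer; if supplied, seeds the RNG first.
#' @return An object of class `"pain_cohort"`: a list of agents, each a list
#'   with `dyad_id`, `subject_id`, `group`, `target_other`, `sex_da`,
#'   `sex_pt`, `same_sex` and `params` (see Details).
#' @export
make_cohort <- function(config = default_run_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  co <- config$cohort
  n <- co$n_couples + co$n_stranger_dyads
  agents <- vector("list", n)
  if (n == 0L) return(structure(agents, class = "pain_cohort"))
  groups <- rep(c("couple", "stranger"), c(co$n_couples, co$n_stranger_dyads))
  for (i in seq_len(n)) {
    group <- groups[i]
    if (group == "couple") {
      sex_da <- if (stats::runif(1) < co$p_female_da_couple) "F" else "M"
      sex_pt <- if (sex_da == "F") "M" else "F"
    } else {
      sex_da <- if (stats::runif(1) < co$p_female_da_stranger) "F" else "M"
      sex_pt <- if (stats::runif(1) < co$p_female_pt_stranger) "F" else "M"
    }
    agents[[i]] <- list(
      dyad_id = i,
      subject_id = sprintf("S%03d", i),
      group = group,
      target_other = if (group == "couple") "Beloved" else "Stranger",
      sex_da = sex_da,
      sex_pt = sex_pt,
      same_sex = as.integer(sex_da == sex_pt),
      params = draw_agent_params(config$generator)
    )
  }
  structure(agents, class = "pain_cohort")
}

draw_coef_block <- function(block) {
  mu <- block$mean
  sd <- block$sd[names(mu)]
  mu + stats::rnorm(length(mu), 0, sd)
}

#' Draw one agent's generative parameters
#'
#' @param generator The `generator` section of a run configuration.
#' @return A list with coefficient vectors `choice` (log-odds of the gamble),
#'   `bid` (MU), `rating` (rating units), a `utility` vector (Arrow-Pratt
#'   `curvature` and softmax `inverse_temperature`) and `noise` SDs.
#' @export
draw_agent_params <- function(generator) {
  list(
    choice = draw_coef_block(generator$choice),
    bid = draw_coef_block(generator$bid),
    rating = draw_coef_block(generator$rating),
    utility = draw_coef_block(generator$utility),
    noise = c(bid_sd = generator$noise$bid_sd,
              rating_sd = generator$noise$rating_sd)
  )
}

#' @export
print.pain_cohort <- function(x, ...) {
  groups <- vapply(x, `[[`, character(1), "group")
  cat(sprintf("Synthetic cohort: %d dyads (%d couples, %d stranger pairs)\n",
              length(x), sum(groups == "couple"), sum(groups == "stranger")))
  invisible(x)
}

#' Build one agent's trial schedule
#'
#' Two blocks of `trials_per_block` trials. Within each block the cues are
#' the full cross of the intensity and probability sets (10 conditions by
#' default, hence each condition exactly once per block), independently
#' shuffled; the block-target order (self-first vs. other-first) is drawn
#' uniformly.
#'
#' @param config A `"run_config"`.
#' @param target_other `"Beloved"` or `"Stranger"` (the dyad's other-block
#'   target label).
#' @return A data frame with columns `block`, `trial`, `target`, `intensity`,
#'   `probability`.
#' @export
build_schedule <- function(config = default_run_config(),
                           target_other = "Stranger") {
  d <- config$design
  cross <- expand.grid(intensity = d$intensities,
                       probability = d$probabilities,
                       KEEP.OUT.ATTRS = FALSE)
  if (nrow(cross) != d$trials_per_block)
    stop("trials_per_block must equal the number of cue conditions (",
         nrow(cross), ") for a balanced schedule")
  if (d$blocks != 2L)
    stop("the paradigm has exactly 2 blocks (one per target)")
  self_first <- stats::runif(1) < 0.5
  targets <- if (self_first) c("Self", target_other) else c(target_other, "Self")
  blocks <- lapply(seq_len(d$blocks), function(b) {
    perm <- cross[sample.int(nrow(cross)), ]
    data.frame(block = b, trial = seq_len(nrow(cross)),
               target = targets[b],
               intensity = perm$intensity, probability = perm$probability,
               row.names = NULL)
  })
  do.call(rbind, blocks)
}
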