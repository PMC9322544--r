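#' Default run configuration
#'
#' All design constants, cohort structure, generator population parameters
#' and analysis settings of the paradigm, as one nested list. The design
#' constants are the task's: a 220-MU endowment per block, bids on a 0--20
#' MU scale, a 2-MU penalty for missed responses, 2 blocks of 10 trials,
#' cue intensities {2, 3} crossed with probabilities
#' {0.1, 0.25, 0.5, 0.75, 0.9}, and 10 MU = 1 CHF for reports.
#'
#' Generator coefficient magnitudes are this package's own choices (signs
#' follow the qualitative findings the simulator is meant to reproduce;
#' magnitudes are free parameters, not taken from any dataset). The `sd`
#' entry on each `intercept` is the subject random-intercept SD; `sd`
#' entries on slopes allow population heterogeneity in coefficients
#' (0 by default).
#'
#' @return A named nested list of class `"run_config"`.
#' @export
default_run_config <- function() {
  cfg <- list(
    seed = 1L,
    design = list(
      endowment = 220, max_bid = 20, penalty = 2,
      trials_per_block = 10L, blocks = 2L,
      intensities = c(2, 3),
      probabilities = c(0.1, 0.25, 0.5, 0.75, 0.9),
      reserve_continuous = FALSE,
      mu_per_chf = 10
    ),
    cohort = list(
      n_couples = 20L, n_stranger_dyads = 43L,
      miss_prob = 0,
      p_female_da_couple = 0.5,
      p_female_da_stranger = 26 / 43,
      p_female_pt_stranger = 29 / 43
    ),
    generator = list(
      choice_policy = "regression",
      choice = list(
        mean = c(intercept = 1.6, ep0 = -0.8, risk0 = 0,
                 beloved = 0, stranger = -0.8),
        sd = c(intercept = 0.6, ep0 = 0, risk0 = 0,
               beloved = 0, stranger = 0)
      ),
      bid = list(
        mean = c(intercept = 6, ep0 = 1.5, choice = 0,
                 beloved = 1.2, stranger = 1.5),
        sd = c(intercept = 1.5, ep0 = 0, choice = 0,
               beloved = 0, stranger = 0)
      ),
      rating = list(
        mean = c(intercept = 2, outcome = 1.5, risk1 = 0.3, wtp = 0.04,
                 beloved = 0.6, stranger = 0.8,
                 beloved_outcome = 0.2, stranger_outcome = 0.4,
                 beloved_risk1 = 0, stranger_risk1 = -0.6,
                 beloved_wtp = 0.04, stranger_wtp = 0.04),
        sd = c(intercept = 0.5, outcome = 0, risk1 = 0, wtp = 0,
               beloved = 0, stranger = 0,
               beloved_outcome = 0, stranger_outcome = 0,
               beloved_risk1 = 0, stranger_risk1 = 0,
               beloved_wtp = 0, stranger_wtp = 0)
      ),
      noise = list(bid_sd = 2.5, rating_sd = 0.8),
      utility = list(
        mean = c(curvature = -0.3, inverse_temperature = 3),
        sd = c(curvature = 0.2, inverse_temperature = 0)
      )
    ),
    analysis = list(
      utility_family = "cara",
      optim_reltol = 1e-6,
      models = c(1L, 2L, 3L)
    )
  )
  structure(cfg, class = "run_config")
}

merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, "$", key) else key
    if (!key %in% names(defaults))
      stop("unknown configuration key: ", full)
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(user[[key]]))
        stop("configuration key ", full, " must be a section (mapping)")
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      val <- user[[key]]
      if (is.list(val)) val <- unlist(val)
      tmpl <- defaults[[key]]
      if (is.numeric(tmpl) && !is.numeric(val))
        stop("configuration key ", full, " must be numeric")
      if (!is.null(names(tmpl)) && length(val) == length(tmpl) &&
          is.null(names(val)))
        names(val) <- names(tmpl)
      if (!is.null(names(tmpl)) && !is.null(names(val))) {
        bad <- setdiff(names(val), names(tmpl))
        if (length(bad))
          stop("unknown entries in ", full, ": ", paste(bad, collapse = ", "))
        tmpl[names(val)] <- val
        val <- tmpl
      }
      defaults[[key]] <- val
    }
  }
  defaults
}

#' Load (and validate) a run configuration
#'
#' Reads a YAML or JSON configuration file, fills every absent field with
#' its default, rejects unknown keys with an error naming the key, and
#' validates constraints. An empty file yields the full default
#' configuration.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` configuration file, or
#'   `NULL` for pure defaults.
#' @return A validated `"run_config"` list.
#' @export
load_run_config <- function(path = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("configuration file not found: ", path)
    user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    }
    if (length(user)) cfg <- merge_config(unclass(cfg), user)
    class(cfg) <- "run_config"
  }
  validate_run_config(cfg)
}

#' @rdname load_run_config
#' @param config A `"run_config"` list to validate in place.
#' @export
validate_run_config <- function(config) {
  d <- config$design
  for (f in c("endowment", "max_bid", "penalty", "trials_per_block", "blocks"))
    if (!(length(d[[f]]) == 1L && is.finite(d[[f]]) && d[[f]] > 0))
      stop("design$", f, " must be a single positive number")
  if (any(d$probabilities <= 0) || any(d$probabilities >= 1))
    stop("design$probabilities must lie strictly in (0, 1)")
  if (any(d$intensities < 1))
    stop("design$intensities must be pain levels >= 1")
  co <- config$cohort
  if (co$n_couples < 0 || co$n_stranger_dyads < 0)
    stop("cohort sizes must be non-negative")
  if (co$miss_prob < 0 || co$miss_prob > 1)
    stop("cohort$miss_prob must lie in [0, 1]")
  g <- config$generator
  if (!g$choice_policy %in% c("regression", "utility"))
    stop("generator$choice_policy must be 'regression' or 'utility'")
  if (g$noise$bid_sd < 0 || g$noise$rating_sd < 0)
    stop("generator noise SDs must be non-negative")
  for (blk in c("choice", "bid", "rating"))
    if (any(g[[blk]]$sd < 0))
      stop("generator$", blk, "$sd entries must be non-negative")
  if (!config$analysis$utility_family %in% c("cara", "crra"))
    stop("analysis$utility_family must be 'cara' or 'crra'")
  if (!(length(config$seed) == 1L && is.finite(config$seed)))
    stop("seed must be a single integer")
  config
}

#' Save a run configuration
#'
#' @param config A `"run_config"` list.
#' @param path Output path; format chosen by extension (`.json` or YAML).
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(config), path, precision = 15)
  }
  invisible(path)
}

# Stable md5 of a configuration (canonical JSON via tempfile; used in
# reproducibility sidecars).
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# Deterministic per-stage seed substreams: fixed positions per stage so
# adding a stage never perturbs another stage's draws.
stage_seed <- function(seed, stage) {
  stages <- c(simulate = 1L, `calibrate-sim` = 2L, analyze = 3L, recover = 4L)
  if (!stage %in% names(stages)) stop("unknown stage: ", stage)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  seeds <- sample.int(.Machine$integer.max - 1L, length(stages))
  if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
    rm(".Random.seed", envir = globalenv())
  seeds[stages[[stage]]]
}
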