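write_sidecar <- function(artifact_path, stage, config, seed) {
  meta <- list(artifact = basename(artifact_path), stage = stage,
               seed = as.integer(seed), config_md5 = config_hash(config),
               package_version = as.character(utils::packageVersion("painchoice")))
  jsonlite::write_json(meta, paste0(artifact_path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
}

log_info <- function(...) message("[painchoice] ", sprintf(...))

#' Run the simulation/analysis pipeline
#'
#' Executes the requested stages in order on shared files under `out_dir`:
#' \describe{
#'   \item{simulate}{writes `trial_log.csv` from [simulate_dataset()]}
#'   \item{calibrate-sim}{writes `calibration_report.csv` from one
#'     simulated calibration run}
#'   \item{analyze}{reads `trial_log.csv`, writes `coefficients.csv`
#'     (Models 1-3), `descriptives.csv`, `gamble_fit.csv`,
#'     `risk_aversion.csv` and a human-readable `report.txt`}
#'   \item{recover}{writes `recovery.csv` from [recovery_report()]}
#' }
#' Every artifact gets a JSON sidecar (`<file>.meta.json`) recording the
#' stage, seed and an md5 hash of the resolved configuration, sufficient to
#' rerun the stage. Each stage draws from its own seed substream derived
#' deterministically from the global seed, so adding a stage never perturbs
#' another stage's draws.
#'
#' @param config A `"run_config"`.
#' @param stages Character vector, subset of
#'   `c("simulate", "calibrate-sim", "analyze", "recover")`.
#' @param out_dir Output directory (created if absent).
#' @param n_replicates Replicates for the recover stage.
#' @return Invisibly, a named list of the artifact paths written.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("simulate", "analyze"),
                         out_dir = ".", n_replicates = 20L) {
  known <- c("simulate", "calibrate-sim", "analyze", "recover")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  validate_run_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  for (stage in intersect(known, stages)) {
    sseed <- stage_seed(config$seed, stage)
    if (stage == "simulate") {
      dat <- simulate_dataset(config, seed = sseed)
      path <- file.path(out_dir, "trial_log.csv")
      write_trial_log(dat, path)
      write_sidecar(path, stage, config, sseed)
      log_info("simulate: %d trials from %d dyads -> %s", nrow(dat),
               length(unique(dat$dyad_id)), path)
      outputs$trial_log <- path
    } else if (stage == "calibrate-sim") {
      set.seed(sseed)
      profile <- psychometric_profile(slope = 8, offset = -9, noise_sd = 0.5)
      res <- run_calibration(profile)
      path <- file.path(out_dir, "calibration_report.csv")
      write_calibration_report(res, path)
      write_sidecar(path, stage, config, sseed)
      log_info("calibrate-sim: selected energies %s J",
               paste(res$energies, collapse = "/"))
      outputs$calibration <- path
    } else if (stage == "analyze") {
      set.seed(sseed)
      tl <- file.path(out_dir, "trial_log.csv")
      if (!file.exists(tl))
        stop("analyze stage needs ", tl, " (run the simulate stage first)")
      dat <- read_trial_log(tl)
      fits <- lapply(config$analysis$models, function(m) fit_model(dat, m))
      cpath <- file.path(out_dir, "coefficients.csv")
      write_coefficient_table(fits, cpath)
      write_sidecar(cpath, stage, config, sseed)
      desc <- descriptives(dat, config$design$endowment,
                           config$design$penalty, config$design$mu_per_chf)
      dpath <- file.path(out_dir, "descriptives.csv")
      utils::write.csv(desc$by_target, dpath, row.names = FALSE)
      gpath <- file.path(out_dir, "gamble_fit.csv")
      utils::write.csv(gamble_proportion_fit(dat), gpath, row.names = FALSE)
      ra <- risk_aversion(dat, family = config$analysis$utility_family)
      rpath <- file.path(out_dir, "risk_aversion.csv")
      utils::write.csv(ra$estimates, rpath, row.names = FALSE)
      report <- file.path(out_dir, "report.txt")
      writeLines(c(
        utils::capture.output({
          cat("== Descriptives ==\n"); print(desc$by_target)
          cat(sprintf("mean payout: %.2f CHF; gamble rate: %.2f%%\n",
                      desc$mean_payout_chf, 100 * desc$gamble_rate))
          cat("\n== Gamble proportion vs EP0 ==\n")
          print(gamble_proportion_fit(dat))
          cat("\n== Risk aversion ==\n"); print(ra)
          cat("\n== Mixed models ==\n")
          for (f in fits) { print(f); cat("\n") }
        })), report)
      log_info("analyze: models %s on %d trials -> %s",
               paste(config$analysis$models, collapse = ","), nrow(dat), cpath)
      outputs$coefficients <- cpath
      outputs$report <- report
    } else if (stage == "recover") {
      rep <- recovery_report(config, n_replicates = n_replicates, seed = sseed)
      path <- file.path(out_dir, "recovery.csv")
      write_recovery_report(rep, path)
      write_sidecar(path, stage, config, sseed)
      log_info("recover: %d replicates -> %s", n_replicates, path)
      outputs$recovery <- path
    }
  }
  invisible(outputs)
}
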