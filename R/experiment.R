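# md5 of the canonical JSON serialization of a scenario config; the hash is
# part of a report's provenance block, so two reports with the same hash and
# seed are regenerable byte-for-byte
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(config_to_list(config), tmp, auto_unbox = TRUE, digits = 15)
  unname(tools::md5sum(tmp))
}

#' Write a trajectory table as plain CSV
#'
#' Counts are written in fixed (never scientific) notation so reruns under
#' the same seed are byte-identical.
#'
#' @param trajectory A trajectory or ensemble-summary `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  old <- options(scipen = 15)
  on.exit(options(old))
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run a named experiment end to end
#'
#' Resolves a scenario preset, runs the replicate ensemble, and assembles a
#' report: the per-time median and 2.5%/97.5% quantile trajectories, tumor
#' volume equivalents (cm^3 at 1e8 cells/cm^3) for in-vivo scenarios, an
#' optional Pearson comparison against observed values, and a provenance
#' block (seed, configuration hash, package and R versions) from which the
#' run can be regenerated exactly. When `out_dir` is given, the trajectory
#' table is written as CSV and the report as JSON.
#'
#' @param name A scenario name accepted by [scenario_preset()].
#' @param seed Integer root seed.
#' @param horizon,replicates,n_chambers,death_rates,egfl6_effect Passed to
#'   [scenario_preset()].
#' @param observed Optional numeric vector of observed values, paired in
#'   order with the median predictions at the final time (ALDH+, ALDH-,
#'   total) for [compare_predictions()].
#' @param out_dir Optional output directory (created if missing).
#' @return An object of class `experiment_report` (a list); invisibly the
#'   same object when `out_dir` is given.
#' @export
run_experiment <- function(name, seed = 1L, horizon = NULL, replicates = 50L,
                           n_chambers = 2000L,
                           death_rates = c(ALDHpos = 0.05, ALDHneg = 0.05),
                           egfl6_effect = 1,
                           observed = NULL, out_dir = NULL) {
  config <- scenario_preset(name, seed = seed, horizon = horizon,
                            replicates = replicates, n_chambers = n_chambers,
                            death_rates = death_rates,
                            egfl6_effect = egfl6_effect)
  ensemble <- run_ensemble(config)
  med <- median_trajectory(ensemble)
  labels <- type_labels(config$types)
  in_vivo <- grepl("invivo", name)

  report <- list(
    scenario = name,
    trajectory = ensemble$summary,
    median_final = stats::setNames(
      as.numeric(med[nrow(med), c(labels, "total")]),
      c(labels, "total")),
    provenance = list(
      seed = as.integer(seed),
      config_hash = config_hash(config),
      package_version = as.character(utils::packageVersion("cscsim")),
      r_version = paste(R.version$major, R.version$minor, sep = ".")
    )
  )
  if (in_vivo) {
    report$volume_cm3 <- data.frame(
      time_hours = med$time_hours,
      total_cells = med$total,
      volume_cm3 = volume_from_cells(med$total)
    )
  }
  if (!is.null(observed)) {
    predicted <- as.numeric(med[nrow(med), c(labels, "total")])
    report$comparison <- compare_predictions(predicted, observed)
  }
  class(report) <- "experiment_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trajectory_csv(ensemble$summary,
                         file.path(out_dir, paste0(name, "_trajectory.csv")))
    json <- report
    json$trajectory <- NULL
    if (!is.null(json$comparison)) json$comparison <- unclass(json$comparison)
    class(json) <- NULL
    jsonlite::write_json(json, file.path(out_dir, paste0(name, "_report.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
  }
  if (is.null(out_dir)) report else invisible(report)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment_report: %s (seed %d, config %s)\n",
              x$scenario, x$provenance$seed, x$provenance$config_hash))
  med <- x$trajectory[x$trajectory$replicate == "median", , drop = FALSE]
  print(med, row.names = FALSE)
  if (!is.null(x$volume_cm3)) {
    cat("tumor volume equivalents (1e8 cells/cm^3):\n")
    print(x$volume_cm3, row.names = FALSE)
  }
  if (!is.null(x$comparison)) print(x$comparison)
  invisible(x)
}
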