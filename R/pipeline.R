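## End-to-end driver: simulate (or read) -> classify/match -> per-mediator
## statistics -> windowed networks -> DyBN, with a manifest for
## reproducibility. Configuration is a validated named list, readable from
## YAML or JSON.

#' Build a run configuration
#'
#' Either `synthetic` (a [SyntheticCohortConfig-class]) or both `patientsCsv`
#' and `measurementsCsv` must be supplied.
#'
#' @param synthetic optional [SyntheticCohortConfig-class].
#' @param patientsCsv,measurementsCsv optional input paths.
#' @param dayWindow,nightWindow injury-time windows, minutes since midnight.
#' @param issMin ISS filter for matching (candidates need `iss > issMin`).
#' @param caliperYears matching caliper.
#' @param windows DyNA windows matrix.
#' @param threshold,method DyNA correlation threshold and method.
#' @param transform,floor concentration transform for statistics/networks.
#' @param grid optional DyBN grid (default: the panel's sample times).
#' @param fanIn DyBN fan-in bound.
#' @param cutoff DyBN consensus posterior cutoff.
#' @param seed integer seed for any stochastic stage.
#' @return validated config (list of class `cytodynConfig`).
#' @export
runConfig <- function(synthetic = NULL, patientsCsv = NULL,
                      measurementsCsv = NULL, dayWindow = c(480, 1020),
                      nightWindow = c(1320, 300), issMin = 20,
                      caliperYears = 10, windows = defaultWindows(),
                      threshold = 0.7, method = "pearson",
                      transform = "log10", floor = 0.01, grid = NULL,
                      fanIn = 3, cutoff = 0.5, seed = 1) {
  cfg <- list(synthetic = synthetic, patientsCsv = patientsCsv,
              measurementsCsv = measurementsCsv, dayWindow = dayWindow,
              nightWindow = nightWindow, issMin = issMin,
              caliperYears = caliperYears, windows = windows,
              threshold = threshold, method = method, transform = transform,
              floor = floor, grid = grid, fanIn = fanIn, cutoff = cutoff,
              seed = as.integer(seed))
  class(cfg) <- "cytodynConfig"
  validateConfig(cfg)
  cfg
}

#' Validate a run configuration
#'
#' @param cfg a config list.
#' @return the config, invisibly; errors name the offending field.
#' @export
validateConfig <- function(cfg) {
  if (is.null(cfg$synthetic) &&
      (is.null(cfg$patientsCsv) || is.null(cfg$measurementsCsv)))
    stop("config needs either 'synthetic' or both 'patientsCsv' and ",
         "'measurementsCsv'")
  for (f in c("patientsCsv", "measurementsCsv"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("config field '", f, "': file not found: ", cfg[[f]])
  if (!is.null(cfg$synthetic)) methods::validObject(cfg$synthetic)
  ## day and night windows must not overlap
  mins <- 0:1439
  dayIn <- classifyTimeOfInjury(mins, cfg$dayWindow, c(0, 0)) == "Day"
  nightIn <- classifyTimeOfInjury(mins, c(0, 0), cfg$nightWindow) == "Night"
  if (any(dayIn & nightIn)) stop("config: day and night windows overlap")
  if (cfg$threshold <= 0 || cfg$threshold > 1)
    stop("config field 'threshold' must be in (0, 1]")
  if (cfg$fanIn < 0) stop("config field 'fanIn' must be >= 0")
  invisible(cfg)
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level keys mirror the [runConfig()] arguments; a
#' `synthetic:` block is passed to [syntheticConfig()] (with `effects` rows
#' and `blocks` entries as lists).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return validated config.
#' @export
readRunConfig <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  syn <- NULL
  if (!is.null(lst$synthetic)) {
    s <- lst$synthetic
    eff <- if (!is.null(s$effects))
      do.call(rbind, lapply(s$effects, function(e) do.call(groupEffect, e)))
    blk <- if (!is.null(s$blocks))
      lapply(s$blocks, function(b) do.call(correlationBlock, b))
    args <- s[setdiff(names(s), c("effects", "blocks"))]
    if (!is.null(eff)) args$effects <- eff
    if (!is.null(blk)) args$blocks <- blk
    syn <- do.call(syntheticConfig, args)
  }
  args <- lst[setdiff(names(lst), "synthetic")]
  args$synthetic <- syn
  if (!is.null(args$windows))
    args$windows <- matrix(unlist(args$windows), ncol = 2, byrow = TRUE,
                           dimnames = list(NULL, c("start_h", "end_h")))
  do.call(runConfig, args)
}

configAsList <- function(cfg) {
  syn <- cfg$synthetic
  lst <- cfg[setdiff(names(cfg), "synthetic")]
  lst$windows <- apply(cfg$windows, 1, as.numeric, simplify = FALSE)
  if (!is.null(syn)) {
    lst$synthetic <- list(
      nDay = syn@nDay, nNight = syn@nNight, seed = syn@seed,
      mediators = syn@mediators, sampleTimes = syn@sampleTimes,
      effects = syn@effects, blocks = syn@blocks,
      noiseSigmaLog = syn@noiseSigmaLog, missingRate = syn@missingRate,
      ageMean = syn@ageMean, ageSd = syn@ageSd, issMean = syn@issMean,
      issSd = syn@issSd, baselineLog = syn@baselineLog,
      peakLog = syn@peakLog, decayH = syn@decayH, floor = syn@floor)
  }
  lst
}

#' Run the full analysis pipeline
#'
#' simulate/read -> day-night classification -> severity filter + 1:1
#' matching -> per-mediator group-by-time statistics -> windowed correlation
#' networks with density trace -> per-group DyBN. All stage outputs land in
#' `outDir` along with `manifest.json` (canonical config JSON, its MD5 hash,
#' seed, package and R versions) and a short human-readable report. The run
#' is deterministic given the config.
#'
#' @param cfg a [runConfig()] (or path handled by [readRunConfig()]).
#' @param outDir output directory (created; must not be an existing
#'   non-empty run unless `overwrite`).
#' @param overwrite allow writing into an existing directory.
#' @return `outDir`, invisibly.
#' @export
runPipeline <- function(cfg, outDir, overwrite = FALSE) {
  if (is.character(cfg)) cfg <- readRunConfig(cfg)
  validateConfig(cfg)
  if (dir.exists(outDir) && length(dir(outDir)) && !overwrite)
    stop("output directory exists and is non-empty: ", outDir)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  logmsg <- function(...) message("[cytodyn] ", ...)

  ## stage 1: data
  if (!is.null(cfg$synthetic)) {
    logmsg("simulate: seed ", cfg$synthetic@seed)
    sim <- generateCohort(cfg$synthetic)
    patients <- sim$patients
    panel <- sim$panel
    patients$injury_minutes <- parseClockTime(patients$injury_time)
  } else {
    logmsg("read: ", cfg$patientsCsv, ", ", cfg$measurementsCsv)
    patients <- readPatients(cfg$patientsCsv, cfg$dayWindow, cfg$nightWindow)
    panel <- readMeasurements(cfg$measurementsCsv)
  }
  patients$group <- classifyTimeOfInjury(patients$injury_minutes,
                                         cfg$dayWindow, cfg$nightWindow)
  writePatients(patients, file.path(outDir, "patients.csv"))
  writeMeasurements(panel, file.path(outDir, "measurements.csv"))

  ## stage 2: matching
  day <- patients[patients$group == "Day", ]
  night <- patients[patients$group == "Night", ]
  match <- propensityMatch(day, night, cfg$issMin, cfg$caliperYears)
  logmsg("match: ", nrow(match@pairs), " pairs, ",
         length(match@unmatched), " unmatched")
  utils::write.csv(match@pairs, file.path(outDir, "match.csv"),
                   row.names = FALSE)
  matchedIds <- c(match@pairs$day_id, match@pairs$night_id)
  if (length(matchedIds) < 4)
    stop("stage match: too few matched patients (", length(matchedIds), ")")
  grp <- stats::setNames(patients$group, patients$patient_id)
  mpanel <- setPanelGroups(subsetPatients(panel, matchedIds), grp)

  ## cohort summaries
  summ <- rbind(
    cbind(cohort = "Day", summarizeCohort(day)),
    cbind(cohort = "Night", summarizeCohort(night)),
    cbind(cohort = "mDay",
          summarizeCohort(patients[patients$patient_id %in%
                                     match@pairs$day_id, ])),
    cbind(cohort = "mNight",
          summarizeCohort(patients[patients$patient_id %in%
                                     match@pairs$night_id, ])))
  utils::write.csv(summ, file.path(outDir, "cohort_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(summ, file.path(outDir, "cohort_summary.json"),
                       dataframe = "rows", na = "null", digits = NA)

  ## stage 3: per-mediator statistics
  logmsg("stats: ", nrow(mpanel), " mediators")
  stats <- mediatorStats(mpanel, transform = cfg$transform,
                         floor = cfg$floor)
  utils::write.csv(stats, file.path(outDir, "stats.csv"), row.names = FALSE)

  ## stage 4: DyNA
  logmsg("dyna: threshold ", cfg$threshold, " (", cfg$method, ")")
  trace <- densityTrace(mpanel, windows = cfg$windows,
                        threshold = cfg$threshold, method = cfg$method,
                        transform = cfg$transform, floor = cfg$floor,
                        returnNetworks = TRUE)
  utils::write.csv(as.data.frame(trace),
                   file.path(outDir, "dyna_density.csv"), row.names = FALSE)
  for (net in attr(trace, "networks")) {
    stem <- file.path(outDir, sprintf("dyna_%s_%g-%gh", net@group,
                                      net@windowStart, net@windowEnd))
    exportSIF(net, paste0(stem, ".sif"))
    exportGraphML(net, paste0(stem, ".graphml"))
  }

  ## stage 5: DyBN per group
  dybnOut <- list()
  for (g in c("Day", "Night")) {
    sub <- mpanel[, !is.na(SummarizedExperiment::colData(mpanel)$group) &
                      SummarizedExperiment::colData(mpanel)$group == g]
    res <- tryCatch({
      tr <- buildTransitions(sub, grid = cfg$grid %||% sampleTimes(sub),
                             transform = cfg$transform, floor = cfg$floor)
      model <- inferStructure(tr, fanIn = cfg$fanIn)
      logmsg("dybn [", g, "]: ", model@nPairs, " pairs, fan-in ",
             model@fanIn)
      ep <- model@edgeProb
      edgesDf <- data.frame(
        group = g,
        child = rep(colnames(ep), each = nrow(ep)),
        parent = rep(rownames(ep), ncol(ep)),
        posterior = as.vector(ep), stringsAsFactors = FALSE)
      edgesDf$best_set_member <- mapply(function(p, ch)
        p %in% model@bestParents[[ch]], edgesDf$parent, edgesDf$child)
      exportDybnSIF(model, file.path(outDir,
                                     sprintf("dybn_%s.sif", g)), cfg$cutoff)
      list(edges = edgesDf,
           central = cbind(group = g, centralNodes(model)))
    }, error = function(e) {
      logmsg("dybn [", g, "] skipped: ", conditionMessage(e))
      NULL
    })
    if (!is.null(res)) dybnOut[[g]] <- res
  }
  if (length(dybnOut)) {
    utils::write.csv(do.call(rbind, lapply(dybnOut, `[[`, "edges")),
                     file.path(outDir, "dybn_edges.csv"), row.names = FALSE)
    utils::write.csv(do.call(rbind, lapply(dybnOut, `[[`, "central")),
                     file.path(outDir, "dybn_central_nodes.csv"),
                     row.names = FALSE)
  }

  ## manifest + report
  cfgJson <- jsonlite::toJSON(configAsList(cfg), auto_unbox = TRUE,
                              digits = NA, null = "null")
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(config = jsonlite::fromJSON(cfgJson,
                                               simplifyDataFrame = FALSE),
                   config_md5 = unname(tools::md5sum(tmp)),
                   seed = cfg$seed,
                   package_version = as.character(
                     utils::packageVersion("cytodyn")),
                   r_version = paste(R.version$major, R.version$minor,
                                     sep = "."))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- c(
    "cytodyn run report",
    sprintf("patients: %d (Day %d, Night %d, Neither %d)", nrow(patients),
            sum(patients$group == "Day"), sum(patients$group == "Night"),
            sum(patients$group == "Neither")),
    sprintf("matched pairs: %d (ISS > %g, caliper %g y)", nrow(match@pairs),
            cfg$issMin, cfg$caliperYears),
    sprintf("mediators with ANOVA group p < 0.05: %d / %d",
            sum(stats$p_group < 0.05, na.rm = TRUE), nrow(stats)),
    "density trace:",
    utils::capture.output(print(as.data.frame(trace))))
  writeLines(report, file.path(outDir, "report.txt"))
  logmsg("done: ", outDir)
  invisible(outDir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
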