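## Seeded synthetic-cohort generator. Emulates the study design the pipeline
## assumes: two injury-time groups, 32 circulating mediators sampled three
## times in the first 24 h then daily to day 7, group-by-time effects on the
## log scale, block-correlated log-normal noise, an assay floor, and i.i.d.
## missingness. Nothing is fitted to published figures.

#' The 32-mediator inflammation panel
#'
#' Mediator names of the assayed panel (cytokines, chemokines, soluble
#' receptors, cortisol, NO2-/NO3-), in ASCII transliteration.
#'
#' @return character vector of length 32.
#' @export
mediatorPanelNames <- function() {
  c("IL-1b", "IL-1Ra", "IL-2", "sIL-2Ra", "IL-4", "IL-5", "IL-6", "IL-7",
    "IL-8", "IL-10", "IL-13", "IL-15", "IL-17A", "IFN-g", "IP-10", "MIG",
    "MIP-1a", "MIP-1b", "MCP-1", "GM-CSF", "Eotaxin", "TNF-a", "IL-9",
    "IL-21", "IL-22", "IL-23", "IL-17E/25", "IL-33", "sST2", "NO2-/NO3-",
    "Cortisol", "TGF-b1")
}

#' Declare a group-by-time effect
#'
#' A multiplicative shift of one mediator in one group on the natural-log
#' scale, active on `[onset_h, offset_h)` hours post-injury.
#'
#' @param mediator mediator name.
#' @param group `"Day"` or `"Night"`.
#' @param onset_h,offset_h active interval in hours, `onset_h < offset_h`.
#' @param log_fold_change natural-log shift while active.
#' @return one-row data.frame.
#' @export
groupEffect <- function(mediator, group, onset_h, offset_h, log_fold_change) {
  stopifnot(onset_h < offset_h)
  data.frame(mediator = mediator, group = group, onset_h = onset_h,
             offset_h = offset_h, log_fold_change = log_fold_change,
             stringsAsFactors = FALSE)
}

#' Declare a correlation block
#'
#' Mediators in a block share an equicorrelated latent component of the
#' log-scale noise (pairwise correlation `rho`). A block may be restricted to
#' one group and/or a time interval, so a configuration can express, e.g.,
#' stronger early co-regulation after nighttime injury.
#'
#' @param mediators >= 2 mediator names.
#' @param rho within-block correlation in `[0, 1)`.
#' @param group `"Day"`, `"Night"` or `"both"`.
#' @param onset_h,offset_h hours during which the block is active.
#' @return a list suitable for the `blocks` field of [syntheticConfig()].
#' @export
correlationBlock <- function(mediators, rho, group = "both",
                             onset_h = 0, offset_h = Inf) {
  list(mediators = mediators, rho = rho, group = group,
       onset_h = onset_h, offset_h = offset_h)
}

defaultEffects <- function() {
  ## qualitative pattern of the study: IL-17A and sST2 persistently higher
  ## after nighttime injury (IL-17A from 24 h onward); IL-7, IL-15, GM-CSF,
  ## MIP-1a higher after daytime injury. Magnitudes are round numbers on the
  ## natural-log scale, not fits.
  rbind(groupEffect("IL-17A", "Night", 24, 169, 1.0),
        groupEffect("sST2", "Night", 0, 169, 0.6),
        groupEffect("IL-7", "Day", 0, 169, 0.7),
        groupEffect("IL-15", "Day", 0, 169, 0.6),
        groupEffect("GM-CSF", "Day", 0, 169, 0.6),
        groupEffect("MIP-1a", "Day", 0, 169, 0.4))
}

defaultBlocks <- function() {
  list(correlationBlock(c("MCP-1", "MIP-1a", "MIP-1b", "IP-10", "MIG",
                          "Eotaxin", "IL-8"), 0.5),
       correlationBlock(c("IL-17A", "IL-6", "IL-21", "IL-22", "IL-23"), 0.4),
       correlationBlock(c("IL-4", "IL-5", "IL-13", "IL-10"), 0.4))
}

#' Configure a synthetic trauma cohort
#'
#' Defaults emulate the matched study design: 15 day-injured and 15
#' night-injured patients, the 32-mediator panel, draws at 0/8/16 h and then
#' daily to 168 h, night-elevated IL-17A (from 24 h) and sST2 plus
#' day-elevated IL-7/IL-15/GM-CSF/MIP-1a, three physiological correlation
#' blocks, log-normal noise with sd 1.0 (natural log), 2% missingness, and
#' moderate/severe injury severities (ISS centered above 20).
#'
#' @param nDay,nNight group sizes.
#' @param seed integer seed; all generator output is reproducible from it.
#' @param mediators mediator names.
#' @param sampleTimes sampling grid in hours post-injury.
#' @param effects data.frame of [groupEffect()] rows (may be empty).
#' @param blocks list of [correlationBlock()]s (may be empty).
#' @param noiseSigmaLog sd of natural-log noise.
#' @param missingRate i.i.d. per-measurement missingness in `[0, 1)`.
#' @param ageMean,ageSd,issMean,issSd demographic distributions.
#' @param baselineLog,peakLog,decayH baseline log-concentration trajectory
#'   `baselineLog + peakLog * exp(-t/decayH)`: an early peak decaying toward
#'   a floor, the qualitative shape of post-trauma mediator time courses.
#' @param floor assay floor, pg/mL.
#' @return a [SyntheticCohortConfig-class].
#' @examples
#' cfg <- syntheticConfig(seed = 1)
#' cohort <- generateCohort(cfg)
#' @export
syntheticConfig <- function(nDay = 15, nNight = 15, seed = 1,
                            mediators = mediatorPanelNames(),
                            sampleTimes = c(0, 8, 16, 24, 48, 72, 96, 120,
                                            144, 168),
                            effects = defaultEffects(),
                            blocks = defaultBlocks(),
                            noiseSigmaLog = 1.0, missingRate = 0.02,
                            ageMean = 45, ageSd = 18,
                            issMean = 25, issSd = 8,
                            baselineLog = log(10), peakLog = 1.5,
                            decayH = 48, floor = 0.01) {
  ## when a custom panel is supplied with the default effects/blocks, restrict
  ## the defaults to the mediators that exist
  if (missing(effects) && !missing(mediators))
    effects <- effects[effects$mediator %in% mediators, , drop = FALSE]
  if (missing(blocks) && !missing(mediators))
    blocks <- Filter(function(b) {
      b$mediators <- intersect(b$mediators, mediators)
      length(b$mediators) >= 2
    }, lapply(blocks, function(b) {
      b$mediators <- intersect(b$mediators, mediators); b
    }))
  if (is.null(effects) || !nrow(effects))
    effects <- groupEffect("x", "Day", 0, 1, 0)[0, ]
  methods::new("SyntheticCohortConfig",
               nDay = as.integer(nDay), nNight = as.integer(nNight),
               seed = as.integer(seed), mediators = mediators,
               sampleTimes = as.numeric(sampleTimes), effects = effects,
               blocks = blocks, noiseSigmaLog = noiseSigmaLog,
               missingRate = missingRate, ageMean = ageMean, ageSd = ageSd,
               issMean = issMean, issSd = issSd, baselineLog = baselineLog,
               peakLog = peakLog, decayH = decayH, floor = floor)
}

setMethod("show", "SyntheticCohortConfig", function(object) {
  cat("SyntheticCohortConfig:", object@nDay, "Day +", object@nNight,
      "Night patients,", length(object@mediators), "mediators,",
      length(object@sampleTimes), "time points (seed", object@seed, ")\n")
  cat("  effects:", nrow(object@effects), " blocks:", length(object@blocks),
      " sigma_log:", object@noiseSigmaLog,
      " missing:", object@missingRate, "\n")
})

## group- and time-resolved correlation Cholesky factor (V x V)
blockCholesky <- function(config, group, t) {
  V <- length(config@mediators)
  C <- diag(V)
  for (b in config@blocks) {
    g <- if (is.null(b$group)) "both" else b$group
    on <- if (is.null(b$onset_h)) 0 else b$onset_h
    off <- if (is.null(b$offset_h)) Inf else b$offset_h
    if (!(g == "both" || g == group)) next
    if (!(t >= on && t < off)) next
    idx <- match(b$mediators, config@mediators)
    C[idx, idx] <- b$rho
    diag(C)[idx] <- 1
  }
  chol(C)  # upper triangular; z %*% R gives correlated rows
}

## log-scale mean for all mediators at time t in a group
logMean <- function(config, group, t) {
  mu <- rep(config@baselineLog + config@peakLog * exp(-t / config@decayH),
            length(config@mediators))
  ef <- config@effects
  if (nrow(ef)) {
    act <- ef$group == group & t >= ef$onset_h & t < ef$offset_h
    for (k in which(act)) {
      i <- match(ef$mediator[k], config@mediators)
      mu[i] <- mu[i] + ef$log_fold_change[k]
    }
  }
  mu
}

#' Generate a synthetic cohort
#'
#' Draws a patient table and a mediator measurement panel from a
#' [syntheticConfig()]. Injury clock times are uniform within the correct
#' day/night window per group. Per patient and time point the mediator vector
#' is `exp(mu(t, group) + sigma * (z %*% R))` with `z` standard normal and
#' `R` the block-correlation Cholesky factor; values are truncated below at
#' the assay floor and missingness is applied i.i.d. Output is byte-identical
#' across runs with the same config.
#'
#' @param config a [SyntheticCohortConfig-class].
#' @return list with `patients` (data.frame in the patients-CSV schema plus
#'   `group`) and `panel` (a [MediatorPanel-class]).
#' @export
generateCohort <- function(config) {
  stopifnot(methods::is(config, "SyntheticCohortConfig"))
  methods::validObject(config)
  set.seed(config@seed)
  nD <- config@nDay; nN <- config@nNight; n <- nD + nN
  group <- c(rep("Day", nD), rep("Night", nN))
  ids <- sprintf("P%03d", seq_len(n))

  ## injury clock times uniform within the group's window
  tDay <- floor(runif(nD, 480, 1020))
  u <- runif(nN, 0, 420)  # night window length 120 + 300
  tNight <- floor(ifelse(u < 120, 1320 + u, u - 120))
  clock <- c(tDay, tNight)

  age <- pmin(pmax(round(rnorm(n, config@ageMean, config@ageSd), 1), 18), 90)
  iss <- pmin(pmax(round(rnorm(n, config@issMean, config@issSd)), 1), 66)
  sex <- ifelse(runif(n) < 0.733, "male", "female")
  mech <- sample(c("MVA", "fall", "motorcycle", "other"), n, replace = TRUE,
                 prob = c(0.57, 0.216, 0.138, 0.076))
  ais <- function() pmin(stats::rpois(n, 1.2), 6)
  icu <- round(stats::rlnorm(n, log(4), 0.8), 1)
  hosp <- round(icu + stats::rlnorm(n, log(5), 0.6), 1)
  vent <- round(stats::rlnorm(n, log(1.5), 1.0), 1)
  ni <- runif(n) < 0.23
  comorbPool <- c("hypertension", "diabetes", "psychiatric", "thyroid",
                  "asthma")
  comorbP <- c(0.30, 0.15, 0.15, 0.07, 0.10)
  comorb <- vapply(seq_len(n), function(i) {
    has <- comorbPool[runif(5) < comorbP]
    paste(has, collapse = ";")
  }, "")

  patients <- data.frame(
    patient_id = ids, age = age, sex = sex, iss = iss,
    ais_head_neck = ais(), ais_face = ais(), ais_chest = ais(),
    ais_abdomen = ais(), ais_extremities = ais(), ais_external = ais(),
    injury_time = formatClockTime(clock), mechanism = mech,
    comorbidities = comorb, icu_los = icu, hospital_los = hosp,
    vent_days = vent, ni = ni, group = group, stringsAsFactors = FALSE)

  ## mediator panel: one column per (patient, time), mediators in rows
  V <- length(config@mediators)
  times <- config@sampleTimes
  Tn <- length(times)
  m <- matrix(NA_real_, V, n * Tn,
              dimnames = list(config@mediators, NULL))
  colPat <- rep(seq_len(n), each = Tn)  # columns sorted by patient, time
  colTime <- rep(times, n)
  for (g in c("Day", "Night")) {
    gi <- which(group == g)
    for (j in seq_len(Tn)) {
      t <- times[j]
      R <- blockCholesky(config, g, t)
      mu <- logMean(config, g, t)
      z <- matrix(rnorm(length(gi) * V), length(gi), V) %*% R
      val <- exp(sweep(config@noiseSigmaLog * z, 2, mu, "+"))
      val <- pmax(val, config@floor)
      if (config@missingRate > 0)
        val[runif(length(val)) < config@missingRate] <- NA_real_
      m[, (gi - 1L) * Tn + j] <- t(val)
    }
  }
  cd <- S4Vectors::DataFrame(patient_id = ids[colPat], time_h = colTime,
                             group = group[colPat])
  panel <- methods::new("MediatorPanel",
                        SummarizedExperiment::SummarizedExperiment(
                          assays = list(conc = m), colData = cd))
  list(patients = patients, panel = panel)
}

#' Simulate a first-order vector-autoregressive mediator panel
#'
#' Generates `nSeries` independent series of `length` time steps following
#' `x[t+1] = coef * A %*% x[t] + e`, `e ~ N(0, noiseSd^2)`, for dynamic-
#' network recovery benchmarks. Requires stability:
#' `|coef| * max(rowSums(abs(A))) < 1`.
#'
#' @param nSeries number of independent series ("patients").
#' @param length number of time steps per series.
#' @param adjacency V x V matrix; entry `[i, j]` is the weight of variable j
#'   at time t in the equation of variable i at time t+1.
#' @param coef global autoregressive coefficient.
#' @param noiseSd innovation standard deviation.
#' @param seed integer seed.
#' @param varNames optional variable names (default `V1..Vn`).
#' @return a [MediatorPanel-class] with times `0:(length-1)` hours. The raw
#'   Gaussian values are offset by a constant to satisfy the container's
#'   non-negativity; the offset is recorded in `metadata(panel)$offset` and
#'   is irrelevant downstream because transition datasets are standardized.
#' @export
generateVar1Panel <- function(nSeries, length, adjacency, coef, noiseSd = 1,
                              seed = 1, varNames = NULL) {
  A <- as.matrix(adjacency)
  V <- nrow(A)
  stopifnot(ncol(A) == V, length >= 2, nSeries >= 1)
  if (abs(coef) * max(rowSums(abs(A))) >= 1)
    stop("unstable VAR(1): |coef| * max row-sum of |adjacency| must be < 1")
  if (is.null(varNames)) varNames <- paste0("V", seq_len(V))
  set.seed(seed)
  recs <- vector("list", nSeries)
  for (s in seq_len(nSeries)) {
    x <- matrix(0, length, V)
    x[1, ] <- rnorm(V, 0, noiseSd)
    for (t in seq_len(length - 1L))
      x[t + 1L, ] <- coef * drop(A %*% x[t, ]) + rnorm(V, 0, noiseSd)
    recs[[s]] <- data.frame(
      patient_id = sprintf("S%03d", s),
      mediator = rep(varNames, each = length),
      time_h = rep(0:(length - 1L), V),
      value_pg_ml = as.vector(x), stringsAsFactors = FALSE)
  }
  long <- do.call(rbind, recs)
  offset <- -min(long$value_pg_ml)
  long$value_pg_ml <- long$value_pg_ml + offset
  panel <- MediatorPanel(long)
  S4Vectors::metadata(panel)$offset <- offset
  panel
}
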