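## Central S4 containers. MediatorPanel rides on SummarizedExperiment so the
## usual Bioconductor subsetting/accessor machinery applies; the remaining
## classes are small result containers with validity checks.

#' MediatorPanel: a mediator-by-sample concentration container
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one assay
#' `"conc"` (concentrations in pg/mL; rows = mediators, columns = one drawn
#' sample per patient per time point) with required column annotations
#' `patient_id`, `time_h` (hours post-injury) and `group`
#' (`Day`/`Night`/`Neither` or `NA`). Missing measurements are `NA` in the
#' assay.
#'
#' @slot ... see SummarizedExperiment.
#' @seealso [MediatorPanel()] for construction from long-format records,
#'   [longFormat()] for the inverse.
#' @export
setClass("MediatorPanel", contains = "SummarizedExperiment")

setValidity("MediatorPanel", function(object) {
  msg <- character()
  if (!"conc" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'conc' is required")
  need <- c("patient_id", "time_h", "group")
  missing <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(missing))
    msg <- c(msg, paste0("colData lacks: ", paste(missing, collapse = ", ")))
  if (!length(msg)) {
    a <- SummarizedExperiment::assay(object, "conc")
    if (any(a < 0, na.rm = TRUE)) msg <- c(msg, "negative concentrations")
    if (anyDuplicated(rownames(object)))
      msg <- c(msg, "duplicated mediator names")
    th <- SummarizedExperiment::colData(object)$time_h
    if (any(is.na(th))) msg <- c(msg, "time_h must not be NA")
  }
  if (length(msg)) msg else TRUE
})

#' MatchResult: outcome of 1:1 propensity matching
#'
#' @slot pairs data.frame with columns `day_id`, `night_id`, `distance`
#'   (absolute age difference in years), sorted by `day_id`.
#' @slot unmatched character vector of eligible-but-unmatched patient ids.
#' @slot issMin ISS filter in force (patients must exceed it).
#' @slot caliper maximum accepted age distance in years.
#' @export
setClass("MatchResult",
  representation(pairs = "data.frame", unmatched = "character",
                 issMin = "numeric", caliper = "numeric"))

setValidity("MatchResult", function(object) {
  p <- object@pairs
  msg <- character()
  if (!all(c("day_id", "night_id", "distance") %in% names(p)))
    msg <- c(msg, "pairs needs day_id, night_id, distance")
  else {
    ids <- c(p$day_id, p$night_id)
    if (anyDuplicated(ids)) msg <- c(msg, "a patient appears in two pairs")
    if (any(p$distance < 0)) msg <- c(msg, "negative match distance")
    if (length(intersect(ids, object@unmatched)))
      msg <- c(msg, "patient both matched and unmatched")
  }
  if (length(msg)) msg else TRUE
})

#' CorrelationNetwork: thresholded mediator graph for one group and window
#'
#' @slot group group label the network was built from.
#' @slot windowStart,windowEnd half-open time window in hours post-injury.
#' @slot nodes mediators with evaluable data in the window.
#' @slot edges data.frame `from`, `to`, `r` (signed correlation); unordered
#'   pairs with `from < to`.
#' @slot threshold correlation threshold in force.
#' @slot method `"pearson"` or `"spearman"`.
#' @slot absolute whether `|r| >= threshold` (TRUE) or `r >= threshold`.
#' @export
setClass("CorrelationNetwork",
  representation(group = "character", windowStart = "numeric",
                 windowEnd = "numeric", nodes = "character",
                 edges = "data.frame", threshold = "numeric",
                 method = "character", absolute = "logical"))

setValidity("CorrelationNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!all(c("from", "to", "r") %in% names(e)))
    msg <- c(msg, "edges needs from, to, r")
  else if (nrow(e)) {
    if (any(e$from == e$to)) msg <- c(msg, "self-edges not allowed")
    if (!all(c(e$from, e$to) %in% object@nodes))
      msg <- c(msg, "edge endpoints outside node set")
    rr <- if (object@absolute) abs(e$r) else e$r
    if (any(rr < object@threshold - 1e-12))
      msg <- c(msg, "edge below threshold")
  }
  if (length(object@threshold) != 1 || object@threshold <= 0 ||
      object@threshold > 1)
    msg <- c(msg, "threshold must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' TransitionDataset: time-sliced observation pairs for DyBN scoring
#'
#' Each row of `x0`/`x1` is one transition: the standardized mediator vector
#' of one patient at consecutive occupied grid slots t and t+1. Gaps in a
#' patient's sampling break the chain (no pair across a missed draw);
#' transitions with any missing variable are dropped (complete case).
#'
#' @slot variables mediator names retained (constant variables are dropped).
#' @slot x0,x1 numeric matrices (pairs x variables), columns z-scored.
#' @slot patient patient id per pair.
#' @slot fromTime,toTime grid times bounding each pair, hours.
#' @slot dropped variables removed for zero variance.
#' @export
setClass("TransitionDataset",
  representation(variables = "character", x0 = "matrix", x1 = "matrix",
                 patient = "character", fromTime = "numeric",
                 toTime = "numeric", dropped = "character"))

setValidity("TransitionDataset", function(object) {
  msg <- character()
  if (!identical(dim(object@x0), dim(object@x1)))
    msg <- c(msg, "x0 and x1 differ in dimension")
  if (ncol(object@x0) != length(object@variables))
    msg <- c(msg, "column count != number of variables")
  n <- nrow(object@x0)
  if (length(object@patient) != n || length(object@fromTime) != n)
    msg <- c(msg, "per-pair annotations wrong length")
  if (n && any(object@fromTime >= object@toTime))
    msg <- c(msg, "fromTime must precede toTime")
  if (length(msg)) msg else TRUE
})

#' DybnModel: dynamic Bayesian network over mediator time slices
#'
#' Result of exact per-child Bayesian model averaging over all parent sets of
#' bounded size under a linear-Gaussian score. All edges are directed from
#' slice t to slice t+1; a self-edge (mediator predicting itself) is reported
#' as a feedback motif.
#'
#' @slot variables variable names (parents and children coincide).
#' @slot edgeProb matrix of posterior edge probabilities, parents in rows,
#'   children in columns; entries in `[0, 1]`.
#' @slot bestParents named list: per child, the highest-scoring parent set.
#' @slot bestScore named numeric: the corresponding log score.
#' @slot fanIn maximum parent-set size enumerated.
#' @slot nPairs number of transition pairs scored.
#' @export
setClass("DybnModel",
  representation(variables = "character", edgeProb = "matrix",
                 bestParents = "list", bestScore = "numeric",
                 fanIn = "integer", nPairs = "integer"))

setValidity("DybnModel", function(object) {
  msg <- character()
  p <- object@edgeProb
  v <- object@variables
  if (!identical(dim(p), c(length(v), length(v))))
    msg <- c(msg, "edgeProb must be V x V")
  if (length(p) && (any(p < -1e-9) || any(p > 1 + 1e-9)))
    msg <- c(msg, "edge posteriors outside [0, 1]")
  if (!identical(sort(names(object@bestParents)), sort(v)))
    msg <- c(msg, "bestParents must name every child")
  if (length(msg)) msg else TRUE
})

#' SyntheticCohortConfig: parameterization of the simulated study
#'
#' Full description of a synthetic two-group trauma cohort: group sizes,
#' mediator panel, sampling grid, group-by-time effects on the log scale,
#' block-correlation structure, log-normal noise, missingness, and the
#' demographic distributions used for the patient table. See
#' [syntheticConfig()].
#'
#' @slot nDay,nNight group sizes.
#' @slot seed integer RNG seed; all output is reproducible from it.
#' @slot mediators unique mediator names.
#' @slot sampleTimes strictly increasing sampling grid, hours post-injury.
#' @slot effects data.frame `mediator`, `group`, `onset_h`, `offset_h`,
#'   `log_fold_change` (natural-log shift while active).
#' @slot blocks list of correlation blocks: `mediators`, `rho`, and optional
#'   `group` (`"Day"`, `"Night"` or `"both"`), `onset_h`, `offset_h`.
#' @slot noiseSigmaLog sd of the natural-log measurement noise.
#' @slot missingRate i.i.d. per-measurement missingness probability.
#' @slot ageMean,ageSd,issMean,issSd demographic distributions.
#' @slot baselineLog,peakLog,decayH baseline trajectory: log-concentration
#'   `baselineLog + peakLog * exp(-t / decayH)`.
#' @slot floor assay floor in pg/mL; values truncated below at it.
#' @export
setClass("SyntheticCohortConfig",
  representation(nDay = "integer", nNight = "integer", seed = "integer",
                 mediators = "character", sampleTimes = "numeric",
                 effects = "data.frame", blocks = "list",
                 noiseSigmaLog = "numeric", missingRate = "numeric",
                 ageMean = "numeric", ageSd = "numeric",
                 issMean = "numeric", issSd = "numeric",
                 baselineLog = "numeric", peakLog = "numeric",
                 decayH = "numeric", floor = "numeric"))

setValidity("SyntheticCohortConfig", function(object) {
  msg <- character()
  if (object@nDay < 1L || object@nNight < 1L)
    msg <- c(msg, "group sizes must be >= 1")
  if (anyDuplicated(object@mediators))
    msg <- c(msg, "duplicate mediator names")
  if (is.unsorted(object@sampleTimes, strictly = TRUE))
    msg <- c(msg, "sample times must be strictly increasing")
  if (object@noiseSigmaLog <= 0) msg <- c(msg, "noiseSigmaLog must be > 0")
  if (object@missingRate < 0 || object@missingRate >= 1)
    msg <- c(msg, "missingRate must be in [0, 1)")
  ef <- object@effects
  if (nrow(ef)) {
    if (!all(ef$mediator %in% object@mediators))
      msg <- c(msg, "effect on unknown mediator")
    if (!all(ef$group %in% c("Day", "Night")))
      msg <- c(msg, "effect group must be Day or Night")
    if (any(ef$onset_h >= ef$offset_h))
      msg <- c(msg, "effect onset must precede offset")
  }
  inBlock <- unlist(lapply(object@blocks, function(b) {
    if (!all(b$mediators %in% object@mediators))
      msg <<- c(msg, "block contains unknown mediator")
    if (b$rho < 0 || b$rho >= 1) msg <<- c(msg, "block rho must be in [0, 1)")
    if (length(b$mediators) < 2) msg <<- c(msg, "block needs >= 2 mediators")
    paste0(b$mediators, "::", if (is.null(b$group)) "both" else b$group)
  }))
  if (anyDuplicated(inBlock))
    msg <- c(msg, "a mediator may belong to at most one block per group")
  if (length(msg)) msg else TRUE
})
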