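## Day/night cohort construction: injury-time classification, severity
## filtering with 1:1 matching, and Table-1-style summaries.

#' Classify time of injury into day/night windows
#'
#' Assigns an injury clock time to the day window (the shortest annual
#' daylight period at the study site, 8:00-17:00), the night window (the
#' shortest night, 22:00-5:00, wrapping midnight), or neither. Windows are
#' half-open `[start, end)` so no minute is double-assigned.
#'
#' @param t injury time in minutes since midnight, in `[0, 1440)`; vectorized.
#' @param dayWindow,nightWindow numeric length-2 vectors of window start/end
#'   minutes; `nightWindow` may wrap midnight (start > end).
#' @return character vector in `c("Day", "Night", "Neither")`.
#' @examples
#' classifyTimeOfInjury(570)   # 09:30 -> "Day"
#' classifyTimeOfInjury(1425)  # 23:45 -> "Night"
#' classifyTimeOfInjury(1140)  # 19:00 -> "Neither"
#' @export
classifyTimeOfInjury <- function(t, dayWindow = c(480, 1020),
                                 nightWindow = c(1320, 300)) {
  if (any(is.na(t)) || any(t < 0 | t >= 1440))
    stop("injury time must be in [0, 1440) minutes since midnight")
  inWin <- function(t, w) {
    if (w[1] <= w[2]) t >= w[1] & t < w[2]
    else t >= w[1] | t < w[2]  # wraps midnight
  }
  out <- rep("Neither", length(t))
  out[inWin(t, dayWindow)] <- "Day"
  out[inWin(t, nightWindow)] <- "Night"
  out
}

#' One-to-one matching of day and night patients
#'
#' Greedy nearest-neighbor matching on age within exact sex strata after an
#' injury-severity filter, the degenerate form a propensity model on (age,
#' sex, ISS > threshold) takes when sex is matched exactly and the score is
#' dominated by age. Candidates are patients with `iss > issMin`. Globally
#' closest age pairs are accepted first; ties are broken by smaller absolute
#' ISS difference, then lexicographically by patient id. Pairs farther apart
#' in age than `caliperYears` are rejected.
#'
#' @param day,night data.frames of patient records (need `patient_id`, `age`,
#'   `sex`, `iss`); the two sets must be disjoint.
#' @param issMin ISS filter: candidates must satisfy `iss > issMin`.
#' @param caliperYears maximum accepted age distance (years).
#' @return a [MatchResult-class]; pairs sorted by day patient id. An empty
#'   candidate set on either side gives zero pairs with all candidates
#'   unmatched (not an error).
#' @examples
#' day <- data.frame(patient_id = "P1", age = 40, sex = "male", iss = 25)
#' night <- data.frame(patient_id = c("Q1", "Q2"), age = c(41, 70),
#'                     sex = c("male", "female"), iss = c(24, 30))
#' matchedPairs(propensityMatch(day, night))
#' @export
propensityMatch <- function(day, night, issMin = 20, caliperYears = 10) {
  stopifnot(issMin >= 0, caliperYears >= 0)
  day$patient_id <- as.character(day$patient_id)
  night$patient_id <- as.character(night$patient_id)
  if (length(intersect(day$patient_id, night$patient_id)))
    stop("day and night groups must be disjoint")
  d <- day[day$iss > issMin, , drop = FALSE]
  n <- night[night$iss > issMin, , drop = FALSE]

  empty <- function() data.frame(day_id = character(), night_id = character(),
                                 distance = numeric(),
                                 stringsAsFactors = FALSE)
  pairs <- empty()
  if (nrow(d) && nrow(n)) {
    cand <- merge(d[c("patient_id", "age", "sex", "iss")],
                  n[c("patient_id", "age", "sex", "iss")],
                  by = "sex", suffixes = c("_day", "_night"))
    cand$distance <- abs(cand$age_day - cand$age_night)
    cand$issDist <- abs(cand$iss_day - cand$iss_night)
    cand <- cand[cand$distance <= caliperYears, , drop = FALSE]
    cand <- cand[order(cand$distance, cand$issDist,
                       cand$patient_id_day, cand$patient_id_night), ,
                 drop = FALSE]
    usedD <- usedN <- character()
    for (k in seq_len(nrow(cand))) {
      if (cand$patient_id_day[k] %in% usedD ||
          cand$patient_id_night[k] %in% usedN) next
      usedD <- c(usedD, cand$patient_id_day[k])
      usedN <- c(usedN, cand$patient_id_night[k])
      pairs <- rbind(pairs, data.frame(day_id = cand$patient_id_day[k],
                                       night_id = cand$patient_id_night[k],
                                       distance = cand$distance[k],
                                       stringsAsFactors = FALSE))
    }
    if (nrow(pairs)) pairs <- pairs[order(pairs$day_id), , drop = FALSE]
    rownames(pairs) <- NULL
  }
  unmatched <- setdiff(c(d$patient_id, n$patient_id),
                       c(pairs$day_id, pairs$night_id))
  methods::new("MatchResult", pairs = pairs, unmatched = unmatched,
               issMin = issMin, caliper = caliperYears)
}

#' @rdname cytodyn-generics
#' @export
setMethod("matchedPairs", "MatchResult", function(x) x@pairs)

#' @rdname cytodyn-generics
#' @export
setMethod("unmatchedIds", "MatchResult", function(x) x@unmatched)

setMethod("show", "MatchResult", function(object) {
  cat("MatchResult:", nrow(object@pairs), "pairs,",
      length(object@unmatched), "unmatched candidates",
      sprintf("(ISS > %g, caliper %g y)\n", object@issMin, object@caliper))
  if (nrow(object@pairs))
    cat("  mean age distance:",
        signif(mean(object@pairs$distance), 3), "years\n")
})

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact test by full hypergeometric enumeration with the
#' sum-of-small-probabilities rule: the p-value is the total probability of
#' all tables with the observed margins whose probability does not exceed
#' that of the observed table (with relative slack 1e-7 on the comparison,
#' guarding against ties broken by floating-point noise).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = group,
#'   columns = outcome), or the count `a` when `b`, `c`, `d` are given.
#' @param b,c,d remaining counts when `tab` is scalar.
#' @return two-sided p-value in `(0, 1]`.
#' @examples
#' fisherExact2x2(matrix(c(1, 0, 0, 1), 2))  # 1
#' fisherExact2x2(5, 10, 2, 13)
#' @export
fisherExact2x2 <- function(tab, b = NULL, c = NULL, d = NULL) {
  if (!is.null(b)) tab <- matrix(c(tab, c, b, d), 2)
  if (!is.matrix(tab) || !identical(dim(tab), c(2L, 2L)))
    stop("need a 2x2 table")
  x <- as.vector(tab)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("counts must be non-negative integers")
  if (sum(x) == 0) stop("all-zero table")
  a <- tab[1, 1]
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0L, c1 - r2); hi <- min(r1, c1)
  support <- lo:hi
  probs <- stats::dhyper(support, r1, r2, c1)
  pObs <- probs[support == a]
  min(1, sum(probs[probs <= pObs * (1 + 1e-7)]))
}

#' Summarize a cohort, clinical-table style
#'
#' Per-variable mean +/- SEM for continuous variables and n (%) for
#' categorical ones, as presented in demographic/outcome tables. SEM is the
#' sample standard deviation (n-1 denominator) over sqrt(n); percentages are
#' rounded half-up to one decimal. Comorbidities are multi-label: each
#' condition is counted, plus a `none` level.
#'
#' @param records data.frame of patient records (see [readPatients()] for the
#'   schema); any subset of the known columns may be present.
#' @return data.frame with columns `variable`, `level`, `type`, `n`, `mean`,
#'   `sem`, `count`, `percent`.
#' @examples
#' rec <- data.frame(patient_id = c("a", "b", "c"), age = c(5, 5, 5),
#'                   sex = c("male", "male", "female"))
#' summarizeCohort(rec)
#' @export
summarizeCohort <- function(records) {
  if (!nrow(records)) stop("empty cohort")
  total <- nrow(records)
  contVars <- intersect(c("age", "iss", "ais_head_neck", "ais_face",
                          "ais_chest", "ais_abdomen", "ais_extremities",
                          "ais_external", "icu_los", "hospital_los",
                          "vent_days"), names(records))
  catVars <- intersect(c("sex", "mechanism", "ni"), names(records))

  rows <- list()
  for (v in contVars) {
    x <- records[[v]][!is.na(records[[v]])]
    rows[[length(rows) + 1L]] <- data.frame(
      variable = v, level = NA_character_, type = "continuous",
      n = length(x), mean = mean(x), sem = semOf(x),
      count = NA_integer_, percent = NA_real_, stringsAsFactors = FALSE)
  }
  for (v in catVars) {
    x <- records[[v]]
    for (lev in sort(unique(as.character(x[!is.na(x)])))) {
      cnt <- sum(x == lev, na.rm = TRUE)
      rows[[length(rows) + 1L]] <- data.frame(
        variable = v, level = lev, type = "categorical",
        n = total, mean = NA_real_, sem = NA_real_,
        count = cnt, percent = percentHalfUp(cnt, total),
        stringsAsFactors = FALSE)
    }
  }
  if ("comorbidities" %in% names(records)) {
    sets <- strsplit(ifelse(is.na(records$comorbidities), "",
                            records$comorbidities), ";", fixed = TRUE)
    sets <- lapply(sets, function(s) trimws(s[nzchar(trimws(s))]))
    levs <- sort(unique(unlist(sets)))
    for (lev in levs) {
      cnt <- sum(vapply(sets, function(s) lev %in% s, TRUE))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = "comorbidities", level = lev, type = "categorical",
        n = total, mean = NA_real_, sem = NA_real_,
        count = cnt, percent = percentHalfUp(cnt, total),
        stringsAsFactors = FALSE)
    }
    cnt <- sum(vapply(sets, length, 1L) == 0L)
    rows[[length(rows) + 1L]] <- data.frame(
      variable = "comorbidities", level = "none", type = "categorical",
      n = total, mean = NA_real_, sem = NA_real_,
      count = cnt, percent = percentHalfUp(cnt, total),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
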