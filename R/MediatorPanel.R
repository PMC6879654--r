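#' Construct a MediatorPanel from long-format measurements
#'
#' Builds the package's central container from tidy records with one row per
#' (patient, mediator, time, concentration) measurement. Duplicate
#' measurements of the same (patient, mediator, time) are averaged; mediator/
#' sample combinations never measured are `NA`.
#'
#' @param records data.frame with columns `patient_id`, `mediator`, `time_h`,
#'   `value_pg_ml` and optionally `group`.
#' @param group optional named character vector mapping patient ids to group
#'   labels (`Day`/`Night`/`Neither`); overrides a `group` column.
#' @return a [MediatorPanel-class] with rows ordered by first appearance of
#'   each mediator and columns ordered by (patient, time).
#' @examples
#' rec <- data.frame(patient_id = "P1", mediator = c("IL-6", "TNF-a"),
#'                   time_h = 0, value_pg_ml = c(10, 5))
#' MediatorPanel(rec)
#' @export
MediatorPanel <- function(records, group = NULL) {
  need <- c("patient_id", "mediator", "time_h", "value_pg_ml")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records lack columns: ", paste(missing, collapse = ", "))
  if (nrow(records) == 0L) stop("no measurements supplied")
  if (any(records$value_pg_ml < 0, na.rm = TRUE))
    stop("negative concentrations are not allowed")

  records$patient_id <- as.character(records$patient_id)
  records$mediator <- as.character(records$mediator)
  meds <- unique(records$mediator)
  sampKey <- paste(records$patient_id, records$time_h, sep = "\r")
  sampTab <- unique(data.frame(patient_id = records$patient_id,
                               time_h = records$time_h, key = sampKey,
                               stringsAsFactors = FALSE))
  sampTab <- sampTab[order(sampTab$patient_id, sampTab$time_h), ]

  m <- matrix(NA_real_, length(meds), nrow(sampTab),
              dimnames = list(meds, NULL))
  i <- match(records$mediator, meds)
  j <- match(sampKey, sampTab$key)
  ## mean over duplicates
  sums <- tapply(records$value_pg_ml, list(i, j), mean, na.rm = TRUE)
  m[cbind(as.integer(rep(rownames(sums), ncol(sums))),
          as.integer(rep(colnames(sums), each = nrow(sums))))] <- as.vector(sums)
  m[is.nan(m)] <- NA_real_

  grp <- rep(NA_character_, nrow(sampTab))
  if (!is.null(group)) {
    grp <- unname(group[sampTab$patient_id])
  } else if ("group" %in% names(records)) {
    gmap <- records$group[!duplicated(records$patient_id)]
    names(gmap) <- records$patient_id[!duplicated(records$patient_id)]
    grp <- unname(as.character(gmap[sampTab$patient_id]))
  }

  cd <- S4Vectors::DataFrame(patient_id = sampTab$patient_id,
                             time_h = sampTab$time_h, group = grp)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(conc = m), colData = cd)
  methods::new("MediatorPanel", se)
}

#' @rdname cytodyn-generics
#' @export
setMethod("mediatorNames", "MediatorPanel", function(x) rownames(x))

#' @rdname cytodyn-generics
#' @export
setMethod("patientIds", "MediatorPanel",
          function(x) unique(SummarizedExperiment::colData(x)$patient_id))

#' @rdname cytodyn-generics
#' @export
setMethod("sampleTimes", "MediatorPanel",
          function(x) sort(unique(SummarizedExperiment::colData(x)$time_h)))

#' @rdname cytodyn-generics
#' @export
setMethod("groupLabels", "MediatorPanel", function(x) {
  cd <- SummarizedExperiment::colData(x)
  stats::setNames(as.character(cd$group), cd$patient_id)[
    !duplicated(cd$patient_id)]
})

#' @rdname cytodyn-generics
#' @param dropNA drop rows with missing concentration (default TRUE).
#' @export
setMethod("longFormat", "MediatorPanel", function(x, dropNA = TRUE) {
  cd <- SummarizedExperiment::colData(x)
  a <- SummarizedExperiment::assay(x, "conc")
  out <- data.frame(
    patient_id = rep(cd$patient_id, each = nrow(a)),
    mediator = rep(rownames(a), ncol(a)),
    time_h = rep(cd$time_h, each = nrow(a)),
    value_pg_ml = as.vector(a),
    group = rep(as.character(cd$group), each = nrow(a)),
    stringsAsFactors = FALSE)
  if (dropNA) out <- out[!is.na(out$value_pg_ml), ]
  rownames(out) <- NULL
  out
})

#' Assign day/night group labels to a panel
#'
#' @param panel a [MediatorPanel-class].
#' @param group named character vector (patient id -> label).
#' @return the panel with updated `group` column annotation.
#' @export
setPanelGroups <- function(panel, group) {
  cd <- SummarizedExperiment::colData(panel)
  SummarizedExperiment::colData(panel)$group <-
    unname(group[cd$patient_id])
  panel
}

#' Subset a panel to given patients
#'
#' @param panel a [MediatorPanel-class].
#' @param ids patient ids to keep.
#' @return the subset panel.
#' @export
subsetPatients <- function(panel, ids) {
  keep <- SummarizedExperiment::colData(panel)$patient_id %in% ids
  panel[, keep]
}

setMethod("show", "MediatorPanel", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("MediatorPanel:", nrow(object), "mediators,",
      length(unique(cd$patient_id)), "patients,",
      ncol(object), "samples\n")
  tg <- table(as.character(cd$group[!duplicated(cd$patient_id)]),
              useNA = "ifany")
  cat("  groups:", paste(names(tg), tg, sep = "=", collapse = ", "), "\n")
  cat("  times (h):", paste(sort(unique(cd$time_h)), collapse = ", "), "\n")
})
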