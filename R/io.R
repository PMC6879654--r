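## CSV readers/writers for the two tidy interchange formats (patients table,
## long-format measurements) and graph exporters (SIF, GraphML).

#' Read long-format mediator measurements
#'
#' CSV with header `patient_id,mediator,time_h,value_pg_ml`. Mediator names
#' are preserved verbatim (open panel; names containing `/` survive the
#' quoting round-trip). Negative concentrations and malformed rows are
#' rejected with their line number.
#'
#' @param path CSV file.
#' @return a [MediatorPanel-class].
#' @export
readMeasurements <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "mediator", "time_h", "value_pg_ml")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("measurements CSV lacks columns: ", paste(missing, collapse = ", "))
  if (!nrow(raw)) stop("empty measurements file: ", path)
  med <- as.character(raw$mediator)
  bad <- which(is.na(raw$time_h) | is.na(suppressWarnings(
    as.numeric(raw$value_pg_ml))) | is.na(raw$patient_id) |
      is.na(med) | !nzchar(med))
  if (length(bad))
    stop("malformed measurement row(s) at line(s): ",
         paste(bad + 1L, collapse = ", "))  # +1 for header
  neg <- which(raw$value_pg_ml < 0)
  if (length(neg))
    stop("negative concentration at line(s): ",
         paste(neg + 1L, collapse = ", "))
  MediatorPanel(raw)
}

#' Write long-format mediator measurements
#'
#' @param panel a [MediatorPanel-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeMeasurements <- function(panel, path) {
  long <- longFormat(panel)
  utils::write.csv(long[c("patient_id", "mediator", "time_h", "value_pg_ml")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read a patients table
#'
#' CSV with header `patient_id,age,sex,iss,ais_head_neck,ais_face,ais_chest,`
#' `ais_abdomen,ais_extremities,ais_external,injury_time,mechanism,`
#' `comorbidities,icu_los,hospital_los,vent_days,ni`; `injury_time` is 24-h
#' `HH:MM`, comorbidities are semicolon-delimited. Adds derived columns
#' `injury_minutes` and `group` (via [classifyTimeOfInjury()]).
#'
#' @param path CSV file.
#' @param dayWindow,nightWindow passed to [classifyTimeOfInjury()].
#' @return data.frame of patient records.
#' @export
readPatients <- function(path, dayWindow = c(480, 1020),
                         nightWindow = c(1320, 300)) {
  p <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "age", "sex", "iss", "injury_time")
  missing <- setdiff(need, names(p))
  if (length(missing))
    stop("patients CSV lacks columns: ", paste(missing, collapse = ", "))
  if (anyDuplicated(p$patient_id)) stop("duplicate patient_id")
  if (any(p$age <= 0, na.rm = TRUE)) stop("age must be positive")
  if (any(p$iss < 0, na.rm = TRUE)) stop("iss must be >= 0")
  aisCols <- grep("^ais_", names(p), value = TRUE)
  for (cc in aisCols) if (any(p[[cc]] < 0 | p[[cc]] > 6, na.rm = TRUE))
    stop("AIS components must be in 0..6 (", cc, ")")
  if ("ni" %in% names(p)) p$ni <- as.logical(p$ni)
  p$injury_minutes <- parseClockTime(p$injury_time)
  p$group <- classifyTimeOfInjury(p$injury_minutes, dayWindow, nightWindow)
  p
}

#' Write a patients table
#'
#' @param patients data.frame (derived columns `injury_minutes`/`group` are
#'   dropped).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writePatients <- function(patients, path) {
  drop <- intersect(c("injury_minutes", "group"), names(patients))
  utils::write.csv(patients[setdiff(names(patients), drop)], path,
                   row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Export a network in SIF format
#'
#' One line per edge: `A pp B`. Isolated nodes are appended as single-column
#' lines so the node set survives the round trip.
#'
#' @param net a [CorrelationNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportSIF <- function(net, path) {
  e <- net@edges
  lines <- if (nrow(e)) paste(e$from, "pp", e$to, sep = "\t") else character()
  iso <- setdiff(net@nodes, c(e$from, e$to))
  writeLines(c(lines, iso), path)
  invisible(path)
}

asIgraph <- function(net) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net@nodes), name = net@nodes)
  if (nrow(net@edges))
    g <- igraph::add_edges(g, rbind(net@edges$from, net@edges$to),
                           r = net@edges$r)
  g
}

#' Export a network as GraphML with the correlation as edge attribute
#'
#' @param net a [CorrelationNetwork-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
exportGraphML <- function(net, path) {
  igraph::write_graph(asIgraph(net), path, format = "graphml")
  invisible(path)
}

#' Export DyBN consensus edges as SIF
#'
#' Directed lines `parent dybn child` for edges at the cutoff.
#'
#' @param model a [DybnModel-class].
#' @param path output file.
#' @param cutoff posterior cutoff.
#' @return `path`, invisibly.
#' @export
exportDybnSIF <- function(model, path, cutoff = 0.5) {
  ce <- consensusEdges(model, cutoff)
  writeLines(if (nrow(ce)) paste(ce$parent, "dybn", ce$child, sep = "\t")
             else character(), path)
  invisible(path)
}
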