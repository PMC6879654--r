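## Dynamic Network Analysis: thresholded correlation networks over adjacent
## time windows and the density statistic that summarizes their complexity.

#' Default adjacent 8-hour analysis windows
#'
#' The three half-open windows covering the first post-injury day:
#' `[0, 8)`, `[8, 16)`, `[16, 24)` hours.
#'
#' @return 2-column matrix `start_h`, `end_h`.
#' @export
defaultWindows <- function() {
  matrix(c(0, 8, 8, 16, 16, 24), ncol = 2, byrow = TRUE,
         dimnames = list(NULL, c("start_h", "end_h")))
}

#' Per-patient mediator values within a time window
#'
#' Selects samples with `start <= time_h < end` (half-open), averages
#' multiple samples of the same (patient, mediator) within the window, and
#' omits patients with no sample in the window.
#'
#' @param panel a [MediatorPanel-class].
#' @param window numeric length-2 `(start_h, end_h)`.
#' @return numeric matrix, patients x mediators (possibly 0 rows); `NA`
#'   where a patient lacks that mediator in the window.
#' @export
windowValues <- function(panel, window) {
  stopifnot(length(window) == 2, window[1] < window[2])
  cd <- SummarizedExperiment::colData(panel)
  sel <- cd$time_h >= window[1] & cd$time_h < window[2]
  a <- SummarizedExperiment::assay(panel, "conc")[, sel, drop = FALSE]
  pid <- cd$patient_id[sel]
  pats <- unique(pid)
  out <- matrix(NA_real_, length(pats), nrow(panel),
                dimnames = list(pats, rownames(panel)))
  for (p in pats) {
    sub <- a[, pid == p, drop = FALSE]
    out[p, ] <- rowMeans(sub, na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out[rowSums(!is.na(out)) > 0, , drop = FALSE]
}

#' Build a thresholded correlation network
#'
#' For each mediator pair, the correlation across patients is computed on
#' pairwise-complete values (>= `minObs` complete pairs required); an edge is
#' created when `|r| >= threshold` (or `r >= threshold` with
#' `absolute = FALSE`). The signed correlation is stored on the edge. The
#' node set is the mediators with evaluable data (>= `minObs` non-missing
#' values); constant mediators are kept as nodes but their pairs are skipped
#' with a message.
#'
#' @param values patients x mediators matrix (see [windowValues()]).
#' @param threshold correlation threshold in `(0, 1]` (default 0.7).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param absolute threshold `|r|` (default) rather than signed `r`.
#' @param transform `"log10"` (default; `log10(x + floor)`) or `"none"`.
#' @param floor offset for the log transform.
#' @param minObs minimum complete pairs per evaluable correlation.
#' @param group,window labels stored on the result.
#' @return a [CorrelationNetwork-class].
#' @export
buildNetwork <- function(values, threshold = 0.7,
                         method = c("pearson", "spearman"), absolute = TRUE,
                         transform = c("log10", "none"), floor = 0.01,
                         minObs = 3, group = NA_character_,
                         window = c(NA_real_, NA_real_)) {
  method <- match.arg(method)
  transform <- match.arg(transform)
  stopifnot(threshold > 0, threshold <= 1)
  x <- as.matrix(values)
  if (transform == "log10") x <- log10(x + floor)

  evaluable <- colSums(!is.na(x)) >= minObs
  nodes <- colnames(x)[evaluable]
  x <- x[, evaluable, drop = FALSE]
  constant <- vapply(seq_along(nodes), function(j) {
    v <- x[, j]; v <- v[!is.na(v)]
    length(unique(v)) <= 1L
  }, TRUE)
  if (any(constant))
    message("constant mediator(s) skipped for edges: ",
            paste(nodes[constant], collapse = ", "))

  ef <- data.frame(from = character(), to = character(), r = numeric(),
                   stringsAsFactors = FALSE)
  if (length(nodes) >= 2) {
    suppressWarnings(
      cm <- stats::cor(x, use = "pairwise.complete.obs", method = method))
    nComplete <- crossprod(!is.na(x))
    idx <- which(upper.tri(cm), arr.ind = TRUE)
    r <- cm[idx]
    okPair <- !constant[idx[, 1]] & !constant[idx[, 2]] &
      nComplete[idx] >= minObs & !is.na(r)
    pass <- okPair & (if (absolute) abs(r) else r) >= threshold - 1e-12
    if (any(pass)) {
      a <- nodes[idx[pass, 1]]; b <- nodes[idx[pass, 2]]
      ef <- data.frame(from = pmin(a, b), to = pmax(a, b), r = r[pass],
                       stringsAsFactors = FALSE)
      ef <- ef[order(ef$from, ef$to), ]
      rownames(ef) <- NULL
    }
  }
  methods::new("CorrelationNetwork", group = as.character(group),
               windowStart = as.numeric(window[1]),
               windowEnd = as.numeric(window[2]), nodes = nodes,
               edges = ef, threshold = threshold, method = method,
               absolute = absolute)
}

#' @rdname cytodyn-generics
#' @export
setMethod("edges", "CorrelationNetwork", function(x, ...) x@edges)

#' Network density
#'
#' The complexity statistic for a thresholded window network:
#' `E * N / (N * (N - 1) / 2)`, i.e. `2E / (N - 1)` — the edge count scaled
#' by the number of nodes over the maximum possible edge count. A complete
#' graph has density `N`. `N` is the number of nodes considered in the
#' window (mediators with evaluable data); at least 2 are required.
#'
#' @param x a [CorrelationNetwork-class], or an edge count `E` when `N` is
#'   given.
#' @param N number of nodes when `x` is an edge count.
#' @param ... unused.
#' @return density (>= 0).
#' @examples
#' networkDensity(6, N = 4)  # complete graph on 4 nodes -> 4
#' networkDensity(4, N = 5)  # 2
#' @export
setMethod("networkDensity", "numeric", function(x, N, ...) {
  if (N < 2) stop("density requires at least 2 nodes")
  stopifnot(x >= 0, x <= N * (N - 1) / 2)
  x * N / (N * (N - 1) / 2)
})

#' @rdname networkDensity
#' @export
setMethod("networkDensity", "CorrelationNetwork", function(x, ...) {
  networkDensity(nrow(x@edges), N = length(x@nodes))
})

setMethod("show", "CorrelationNetwork", function(object) {
  cat(sprintf("CorrelationNetwork [%s, %g-%g h): %d nodes, %d edges (%s, %s%g)\n",
              object@group, object@windowStart, object@windowEnd,
              length(object@nodes), nrow(object@edges), object@method,
              if (object@absolute) "|r| >= " else "r >= ",
              object@threshold))
  if (length(object@nodes) >= 2)
    cat("  density:", signif(networkDensity(object), 4), "\n")
})

#' Density trace over windows and groups
#'
#' Builds one correlation network per group per window and tabulates node
#' counts, edge counts and density, ordered by window start within group —
#' the quantification of dynamic network complexity over the first day.
#'
#' @param panel a [MediatorPanel-class] with group labels.
#' @param windows 2-column matrix of half-open windows (default
#'   [defaultWindows()]).
#' @param ... passed to [buildNetwork()] (`threshold`, `method`, `absolute`,
#'   `transform`, ...).
#' @param returnNetworks if TRUE, attach the networks as attribute
#'   `"networks"`.
#' @return data.frame `group`, `window_start`, `window_end`, `n_nodes`,
#'   `n_edges`, `density` (`NA` density where < 2 evaluable nodes).
#' @export
densityTrace <- function(panel, windows = defaultWindows(), ...,
                         returnNetworks = FALSE) {
  cd <- SummarizedExperiment::colData(panel)
  groups <- sort(unique(as.character(cd$group[!is.na(cd$group)])))
  if (!length(groups)) stop("panel has no group labels")
  nets <- list()
  rows <- list()
  for (g in groups) {
    sub <- panel[, !is.na(cd$group) & cd$group == g]
    for (w in seq_len(nrow(windows))) {
      vals <- windowValues(sub, windows[w, ])
      net <- buildNetwork(vals, group = g, window = windows[w, ], ...)
      nets[[paste(g, windows[w, 1], sep = "_")]] <- net
      dens <- if (length(net@nodes) >= 2) networkDensity(net) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        group = g, window_start = windows[w, 1], window_end = windows[w, 2],
        n_nodes = length(net@nodes), n_edges = nrow(net@edges),
        density = dens, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$group, out$window_start), ]
  rownames(out) <- NULL
  if (returnNetworks) attr(out, "networks") <- nets
  out
}
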