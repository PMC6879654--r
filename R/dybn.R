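## Dynamic Bayesian network structure inference over time-sliced mediator
## panels. Because every edge runs from slice t to slice t+1, the structure
## factorizes over children: exact per-child enumeration of all parent sets
## up to a fan-in bound, scored with a linear-Gaussian BIC, composes into the
## exact global optimum; Bayesian model averaging over the same enumeration
## gives posterior edge probabilities. No search heuristics are involved.

#' Build a transition dataset from a mediator panel
#'
#' Snaps each sample to the nearest grid level (within `tol` hours), averages
#' duplicates in a slot, and forms one observation pair per patient per pair
#' of consecutive occupied grid slots. A gap (missed draw) breaks the chain:
#' no pair is formed across it, so no dynamics are fabricated. Pairs with any
#' missing variable are dropped (complete case). Constant variables are
#' dropped with a warning; remaining columns of the t and t+1 matrices are
#' z-scored independently, which makes the downstream score invariant to
#' affine rescaling of any variable.
#'
#' @param panel a [MediatorPanel-class].
#' @param grid strictly increasing time levels (hours); default = the
#'   panel's distinct sample times.
#' @param tol snapping tolerance in hours (default 2).
#' @param transform `"log10"` (default) or `"none"`; applied before
#'   standardization.
#' @param floor offset for the log transform.
#' @return a [TransitionDataset-class].
#' @export
buildTransitions <- function(panel, grid = sampleTimes(panel), tol = 2,
                             transform = c("log10", "none"), floor = 0.01) {
  transform <- match.arg(transform)
  if (is.unsorted(grid, strictly = TRUE))
    stop("grid must be strictly increasing")
  cd <- SummarizedExperiment::colData(panel)
  a <- SummarizedExperiment::assay(panel, "conc")
  if (transform == "log10") a <- log10(a + floor)

  slot <- vapply(cd$time_h, function(t) {
    i <- which.min(abs(grid - t))
    if (abs(grid[i] - t) <= tol) i else NA_integer_
  }, 1L)

  vars <- rownames(panel)
  x0 <- x1 <- list(); pat <- character(); ft <- tt <- numeric()
  for (p in unique(cd$patient_id)) {
    pi <- which(cd$patient_id == p & !is.na(slot))
    if (!length(pi)) next
    occupied <- sort(unique(slot[pi]))
    ## average duplicates per slot
    vals <- vapply(occupied, function(s) {
      rowMeans(a[, pi[slot[pi] == s], drop = FALSE], na.rm = TRUE)
    }, numeric(length(vars)))
    if (is.null(dim(vals))) vals <- matrix(vals, ncol = length(occupied))
    vals[is.nan(vals)] <- NA_real_
    if (length(occupied) < 2) next
    for (k in seq_len(length(occupied) - 1L)) {
      if (occupied[k + 1L] != occupied[k] + 1L) next  # gap breaks the chain
      v0 <- vals[, k]; v1 <- vals[, k + 1L]
      if (anyNA(v0) || anyNA(v1)) next  # complete case
      x0[[length(x0) + 1L]] <- v0
      x1[[length(x1) + 1L]] <- v1
      pat <- c(pat, p)
      ft <- c(ft, grid[occupied[k]]); tt <- c(tt, grid[occupied[k + 1L]])
    }
  }
  if (length(x0) < 3) stop("fewer than 3 retained transition pairs")
  X0 <- do.call(rbind, x0); X1 <- do.call(rbind, x1)
  colnames(X0) <- colnames(X1) <- vars

  constant <- vapply(seq_along(vars), function(j) {
    stats::var(X0[, j]) < 1e-12 || stats::var(X1[, j]) < 1e-12
  }, TRUE)
  if (any(constant))
    warning("constant variable(s) dropped: ",
            paste(vars[constant], collapse = ", "))
  keep <- !constant
  X0 <- scale(X0[, keep, drop = FALSE])
  X1 <- scale(X1[, keep, drop = FALSE])
  methods::new("TransitionDataset", variables = vars[keep],
               x0 = unclass(X0)[, , drop = FALSE],
               x1 = unclass(X1)[, , drop = FALSE],
               patient = pat, fromTime = ft, toTime = tt,
               dropped = vars[constant])
}

setMethod("show", "TransitionDataset", function(object) {
  cat("TransitionDataset:", nrow(object@x0), "pairs,",
      length(object@variables), "variables",
      if (length(object@dropped))
        paste0("(dropped: ", paste(object@dropped, collapse = ", "), ")"),
      "\n")
})

## BIC-style log score of child ~ intercept + parents
## score = -n/2 log(RSS/n) - (k+2)/2 log(n), k = |parents|
scoreFromRss <- function(rss, n, k) {
  -n / 2 * log(pmax(rss, 1e-12 * n) / n) - (k + 2) / 2 * log(n)
}

#' Score a parent set for one child
#'
#' Linear-Gaussian BIC-type log score of the regression of the child at
#' slice t+1 on the candidate parents at slice t (plus intercept):
#' `-n/2 * log(RSS/n) - (|parents| + 2)/2 * log(n)`; higher is better. A
#' zero-residual fit is floored at variance 1e-12; a singular (collinear)
#' design falls back to a pseudo-inverse fit with a warning.
#'
#' @param data a [TransitionDataset-class].
#' @param child child variable name.
#' @param parents character vector of parent names (may be empty; may
#'   include the child itself: a self-edge models feedback).
#' @return log score (scalar).
#' @export
scoreParentSet <- function(data, child, parents = character()) {
  stopifnot(child %in% data@variables, all(parents %in% data@variables))
  y <- data@x1[, child]
  n <- length(y)
  X <- cbind(1, data@x0[, parents, drop = FALSE])
  if (qr(X)$rank < ncol(X)) {
    warning("collinear parent set {", paste(parents, collapse = ", "),
            "}: pseudo-inverse fit")
    beta <- pinvCoef(X, y)
    rss <- sum((y - X %*% beta)^2)
  } else {
    rss <- sum(stats::lm.fit(X, y)$residuals^2)
  }
  scoreFromRss(rss, n, length(parents))
}

## all index subsets of 1..V with size <= fanIn, ordered by size then
## lexicographically (so which.max tie-breaks to smaller set, then lex)
enumerateParentSets <- function(V, fanIn) {
  sets <- list(integer())
  for (k in seq_len(min(fanIn, V))) {
    cmb <- utils::combn(V, k)
    sets <- c(sets, lapply(seq_len(ncol(cmb)), function(j) cmb[, j]))
  }
  sets
}

#' Infer dynamic Bayesian network structure
#'
#' Exact structure learning over slice-t to slice-t+1 edges: for every child,
#' all parent sets of size up to `fanIn` are enumerated and scored with
#' [scoreParentSet()]'s linear-Gaussian BIC. The best parent set is the score
#' argmax (ties to the smaller, then lexicographically earlier set); the
#' posterior over parent sets is `exp(score - max)` normalized under a
#' uniform structure prior, and the posterior probability of an edge is the
#' total mass of sets containing that parent. Per-child optima compose into
#' the exact global optimum because no edge crosses children.
#'
#' @param data a [TransitionDataset-class].
#' @param fanIn maximum parent-set size (default 3); capped at the number of
#'   variables with a warning.
#' @return a [DybnModel-class].
#' @examples
#' pan <- generateVar1Panel(20, 10, diag(3), 0.8, seed = 7)
#' tr <- buildTransitions(pan, transform = "none")
#' inferStructure(tr, fanIn = 2)
#' @export
inferStructure <- function(data, fanIn = 3) {
  stopifnot(fanIn >= 0)
  vars <- data@variables
  V <- length(vars)
  if (fanIn > V) {
    warning("fanIn capped at the number of variables (", V, ")")
    fanIn <- V
  }
  nSets <- sum(choose(V, 0:fanIn))
  if (nSets > 1e6) stop("parent-set enumeration too large (", nSets,
                        " sets per child); reduce fanIn or variables")
  n <- nrow(data@x0)
  sets <- enumerateParentSets(V, fanIn)
  X <- cbind(`(Intercept)` = 1, data@x0)
  G <- crossprod(X)                    # (V+1) x (V+1)
  XtY <- crossprod(X, data@x1)         # (V+1) x V, all children at once
  yty <- colSums(data@x1^2)

  scores <- matrix(NA_real_, length(sets), V,
                   dimnames = list(NULL, vars))
  for (s in seq_along(sets)) {
    cols <- c(1L, sets[[s]] + 1L)
    Gs <- G[cols, cols, drop = FALSE]
    Rs <- tryCatch(chol(Gs), error = function(e) NULL)
    if (!is.null(Rs)) {
      B <- backsolve(Rs, forwardsolve(t(Rs), XtY[cols, , drop = FALSE]))
      rss <- pmax(yty - colSums(B * XtY[cols, , drop = FALSE]), 0)
    } else {
      ## singular design: per-child pseudo-inverse
      rss <- vapply(seq_len(V), function(j) {
        beta <- pinvCoef(X[, cols, drop = FALSE], data@x1[, j])
        sum((data@x1[, j] - X[, cols, drop = FALSE] %*% beta)^2)
      }, 1)
    }
    scores[s, ] <- scoreFromRss(rss, n, length(sets[[s]]))
  }

  edgeProb <- matrix(0, V, V, dimnames = list(parent = vars, child = vars))
  bestParents <- stats::setNames(vector("list", V), vars)
  bestScore <- stats::setNames(numeric(V), vars)
  membership <- matrix(FALSE, length(sets), V)  # set s contains parent v?
  for (s in seq_along(sets)) membership[s, sets[[s]]] <- TRUE
  for (j in seq_len(V)) {
    sc <- scores[, j]
    b <- which.max(sc)  # first max = smallest then lexicographic
    bestParents[[j]] <- vars[sets[[b]]]
    bestScore[j] <- sc[b]
    w <- exp(sc - sc[b])
    w <- w / sum(w)
    edgeProb[, j] <- colSums(w * membership)
  }
  methods::new("DybnModel", variables = vars, edgeProb = edgeProb,
               bestParents = bestParents, bestScore = bestScore,
               fanIn = as.integer(fanIn), nPairs = as.integer(n))
}

#' @rdname cytodyn-generics
#' @export
setMethod("edgeProbabilities", "DybnModel", function(x) x@edgeProb)

#' @rdname cytodyn-generics
#' @export
setMethod("bestParents", "DybnModel", function(x) x@bestParents)

#' Consensus edges at a posterior cutoff
#'
#' @param x a [DybnModel-class].
#' @param cutoff posterior probability cutoff (default 0.5).
#' @param ... unused.
#' @return data.frame `parent`, `child`, `posterior`, `feedback` (self-edge),
#'   sorted by decreasing posterior.
#' @export
setMethod("consensusEdges", "DybnModel", function(x, cutoff = 0.5, ...) {
  idx <- which(x@edgeProb >= cutoff, arr.ind = TRUE)
  out <- data.frame(parent = x@variables[idx[, 1]],
                    child = x@variables[idx[, 2]],
                    posterior = x@edgeProb[idx],
                    stringsAsFactors = FALSE)
  out$feedback <- out$parent == out$child
  out <- out[order(-out$posterior, out$parent, out$child), ]
  rownames(out) <- NULL
  out
})

#' @rdname cytodyn-generics
#' @param cutoff posterior cutoff for feedback self-edges (default 0.5).
#' @export
setMethod("feedbackNodes", "DybnModel", function(x, cutoff = 0.5, ...) {
  x@variables[diag(x@edgeProb) >= cutoff]
})

#' Central nodes of a dynamic Bayesian network
#'
#' Ranks variables by total outgoing posterior edge mass (the sum of the
#' variable's posterior edge probabilities into all children) — the
#' operationalization of a "central node" as the mediator with greatest
#' inferred downstream influence. Ties break lexicographically.
#'
#' @param x a [DybnModel-class].
#' @param k number of top variables to return (default all; capped at V).
#' @param ... unused.
#' @return data.frame `variable`, `score`, in descending score order.
#' @export
setMethod("centralNodes", "DybnModel", function(x, k = Inf, ...) {
  sc <- rowSums(x@edgeProb)
  ord <- order(-sc, x@variables)
  k <- min(k, length(sc))
  data.frame(variable = x@variables[ord][seq_len(k)],
             score = unname(sc[ord][seq_len(k)]),
             stringsAsFactors = FALSE)
})

setMethod("show", "DybnModel", function(object) {
  cat("DybnModel:", length(object@variables), "variables, fan-in",
      object@fanIn, ",", object@nPairs, "transition pairs\n")
  ce <- consensusEdges(object, 0.5)
  cat("  edges with posterior >= 0.5:", nrow(ce),
      "(", sum(ce$feedback), "feedback )\n")
  top <- centralNodes(object, 3)
  cat("  top central nodes:",
      paste(sprintf("%s (%.2f)", top$variable, top$score), collapse = ", "),
      "\n")
})
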