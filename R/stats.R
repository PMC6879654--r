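## Group-by-time mediator statistics: fixed-effects two-way ANOVA with
## interaction (Type II sums of squares for unbalanced data), Mann-Whitney U,
## and Spearman correlation. The ANOVA core works on model matrices directly
## so thousands of fits (null-calibration sweeps) stay cheap.

rssOf <- function(X, y) {
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

dfOf <- function(X) qr(X)$rank

#' Two-way fixed-effects ANOVA with interaction
#'
#' Tests group, time and group-by-time effects on a (typically
#' log-transformed) response. For unbalanced data, Type II sums of squares
#' are used by default: each main effect is adjusted for the other main
#' effect (not the interaction), which is well-defined without choosing
#' reference levels; Type III (each term adjusted for everything else, with
#' sum-to-zero contrasts) is available via `type`. Observations are treated
#' as independent; repeated measures per patient are not modeled.
#'
#' @param response numeric response vector.
#' @param group,time factors (coerced) of equal length; each needs >= 2
#'   levels present.
#' @param type `"II"` (default) or `"III"`.
#' @param transform `"log10"` (default: `log10(response + floor)`) or
#'   `"none"`.
#' @param floor offset added before the log transform.
#' @return data.frame with rows `group`, `time`, `group:time`, `Residuals`
#'   and columns `sum_sq`, `df`, `F`, `p`.
#' @examples
#' d <- expand.grid(g = c("a", "b"), t = c("t0", "t1"), rep = 1:3)
#' y <- rnorm(nrow(d))
#' twoWayAnova(y, d$g, d$t, transform = "none")
#' @export
twoWayAnova <- function(response, group, time, type = c("II", "III"),
                        transform = c("log10", "none"), floor = 0.01) {
  type <- match.arg(type)
  transform <- match.arg(transform)
  ok <- stats::complete.cases(response, group, time)
  y <- response[ok]
  g <- factor(as.character(group)[ok])
  t <- factor(as.character(time)[ok])
  if (nlevels(g) < 2 || nlevels(t) < 2)
    stop("both factors need at least two levels with data")
  if (transform == "log10") y <- log10(y + floor)

  d <- data.frame(y = y, g = g, t = t)
  if (type == "III") {  # sum-to-zero contrasts make Type III well-defined
    stats::contrasts(d$g) <- stats::contr.sum(nlevels(g))
    stats::contrasts(d$t) <- stats::contr.sum(nlevels(t))
  }
  mm <- function(fml) stats::model.matrix(fml, d)

  Xfull <- mm(y ~ g * t)
  rssFull <- rssOf(Xfull, y)
  dfRes <- length(y) - dfOf(Xfull)
  if (dfRes <= 0) stop("no residual degrees of freedom")

  Xgt <- mm(y ~ g + t)
  ssInt <- rssOf(Xgt, y) - rssFull
  dfInt <- dfOf(Xfull) - dfOf(Xgt)

  if (type == "II") {
    ssG <- rssOf(mm(y ~ t), y) - rssOf(Xgt, y)
    ssT <- rssOf(mm(y ~ g), y) - rssOf(Xgt, y)
    dfG <- dfOf(Xgt) - dfOf(mm(y ~ t))
    dfT <- dfOf(Xgt) - dfOf(mm(y ~ g))
  } else {
    ## Type III: drop each term from the full sum-to-zero model
    asg <- attr(Xfull, "assign")  # 0 int, 1 g, 2 t, 3 g:t
    dropTerm <- function(term) rssOf(Xfull[, asg != term, drop = FALSE], y)
    ssG <- dropTerm(1) - rssFull
    ssT <- dropTerm(2) - rssFull
    dfG <- sum(asg == 1); dfT <- sum(asg == 2)
  }

  msRes <- rssFull / dfRes
  tab <- data.frame(
    sum_sq = pmax(c(ssG, ssT, ssInt), 0),
    df = c(dfG, dfT, dfInt),
    row.names = c("group", "time", "group:time"))
  tot <- sum((y - mean(y))^2)
  if (rssFull <= 1e-12 * max(tot, 1)) {
    ## exactly cell-constant data: zero-variation terms get F = 0, terms
    ## that absorb all variation get F = Inf (p = 0)
    tab$F <- ifelse(tab$sum_sq <= 1e-12 * max(tot, 1), 0, Inf)
  } else {
    tab$F <- (tab$sum_sq / tab$df) / msRes
  }
  tab$p <- stats::pf(tab$F, tab$df, dfRes, lower.tail = FALSE)
  rbind(tab, Residuals = data.frame(sum_sq = rssFull, df = dfRes,
                                    F = NA_real_, p = NA_real_))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples with midranks for ties.
#' The p-value is exact (distribution of U enumerated) when
#' `length(x) * length(y) <= 400` and there are no ties, otherwise a normal
#' approximation with tie and continuity corrections is used.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `U` (statistic for `x`) and `p` (two-sided).
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0
#' @export
mannWhitneyU <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (!length(x) || !length(y)) stop("empty sample")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && length(x) * length(y) <= 400
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, exact = exact, correct = TRUE, alternative = "two.sided"))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks; the p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` with `n - 2` degrees of freedom.
#' Pairs with a missing value in either variable are dropped.
#'
#' @param x,y paired samples; >= 3 complete pairs required.
#' @return list with `rho` and `p` (two-sided).
#' @examples
#' spearmanCor(1:5, c(2, 4, 5, 8, 9))$rho  # 1
#' @export
spearmanCor <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(abs(tt), n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p)
}

#' Per-group, per-time mean and SEM of one mediator
#'
#' The summary behind time-course plots: mean, SEM (sample sd over sqrt(n))
#' and n per group and time point, ordered by time.
#'
#' @param panel a [MediatorPanel-class] with group labels assigned.
#' @param mediator mediator name.
#' @return data.frame `group`, `time_h`, `n`, `mean`, `sem`.
#' @export
timecourseTable <- function(panel, mediator) {
  stopifnot(mediator %in% rownames(panel))
  cd <- SummarizedExperiment::colData(panel)
  v <- SummarizedExperiment::assay(panel, "conc")[mediator, ]
  ok <- !is.na(v) & !is.na(cd$group)
  d <- data.frame(group = as.character(cd$group)[ok], time_h = cd$time_h[ok],
                  v = v[ok])
  if (!nrow(d)) stop("no measurements for ", mediator)
  agg <- do.call(rbind, lapply(split(d, list(d$group, d$time_h), drop = TRUE),
    function(s) data.frame(group = s$group[1], time_h = s$time_h[1],
                           n = nrow(s), mean = mean(s$v), sem = semOf(s$v))))
  agg <- agg[order(agg$time_h, agg$group), ]
  rownames(agg) <- NULL
  agg
}

#' Group-by-time statistics for every mediator
#'
#' Runs the two-way ANOVA (group, time, interaction) per mediator on the
#' transformed concentrations, plus a per-time-point Mann-Whitney comparison
#' of the two groups pooled to a single per-mediator p as the minimum over
#' time points (a nonparametric confirmation of group differences when raw
#' values are skewed; no multiplicity adjustment unless `adjust`). A mediator
#' whose ANOVA fails (e.g. a factor collapses to one level after missingness)
#' is reported as `NA` and noted, without aborting the others.
#'
#' @param panel a [MediatorPanel-class] with exactly two non-NA groups.
#' @param transform,floor,type passed to [twoWayAnova()].
#' @param adjust if TRUE, add Benjamini-Hochberg adjusted ANOVA group
#'   p-values as `p_group_adj`.
#' @return data.frame, one row per mediator: `mediator`, `F_group`,
#'   `p_group`, `F_time`, `p_time`, `F_int`, `p_int`, `mw_p`.
#' @export
mediatorStats <- function(panel, transform = "log10", floor = 0.01,
                          type = "II", adjust = FALSE) {
  cd <- SummarizedExperiment::colData(panel)
  grp <- as.character(cd$group)
  keep <- !is.na(grp)
  groups <- unique(grp[keep])
  if (length(groups) != 2)
    stop("need exactly two groups, got: ", paste(groups, collapse = ", "))
  a <- SummarizedExperiment::assay(panel, "conc")
  rows <- lapply(rownames(a), function(med) {
    v <- a[med, keep]
    g <- grp[keep]; th <- cd$time_h[keep]
    res <- tryCatch({
      at <- twoWayAnova(v, g, th, type = type, transform = transform,
                        floor = floor)
      mw <- vapply(sort(unique(th)), function(tt) {
        x <- v[g == groups[1] & th == tt]; y <- v[g == groups[2] & th == tt]
        x <- x[!is.na(x)]; y <- y[!is.na(y)]
        if (!length(x) || !length(y)) return(NA_real_)
        mannWhitneyU(x, y)$p
      }, 1)
      data.frame(mediator = med,
                 F_group = at["group", "F"], p_group = at["group", "p"],
                 F_time = at["time", "F"], p_time = at["time", "p"],
                 F_int = at["group:time", "F"], p_int = at["group:time", "p"],
                 mw_p = if (all(is.na(mw))) NA_real_ else min(mw, na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      message("mediator ", med, " skipped: ", conditionMessage(e))
      data.frame(mediator = med, F_group = NA_real_, p_group = NA_real_,
                 F_time = NA_real_, p_time = NA_real_, F_int = NA_real_,
                 p_int = NA_real_, mw_p = NA_real_, stringsAsFactors = FALSE)
    })
    res
  })
  out <- do.call(rbind, rows)
  if (adjust) out$p_group_adj <- stats::p.adjust(out$p_group, method = "BH")
  rownames(out) <- NULL
  out
}
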