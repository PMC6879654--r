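## Independent oracles, deliberately coded by different routes than the
## package implementations they cross-check.

## Fisher two-sided p by log-binomial-coefficient enumeration (implementation
## uses dhyper; this uses lchoose directly).
fisherOracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  k <- max(0, c1 - r2):min(r1, c1)
  p <- exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  pObs <- p[k == a]
  min(1, sum(p[p <= pObs * (1 + 1e-7)]))
}

## Mann-Whitney U (for x) and exact two-sided p by complete enumeration of
## which ranks the x-sample occupies.
mannWhitneyOracle <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  picks <- combn(nx + ny, nx)
  us <- apply(picks, 2, function(ix) sum(ix) - nx * (nx + 1) / 2)
  pLe <- mean(us <= U); pGe <- mean(us >= U)
  list(U = U, p = min(1, 2 * min(pLe, pGe)))
}

## Naive DyBN re-enumeration: per child, loop parent subsets, fit with lm(),
## recompute the score from the definition, average naively.
dybnOracle <- function(tr, fanIn) {
  vars <- tr@variables
  V <- length(vars)
  n <- nrow(tr@x0)
  sets <- list(integer(0))
  for (k in seq_len(min(fanIn, V)))
    sets <- c(sets, lapply(seq_len(ncol(combn(V, k))),
                           function(j) combn(V, k)[, j]))
  edgeProb <- matrix(0, V, V, dimnames = list(parent = vars, child = vars))
  best <- vector("list", V); names(best) <- vars
  for (j in seq_len(V)) {
    sc <- vapply(sets, function(s) {
      d <- data.frame(y = tr@x1[, j], tr@x0[, s, drop = FALSE])
      rss <- sum(residuals(lm(y ~ ., data = d))^2)
      -n / 2 * log(max(rss, 1e-12 * n) / n) - (length(s) + 2) / 2 * log(n)
    }, 1)
    b <- which.max(sc)
    best[[j]] <- vars[sets[[b]]]
    w <- exp(sc - max(sc)); w <- w / sum(w)
    for (s in seq_along(sets))
      edgeProb[sets[[s]], j] <- edgeProb[sets[[s]], j] + w[s]
  }
  list(edgeProb = edgeProb, best = best)
}

## All-pairs brute-force correlation network on a small panel.
networkOracle <- function(values, threshold, transform = "log10",
                          floor = 0.01) {
  x <- as.matrix(values)
  if (transform == "log10") x <- log10(x + floor)
  meds <- colnames(x)
  out <- list()
  for (i in seq_along(meds)) for (j in seq_along(meds)) {
    if (i >= j) next
    ok <- complete.cases(x[, i], x[, j])
    if (sum(ok) < 3) next
    if (sd(x[ok, i]) == 0 || sd(x[ok, j]) == 0) next
    r <- cor(x[ok, i], x[ok, j])
    if (abs(r) >= threshold - 1e-12)
      out[[length(out) + 1L]] <- data.frame(from = meds[i], to = meds[j],
                                            r = r)
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(from = character(), to = character(), r = numeric())
}

## small random patient tables for matching tests
randomPatients <- function(n, prefix, seed) {
  set.seed(seed)
  data.frame(patient_id = paste0(prefix, seq_len(n)),
             age = round(runif(n, 18, 90), 1),
             sex = sample(c("male", "female"), n, TRUE),
             iss = sample(5:50, n, TRUE), stringsAsFactors = FALSE)
}
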