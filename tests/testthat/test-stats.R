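test_that("balanced two-way ANOVA matches the closed-form sums of squares", {
  # 2 groups x 2 times x 3 replicates, small integers
  g <- rep(c("A", "B"), each = 6)
  t <- rep(rep(c("t0", "t1"), each = 3), 2)
  y <- c(1, 2, 3, 5, 6, 7, 2, 3, 4, 9, 10, 11)
  at <- twoWayAnova(y, g, t, transform = "none")

  # textbook balanced formulas, computed from cell/marginal means
  cellMean <- tapply(y, list(g, t), mean)
  gm <- mean(y); r <- 3
  ssG <- r * 2 * sum((rowMeans(cellMean) - gm)^2)
  ssT <- r * 2 * sum((colMeans(cellMean) - gm)^2)
  ssCells <- r * sum((cellMean - gm)^2)
  ssInt <- ssCells - ssG - ssT
  ssRes <- sum((y - cellMean[cbind(g, t)])^2)
  expect_equal(at["group", "sum_sq"], ssG, tolerance = 1e-10)
  expect_equal(at["time", "sum_sq"], ssT, tolerance = 1e-10)
  expect_equal(at["group:time", "sum_sq"], ssInt, tolerance = 1e-10)
  expect_equal(at["Residuals", "sum_sq"], ssRes, tolerance = 1e-10)
  expect_equal(at["group", "F"], (ssG / 1) / (ssRes / 8), tolerance = 1e-10)
})

test_that("ANOVA F is zero without between-cell variation and is
           scale-invariant", {
  g <- rep(c("A", "B"), each = 4)
  t <- rep(c("t0", "t1"), 4)
  # response depends on time only, constant within cells
  y <- ifelse(t == "t0", 1, 5)
  at <- twoWayAnova(y, g, t, transform = "none")
  expect_equal(at["group", "F"], 0)
  expect_equal(at["group:time", "F"], 0)
  expect_gt(at["time", "F"], 1e10)  # all residual variance is zero

  set.seed(4)
  y2 <- rnorm(8)
  a1 <- twoWayAnova(y2, g, t, transform = "none")
  a2 <- twoWayAnova(10 * y2, g, t, transform = "none")
  expect_equal(a1$F, a2$F, tolerance = 1e-10)
  expect_equal(a1$p, a2$p, tolerance = 1e-10)
})

test_that("Type II and Type III ANOVA match car::Anova on random
           unbalanced designs", {
  library(car)
  set.seed(12)
  for (i in 1:30) {
    ## unbalanced but with every cell occupied (aliased fits are tested
    ## separately); 1-10 replicates per cell
    cells <- expand.grid(g = c("A", "B"), t = paste0("t", 1:3),
                         stringsAsFactors = FALSE)
    reps <- sample(1:10, nrow(cells), TRUE)
    g <- factor(rep(cells$g, reps))
    t <- factor(rep(cells$t, reps))
    n <- length(g)
    y <- rnorm(n) + as.numeric(g) + 0.5 * as.numeric(t) +
      0.3 * as.numeric(g) * as.numeric(t)
    at <- twoWayAnova(y, g, t, transform = "none")
    ref <- car::Anova(lm(y ~ g * t), type = 2)
    expect_equal(at["group", "sum_sq"], ref["g", "Sum Sq"], tolerance = 1e-8)
    expect_equal(at["time", "sum_sq"], ref["t", "Sum Sq"], tolerance = 1e-8)
    expect_equal(at["group:time", "sum_sq"], ref["g:t", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(at["group", "p"], ref["g", "Pr(>F)"], tolerance = 1e-8)

    at3 <- twoWayAnova(y, g, t, type = "III", transform = "none")
    d <- data.frame(y = y, g = g, t = t)
    contrasts(d$g) <- contr.sum(2); contrasts(d$t) <- contr.sum(3)
    ref3 <- car::Anova(lm(y ~ g * t, data = d), type = 3)
    expect_equal(at3["group", "sum_sq"], ref3["g", "Sum Sq"],
                 tolerance = 1e-8)
    expect_equal(at3["group:time", "sum_sq"], ref3["g:t", "Sum Sq"],
                 tolerance = 1e-8)
  }
})

test_that("ANOVA rejects degenerate factors", {
  expect_error(twoWayAnova(rnorm(6), rep("A", 6), rep(c("x", "y"), 3)),
               "two levels")
})

test_that("Mann-Whitney U handles separation, symmetry, and exact cases", {
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6))$U, 0)
  x <- c(2, 9, 4, 7)
  expect_equal(mannWhitneyU(x, x)$U, length(x)^2 / 2)
  o <- mannWhitneyOracle(c(1, 3), c(2, 4))
  m <- mannWhitneyU(c(1, 3), c(2, 4))
  expect_equal(m$U, o$U)
  expect_equal(m$p, o$p, tolerance = 1e-12)
  expect_error(mannWhitneyU(numeric(), 1:3), "empty")
})

test_that("Mann-Whitney exact mode agrees with full enumeration for small
           tie-free samples", {
  set.seed(21)
  for (i in 1:20) {
    nx <- sample(2:8, 1); ny <- sample(2:8, 1)
    z <- sample(100, nx + ny)  # distinct -> no ties
    x <- z[seq_len(nx)]; y <- z[-seq_len(nx)]
    o <- mannWhitneyOracle(x, y)
    m <- mannWhitneyU(x, y)
    expect_equal(m$U, o$U)
    expect_equal(m$p, o$p, tolerance = 1e-12)
  }
})

test_that("Spearman correlation: perfect ranks, ties, and monotone
           invariance", {
  expect_equal(spearmanCor(1:5, c(2, 4, 5, 8, 9))$rho, 1)
  expect_equal(spearmanCor(1:5, c(9, 8, 5, 4, 2))$rho, -1)

  # tie case against hand-assigned midranks
  x <- c(1, 2, 2, 4); y <- c(3, 1, 1, 2)
  rx <- c(1, 2.5, 2.5, 4); ry <- c(4, 1.5, 1.5, 3)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanCor(x, y)$rho, num / den, tolerance = 1e-12)
  expect_equal(spearmanCor(x, y)$rho,
               suppressWarnings(cor.test(x, y, method = "spearman"))$estimate,
               tolerance = 1e-12, ignore_attr = TRUE)

  # invariant under strictly monotone transforms
  set.seed(5)
  a <- rnorm(20); b <- rnorm(20)
  expect_equal(spearmanCor(a, b)$rho, spearmanCor(exp(a), b)$rho)
  expect_equal(spearmanCor(a, b)$p, spearmanCor(a, b^3 + 5 * b)$p)

  expect_error(spearmanCor(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearmanCor(1:2, 1:2), "3 complete pairs")
  # missing pairs dropped
  expect_equal(spearmanCor(c(1:5, NA), c(2, 4, 5, 8, 9, 1))$rho, 1)
})

test_that("time-course tables give per-group per-time mean and SEM in time
           order", {
  rec <- expand.grid(patient_id = paste0("P", 1:4), time_h = c(8, 0),
                     stringsAsFactors = FALSE)
  rec$mediator <- "IL-6"
  rec$value_pg_ml <- c(1, 2, 3, 4, 10, 20, 30, 40)
  rec$group <- rep(c("Day", "Day", "Night", "Night"), 2)
  tc <- timecourseTable(MediatorPanel(rec), "IL-6")
  expect_equal(tc$time_h, c(0, 0, 8, 8))
  expect_equal(tc$mean[tc$time_h == 0 & tc$group == "Day"], 15)
  expect_equal(tc$sem[tc$time_h == 8 & tc$group == "Night"],
               sd(c(3, 4)) / sqrt(2))
  expect_equal(tc$n, rep(2L, 4), ignore_attr = TRUE)
})

test_that("per-mediator statistics survive a failing mediator and flag group
           effects", {
  sim <- generateCohort(syntheticConfig(seed = 31))
  st <- mediatorStats(sim$panel)
  expect_equal(nrow(st), 32)
  expect_true(all(st$p_group >= 0 & st$p_group <= 1, na.rm = TRUE))
  # planted persistent effects are detected
  expect_lt(st$p_group[st$mediator == "IL-7"], 0.05)
  expect_lt(st$p_group[st$mediator == "IL-17A"], 0.05)
  expect_true(all(!is.na(st$mw_p)))

  # a mediator observed at a single time point fails alone, others survive
  lf <- longFormat(sim$panel)
  lf <- rbind(lf[lf$mediator != "IL-33" | lf$time_h == 0, ])
  pan2 <- MediatorPanel(lf)
  expect_message(st2 <- mediatorStats(pan2), "IL-33 skipped")
  expect_true(is.na(st2$p_group[st2$mediator == "IL-33"]))
  expect_false(anyNA(st2$p_group[st2$mediator != "IL-33"]))

  # BH adjustment is monotone in the raw p-values
  st3 <- mediatorStats(sim$panel, adjust = TRUE)
  expect_true(all(st3$p_group_adj >= st3$p_group, na.rm = TRUE))
})
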