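test_that("transition pairs come from consecutive occupied grid slots only", {
  # one patient sampled at all 10 grid levels -> 9 pairs
  grid <- c(0, 8, 16, 24, 48, 72, 96, 120, 144, 168)
  rec <- expand.grid(patient_id = "P1", mediator = c("A", "B"),
                     time_h = grid, stringsAsFactors = FALSE)
  set.seed(1)
  rec$value_pg_ml <- rlnorm(nrow(rec))
  tr <- buildTransitions(MediatorPanel(rec), grid = grid)
  expect_equal(nrow(tr@x0), 9)
  expect_equal(tr@fromTime, grid[-10])
  expect_equal(tr@toTime, grid[-1])

  # a missing 16-h draw removes the 8->16 and 16->24 pairs and does NOT
  # create an 8->24 pair
  rec2 <- rec[rec$time_h != 16, ]
  tr2 <- buildTransitions(MediatorPanel(rec2), grid = grid)
  expect_equal(nrow(tr2@x0), 7)
  expect_false(any(tr2@fromTime == 8 | tr2@toTime == 24))

  # samples snap to the nearest grid level within tolerance
  rec3 <- rec
  rec3$time_h[rec3$time_h == 8] <- 9.5
  tr3 <- buildTransitions(MediatorPanel(rec3), grid = grid, tol = 2)
  expect_equal(nrow(tr3@x0), 9)
  rec4 <- rec
  rec4$time_h[rec4$time_h == 8] <- 12  # 4 h from both 8 and 16: dropped
  tr4 <- buildTransitions(MediatorPanel(rec4), grid = grid, tol = 2)
  expect_equal(nrow(tr4@x0), 7)
})

test_that("transitions are complete-case, standardized, and constant
           variables are dropped", {
  grid <- 0:5
  rec <- expand.grid(patient_id = paste0("P", 1:6), mediator = c("A", "B", "K"),
                     time_h = grid, stringsAsFactors = FALSE)
  set.seed(2)
  rec$value_pg_ml <- rlnorm(nrow(rec))
  rec$value_pg_ml[rec$mediator == "K"] <- 7  # constant
  # one missing measurement kills exactly the two pairs that touch it
  drop <- rec$patient_id == "P1" & rec$mediator == "A" & rec$time_h == 2
  expect_warning(
    tr <- buildTransitions(MediatorPanel(rec[!drop, ]), grid = grid),
    "constant")
  expect_equal(tr@dropped, "K")
  expect_equal(tr@variables, c("A", "B"))
  expect_equal(nrow(tr@x0), 6 * 5 - 2)
  expect_equal(unname(colMeans(tr@x0)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(tr@x1, 2, sd)), c(1, 1), tolerance = 1e-12)

  # fewer than 3 retained pairs is unscorable
  rec5 <- rec[rec$patient_id == "P1" & rec$time_h <= 1, ]
  expect_error(suppressWarnings(buildTransitions(MediatorPanel(rec5),
                                                 grid = 0:1)), "3 retained")
})

test_that("the parent-set score is the BIC of the child-on-parents
           regression", {
  pan <- generateVar1Panel(10, 8, diag(3), 0.7, seed = 11)
  tr <- buildTransitions(pan, transform = "none")
  n <- nrow(tr@x0)
  # empty set: intercept-only regression, RSS = (n-1) * var(y)
  y <- tr@x1[, "V1"]
  expect_equal(scoreParentSet(tr, "V1", character()),
               -n / 2 * log((n - 1) * var(y) / n) - log(n),
               tolerance = 1e-12)

  # hand-built panel: C at time t+1 is exactly 2 * A at time t + 1, and D is
  # an affine copy of A (collinear with it in the parent slice)
  set.seed(11)
  base <- expand.grid(patient_id = paste0("P", 1:6), time_h = 0:4,
                      stringsAsFactors = FALSE)
  base$a <- rlnorm(nrow(base))
  key <- function(p, t) paste(p, t)
  aAt <- setNames(base$a, key(base$patient_id, base$time_h))
  mk <- function(med, val) data.frame(patient_id = base$patient_id,
                                      mediator = med, time_h = base$time_h,
                                      value_pg_ml = val,
                                      stringsAsFactors = FALSE)
  lagA <- ifelse(base$time_h == 0, rlnorm(nrow(base)),
                 2 * aAt[key(base$patient_id, base$time_h - 1)] + 1)
  rec <- rbind(mk("A", base$a), mk("B", rlnorm(nrow(base))),
               mk("C", unname(lagA)), mk("D", 2 * base$a + 3))
  tr2 <- buildTransitions(MediatorPanel(rec), grid = 0:4,
                          transform = "none")
  # zero-residual fit: the variance floor keeps the score finite; the true
  # parent still beats the empty set
  sExact <- scoreParentSet(tr2, "C", "A")
  expect_true(is.finite(sExact))
  expect_gt(sExact, scoreParentSet(tr2, "C", character()))

  # collinear parents fall back to a pseudo-inverse fit
  expect_warning(s <- scoreParentSet(tr2, "B", c("A", "D")), "collinear")
  expect_true(is.finite(s))

  # an unrelated candidate parent loses to the empty set at large n
  pan3 <- generateVar1Panel(50, 11, matrix(0, 2, 2), 0.5, seed = 12)
  tr3 <- buildTransitions(pan3, transform = "none")
  expect_equal(nrow(tr3@x0), 500)
  expect_gt(scoreParentSet(tr3, "V1", character()),
            scoreParentSet(tr3, "V1", "V2"))
})

test_that("exact enumeration matches the brute-force oracle", {
  for (seed in c(3, 4)) {
    A <- matrix(0, 4, 4)
    A[cbind(c(1, 2, 3), c(2, 3, 3))] <- 1
    pan <- generateVar1Panel(8, 6, A, 0.5, noiseSd = 1, seed = seed)
    tr <- buildTransitions(pan, transform = "none")
    m <- inferStructure(tr, fanIn = 2)
    o <- dybnOracle(tr, 2)
    expect_equal(edgeProbabilities(m), o$edgeProb, tolerance = 1e-8)
    expect_identical(bestParents(m), o$best)
    # per-child posteriors are proper: edge probabilities within [0, 1]
    expect_true(all(edgeProbabilities(m) >= 0 & edgeProbabilities(m) <= 1))
  }
})

test_that("self-dynamics are recovered as feedback and nulls stay sparse", {
  pan <- generateVar1Panel(30, 10, diag(4), 0.9, seed = 13)
  tr <- buildTransitions(pan, transform = "none")
  m <- inferStructure(tr, fanIn = 2)
  expect_identical(bestParents(m), list(V1 = "V1", V2 = "V2", V3 = "V3",
                                        V4 = "V4"))
  expect_setequal(feedbackNodes(m), c("V1", "V2", "V3", "V4"))
  expect_true(all(consensusEdges(m)$feedback))

  # pure noise: few edges pass the consensus cutoff
  pan0 <- generateVar1Panel(50, 11, matrix(0, 5, 5), 0.5, seed = 14)
  m0 <- inferStructure(buildTransitions(pan0, transform = "none"), fanIn = 2)
  expect_lte(nrow(consensusEdges(m0, 0.5)), 0.05 * 25)
})

test_that("score and structure are invariant to affine rescaling of a
           variable", {
  pan <- generateVar1Panel(12, 8, diag(3), 0.6, seed = 15)
  lf <- longFormat(pan)
  lf2 <- lf
  sel <- lf2$mediator == "V2"
  lf2$value_pg_ml[sel] <- 5 * lf2$value_pg_ml[sel] + 2
  tr1 <- buildTransitions(MediatorPanel(lf), transform = "none")
  tr2 <- buildTransitions(MediatorPanel(lf2), transform = "none")
  m1 <- inferStructure(tr1, fanIn = 2)
  m2 <- inferStructure(tr2, fanIn = 2)
  expect_equal(edgeProbabilities(m1), edgeProbabilities(m2),
               tolerance = 1e-9)
  expect_equal(scoreParentSet(tr1, "V1", "V2"),
               scoreParentSet(tr2, "V1", "V2"), tolerance = 1e-9)
})

test_that("central nodes rank by outgoing posterior mass", {
  # X drives all others: X must rank first
  V <- 5
  A <- matrix(0, V, V)
  A[, 1] <- 0.9  # every child listens to variable 1
  A[1, 1] <- 0.9
  pan <- generateVar1Panel(40, 10, A, 0.9, seed = 16)
  tr <- buildTransitions(pan, transform = "none")
  m <- inferStructure(tr, fanIn = 2)
  cn <- centralNodes(m)
  expect_equal(cn$variable[1], "V1")
  expect_true(all(diff(cn$score) <= 1e-12))
  # k larger than V returns V entries
  expect_equal(nrow(centralNodes(m, 99)), V)
  expect_equal(nrow(centralNodes(m, 2)), 2)

  # symmetric independent variables: outgoing mass is near-uniformly small
  pan0 <- generateVar1Panel(60, 11, matrix(0, 4, 4), 0.5, seed = 17)
  m0 <- inferStructure(buildTransitions(pan0, transform = "none"), fanIn = 2)
  cn0 <- centralNodes(m0)
  expect_lt(max(cn0$score) - min(cn0$score), 1)
})

test_that("fan-in is capped at the number of variables with a warning", {
  pan <- generateVar1Panel(10, 6, diag(2), 0.5, seed = 18)
  tr <- buildTransitions(pan, transform = "none")
  expect_warning(m <- inferStructure(tr, fanIn = 5), "capped")
  expect_equal(m@fanIn, 2L)
})
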