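makePanel <- function(df) MediatorPanel(df)

test_that("window assignment is half-open, averaging, and omits absent
           patients", {
  rec <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2"),
    mediator = "IL-6",
    time_h = c(1, 7, 8, 20),
    value_pg_ml = c(10, 20, 99, 5))
  pan <- makePanel(rec)
  w1 <- windowValues(pan, c(0, 8))
  expect_equal(unname(w1["P1", "IL-6"]), 15)  # mean of 10, 20; 8 h excluded
  expect_false("P2" %in% rownames(w1))
  w2 <- windowValues(pan, c(8, 16))
  expect_equal(unname(w2["P1", "IL-6"]), 99)  # t = 8 in [8, 16) only
  w3 <- windowValues(pan, c(16, 24))
  expect_false("P1" %in% rownames(w3))
  expect_equal(rownames(w3), "P2")
})

test_that("network edges follow the absolute-threshold rule with signed r", {
  set.seed(2)
  a <- rlnorm(8)
  vals <- cbind(A = a, B = 2 * a, C = max(a) * 1.1 - a, D = rlnorm(8))
  rownames(vals) <- paste0("P", 1:8)
  net <- buildNetwork(vals, threshold = 0.99, transform = "none")
  e <- edges(net)
  key <- paste(e$from, e$to)
  expect_true("A B" %in% key)
  expect_equal(e$r[key == "A B"], 1, tolerance = 1e-12)
  # on the default log scale a proportional pair is exactly linear too
  expect_equal(edges(buildNetwork(cbind(A = vals[, "A"],
                                        B = 2 * vals[, "A"]),
                                  threshold = 0.99, floor = 0))$r, 1,
               tolerance = 1e-12)
  # B = const - A is perfectly anticorrelated on the raw scale
  netRaw <- buildNetwork(vals, threshold = 0.99, transform = "none")
  eRaw <- edges(netRaw)
  expect_equal(eRaw$r[paste(eRaw$from, eRaw$to) == "A C"], -1,
               tolerance = 1e-12)
  # signed thresholding drops the negative edge
  netSigned <- buildNetwork(vals, threshold = 0.99, transform = "none",
                            absolute = FALSE)
  eS <- edges(netSigned)
  expect_false("A C" %in% paste(eS$from, eS$to))
  expect_true("A B" %in% paste(eS$from, eS$to))
})

test_that("networks agree with the all-pairs brute-force oracle", {
  set.seed(9)
  for (i in 1:10) {
    vals <- matrix(rlnorm(10 * 8), 10, 8,
                   dimnames = list(paste0("P", 1:10), paste0("M", 1:8)))
    vals[sample(length(vals), 8)] <- NA
    thr <- runif(1, 0.3, 0.9)
    net <- buildNetwork(vals, threshold = thr)
    o <- networkOracle(vals, thr)
    e <- edges(net)
    expect_equal(paste(e$from, e$to), paste(o$from, o$to))
    expect_equal(e$r, o$r, tolerance = 1e-12)
  }
})

test_that("constant mediators are skipped for edges but stay nodes", {
  vals <- cbind(A = c(1, 1, 1, 1), B = c(1, 2, 3, 4), C = c(2, 4, 6, 8))
  rownames(vals) <- paste0("P", 1:4)
  expect_message(net <- buildNetwork(vals, threshold = 0.5,
                                     transform = "none"), "constant")
  expect_equal(net@nodes, c("A", "B", "C"))
  e <- edges(net)
  expect_equal(paste(e$from, e$to), "B C")
})

test_that("density follows edge-count times nodes over possible edges", {
  expect_equal(networkDensity(0, N = 7), 0)
  expect_equal(networkDensity(6, N = 4), 4)  # complete graph: density = N
  expect_equal(networkDensity(4, N = 5), 2)
  expect_error(networkDensity(0, N = 1), "2 nodes")
  net <- buildNetwork(cbind(A = c(1, 2, 3), B = c(2, 4, 6)),
                      threshold = 0.7, group = "Day", window = c(0, 8))
  expect_equal(networkDensity(net), 2)  # 1 edge, 2 nodes: 1*2/1
})

test_that("density is non-increasing in the threshold", {
  set.seed(14)
  for (i in 1:10) {
    vals <- matrix(rlnorm(12 * 6), 12, 6,
                   dimnames = list(paste0("P", 1:12), paste0("M", 1:6)))
    dens <- vapply(c(0.2, 0.4, 0.6, 0.8, 1.0), function(thr)
      networkDensity(buildNetwork(vals, threshold = thr)), 1)
    expect_true(all(diff(dens) <= 1e-12))
  }
})

test_that("edge sets are invariant under mediator relabeling and patient
           reordering", {
  set.seed(15)
  vals <- matrix(rlnorm(10 * 5), 10, 5,
                 dimnames = list(paste0("P", 1:10), paste0("M", 1:5)))
  net <- buildNetwork(vals, threshold = 0.4)
  perm <- sample(10)
  net2 <- buildNetwork(vals[perm, ], threshold = 0.4)
  expect_equal(edges(net), edges(net2))
  # relabel mediators: edges map through the relabeling
  relabel <- setNames(paste0("X", 5:1), colnames(vals))
  vals3 <- vals; colnames(vals3) <- relabel[colnames(vals)]
  net3 <- buildNetwork(vals3, threshold = 0.4)
  e <- edges(net)
  mapped <- data.frame(from = pmin(relabel[e$from], relabel[e$to]),
                       to = pmax(relabel[e$from], relabel[e$to]),
                       r = e$r, stringsAsFactors = FALSE)
  mapped <- mapped[order(mapped$from, mapped$to), ]
  e3 <- edges(net3)[order(edges(net3)$from, edges(net3)$to), ]
  expect_equal(e3$r[match(paste(mapped$from, mapped$to),
                          paste(e3$from, e3$to))], mapped$r)
})

test_that("density traces are ordered, group-resolved, and degenerate
           sensibly", {
  sim <- generateCohort(syntheticConfig(seed = 41))
  tr <- densityTrace(sim$panel)
  expect_equal(nrow(tr), 6)
  expect_equal(tr$window_start, rep(c(0, 8, 16), 2))
  expect_true(all(tr$density >= 0))

  # threshold 1: no perfect correlations in noisy data
  tr1 <- densityTrace(sim$panel, threshold = 1)
  expect_true(all(tr1$n_edges == 0))
  expect_true(all(tr1$density == 0))

  # identical data in both groups: identical traces
  lf <- longFormat(sim$panel)
  lfD <- lf[lf$group == "Day", ]
  lfN <- lfD
  lfN$patient_id <- sub("^P", "Q", lfN$patient_id)
  lfN$group <- "Night"
  tr2 <- densityTrace(MediatorPanel(rbind(lfD, lfN)))
  expect_equal(tr2$density[tr2$group == "Day"],
               tr2$density[tr2$group == "Night"])
})

test_that("networks export to SIF and GraphML and round-trip through
           igraph", {
  vals <- cbind(A = c(1, 2, 3, 4), `NO2-/NO3-` = c(2, 4, 6, 8),
                C = c(5, 5.1, 4.9, 5))
  rownames(vals) <- paste0("P", 1:4)
  net <- buildNetwork(vals, threshold = 0.9, group = "Day", window = c(0, 8))
  sif <- tempfile(fileext = ".sif")
  gml <- tempfile(fileext = ".graphml")
  exportSIF(net, sif)
  exportGraphML(net, gml)
  lines <- readLines(sif)
  expect_true(any(grepl("NO2-/NO3-", lines, fixed = TRUE)))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_setequal(igraph::V(g)$name, net@nodes)
  expect_equal(igraph::ecount(g), nrow(edges(net)))
  expect_equal(sort(igraph::E(g)$r), sort(edges(net)$r), tolerance = 1e-6)
})
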