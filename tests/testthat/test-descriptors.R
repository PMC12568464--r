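test_that("edge weights are the degree product and sum", {
  expect_equal(edgeWeights(2, 3), list(wStar = 6, wPlus = 5))
  expect_equal(edgeWeights(1, 1), list(wStar = 1, wPlus = 2))
  expect_equal(edgeWeights(3, 6), list(wStar = 18, wPlus = 9))
  expect_error(edgeWeights(0, 2), "positive")
})

test_that("per-edge contributions match their definitions", {
  expect_equal(edgeContribution("GA", 2, 2), 1)
  expect_equal(edgeContribution("ABC", 3, 3), 2 / 3)
  expect_equal(edgeContribution("R", 2, 3), 6^-0.5)
  expect_equal(edgeContribution("ABC", 1, 1), 0)  # w+ - 2 = 0, allowed in sums
  expect_equal(edgeContribution("Ralpha", 2, 3, alpha = 2), 36)
  expect_error(edgeContribution("Ralpha", 2, 3), "alpha")
  expect_error(edgeContribution("M1", 2, 3, alpha = 1), "does not take")
  expect_error(descriptorSpec("wiener"), "unknown descriptor")
})

test_that("index sums over partitions reproduce hand-derived values", {
  expect_equal(indexFromPartition(kekulenePartition(1), "M1"), 312)
  expect_equal(indexFromPartition(sierpinskiPartition(1), "M2"), 1524)
  expect_equal(indexFromPartition(sierpinskiPartition(1), "HM"), 6366)
})

test_that("index sums over graphs match direct edge enumeration", {
  c6 <- ringGraph(6)
  expect_equal(indexFromGraph(c6, "M1"), 24)
  expect_equal(indexFromGraph(c6, "H"), 3)
  expect_equal(indexFromGraph(buildKekulene(), "M1"), 312)
  expect_error(indexFromGraph(igraph::make_empty_graph(0, directed = FALSE),
                              "M1"), "no edges")
})

test_that("graph-level and partition-level index routes agree for all descriptors", {
  alphas <- c(Ralpha = 0.7, CHIalpha = -1.3)
  for (seed in 1:20) {
    p <- randomPartition(seed)
    g <- realizePartition(p, seed = seed)$graph
    for (d in descriptorNames()) {
      a <- if (d %in% c("Ralpha", "CHIalpha")) alphas[[d]] else NULL
      expect_equal(indexFromGraph(g, d, alpha = a),
                   indexFromPartition(edgePartition(g), d, alpha = a),
                   tolerance = 1e-9, info = paste(d, "seed", seed))
    }
  }
})

test_that("specialization identities between descriptors hold", {
  for (seed in 21:30) {
    p <- randomPartition(seed)
    expect_equal(indexFromPartition(p, "R"),
                 indexFromPartition(p, "Ralpha", alpha = -0.5))
    expect_equal(indexFromPartition(p, "SCI"),
                 indexFromPartition(p, "CHIalpha", alpha = -0.5))
    expect_equal(indexFromPartition(p, "M1"),
                 indexFromPartition(p, "CHIalpha", alpha = 1))
    expect_equal(indexFromPartition(p, "HM"),
                 indexFromPartition(p, "CHIalpha", alpha = 2))
    expect_equal(indexFromPartition(p, "M2"),
                 indexFromPartition(p, "Ralpha", alpha = 1))
    expect_equal(indexFromPartition(p, "H"),
                 2 * indexFromPartition(p, "CHIalpha", alpha = -1))
  }
})

test_that("GA contributions respect the AM-GM bound and positivity", {
  for (seed in 31:40) {
    p <- randomPartition(seed)
    dp <- degreePairs(p)
    ga <- edgeContribution("GA", dp[, "dLo"], dp[, "dHi"])
    expect_true(all(ga <= 1 + 1e-12))
    expect_true(all(ga[dp[, "dLo"] == dp[, "dHi"]] == 1))
    expect_lte(indexFromPartition(p, "GA"), nEdges(p) + 1e-9)
    # all contributions positive except ABC on (1,1)
    for (d in setdiff(descriptorNames(), c("Ralpha", "CHIalpha"))) {
      j <- edgeContribution(d, dp[, "dLo"], dp[, "dHi"])
      ok <- j > 0 | (d == "ABC" & dp[, "dLo"] == 1 & dp[, "dHi"] == 1)
      expect_true(all(ok), info = d)
    }
  }
})
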