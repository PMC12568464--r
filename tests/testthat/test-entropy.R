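test_that("shannonEntropy matches closed-form values and validates input", {
  expect_equal(shannonEntropy(rep(1 / 4, 4), base = 2), 2)
  expect_equal(shannonEntropy(c(1, 0, 0), base = 10), 0)
  expect_equal(shannonEntropy(rep(1 / 6, 6)), log(6))
  expect_error(shannonEntropy(c(0.5, 0.6)), "sum to 1")
  expect_error(shannonEntropy(c(-0.1, 1.1)), "non-negative")
  expect_error(shannonEntropy(rep(1 / 4, 4), base = 1), "> 1")
})

test_that("index-weighted entropy reproduces published single values", {
  e <- entropyFromPartition(kekulenePartition(1), "M1")
  expect_equal(round(entropyValue(e), 4), 4.0876)
  expect_equal(indexTotal(e), 312)

  expect_equal(round(entropyValue(
    entropyFromPartition(sierpinskiPartition(1), "HM")), 4), 5.2198)

  ke <- buildKekulene()
  expect_equal(round(entropyValue(entropyFromGraph(ke, "HM")), 4), 4.0683)
  expect_equal(round(entropyValue(entropyFromGraph(ke, "GA")), 4), 4.0943)
})

test_that("single-class partitions attain the maximal entropy log|E|", {
  p <- EdgePartition(2, 2, 6)
  for (d in c("M1", "M2", "GA", "ABC", "H"))
    expect_equal(entropyValue(entropyFromPartition(p, d)), log(6))
  expect_equal(entropyValue(entropyFromGraph(ringGraph(6), "M2")), log(6))
  # complete graph K5 is regular: entropy log(10) for every descriptor
  k5 <- igraph::make_full_graph(5)
  expect_equal(entropyValue(entropyFromGraph(k5, "HM")), log(10))
})

test_that("entropy rejects non-positive contributions", {
  single <- igraph::graph_from_edgelist(cbind("a", "b"), directed = FALSE)
  expect_error(entropyFromGraph(single, "ABC"), "non-positive contributions")
  expect_error(entropyFromPartition(EdgePartition(c(1, 2), c(1, 2), c(1, 3)),
                                    "ABC"), "non-positive contributions")
  # but the same partition is fine for indices whose contributions stay positive
  expect_silent(entropyFromPartition(EdgePartition(c(1, 2), c(1, 2), c(1, 3)),
                                     "M1"))
})

test_that("index-weighted entropy equals Shannon entropy of normalised contributions", {
  alphas <- c(Ralpha = 0.5, CHIalpha = -1)
  for (seed in 41:60) {
    p <- randomPartition(seed)
    dp <- degreePairs(p)
    cnt <- edgeCounts(p)
    for (d in descriptorNames()) {
      a <- if (d %in% c("Ralpha", "CHIalpha")) alphas[[d]] else NULL
      j <- edgeContribution(d, dp[, "dLo"], dp[, "dHi"], alpha = a)
      if (any(j <= 0)) next
      probs <- rep(j, cnt) / sum(rep(j, cnt))
      expect_equal(entropyValue(entropyFromPartition(p, d, alpha = a)),
                   shannonEntropy(probs), tolerance = 1e-12,
                   info = paste(d, "seed", seed))
    }
  }
})

test_that("entropy is scale invariant in the contributions", {
  # H = 2 * chi(-1) and HM = chi(2)^... differ only by a constant factor per
  # edge, so their entropies coincide exactly
  for (seed in 61:70) {
    p <- randomPartition(seed)
    expect_equal(entropyValue(entropyFromPartition(p, "H")),
                 entropyValue(entropyFromPartition(p, "CHIalpha", alpha = -1)),
                 tolerance = 1e-12)
    expect_equal(entropyValue(entropyFromPartition(p, "HM")),
                 entropyValue(entropyFromPartition(p, "CHIalpha", alpha = 2)),
                 tolerance = 1e-12)
    expect_equal(entropyValue(entropyFromPartition(p, "R")),
                 entropyValue(entropyFromPartition(p, "Ralpha", alpha = -0.5)),
                 tolerance = 1e-12)
  }
})

test_that("entropy lies within [0, log |E|]", {
  for (seed in 71:85) {
    p <- randomPartition(seed)
    m <- nEdges(p)
    for (d in c("M1", "M2", "R", "HM", "SCI", "GA", "H")) {
      v <- entropyValue(entropyFromPartition(p, d))
      expect_gte(v, 0)
      expect_lte(v, log(m))
    }
  }
})
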