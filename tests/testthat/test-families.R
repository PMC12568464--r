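test_that("kekulene partition model evaluates to the expected counts", {
  expect_equal(edgeCounts(kekulenePartition(1)),
               c("2,2" = 6, "2,3" = 36, "3,3" = 18))
  expect_equal(edgeCounts(kekulenePartition(2)),
               c("2,2" = 24, "2,3" = 288, "3,3" = 216))
  expect_equal(edgeCounts(kekulenePartition(3)),
               c("2,2" = 192, "2,3" = 2304, "3,3" = 2592))
  expect_error(kekulenePartition(0), "n must be")
  expect_error(kekulenePartition(1.5), "n must be")
})

test_that("Sierpinski partition model evaluates to the expected counts", {
  expect_equal(edgeCounts(sierpinskiPartition(1)),
               c("1,3" = 6, "2,2" = 48, "2,3" = 84, "3,3" = 54, "3,6" = 18))
  expect_equal(nEdges(sierpinskiPartition(1)), 210)
  expect_equal(unname(edgeCounts(sierpinskiPartition(10))["2,2"]), 2649)
  expect_error(sierpinskiPartition(-1), "n must be")
})

test_that("family partitions are non-negative integers and realizable", {
  for (n in 1:20) {
    for (fam in list(kekulenePartition, sierpinskiPartition)) {
      cnt <- edgeCounts(fam(n))
      expect_true(all(cnt >= 0))
      expect_true(all(cnt == round(cnt)))
    }
  }
  for (n in 1:10) {
    expect_true(partitionRealizability(kekulenePartition(n))$feasible)
    expect_true(partitionRealizability(sierpinskiPartition(n))$feasible)
  }
})

test_that("closed-form index values match hand-evaluated theorem expressions", {
  expect_equal(as.numeric(closedFormIndex("SE", "M1", 1)), 1122)
  expect_equal(as.numeric(closedFormIndex("SE", "HM", 2)), 18544)
  expect_equal(as.numeric(closedFormIndex("KE", "HM", 1)), 1644)
  expect_error(closedFormIndex("XX", "M1", 1))
})

test_that("closed forms agree with partition sums except the Sierpinski harmonic erratum", {
  repKE <- verifyClosedForms("KE", 1:10)
  expect_equal(nrow(flaggedMismatches(repKE)), 0)
  expect_equal(nrow(comparisonTable(repKE)), 100)  # 10 descriptors x 10 stages

  repSE <- verifyClosedForms("SE", 1:10)
  bad <- flaggedMismatches(repSE)
  expect_true(all(bad$descriptor == "H"))
  expect_equal(nrow(bad), 10)
  h1 <- bad[bad$n == 1, ]
  expect_equal(h1$closedForm, 151.1)
  expect_equal(h1$partitionSum, 82.6)
  expect_equal(unique(bad$source), "printed-erratum")
})

test_that("entropy tables reproduce the published values within 0.002 on concordant cells", {
  # full-table reproduction (incl. the paper's few discordant cells) is
  # asserted in the acceptance suite; here a quick row-level sanity check
  tabKE <- referenceEntropyTable("KE", 2)
  expect_equal(round(tabKE$EM1[1], 4), 4.0876)
  expect_equal(round(tabKE$EM1[2], 4), 6.2634)
  tabSE <- referenceEntropyTable("SE", 1)
  expect_equal(round(tabSE$ESCI1[1], 4), 5.3413)
  expect_equal(round(tabSE$ERalpha[1], 4), 5.3210)
  tabSE10 <- familyEntropyTable("SE", 10, "H")
  expect_equal(round(tabSE10$H[10], 4), 9.2524)
})

test_that("kekulene entropy spacing approaches log 12 for large n", {
  tab <- familyEntropyTable("KE", 20, "M1")
  gaps <- diff(tab$M1)
  expect_lt(abs(gaps[19] - log(12)), 0.001)
  expect_true(all(diff(gaps) > 0))  # monotone approach from below
})
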