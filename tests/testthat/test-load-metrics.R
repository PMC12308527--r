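cls <- fitnessScheme("classical")
alt <- fitnessScheme("alternative")

test_that("inbreeding load follows B = sum(2 d p q) with class partitions", {
  # one symmetric OD locus at q = 1/2 contributes exactly s_o / 2
  pop <- singleLocusPop(nAA = 1, nAa = 2, naa = 1, class = 1L, s = 0.04, h = 0.04)
  B <- inbreedingLoad(pop, cls)
  expect_equal(unname(B["B_o"]), 0.02)
  expect_equal(unname(B["B"]), 0.02)

  # an additive deleterious locus contributes nothing at any frequency
  popAdd <- singleLocusPop(nAA = 5, nAa = 3, naa = 2, class = 0L, s = 0.3, h = 0.5)
  expect_equal(unname(inbreedingLoad(popAdd, cls)["B"]), 0)

  # 153 symmetric OD loci all at q = 1/2: B_o = 153 * 0.04 / 2 = 3.06
  n <- 4L
  reg <- data.frame(id = 1:153, class = 1L, s = 0.04, h = 0.04, pos = 0, birth = 0L)
  haps <- rep(list(integer(0)), 2L * n)
  for (j in 1:4) haps[[j]] <- 1:153 # 4 of 8 haplotypes carry every locus
  pop153 <- populationFromTables(reg, haps)
  expect_equal(unname(inbreedingLoad(pop153, cls)["B_o"]), 3.06)

  # class split at s = 0.9 and additivity of partitions
  set.seed(11)
  mix <- mergePops(
    hwPop(20, 30, q = 0.1, class = 0L, s = 0.2, h = 0.1),
    hwPop(20, 10, q = 0.02, class = 0L, s = 1, h = 0.02, idOffset = 1000L)
  )
  B2 <- inbreedingLoad(mix, cls)
  expect_equal(unname(B2["B"]), unname(B2["B_del"] + B2["B_let"] + B2["B_o"]))
  expect_gt(B2["B_let"], 0)
})

test_that("B is invariant to relabelling alleles at a symmetric OD locus", {
  popLow <- singleLocusPop(nAA = 6, nAa = 2, naa = 2, class = 1L, s = 0.1, h = 0.1)
  popFlip <- singleLocusPop(nAA = 2, nAa = 2, naa = 6, class = 1L, s = 0.1, h = 0.1)
  expect_equal(inbreedingLoad(popLow, cls), inbreedingLoad(popFlip, cls))
})

test_that("monomorphic registry rows contribute nothing to B, L or Wmax", {
  reg <- data.frame(
    id = 1:2, class = c(0L, 0L), s = c(0.5, 0.3), h = c(0.1, 0.1),
    pos = 0, birth = 0L
  )
  # locus 2 lost: only locus 1 segregates
  withLost <- populationFromTables(reg, list(1L, integer(0), integer(0), integer(0)))
  onlySeg <- populationFromTables(reg[1, ], list(1L, integer(0), integer(0), integer(0)))
  expect_equal(inbreedingLoad(withLost, cls), inbreedingLoad(onlySeg, cls))
  expect_equal(maxFitness(withLost, cls), maxFitness(onlySeg, cls))
  expect_equal(meanFitness(withLost, cls), meanFitness(onlySeg, cls))
})

test_that("maximum attainable fitness follows the fixed-load accounting", {
  pop <- newPopulation(4)
  expect_equal(maxFitness(pop, cls), 1)

  # fixed deleterious load 0.9 and two classical OD loci out of polymorphism
  pop2 <- pop
  pop2@wFixDel <- 0.9
  pop2@odFixFactor <- 0.96^2
  pop2@nOFixed <- 2L
  expect_equal(maxFitness(pop2, cls), 0.9 * 0.96^2) # 0.82944

  # alternative viability model: capped at one
  popAlt <- singleLocusPop(nAA = 2, nAa = 1, naa = 1, class = 1L, s = 0.04, h = 0.04)
  expect_equal(maxFitness(popAlt, alt), 1)
  # and uncapped for fecundity
  altFec <- fitnessScheme("alternative", "fecundity")
  expect_equal(maxFitness(popAlt, altFec), 1.04)
})

test_that("expressed load is the proportional gap to the best genotype", {
  expect_equal(expressedLoad(1, 1), 0)
  expect_equal(expressedLoad(0.05, 1), 0.95)
  expect_equal(expressedLoad(0.69, 1), 0.31)
  expect_error(expressedLoad(0.5, 0), "Wmax")
})

test_that("every individual's fitness stays at or below Wmax", {
  set.seed(12)
  for (scheme in list(cls, alt)) {
    res <- evolve(newPopulation(40), 80,
      scheme = scheme,
      dfe = dfeConfig(UO = 0.02, UN = 0), trackFixed = TRUE
    )
    expect_lte(max(res$W), maxFitness(res$population, scheme) + 1e-12)
  }
})

test_that("the marker-based inbreeding estimator evaluates the quadratic form", {
  expect_equal(yangInbreeding(1, p = 0.5), -1)
  expect_equal(yangInbreeding(2, p = 0.5), 1)
  # Hardy-Weinberg sample: expectation zero
  set.seed(13)
  p <- runif(400, 0.05, 0.5)
  x <- vapply(p, function(pk) stats::rbinom(500, 2, pk), integer(500))
  fhat <- yangInbreeding(x, p)
  expect_lt(abs(mean(fhat)), 3 * stats::sd(fhat) / sqrt(length(fhat)) + 0.01)
  expect_error(yangInbreeding(c(1, 1), p = c(0.5, 0)), "monomorphic")
  expect_error(yangInbreeding(matrix(1, 2, 1), p = c(0.4, 0.2)), "per locus")
})

test_that("depression statistics invert the exponential load model", {
  expect_equal(depressionStats(1, 1)@delta, 0)
  r <- depressionStats(WO = 1, WS = exp(-0.5), FHatS = 0.5, FHatO = 0)
  expect_equal(r@delta, 0.5)
  expect_equal(r@deltaStar, 1.0)
  expect_error(depressionStats(0, 1), "positive")
  expect_warning(
    rr <- depressionStats(1, 0.9, FHatS = 0.1, FHatO = 0.2),
    "undefined"
  )
  expect_true(is.na(rr@deltaStar))
  expect_equal(rr@delta, log(1 / 0.9))
})

test_that("the rate of inbreeding depression recovers a known load", {
  # population with known B from partially recessive deleterious loci plus
  # neutral markers; delta* from one selfing assay should estimate B and
  # the selfed mean should match W_o exp(-B/2)
  set.seed(14)
  n <- 80
  sel <- hwPop(n, 120, q = 0.15, class = 0L, s = 0.05, h = 0.05)
  mrk <- hwPop(n, 300, q = runif(300, 0.1, 0.5), class = 2L, idOffset = 5000L)
  pop <- mergePops(sel, mrk)
  Btrue <- unname(inbreedingLoad(pop, cls)["B"])
  expect_gt(Btrue, 0.3)
  assay <- selfingAssay(pop, cls,
    nPairs = 400, progenyPerSelf = 8,
    progenyPerPair = 1
  )
  expect_lt(abs(assay@FHatS - assay@FHatO - 0.5), 0.06)
  expect_lt(abs(assay@deltaStar - Btrue) / Btrue, 0.2)
  predicted <- predictedInbredFitness(assay@WO, Btrue, 0.5)
  expect_lt(abs(assay@WS - predicted) / predicted, 0.05)
})

test_that("load summary rows carry the bottleneck-table quantities", {
  # three deleterious loci at q = 0.1, 0.2, 0.3
  n <- 5L
  reg <- data.frame(
    id = 1:3, class = 0L, s = 0.1, h = 0.2, pos = 0, birth = 0L
  )
  haps <- rep(list(integer(0)), 10)
  haps[[1]] <- 1L
  haps[[2]] <- 2L
  haps[[3]] <- c(2L, 3L)
  haps[[4]] <- 3L
  haps[[5]] <- 3L
  pop <- populationFromTables(reg, haps)
  row <- loadSummaryRow(pop, cls, W0 = NA)
  expect_equal(row$n_del, 3)
  expect_equal(row$q_del, 0.2)
  expect_true(is.na(row$dW_pct))
  rowW <- loadSummaryRow(pop, cls, W0 = row$W)
  expect_equal(rowW$dW_pct, 0)
})
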