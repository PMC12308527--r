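test_that("selfing equilibrium formulas evaluate correctly", {
  expect_equal(equilibriumF(c(0, 0.5, 1)), c(0, 1 / 3, 1))
  expect_error(equilibriumF(1.2), "S must")
  # F_s = (1 + F) / 2 = 1 / (2 - S)
  S <- seq(0, 1, by = 0.25)
  expect_equal((1 + equilibriumF(S)) / 2, 1 / (2 - S))

  expect_equal(expectedSelfedDepression(2, 0), 1)
  expect_equal(expectedSelfedDepression(2, 1), 2)
  expect_equal(expectedSelfedDepression(0, 0.3), 0)

  expect_equal(predictedInbredFitness(0.8, 1.5, 0), 0.8)
  expect_equal(predictedInbredFitness(1, 0.4, 1), exp(-0.4))
  # log-linearity in F with slope -B
  f <- c(0.2, 0.5, 0.9)
  lw <- log(predictedInbredFitness(0.7, 1.3, f))
  expect_equal(diff(lw) / diff(f), rep(-1.3, 2))

  expect_equal(expectedBo(0, 0.04), 0)
  expect_equal(expectedBo(153, 0.04), 3.06)
  expect_equal(expectedBo(1, 0.2), 0.1)
})

test_that("the asymmetric-overdominance stability condition is F < sA/sa", {
  expect_true(asymPolymorphismStable(0, 0.02, 0.04))
  expect_false(asymPolymorphismStable(0.6, 0.02, 0.04))
  expect_true(asymPolymorphismStable(0.4, 0.02, 0.04))
  expect_error(asymPolymorphismStable(0.5, 0.04, 0.02), "sA < sa")
})

test_that("the exact chain gives neutral fixation probability 1/(2N)", {
  ch <- singleLocusChain(10, s = 0, h = 0)
  st <- which(ch$states[, "nAa"] == 1 & ch$states[, "naa"] == 0)
  expect_equal(ch$fixProb[st], 1 / 20, tolerance = 1e-9)
  # absorption probabilities are complementary
  expect_equal(ch$fixProb + ch$lossProb, rep(1, nrow(ch$states)), tolerance = 1e-9)
  # fixation probability equals the starting allele frequency everywhere
  q0 <- (ch$states[, "nAa"] + 2 * ch$states[, "naa"]) / 20
  expect_equal(ch$fixProb, q0, tolerance = 1e-8)
})

test_that("balancing selection lengthens sojourn relative to neutrality", {
  neu <- singleLocusChain(8, s = 0, h = 0)
  od <- singleLocusChain(8, sHomWild = 0.3, sHomMut = 0.3)
  st <- which(neu$states[, "nAa"] == 8) # all heterozygotes
  expect_gt(od$meanTime[st], neu$meanTime[st])
})

test_that("a recessive lethal under full selfing loses polymorphism rapidly", {
  ch <- singleLocusChain(6, s = 1, h = 0, S = 1)
  st <- which(ch$states[, "nAa"] == 6)
  # distribute 10 generations forward from the all-het state
  v <- numeric(nrow(ch$states))
  v[st] <- 1
  for (k in 1:10) v <- as.vector(v %*% ch$transition)
  absorbing <- ch$states[, "nAa"] == 0 &
    (ch$states[, "nAA"] == 0 | ch$states[, "naa"] == 0)
  expect_gt(sum(v[absorbing]), 0.9)
  # and the lethal allele cannot fix under viability selection
  expect_lt(ch$fixProb[st], 1e-12)
})

test_that("the deterministic recursion matches classical equilibria", {
  # symmetry keeps q at 1/2 for any selfing rate below one
  for (S in c(0, 0.5, 0.9)) {
    r <- selfingRecursion(sHomWild = 0.1, sHomMut = 0.1, S = S, q0 = 0.5)
    expect_equal(r$q, 0.5, tolerance = 1e-9)
  }
  # panmictic asymmetric overdominance: q* = sA / (sA + sa)
  r0 <- selfingRecursion(sHomWild = 0.02, sHomMut = 0.04, S = 0, q0 = 0.3)
  expect_equal(r0$q, 0.02 / 0.06, tolerance = 1e-6)
  # neutral locus: equilibrium F = S / (2 - S), q unchanged
  rn <- selfingRecursion(s = 0, h = 0, S = 0.5, q0 = 0.3)
  expect_equal(rn$F, equilibriumF(0.5), tolerance = 1e-9)
  expect_equal(rn$q, 0.3, tolerance = 1e-9)
})

test_that("the recursion reproduces the asymmetric stability boundary", {
  # sA/sa = 0.5 <=> F = 0.5 <=> S = 2/3
  below <- selfingRecursion(sHomWild = 0.02, sHomMut = 0.04, S = 0.55, q0 = 0.4)
  above <- selfingRecursion(sHomWild = 0.02, sHomMut = 0.04, S = 0.8, q0 = 0.4)
  expect_true(below$q > 0.01 && below$q < 0.99)
  expect_true(above$q < 1e-4 || above$q > 1 - 1e-4)
  expect_true(asymPolymorphismStable(equilibriumF(0.55), 0.02, 0.04))
  expect_false(asymPolymorphismStable(equilibriumF(0.8), 0.02, 0.04))
})

test_that("engine fixation probabilities match the exact chain", {
  # (a) effectively neutral mutation, one copy in N = 10
  chNeu <- singleLocusChain(10, s = 0, h = 0)
  stNeu <- which(chNeu$states[, "nAa"] == 1 & chNeu$states[, "naa"] == 0)
  set.seed(15)
  popNeu <- singleLocusPop(nAA = 9, nAa = 1, naa = 0, class = 0L, s = 1e-9, h = 0.5)
  fixNeu <- replicate(4000, {
    runToAbsorption(popNeu, fitnessScheme(), maxGens = 600)$pop@wFixDel < 1
  })
  seN <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(mean(fixNeu) - chNeu$fixProb[stNeu]), 3 * seN)

  # (b) partially recessive deleterious mutation, two het copies in N = 8
  chDel <- singleLocusChain(8, s = 0.25, h = 0.2)
  stDel <- which(chDel$states[, "nAa"] == 2 & chDel$states[, "naa"] == 0)
  popDel <- singleLocusPop(nAA = 6, nAa = 2, naa = 0, class = 0L, s = 0.25, h = 0.2)
  fixDel <- replicate(4000, {
    runToAbsorption(popDel, fitnessScheme(), maxGens = 800)$pop@wFixDel < 1
  })
  pD <- chDel$fixProb[stDel]
  expect_lt(abs(mean(fixDel) - pD), 3 * sqrt(pD * (1 - pD) / 4000))

  # (c) asymmetric classical overdominance from q = 1/4 in N = 8; the
  # surviving homozygote identifies fixation vs loss via odFixFactor
  chOd <- singleLocusChain(8, sHomWild = 0.25, sHomMut = 0.15)
  stOd <- which(chOd$states[, "nAa"] == 4 & chOd$states[, "naa"] == 0)
  popOd <- singleLocusPop(nAA = 4, nAa = 4, naa = 0, class = 1L, s = 0.25, h = 0.15)
  outOd <- replicate(3000, {
    p <- runToAbsorption(popOd, fitnessScheme("classical"), maxGens = 2000)$pop
    stopifnot(p@nOFixed == 1L)
    isTRUE(all.equal(p@odFixFactor, 1 - 0.15)) # mutant homozygote survived
  })
  pO <- chOd$fixProb[stOd]
  expect_lt(abs(mean(outOd) - pO), 3 * sqrt(pO * (1 - pO) / 3000))

  # mean sojourn of the deleterious case within Monte-Carlo error
  set.seed(16)
  tau <- replicate(2000, runToAbsorption(popDel, fitnessScheme(), maxGens = 800)$t)
  expect_lt(
    abs(mean(tau) - chDel$meanTime[stDel]),
    3 * stats::sd(tau) / sqrt(length(tau))
  )
})
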