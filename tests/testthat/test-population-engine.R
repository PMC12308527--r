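noMut <- dfeConfig(U = 0, ULet = 0, UO = 0, UN = 0)
neutralScheme <- fitnessScheme("none", "viability")

test_that("homozygous sites always transmit; heterozygous sites segregate 1:1", {
  set.seed(1)
  popHom <- singleLocusPop(nAA = 0, nAa = 0, naa = 4)
  g <- replicate(200, makeGamete(popHom, 1))
  expect_true(all(vapply(g, identical, TRUE, y = 1L)))

  popHet <- singleLocusPop(nAA = 3, nAa = 1, naa = 0)
  het <- which(vapply(1:4, genotypeOf, 0L, pop = popHet, id = 1L) == 1L)
  carry <- replicate(1e4, length(makeGamete(popHet, het)) == 1L)
  se <- sqrt(0.25 / 1e4)
  expect_lt(abs(mean(carry) - 0.5), 3 * se)
})

test_that("map-based meiosis recombines at the Haldane frequency", {
  # individual in coupling phase at two loci 0.5 Morgans apart:
  # recombinant gametes carry exactly one id, expected frequency (1 - e^-1)/2
  reg <- data.frame(
    id = 1:2, class = 2L, s = 0, h = 0, pos = c(0.25, 0.75), birth = 0L
  )
  haps <- list(c(1L, 2L), integer(0))
  pop <- populationFromTables(reg, haps)
  map <- recombinationMap("mapped", totalLength = 20)
  set.seed(2)
  nG <- 4e4
  rec <- replicate(nG, length(makeGamete(pop, 1, map)) == 1L)
  expected <- (1 - exp(-2 * 0.5)) / 2
  se <- sqrt(expected * (1 - expected) / nG)
  expect_lt(abs(mean(rec) - expected), 3 * se)
})

test_that("with all mutation rates zero a clonal population never changes", {
  set.seed(3)
  pop <- hwPop(20, 5, q = 0.4, class = 2L)
  res <- evolve(pop, 10, scheme = neutralScheme, dfe = noMut)
  expect_identical(
    sort(res$population@registry$id),
    sort(pop@registry$id[pop@registry$count > 0])
  )
  expect_true(all(res$W == 1))
})

test_that("multiplicative fitness matches the engine's cached values", {
  # no mutations -> fitness one
  expect_equal(individualFitness(newPopulation(3), 1), 1)
  # one classical OD heterozygote and one deleterious heterozygote -> 0.98
  reg <- data.frame(
    id = 1:2, class = c(1L, 0L), s = c(0.04, 0.1), h = c(0.04, 0.2),
    pos = c(0.1, 0.2), birth = 0L
  )
  pop <- populationFromTables(reg, list(c(1L, 2L), integer(0), 1L, 1L))
  cls <- fitnessScheme("classical")
  expect_equal(individualFitness(pop, 1, cls), 1 * 0.98)
  # individual 2 is homozygous at the OD locus: factor 1 - sM
  expect_equal(individualFitness(pop, 2, cls), 0.96)

  # wild-type homozygote at 153 segregating classical OD loci
  nL <- 153L
  reg2 <- data.frame(
    id = 1:nL, class = 1L, s = 0.04, h = 0.04, pos = 0.5, birth = 0L
  )
  hap <- rep(list(integer(0)), 4)
  hap[[1]] <- 1:nL # one carrier keeps every locus segregating
  pop2 <- populationFromTables(reg2, hap)
  expect_equal(individualFitness(pop2, 2, cls), 0.96^153, tolerance = 1e-10)

  # R reference vs C++ cache on an evolved population
  set.seed(4)
  res <- evolve(newPopulation(40), 60,
    scheme = cls,
    dfe = dfeConfig(UO = 0.01, UN = 0.1)
  )
  wr <- vapply(1:40, function(i) individualFitness(res$population, i, cls), 0)
  expect_equal(wr, res$W, tolerance = 1e-12)
})

test_that("registry copy counts equal the haplotype tally every generation", {
  set.seed(5)
  res <- evolve(newPopulation(30), 50, dfe = dfeConfig(UO = 0.02, UN = 0.3),
    scheme = fitnessScheme("classical")
  )
  expect_identical(
    recountedRegistry(res$population)$count,
    res$population@registry$count
  )
  expect_true(all(res$population@registry$count >= 1L &
    res$population@registry$count <= 59L))
})

test_that("neutral heterozygosity decays like (1 - 1/(2n))^t", {
  set.seed(6)
  n <- 50
  t <- 10
  reps <- 200
  H <- replicate(reps, {
    pop <- hwPop(n, 20, q = 0.5, class = 2L)
    out <- evolve(pop, t, scheme = neutralScheme, dfe = noMut)
    p <- out$population
    mean(vapply(seq_len(n), function(i) {
      a <- p@haplotypes[[2L * i - 1L]]
      b <- p@haplotypes[[2L * i]]
      (length(setdiff(a, b)) + length(setdiff(b, a))) / 20
    }, 0))
  })
  expected <- 0.5 * (1 - 1 / (2 * n))^t
  se <- stats::sd(H) / sqrt(reps)
  expect_lt(abs(mean(H) - expected), 3 * se + 0.005)
})

test_that("full selfing makes a heterozygous site homozygous at rate 1/2", {
  set.seed(7)
  pop <- singleLocusPop(nAA = 0, nAa = 1, naa = 0)
  stillHet <- replicate(2000, {
    out <- evolve(pop, 1, S = 1, scheme = neutralScheme, dfe = noMut)
    genotypeOf(out$population, 1, 1L) == 1L
  })
  se <- sqrt(0.25 / 2000)
  expect_lt(abs(mean(stillHet) - 0.5), 3 * se)
})

test_that("viability rejection never accepts a homozygous lethal", {
  set.seed(8)
  pop <- singleLocusPop(nAA = 1, nAa = 1, naa = 0, class = 0L, s = 1, h = 0)
  for (r in 1:200) {
    out <- evolve(pop, 1, scheme = fitnessScheme(), dfe = noMut)
    g <- vapply(1:2, genotypeOf, 0L, pop = out$population, id = 1L)
    expect_true(all(g < 2L))
  }
})

test_that("selectively neutral allele frequency is a martingale", {
  # a dominance-type mutation with s = 1e-9 is selectively invisible but,
  # with fixed-load tracking on, leaves wFixDel < 1 on fixation, so fixed
  # and lost runs can be told apart after the registry is pruned
  set.seed(9)
  n <- 30
  pop <- singleLocusPop(nAA = 15, nAa = 12, naa = 3, class = 0L, s = 1e-9, h = 0.5)
  q0 <- sum(pop@registry$count) / (2 * n)
  qf <- replicate(600, {
    out <- evolve(pop, 10,
      scheme = neutralScheme, dfe = noMut,
      trackFixed = TRUE
    )
    reg <- out$population@registry
    if (nrow(reg)) reg$count / (2 * n) else as.numeric(out$population@wFixDel < 1)
  })
  se <- stats::sd(qf) / sqrt(length(qf))
  expect_lt(abs(mean(qf) - q0), 3 * se)
})

test_that("strong symmetric overdominance holds a large population near q = 1/2", {
  set.seed(10)
  pop <- singleLocusPop(
    nAA = 50, nAa = 100, naa = 50, class = 1L,
    s = 0.2, h = 0.2
  )
  out <- evolve(pop, 300, scheme = fitnessScheme("classical"), dfe = noMut)
  reg <- out$population@registry
  expect_equal(nrow(reg), 1L) # still polymorphic
  q <- reg$count / 400
  expect_gt(q, 0.3)
  expect_lt(q, 0.7)
})

test_that("an extinct population is flagged, not silently continued", {
  # every individual homozygous lethal: zero fitness cohort
  pop <- singleLocusPop(nAA = 0, nAa = 0, naa = 5, class = 0L, s = 1, h = 0)
  out <- evolve(pop, 5, scheme = fitnessScheme(), dfe = noMut)
  expect_identical(out$population@status, "extinct")
  expect_error(
    evolve(out$population, 1, scheme = fitnessScheme(), dfe = noMut),
    "extinct"
  )
})

test_that("haplotypes referencing unknown mutation ids are rejected", {
  reg <- data.frame(id = 1L, class = 2L, s = 0, h = 0, pos = 0, birth = 0L)
  expect_error(
    populationFromTables(reg, list(c(1L, 99L), integer(0))),
    "missing from the registry"
  )
})
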