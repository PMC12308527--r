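cls <- fitnessScheme("classical")

tinyCfg <- function(...) {
  runConfig(
    nBase = 60, burninGens = 40, sampleSize = 20, lineGens = 20,
    nReplicates = 2, reportInterval = 10, baseSeed = 77,
    dfe = dfeConfig(UN = 0.2), ...
  )
}

test_that("a burn-in without selective mutations carries no load", {
  cfg <- runConfig(
    nBase = 40, burninGens = 30, nReplicates = 1, reportInterval = 5,
    sampleSize = 10,
    dfe = dfeConfig(U = 0, ULet = 0, UO = 0, UN = 0.5)
  )
  out <- runBurnin(cfg, seed = 1)
  expect_true(all(out$trajectory$B == 0))
  expect_true(all(out$trajectory$W == 1))
  expect_true(all(out$trajectory$Wmax == 1))
})

test_that("sampling the whole population preserves every frequency", {
  set.seed(17)
  base <- evolve(newPopulation(30), 30, dfe = dfeConfig(UN = 0.3))$population
  smp <- foundSample(base, 30)
  a <- base@registry[order(base@registry$id), c("id", "count")]
  b <- smp@registry[order(smp@registry$id), c("id", "count")]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  expect_equal(smp@generation, 0L)
})

test_that("founder sampling is frequency-unbiased (hypergeometric mean)", {
  set.seed(18)
  base <- singleLocusPop(nAA = 60, nAa = 0, naa = 40) # q = 0.4 in n = 100
  qhat <- replicate(400, {
    smp <- foundSample(base, 10)
    # monomorphic samples are nearly always losses here (P(fixed) ~ 1e-4)
    if (nrow(smp@registry)) smp@registry$count / 20 else 0
  })
  se <- stats::sd(qhat) / sqrt(length(qhat))
  expect_lt(abs(mean(qhat) - 0.4), 3 * se)
})

test_that("overdominant loci without founder polymorphism are dropped cleanly", {
  # base where one OD locus is fixed (count = 2n) and one segregates
  reg <- data.frame(
    id = 1:2, class = 1L, s = 0.04, h = 0.04, pos = 0, birth = 0L
  )
  n <- 6L
  haps <- rep(list(1L), 2L * n) # locus 1 fixed everywhere
  haps[[1]] <- c(1L, 2L) # locus 2 in one copy
  base <- populationFromTables(reg, haps)
  smp <- foundSample(base, n, cls)
  expect_false(1L %in% smp@registry$id)
  expect_equal(smp@odFixFactor, 1) # no W_max penalty from the base-fixed locus
  expect_equal(smp@nOFixed, 0L)
  expect_equal(smp@wFixDel, 1)
  # a dominance-type mutation fixed in the sample folds into wFixDel instead
  regD <- data.frame(id = 1L, class = 0L, s = 0.2, h = 0.1, pos = 0, birth = 0L)
  baseD <- populationFromTables(regD, rep(list(1L), 8))
  smpD <- foundSample(baseD, 4, cls)
  expect_equal(smpD@wFixDel, 0.8)
  expect_equal(nrow(smpD@registry), 0L)
})

test_that("a clonal mutation-free population shows no inbreeding depression", {
  pop <- newPopulation(10)
  set.seed(19)
  r <- selfingAssay(pop, cls, nPairs = 10)
  expect_equal(r@delta, 0)
  expect_true(is.na(r@deltaStar)) # no neutral markers segregate
})

test_that("private heterozygous lethals depress selfed but not outbred progeny", {
  set.seed(20)
  pop <- privateHetPop(40, perInd = 1L, class = 0L, s = 1, h = 0)
  r <- selfingAssay(pop, cls, nPairs = 200, progenyPerSelf = 50)
  expect_equal(r@WO, 1) # unrelated parents carry different lethals
  expect_lt(abs(r@WS - 0.75), 3 * sqrt(0.75 * 0.25 / 2000))
  expect_gte(r@delta, log(1 / 0.78))
})

test_that("identical seeds reproduce identical experiment outputs", {
  cfg <- tinyCfg()
  a <- runBurnin(cfg, seed = 5)
  b <- runBurnin(cfg, seed = 5)
  expect_identical(a$trajectory, b$trajectory)
  expect_identical(a$population@registry, b$population@registry)
  r1 <- runBottleneckLines(tinyCfg(sharedBase = TRUE))
  r2 <- runBottleneckLines(tinyCfg(sharedBase = TRUE))
  expect_identical(r1$summary, r2$summary)
})

test_that("orchestrator standard errors equal sd/sqrt(replicates)", {
  cfg <- tinyCfg()
  cfg@nReplicates <- 4L
  res <- runReplicates(cfg, "burnin")
  reps <- res$replicates
  expect_equal(
    unname(unlist(res$summary[paste0("se_", "B")])),
    stats::sd(reps$B) / sqrt(nrow(reps))
  )
  expect_equal(unname(unlist(res$summary["W"])), mean(reps$W))
})

test_that("full selfing eliminates overdominant polymorphism", {
  set.seed(21)
  pop <- hwPop(50, 30, q = 0.5, sW = 0.04, sM = 0.04)
  out <- evolve(pop, 120,
    S = 1, scheme = cls,
    dfe = dfeConfig(U = 0, ULet = 0, UO = 0, UN = 0), trackFixed = TRUE
  )
  expect_equal(sum(out$population@registry$class == 1L), 0L)
  bo <- out$trajectory$B_o
  expect_equal(bo[length(bo)], 0)
  expect_gt(bo[1], 0.2)
})

test_that("bottleneck lines purge recessive load faster than drift alone", {
  set.seed(22)
  base <- hwPop(400, 60, q = 0.05, class = 0L, s = 0.8, h = 0)
  B50 <- replicate(10, {
    line <- foundSample(base, 50, cls)
    out <- evolve(line, 50,
      scheme = cls,
      dfe = dfeConfig(U = 0, ULet = 0, UO = 0, UN = 0), trackFixed = TRUE
    )
    tr <- out$trajectory
    # lines absorbed before generation 50 carry no load from then on
    c(tr$B[1], if (any(tr$t == 50)) tr$B[tr$t == 50] else 0)
  })
  drift <- mean(B50[1, ]) * (1 - 1 / 100)^50
  expect_lt(mean(B50[2, ]), drift)
})

test_that("inbreeding load declines with the selfing rate (dominance model)", {
  cfg <- runConfig(
    nBase = 120, burninGens = 350, sampleSize = 30, nReplicates = 2,
    reportInterval = 350, baseSeed = 30, assayPairs = 30,
    dfe = dfeConfig(UN = 0.3)
  )
  sweep <- selfingSweep(cfg, S = c(0, 0.5, 1))
  expect_lt(stats::cor(sweep$S, sweep$B), 0)
  expect_lt(sweep$B[3], 0.6 * sweep$B[1])
  expect_equal(sweep$E_delta[1], sweep$B[1] / 2) # F = 0 at S = 0
})

test_that("manifest round-trips reproduce outputs bit-identically", {
  dir1 <- file.path(tempdir(), "run1")
  dir2 <- file.path(tempdir(), "run2")
  unlink(c(dir1, dir2), recursive = TRUE)
  cfg <- tinyCfg()
  res1 <- runReplicates(cfg, "burnin", outDir = dir1)
  cfg2 <- manifestConfig(file.path(dir1, "burnin_manifest.json"))
  res2 <- runReplicates(cfg2, "burnin", outDir = dir2)
  for (f in c("burnin.tsv", "burnin_full.tsv")) {
    expect_identical(
      readLines(file.path(dir1, f)),
      readLines(file.path(dir2, f))
    )
  }
})
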