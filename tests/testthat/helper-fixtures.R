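# Fixture builders: tiny populations with exactly known genotypes.

# Population of n individuals with a single locus at given genotype counts.
# class: 0 dominance-type, 1 overdominant, 2 neutral (registry codes).
singleLocusPop <- function(nAA, nAa, naa, class = 2L, s = 0, h = 0, id = 1L) {
  n <- nAA + nAa + naa
  haps <- vector("list", 2L * n)
  g <- rep(c(0L, 1L, 2L), c(nAA, nAa, naa))
  for (i in seq_len(n)) {
    haps[[2L * i - 1L]] <- if (g[i] >= 1L) id else integer(0)
    haps[[2L * i]] <- if (g[i] == 2L) id else integer(0)
  }
  reg <- data.frame(
    id = id, class = as.integer(class), s = s, h = h, pos = 0.5, birth = 0L
  )
  populationFromTables(reg, haps)
}

# n individuals, each heterozygous at `perInd` private loci of one class.
privateHetPop <- function(n, perInd = 1L, class = 0L, s = 1, h = 0) {
  nl <- n * perInd
  reg <- data.frame(
    id = seq_len(nl), class = as.integer(class), s = s, h = h,
    pos = runif(nl), birth = 0L
  )
  haps <- rep(list(integer(0)), 2L * n)
  for (i in seq_len(n)) {
    haps[[2L * i - 1L]] <- as.integer((i - 1L) * perInd + seq_len(perInd))
  }
  populationFromTables(reg, haps)
}

# Population with `nLoci` independent loci at Hardy-Weinberg proportions
# (genotypes sampled with the current RNG); q can be scalar or per-locus.
hwPop <- function(n, nLoci, q, class = 0L, s = 0, h = 0,
                  sW = NULL, sM = NULL, idOffset = 0L) {
  q <- rep(q, length.out = nLoci)
  if (!is.null(sW)) { # overdominant parameterisation
    s <- rep(sW, length.out = nLoci)
    h <- rep(if (is.null(sM)) sW else sM, length.out = nLoci)
    class <- 1L
  } else {
    s <- rep(s, length.out = nLoci)
    h <- rep(h, length.out = nLoci)
  }
  reg <- data.frame(
    id = idOffset + seq_len(nLoci), class = as.integer(class), s = s, h = h,
    pos = runif(nLoci), birth = 0L
  )
  haps <- rep(list(integer(0)), 2L * n)
  for (k in seq_len(nLoci)) {
    carried <- runif(2L * n) < q[k]
    for (j in which(carried)) haps[[j]] <- c(haps[[j]], reg$id[k])
  }
  populationFromTables(reg, haps)
}

# merge two populations' loci into one population (same n)
mergePops <- function(a, b) {
  stopifnot(a@n == b@n)
  reg <- rbind(
    a@registry[, c("id", "class", "s", "h", "pos", "birth")],
    b@registry[, c("id", "class", "s", "h", "pos", "birth")]
  )
  haps <- mapply(function(x, y) c(x, y), a@haplotypes, b@haplotypes,
    SIMPLIFY = FALSE
  )
  populationFromTables(reg, haps)
}

# genotype (0/1/2 copies) of individual i at mutation id
genotypeOf <- function(pop, i, id) {
  sum(id %in% pop@haplotypes[[2L * i - 1L]], id %in% pop@haplotypes[[2L * i]])
}

# Run a single-mutation population to absorption with mutation switched off.
# Fixation and loss are told apart through the fixed-load accumulators
# (dominance-type: wFixDel = 1 - s on fixation, 1 on loss; classical OD with
# sW != sM: odFixFactor = 1 - sM on fixation, 1 - sW on loss).  Returns the
# absorbed population and the absorption generation.
runToAbsorption <- function(pop, scheme, maxGens = 5000) {
  dfe0 <- dfeConfig(U = 0, ULet = 0, UO = 0, UN = 0)
  res <- evolve(pop, maxGens,
    scheme = scheme, dfe = dfe0, reportEvery = 1L,
    trackFixed = TRUE
  )
  p <- res$population
  tr <- res$trajectory
  gone <- which(tr$n_del + tr$n_let + tr$n_o == 0)
  list(
    absorbed = nrow(p@registry) == 0,
    t = if (length(gone)) tr$t[gone[1]] else NA_real_,
    pop = p
  )
}
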