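#' @include AllClasses.R mutation-model.R
NULL

#' Evolve a population forward in time
#'
#' Runs the Wright-Fisher life cycle for `generations` generations: each of
#' the `n` offspring is produced by selfing with probability `S` (one parent)
#' or by two distinct parents otherwise.  Under the viability trait parents
#' are drawn uniformly and candidate offspring are accepted by rejection
#' sampling proportional to their viability (against the running cohort
#' maximum; only relative viabilities affect survivor composition at fixed
#' `n`).  Under the fecundity trait parents are drawn with probability
#' proportional to their fecundity and offspring are accepted
#' unconditionally.  Gametes recombine (free or mapped), then receive new
#' mutations at the configured rates.  Mutations reaching count 0 or `2 n`
#' are pruned the same generation; when `trackFixed = TRUE` fixed
#' dominance-type mutations are folded into `wFixDel` and overdominant loci
#' leaving polymorphism into `odFixFactor` / `nOFixed`.
#'
#' All randomness is drawn from R's RNG: call `set.seed()` beforehand for a
#' reproducible run.
#'
#' @param pop a [WFPopulation-class].
#' @param generations number of generations to run.
#' @param scheme a [FitnessScheme-class].
#' @param dfe a [DFEConfig-class].
#' @param S selfing rate in `[0, 1]`.
#' @param map a [RecombinationMap-class].
#' @param reportEvery log a trajectory row every this many generations (the
#'   final generation is always logged).
#' @param trackFixed accumulate fixed load (use `TRUE` for bottleneck lines
#'   after [foundSample()], `FALSE` during burn-in, where load fixed before
#'   line foundation is excluded from reported fitness).
#' @param keepInitialRow include the starting state as the first trajectory
#'   row.
#'
#' @return list with `population` (the evolved [WFPopulation-class]),
#'   `trajectory` (data.frame of per-generation summaries: `t`, `W`, `Wmax`,
#'   `L`, `B`, `B_del`, `B_let`, `B_o`, `n_del`, `q_del`, `n_let`, `q_let`,
#'   `n_o`, `q_o`, `n_o_fixed`, `w_fix_del`, `od_fix_factor`) and `W`
#'   (final-generation individual fitnesses).
#' @examples
#' set.seed(1)
#' res <- evolve(newPopulation(30), 20, dfe = dfeConfig(UN = 0))
#' tail(res$trajectory, 2)
#' @export
evolve <- function(pop, generations, scheme = fitnessScheme(),
                   dfe = dfeConfig(), S = 0, map = recombinationMap(),
                   reportEvery = 1L, trackFixed = FALSE,
                   keepInitialRow = TRUE) {
  stopifnot(is(pop, "WFPopulation"))
  if (S < 0 || S > 1) stop("S must lie in [0, 1]")
  if (pop@n < 2 && S < 1) stop("need n >= 2 unless S = 1")
  if (pop@status != "ok") stop("population is not in an evolvable state: ", pop@status)
  cfg <- .engineConfig(scheme, dfe, map, S = S, trackFixed = trackFixed)
  out <- .cpp_evolve(
    pop@haplotypes, pop@registry, pop@nextId, pop@n, pop@generation,
    as.integer(generations), cfg, pop@wFixDel, pop@odFixFactor, pop@nOFixed,
    as.integer(reportEvery), isTRUE(keepInitialRow)
  )
  newPop <- new("WFPopulation",
    n = pop@n, generation = as.integer(out$generation),
    haplotypes = out$haplotypes, registry = out$registry,
    nextId = as.integer(out$nextId), wFixDel = out$wFixDel,
    odFixFactor = out$odFixFactor, nOFixed = as.integer(out$nOFixed),
    status = out$status
  )
  traj <- as.data.frame(out$trajectory)
  list(population = newPop, trajectory = traj, W = out$W)
}

#' Draw one gamete from an individual
#'
#' Meiosis only (no new mutations).  Under free recombination every
#' heterozygous site transmits independently with probability 1/2 and
#' homozygous sites always transmit; under a genetic map, crossover counts
#' are Poisson with mean equal to the map length in Morgans, breakpoints are
#' uniform and the starting haplotype is chosen at random.
#'
#' @param pop a [WFPopulation-class].
#' @param individual individual index in `1..n`.
#' @param map a [RecombinationMap-class].
#' @return sorted integer vector of transmitted mutation ids.
#' @export
makeGamete <- function(pop, individual, map = recombinationMap()) {
  stopifnot(is(pop, "WFPopulation"), is(map, "RecombinationMap"))
  i <- as.integer(individual)
  if (i < 1 || i > pop@n) stop("individual out of range")
  a <- pop@haplotypes[[2L * i - 1L]]
  b <- pop@haplotypes[[2L * i]]
  reg <- pop@registry
  posOf <- function(ids) reg$pos[match(ids, reg$id)]
  .cpp_gamete(
    a, b, posOf(a), posOf(b),
    if (map@mode == "free") 0L else 1L, map@totalLength
  )
}

## R reference implementation of multiplicative fitness; the engine caches
## the same quantity in C++.  Kept in R so tests can cross-check the engine.
.individualFitnessR <- function(pop, scheme, i, reg = pop@registry,
                                odBase = NULL) {
  a <- pop@haplotypes[[2L * i - 1L]]
  b <- pop@haplotypes[[2L * i]]
  hom <- intersect(a, b)
  het <- c(setdiff(a, b), setdiff(b, a))
  alt <- scheme@odModel == "alternative"
  if (is.null(odBase)) {
    odBase <- if (alt) 1 else prod(1 - reg$s[reg$class == .CLS_OD])
  }
  w <- pop@wFixDel * pop@odFixFactor * odBase
  if (length(hom)) {
    k <- match(hom, reg$id)
    f <- rep(1, length(k))
    dom <- reg$class[k] == .CLS_DOM
    od <- reg$class[k] == .CLS_OD
    f[dom] <- 1 - reg$s[k[dom]]
    f[od] <- if (alt) 1 else (1 - reg$h[k[od]]) / (1 - reg$s[k[od]])
    w <- w * prod(f)
  }
  if (length(het)) {
    k <- match(het, reg$id)
    f <- rep(1, length(k))
    dom <- reg$class[k] == .CLS_DOM
    od <- reg$class[k] == .CLS_OD
    f[dom] <- 1 - reg$s[k[dom]] * reg$h[k[dom]]
    f[od] <- if (alt) 1 + reg$s[k[od]] else 1 / (1 - reg$s[k[od]])
    w <- w * prod(f)
  }
  if (scheme@capAtOne) min(w, 1) else w
}

#' Multiplicative fitness of one individual
#'
#' Product over all segregating selective loci of the genotype fitness
#' factor, times the fixed-load accumulators, capped at one for viability.
#' Under the classical overdominance model an individual carrying zero
#' copies at a segregating overdominant locus still contributes the factor
#' `1 - sHomWild`: the locus penalises every wild-type homozygote once the
#' mutation has arisen.
#'
#' @param pop a [WFPopulation-class].
#' @param individual index in `1..n`.
#' @param scheme a [FitnessScheme-class].
#' @return a positive scalar.
#' @export
individualFitness <- function(pop, individual, scheme = fitnessScheme()) {
  stopifnot(is(pop, "WFPopulation"), is(scheme, "FitnessScheme"))
  i <- as.integer(individual)
  if (i < 1 || i > pop@n) stop("individual out of range")
  ids <- c(pop@haplotypes[[2L * i - 1L]], pop@haplotypes[[2L * i]])
  if (length(ids) && !all(ids %in% pop@registry$id)) {
    stop("internal consistency error: haplotype refers to unknown mutation id")
  }
  .individualFitnessR(pop, scheme, i)
}

#' Mean fitness of a population
#'
#' @param pop a [WFPopulation-class].
#' @param scheme a [FitnessScheme-class].
#' @return mean over individuals of [individualFitness()].
#' @export
meanFitness <- function(pop, scheme = fitnessScheme()) {
  stopifnot(is(pop, "WFPopulation"))
  reg <- pop@registry
  odBase <- if (scheme@odModel == "alternative") {
    1
  } else {
    prod(1 - reg$s[reg$class == .CLS_OD])
  }
  mean(vapply(
    seq_len(pop@n),
    function(i) .individualFitnessR(pop, scheme, i, reg, odBase), 0
  ))
}

#' Recount mutation copy numbers from the haplotypes
#'
#' Returns the registry with `count` recomputed; used by tests to verify
#' copy-count conservation.
#'
#' @param pop a [WFPopulation-class].
#' @return the registry data.frame with a fresh `count` column.
#' @export
recountedRegistry <- function(pop) {
  stopifnot(is(pop, "WFPopulation"))
  reg <- pop@registry
  ids <- unlist(pop@haplotypes, use.names = FALSE)
  reg$count <- as.integer(table(factor(ids, levels = reg$id)))
  reg
}
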