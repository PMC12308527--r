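#' @include AllClasses.R
NULL

#' Inbreeding load B of a population
#'
#' `B = sum(2 d p q)` over all segregating selective loci, in lethal
#' equivalents, partitioned into the deleterious (`s < 0.9`), lethal
#' (`s >= 0.9`) and overdominant classes.  The dominance deviation `d` is
#' `s (1/2 - h)` for dominance-type loci, `(sHomWild + sHomMut) / 2` for
#' classical overdominance (`s_o` in the symmetric case, so one locus at
#' `q = 1/2` contributes `s_o / 2`) and `s_o / (1 + s_o)` for the
#' alternative model.  Fixed and lost loci contribute nothing.
#'
#' @param pop a [WFPopulation-class].
#' @param scheme a [FitnessScheme-class].
#' @return named numeric vector with elements `B`, `B_del`, `B_let`, `B_o`.
#' @examples
#' reg <- data.frame(id = 1L, class = 1L, s = 0.04, h = 0.04)
#' haps <- c(rep(list(1L), 2), rep(list(integer(0)), 2)) # one locus at q = 1/2
#' pop <- populationFromTables(reg, haps)
#' inbreedingLoad(pop, fitnessScheme("classical"))["B_o"] # 0.02 = s_o / 2
#' @export
inbreedingLoad <- function(pop, scheme = fitnessScheme()) {
  stopifnot(is(pop, "WFPopulation"), is(scheme, "FitnessScheme"))
  reg <- pop@registry
  twoN <- 2 * pop@n
  seg <- reg$count > 0L & reg$count < twoN
  q <- reg$count / twoN
  p <- 1 - q
  alt <- scheme@odModel == "alternative"
  d <- numeric(nrow(reg))
  dom <- reg$class == .CLS_DOM
  od <- reg$class == .CLS_OD
  d[dom] <- reg$s[dom] * (0.5 - reg$h[dom])
  d[od] <- if (alt) reg$s[od] / (1 + reg$s[od]) else (reg$s[od] + reg$h[od]) / 2
  contrib <- ifelse(seg, 2 * d * p * q, 0)
  c(
    B = sum(contrib[dom | od]),
    B_del = sum(contrib[dom & reg$s < 0.9]),
    B_let = sum(contrib[dom & reg$s >= 0.9]),
    B_o = sum(contrib[od])
  )
}

#' Maximum attainable fitness W_max
#'
#' Fitness of the best genotype constructible from the alleles currently
#' present.  Classical overdominance: `wFixDel * odFixFactor`, i.e. the fixed
#' deleterious load times the product of `1 - s_hom` of the surviving allele
#' over overdominant loci that lost polymorphism (the best genotype is
#' heterozygous at every segregating overdominant locus and wild-type
#' elsewhere).  Alternative model: `wFixDel * prod(1 + s_o)` over segregating
#' overdominant loci, capped at one for viability.  Dominance-only:
#' `wFixDel`.
#'
#' @param pop a [WFPopulation-class].
#' @param scheme a [FitnessScheme-class].
#' @return a positive scalar.
#' @export
maxFitness <- function(pop, scheme = fitnessScheme()) {
  stopifnot(is(pop, "WFPopulation"), is(scheme, "FitnessScheme"))
  reg <- pop@registry
  if (scheme@odModel == "alternative") {
    seg <- reg$class == .CLS_OD & reg$count > 0L & reg$count < 2L * pop@n
    w <- pop@wFixDel * prod(1 + reg$s[seg])
  } else {
    w <- pop@wFixDel * pop@odFixFactor
  }
  if (scheme@capAtOne) min(w, 1) else w
}

#' Expressed (genetic) load
#'
#' `L = (W_max - W) / W_max`: the proportional reduction of mean fitness
#' below the best attainable genotype.
#'
#' @param W mean fitness.
#' @param Wmax maximum attainable fitness (> 0).
#' @return the expressed load.
#' @examples
#' expressedLoad(0.69, 1) # 0.31
#' @export
expressedLoad <- function(W, Wmax) {
  if (any(Wmax <= 0)) stop("Wmax must be > 0")
  (Wmax - W) / Wmax
}

#' Marker-based inbreeding coefficient (SNP estimator)
#'
#' For each individual, the mean over loci of
#' `(x^2 - (1 + 2 p) x + 2 p^2) / (2 p (1 - p))`, where `x` is the number of
#' minor alleles carried (0, 1 or 2) and `p` the minor-allele frequency in
#' the reference sample.  The estimator has expectation 0 under
#' Hardy-Weinberg proportions and 1 for fully inbred individuals.
#'
#' @param x matrix of minor-allele counts (individuals x loci), or a vector
#'   for a single individual.
#' @param p vector of minor-allele frequencies, one per locus, all in (0, 1);
#'   monomorphic loci must be filtered out beforehand.
#' @return numeric vector of per-individual estimates.
#' @examples
#' yangInbreeding(matrix(c(1, 2), 2, 1), p = 0.5) # -1 and +1
#' @export
yangInbreeding <- function(x, p) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != length(p)) stop("one allele frequency per locus is required")
  if (length(p) < 1) stop("at least one locus is required")
  if (any(p <= 0 | p >= 1)) {
    stop("monomorphic loci (p = 0 or 1) must be filtered out before estimation")
  }
  if (any(!x %in% 0:2)) stop("x must contain minor-allele counts 0, 1 or 2")
  fmat <- matrix(0, nrow(x), ncol(x))
  for (k in seq_along(p)) {
    pk <- p[k]
    fmat[, k] <- (x[, k]^2 - (1 + 2 * pk) * x[, k] + 2 * pk^2) /
      (2 * pk * (1 - pk))
  }
  rowMeans(fmat)
}

#' Inbreeding depression statistics of a selfing assay
#'
#' `delta = log(WO / WS)` and its rate `delta* = delta / (FHatS - FHatO)`,
#' the marker-based estimate of the inbreeding load B.
#'
#' @param WO,WS mean fitness of outbred and selfed progeny (both > 0).
#' @param FHatS,FHatO mean marker-based inbreeding of selfed and outbred
#'   progeny; when `FHatS <= FHatO` the rate is undefined and returned as
#'   `NA` (with a warning), while `delta` is still computed.
#' @return a [SelfingAssayResult-class].
#' @examples
#' depressionStats(WO = 1, WS = exp(-0.5), FHatS = 0.5, FHatO = 0) # delta* = 1
#' @export
depressionStats <- function(WO, WS, FHatS = NA_real_, FHatO = NA_real_) {
  if (!is.finite(WO) || !is.finite(WS) || WO <= 0 || WS <= 0) {
    stop("mean fitnesses must be positive to compute log depression")
  }
  delta <- log(WO / WS)
  deltaStar <- NA_real_
  if (is.finite(FHatS) && is.finite(FHatO)) {
    if (FHatS > FHatO) {
      deltaStar <- delta / (FHatS - FHatO)
    } else {
      warning("FHatS <= FHatO: rate of inbreeding depression is undefined")
    }
  }
  new("SelfingAssayResult",
    WO = WO, WS = WS, delta = delta, deltaStar = deltaStar,
    FHatS = as.numeric(FHatS), FHatO = as.numeric(FHatO)
  )
}

#' One summary row of load statistics
#'
#' Computes the per-generation record used throughout the bottleneck-line
#' tables: segregating counts and mean mutant frequencies by class, the
#' partitioned inbreeding load, mean and maximum fitness, expressed load and
#' the proportional fitness decline relative to a baseline `W0`.
#'
#' @param pop a [WFPopulation-class].
#' @param scheme a [FitnessScheme-class].
#' @param W0 mean fitness at line foundation (baseline for `dW_pct`); `NA`
#'   gives `dW_pct = NA`.
#' @return a one-row data.frame with columns `t`, `n_del`, `q_del`, `B_del`,
#'   `n_let`, `q_let`, `B_let`, `n_o`, `q_o`, `B_o`, `dW_pct` plus `W`,
#'   `Wmax`, `L` and `B`.
#' @export
loadSummaryRow <- function(pop, scheme = fitnessScheme(), W0 = NA_real_) {
  stopifnot(is(pop, "WFPopulation"))
  reg <- pop@registry
  twoN <- 2 * pop@n
  seg <- reg$count > 0L & reg$count < twoN
  q <- reg$count / twoN
  del <- seg & reg$class == .CLS_DOM & reg$s < 0.9
  let <- seg & reg$class == .CLS_DOM & reg$s >= 0.9
  od <- seg & reg$class == .CLS_OD
  B <- inbreedingLoad(pop, scheme)
  W <- meanFitness(pop, scheme)
  Wmax <- maxFitness(pop, scheme)
  data.frame(
    t = pop@generation,
    n_del = sum(del), q_del = if (any(del)) mean(q[del]) else NA_real_,
    B_del = unname(B["B_del"]),
    n_let = sum(let), q_let = if (any(let)) mean(q[let]) else NA_real_,
    B_let = unname(B["B_let"]),
    n_o = sum(od), q_o = if (any(od)) mean(q[od]) else NA_real_,
    B_o = unname(B["B_o"]),
    dW_pct = if (is.na(W0)) NA_real_ else 100 * (W0 - W) / W0,
    W = W, Wmax = Wmax, L = expressedLoad(W, Wmax), B = unname(B["B"])
  )
}
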