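#' @include AllClasses.R
NULL

#' Equilibrium inbreeding coefficient under partial selfing
#'
#' `F = S / (2 - S)` for an infinite population with selfing rate `S`.
#'
#' @param S selfing rate(s) in `[0, 1]`.
#' @return equilibrium inbreeding coefficient(s).
#' @examples
#' equilibriumF(c(0, 0.5, 1)) # 0, 1/3, 1
#' @export
equilibriumF <- function(S) {
  if (any(S < 0 | S > 1)) stop("S must lie in [0, 1]")
  S / (2 - S)
}

#' Expected inbreeding depression of selfed progeny
#'
#' `delta = (B / 2)(1 + F) = B / (2 - S)`: in a panmictic population the
#' expectation is `B / 2`, rising to `B` under full selfing.
#'
#' @param B inbreeding load (>= 0).
#' @param S selfing rate in `[0, 1]`.
#' @return expected `delta`.
#' @export
expectedSelfedDepression <- function(B, S) {
  if (any(B < 0)) stop("B must be >= 0")
  if (any(S < 0 | S > 1)) stop("S must lie in [0, 1]")
  B / (2 - S)
}

#' Predicted fitness of inbred individuals
#'
#' Purging-free prediction `W_i = W_o * exp(-B * F_i)`: fitness declines
#' exponentially in the inbreeding coefficient at rate B.
#'
#' @param WO outbred mean fitness (> 0).
#' @param B inbreeding load.
#' @param FI inbreeding coefficient(s) in `[0, 1]`.
#' @return predicted inbred fitness.
#' @examples
#' predictedInbredFitness(1, 0.4, 1) # exp(-0.4)
#' @export
predictedInbredFitness <- function(WO, B, FI) {
  if (any(WO <= 0)) stop("WO must be > 0")
  if (any(FI < 0 | FI > 1)) stop("FI must lie in [0, 1]")
  WO * exp(-B * FI)
}

#' Expected overdominant inbreeding load
#'
#' For `nO` symmetric overdominant loci of equal effect `sO`,
#' `B_o = nO * sO / 2` (each locus contributes at most `sO / 2`, attained at
#' `q = 1/2`).
#'
#' @param nO number of segregating overdominant loci (>= 0).
#' @param sO homozygote disadvantage.
#' @return expected `B_o`.
#' @examples
#' expectedBo(153, 0.04) # 3.06
#' @export
expectedBo <- function(nO, sO) {
  if (any(nO < 0)) stop("nO must be >= 0")
  nO * sO / 2
}

#' Stability of an asymmetric overdominant polymorphism under inbreeding
#'
#' With homozygote disadvantages `sA < sa`, the polymorphism is stable iff
#' the population inbreeding coefficient satisfies `F < sA / sa`.
#'
#' @param F inbreeding coefficient in `[0, 1]`.
#' @param sA smaller homozygote disadvantage.
#' @param sa larger homozygote disadvantage (must exceed `sA`).
#' @return logical.
#' @examples
#' asymPolymorphismStable(0.4, 0.02, 0.04) # TRUE
#' @export
asymPolymorphismStable <- function(F, sA, sa) {
  if (any(sA <= 0) || any(sA >= sa)) stop("need 0 < sA < sa")
  if (any(F < 0 | F > 1)) stop("F must lie in [0, 1]")
  F < sA / sa
}

## genotype fitness triple (wAA, wAa, waa) from scheme-like inputs
.fitnessTriple <- function(s = NULL, h = NULL, sHomWild = NULL,
                           sHomMut = NULL, alternative = FALSE) {
  if (!is.null(s) && is.null(sHomWild)) {
    c(1, 1 - s * h, 1 - s)
  } else if (alternative) {
    c(1, 1 + sHomWild, 1)
  } else {
    c(1 - sHomWild, 1, 1 - sHomMut)
  }
}

## Offspring genotype distribution for one generation of the life cycle used
## by the engine, given parental genotype counts (nAA, nAa, naa) out of N.
## viability: parents uniform (selfed parent uniform; outcross pair without
## replacement), offspring genotype probabilities reweighted by viability.
## fecundity: parents weighted by fitness, offspring unweighted.
.offspringDist <- function(cnt, w, S, trait) {
  N <- sum(cnt)
  g <- cnt / N
  pw <- if (trait == "fecundity") {
    if (sum(cnt * w) <= 0) {
      return(NULL) # extinction
    }
    cnt * w / sum(cnt * w)
  } else {
    g
  }
  ## Mendelian tables: offspring distribution of each mating type
  selfTab <- rbind(
    AA = c(1, 0, 0),
    Aa = c(0.25, 0.5, 0.25),
    aa = c(0, 0, 1)
  )
  gam <- c(AA = 1, Aa = 0.5, aa = 0) # P(transmit A)
  off <- numeric(3)
  if (S > 0) off <- off + S * colSums(pw * selfTab)
  if (S < 1) {
    ## two distinct parents; under fecundity weighting use the
    ## without-replacement analogue of the uniform case
    for (i in 1:3) {
      for (j in 1:3) {
        pij <- if (trait == "fecundity") {
          if (i == j) pw[i] * (cnt[i] - 1) * w[i] / max(sum(cnt * w) - w[i], .Machine$double.xmin)
          else pw[i] * cnt[j] * w[j] / max(sum(cnt * w) - w[i], .Machine$double.xmin)
        } else {
          if (i == j) g[i] * (cnt[i] - 1) / (N - 1) else g[i] * cnt[j] / (N - 1)
        }
        if (pij <= 0) next
        pA1 <- gam[i]
        pA2 <- gam[j]
        off <- off + (1 - S) * pij * c(
          pA1 * pA2,
          pA1 * (1 - pA2) + (1 - pA1) * pA2,
          (1 - pA1) * (1 - pA2)
        )
      }
    }
  }
  if (trait == "viability") {
    off <- off * w
    if (sum(off) <= 0) {
      return(NULL)
    }
    off <- off / sum(off)
  }
  off
}

#' Exact single-locus Markov chain for small populations
#'
#' Enumerates all genotype-count states `(nAA, nAa, naa)` of a population of
#' `N` diploids at one locus and builds the exact transition matrix of the
#' reproduction scheme used by the simulation engine (partial selfing,
#' viability or fecundity selection, multinomial offspring sampling).
#' Absorption probabilities into the two monomorphic states and expected
#' absorption times are obtained by linear solves, providing a brute-force
#' reference for the stochastic engine.
#'
#' @param N number of diploids (kept small; the state space has
#'   `(N+1)(N+2)/2` states and `N > 30` is refused).
#' @param s,h dominance-type fitness parameters, or
#' @param sHomWild,sHomMut overdominant homozygote disadvantages
#'   (`alternative = TRUE` selects the 1, 1+s, 1 parameterisation).
#' @param alternative logical, see above.
#' @param S selfing rate.
#' @param trait `"viability"` or `"fecundity"`.
#' @return list with `states` (matrix of genotype counts), `fixProb`
#'   (probability that the mutant allele `a` fixes, per starting state),
#'   `lossProb`, `meanTime` (expected generations to absorption) and
#'   `transition` (the full transition matrix).
#' @examples
#' ch <- singleLocusChain(10, s = 0, h = 0)
#' # one mutant copy: neutral fixation probability 1 / (2N)
#' st <- which(ch$states[, "nAa"] == 1 & ch$states[, "naa"] == 0)
#' ch$fixProb[st] # 0.05
#' @export
singleLocusChain <- function(N, s = NULL, h = NULL, sHomWild = NULL,
                             sHomMut = sHomWild, alternative = FALSE,
                             S = 0, trait = c("viability", "fecundity")) {
  trait <- match.arg(trait)
  if (N > 30) stop("state space too large; use N <= 30 for the exact chain")
  w <- .fitnessTriple(s, h, sHomWild, sHomMut, alternative)
  if (trait == "viability") w <- pmin(w, 1)
  ## enumerate states
  states <- do.call(rbind, lapply(0:N, function(nAA) {
    do.call(rbind, lapply(0:(N - nAA), function(nAa) {
      c(nAA = nAA, nAa = nAa, naa = N - nAA - nAa)
    }))
  }))
  ns <- nrow(states)
  key <- function(cnt) paste(cnt[1], cnt[2], sep = "/")
  idx <- structure(seq_len(ns), names = apply(states, 1, function(x) key(x)))
  lfact <- lgamma(seq_len(N + 1)) # lgamma(k + 1) = lfact[k + 1]
  P <- matrix(0, ns, ns)
  absorbing <- logical(ns)
  for (r in seq_len(ns)) {
    cnt <- states[r, ]
    if (cnt[2] == 0 && (cnt[1] == 0 || cnt[3] == 0)) {
      absorbing[r] <- TRUE
      P[r, r] <- 1
      next
    }
    off <- .offspringDist(cnt, w, S, trait)
    if (is.null(off)) { # extinction: treated as absorbing in-place
      absorbing[r] <- TRUE
      P[r, r] <- 1
      next
    }
    lg <- log(pmax(off, .Machine$double.xmin))
    for (c2 in seq_len(ns)) {
      k <- states[c2, ]
      if (off[1] <= 0 && k[1] > 0) next
      if (off[2] <= 0 && k[2] > 0) next
      if (off[3] <= 0 && k[3] > 0) next
      lp <- lfact[N + 1] - lfact[k[1] + 1] - lfact[k[2] + 1] - lfact[k[3] + 1] +
        k[1] * lg[1] + k[2] * lg[2] + k[3] * lg[3]
      P[r, c2] <- exp(lp)
    }
    P[r, ] <- P[r, ] / sum(P[r, ])
  }
  fixedState <- idx[[key(c(0, 0))]] # all aa
  lostState <- idx[[key(c(N, 0))]] # all AA
  trans <- which(!absorbing)
  Q <- P[trans, trans, drop = FALSE]
  I <- diag(length(trans))
  fix <- loss <- tau <- numeric(ns)
  fix[fixedState] <- 1
  loss[lostState] <- 1
  if (length(trans)) {
    Ninv <- solve(I - Q)
    fix[trans] <- Ninv %*% P[trans, fixedState, drop = FALSE]
    loss[trans] <- Ninv %*% P[trans, lostState, drop = FALSE]
    tau[trans] <- Ninv %*% rep(1, length(trans))
  }
  list(
    states = states, fixProb = fix, lossProb = loss, meanTime = tau,
    transition = P
  )
}

#' Deterministic single-locus recursion under partial selfing
#'
#' Iterates the exact infinite-population genotype-frequency recursion
#' (mating with selfing rate `S`, then selection on the offspring for the
#' viability trait, or fecundity-weighted parents for the fecundity trait)
#' until the change per generation falls below `tol`.
#'
#' @param s,h,sHomWild,sHomMut,alternative fitness parameters as in
#'   [singleLocusChain()].
#' @param S selfing rate.
#' @param q0 initial mutant-allele frequency (initial genotypes at
#'   Hardy-Weinberg proportions).
#' @param trait `"viability"` or `"fecundity"`.
#' @param tol convergence tolerance on genotype frequencies.
#' @param maxit iteration cap (error when exceeded).
#' @return list with `genotypes` (equilibrium frequencies), `q` (mutant
#'   frequency), `F` (fixation index `1 - het / (2 p q)`, `NA` when
#'   monomorphic) and `iterations`.
#' @examples
#' # panmictic asymmetric overdominance: q* = sA / (sA + sa)
#' selfingRecursion(sHomWild = 0.02, sHomMut = 0.04, S = 0, q0 = 0.3)$q
#' @export
selfingRecursion <- function(s = NULL, h = NULL, sHomWild = NULL,
                             sHomMut = sHomWild, alternative = FALSE,
                             S = 0, q0 = 0.5,
                             trait = c("viability", "fecundity"),
                             tol = 1e-12, maxit = 1e6) {
  trait <- match.arg(trait)
  w <- .fitnessTriple(s, h, sHomWild, sHomMut, alternative)
  if (trait == "viability") w <- pmin(w, 1)
  g <- c((1 - q0)^2, 2 * q0 * (1 - q0), q0^2)
  selfTab <- rbind(c(1, 0, 0), c(0.25, 0.5, 0.25), c(0, 0, 1))
  it <- 0
  repeat {
    it <- it + 1
    parents <- if (trait == "fecundity") {
      gw <- g * w
      if (sum(gw) <= 0) stop("population fitness collapsed to zero")
      gw / sum(gw)
    } else {
      g
    }
    q <- parents[2] / 2 + parents[3]
    outcross <- c((1 - q)^2, 2 * q * (1 - q), q^2)
    off <- S * colSums(parents * selfTab) + (1 - S) * outcross
    if (trait == "viability") {
      off <- off * w
      if (sum(off) <= 0) stop("population fitness collapsed to zero")
      off <- off / sum(off)
    }
    if (max(abs(off - g)) < tol) {
      g <- off
      break
    }
    g <- off
    if (it >= maxit) stop("recursion failed to converge within maxit iterations")
  }
  q <- g[2] / 2 + g[3]
  Fhat <- if (q <= 0 || q >= 1) NA_real_ else 1 - g[2] / (2 * q * (1 - q))
  list(genotypes = g, q = q, F = Fhat, iterations = it)
}
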