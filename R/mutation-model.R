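#' @include AllClasses.R
NULL

## Shared translation of S4 configuration into the flat list the C++ engine
## reads.  "none" behaves exactly like "classical" when no overdominant
## mutations exist; it is mapped onto the classical code path.
.engineConfig <- function(scheme, dfe, map = recombinationMap(), S = 0,
                          trackFixed = FALSE, maxTries = 5e7) {
  validObject(scheme)
  validObject(dfe)
  validObject(map)
  if (scheme@odModel == "none" && dfe@UO > 0) {
    stop("dfe has UO > 0 but the fitness scheme has odModel = 'none'")
  }
  list(
    S = as.numeric(S),
    trait = if (scheme@trait == "viability") 0L else 1L,
    odModel = switch(scheme@odModel, none = 1L, classical = 1L, alternative = 2L),
    U = dfe@U, ULet = dfe@ULet, UO = dfe@UO, UN = dfe@UN,
    sShape = dfe@sShape, sMean = dfe@sMean, hMax = dfe@hMax,
    hRate = dfe@hRate, hLethal = dfe@hLethal, sOWild = dfe@sOWild,
    sOMut = dfe@sOMut,
    mapMode = if (map@mode == "free") 0L else 1L,
    mapLen = map@totalLength,
    trackFixed = isTRUE(trackFixed), maxTries = as.numeric(maxTries)
  )
}

#' Sample selection and dominance coefficients of deleterious mutations
#'
#' Draws `(s, h)` pairs from the configured family: gamma-distributed `s`
#' (shape `sShape`, mean `sMean`) truncated to (0, 1] — or a point mass at
#' `sMean` when `sShape = 0` — with `h = hMax * exp(-hRate * s)`.  Lethals are
#' not drawn here; they enter separately at rate `ULet` with `s = 1`.
#'
#' @param n number of draws.
#' @param dfe a [DFEConfig-class].
#' @return data.frame with columns `s` and `h`.
#' @examples
#' set.seed(1)
#' sampleDeleteriousEffects(5, dfeConfig(sShape = 0, sMean = 0.1, hMax = 0.3, hRate = 0))
#' @export
sampleDeleteriousEffects <- function(n, dfe) {
  validObject(dfe)
  m <- .cpp_sample_effects(as.integer(n), .engineConfig(fitnessScheme("classical"), dfe))
  as.data.frame(m)
}

#' Per-gamete counts of new mutations by class
#'
#' Draws, for `n` gametes, the Poisson numbers of new deleterious, lethal,
#' overdominant and neutral mutations at the configured haploid rates.
#'
#' @param n number of gametes.
#' @param dfe a [DFEConfig-class].
#' @return integer matrix with one row per gamete.
#' @export
sampleGameteMutationCounts <- function(n, dfe) {
  validObject(dfe)
  .cpp_mutation_counts(as.integer(n), .engineConfig(fitnessScheme("classical"), dfe))
}

#' Genotype fitness factor of a single mutation
#'
#' Returns the multiplicative fitness factor contributed by one locus given
#' the number of mutant copies carried:
#' dominance-type `1, 1 - sh, 1 - s`; classical overdominance `1 - sHomWild,
#' 1, 1 - sHomMut`; alternative overdominance `1, 1 + s, 1`; neutral always 1.
#'
#' @param m a [MutationRecord-class].
#' @param copies number of mutant copies: 0, 1 or 2.
#' @param scheme a [FitnessScheme-class].
#' @return a positive scalar.
#' @examples
#' scheme <- fitnessScheme("classical")
#' m <- mutationRecord("deleterious", s = 0.1, h = 0.2)
#' genotypeFitnessFactor(m, 1, scheme) # 0.98
#' @export
genotypeFitnessFactor <- function(m, copies, scheme) {
  stopifnot(is(m, "MutationRecord"), is(scheme, "FitnessScheme"))
  if (!copies %in% 0:2) stop("copies must be 0, 1 or 2")
  switch(m@mclass,
    neutral = 1,
    deleterious = ,
    lethal = c(1, 1 - m@s * m@h, 1 - m@s)[copies + 1],
    overdominant = {
      if (scheme@odModel == "alternative") {
        c(1, 1 + m@sHomWild, 1)[copies + 1]
      } else {
        c(1 - m@sHomWild, 1, 1 - m@sHomMut)[copies + 1]
      }
    }
  )
}

#' Dominance deviation d of a selective mutation
#'
#' The deviation of the heterozygote from the homozygote midpoint, the
#' per-locus ingredient of the inbreeding load `B = sum(2 d p q)`.  For
#' dominance-type mutations `d = s (1/2 - h)` (positive for partially
#' recessive alleles); for classical overdominance `d = (sHomWild +
#' sHomMut) / 2` (equal to `s_o` in the symmetric case); for the alternative
#' model `d = s_o / (1 + s_o)`.
#'
#' @param m a [MutationRecord-class]; neutral mutations are an error.
#' @param scheme a [FitnessScheme-class].
#' @return the dominance deviation (can be negative when `h > 1/2`).
#' @examples
#' dominanceDeviation(mutationRecord("overdominant", sHomWild = 0.04), fitnessScheme("classical"))
#' @export
dominanceDeviation <- function(m, scheme) {
  stopifnot(is(m, "MutationRecord"), is(scheme, "FitnessScheme"))
  switch(m@mclass,
    neutral = stop("dominance deviation is undefined for neutral mutations"),
    deleterious = ,
    lethal = m@s * (0.5 - m@h),
    overdominant = {
      if (scheme@odModel == "alternative") {
        m@sHomWild / (1 + m@sHomWild)
      } else {
        (m@sHomWild + m@sHomMut) / 2
      }
    }
  )
}
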