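#' @import methods
NULL

## ---------------------------------------------------------------------------
## Mutation classes are stored as integer codes in the registry:
##   0 = dominance-type (deleterious or lethal; fitnesses 1, 1-sh, 1-s)
##   1 = overdominant   (classical 1-sW, 1, 1-sM  or alternative 1, 1+s, 1)
##   2 = neutral
## For reporting, dominance-type mutations are split into "deleterious"
## (s < 0.9) and "lethal" (s >= 0.9).
## ---------------------------------------------------------------------------

.CLS_DOM <- 0L
.CLS_OD <- 1L
.CLS_NEU <- 2L

.emptyRegistry <- function() {
  data.frame(
    id = integer(0), class = integer(0), s = numeric(0), h = numeric(0),
    pos = numeric(0), birth = integer(0), count = integer(0)
  )
}

#' Distribution of fitness effects and mutation-rate configuration
#'
#' Container for the genome-wide haploid mutation rates of the four mutation
#' classes and the distributions from which per-mutation effects are drawn.
#'
#' Non-lethal deleterious mutations draw their homozygous selection
#' coefficient `s` from a gamma distribution with shape `sShape` and mean
#' `sMean`, truncated to (0, 1]; `sShape = 0` selects a point mass at `sMean`.
#' The dominance coefficient is the deterministic decreasing function
#' `h = hMax * exp(-hRate * s)`, so that mutations of large effect are nearly
#' recessive while mutations of very small effect are nearly additive.
#' Lethals enter at rate `ULet` with `s = 1` and dominance `hLethal`.
#' Overdominant mutations enter at rate `UO` with fixed homozygote
#' disadvantages `sOWild` (wild-type homozygote) and `sOMut` (mutant
#' homozygote); the symmetric case has `sOWild == sOMut`.  Under the
#' alternative overdominance scheme `sOWild` is the heterozygote advantage.
#'
#' The default deleterious/lethal parameters are calibrated, not taken from a
#' published table: they were chosen once so that a panmictic population of
#' n = 1000 at mutation-selection-drift balance shows the canonical anchor
#' values for this model class (mean viability near 0.69, about 1500
#' segregating deleterious mutations at mean frequency 0.09, about 70
#' segregating lethals at mean frequency 0.01, and a total inbreeding load
#' near 2.3-2.5 lethal equivalents).  See the package vignette.
#'
#' @slot U genome-wide haploid rate of non-lethal deleterious mutations.
#' @slot ULet haploid rate of lethal (or sterile, for fecundity) mutations.
#' @slot UO haploid rate of overdominant mutations.
#' @slot UN haploid rate of neutral marker mutations.
#' @slot sShape gamma shape for deleterious `s` (0 = point mass).
#' @slot sMean mean deleterious `s` before truncation.
#' @slot hMax,hRate parameters of `h = hMax * exp(-hRate * s)`.
#' @slot hLethal dominance coefficient of lethals.
#' @slot sOWild,sOMut overdominant homozygote disadvantages.
#' @export
setClass("DFEConfig",
  representation(
    U = "numeric", ULet = "numeric", UO = "numeric", UN = "numeric",
    sShape = "numeric", sMean = "numeric", hMax = "numeric",
    hRate = "numeric", hLethal = "numeric", sOWild = "numeric",
    sOMut = "numeric"
  )
)

setValidity("DFEConfig", function(object) {
  msg <- character(0)
  for (nm in c("U", "ULet", "UO", "UN")) {
    v <- slot(object, nm)
    if (length(v) != 1 || is.na(v) || v < 0) {
      msg <- c(msg, sprintf("mutation rate '%s' must be a single value >= 0", nm))
    }
  }
  if (object@sShape < 0) msg <- c(msg, "sShape must be >= 0")
  if (object@sMean <= 0 || object@sMean > 1) {
    msg <- c(msg, "sMean must lie in (0, 1]")
  }
  if (object@hMax < 0 || object@hMax > 1) msg <- c(msg, "hMax must lie in [0, 1]")
  if (object@hRate < 0) msg <- c(msg, "hRate must be >= 0")
  if (object@hLethal < 0 || object@hLethal > 1) {
    msg <- c(msg, "hLethal must lie in [0, 1]")
  }
  if (object@sOWild < 0 || object@sOWild >= 1) {
    msg <- c(msg, "sOWild must lie in [0, 1)")
  }
  if (object@sOMut < 0 || object@sOMut >= 1) msg <- c(msg, "sOMut must lie in [0, 1)")
  if (length(msg)) msg else TRUE
})

#' Create a DFE / mutation-rate configuration
#'
#' @param U,ULet,UO,UN genome-wide haploid mutation rates of the deleterious,
#'   lethal, overdominant and neutral classes.
#' @param sShape,sMean gamma shape and mean of the deleterious selection
#'   coefficient (`sShape = 0` gives a point mass at `sMean`).
#' @param hMax,hRate dominance rule `h = hMax * exp(-hRate * s)`.
#' @param hLethal dominance coefficient of lethal mutations.
#' @param sOWild,sOMut homozygote disadvantages of overdominant mutations
#'   (equal for the symmetric classical model; `sOWild` doubles as the
#'   heterozygote advantage of the alternative model).
#'
#' @return a [DFEConfig-class] object.
#' @examples
#' dfe <- dfeConfig(UO = 1e-4, sOWild = 0.04, sOMut = 0.04)
#' @export
dfeConfig <- function(U = 0.2, ULet = 0.02, UO = 0, UN = 1.0,
                      sShape = 0.33, sMean = 0.2, hMax = 0.5, hRate = 7,
                      hLethal = 0.02, sOWild = 0.04, sOMut = sOWild) {
  new("DFEConfig",
    U = as.numeric(U), ULet = as.numeric(ULet), UO = as.numeric(UO),
    UN = as.numeric(UN), sShape = as.numeric(sShape), sMean = as.numeric(sMean),
    hMax = as.numeric(hMax), hRate = as.numeric(hRate),
    hLethal = as.numeric(hLethal), sOWild = as.numeric(sOWild),
    sOMut = as.numeric(sOMut)
  )
}

#' Fitness scheme
#'
#' Which single-locus fitness model applies to overdominant loci and whether
#' fitness acts as viability (a survival probability, capped at one) or
#' fecundity (an expected offspring number, uncapped).
#'
#' @slot odModel `"none"`, `"classical"` (genotype fitnesses `1 - sW, 1,
#'   1 - sM`; symmetric when `sW == sM`) or `"alternative"` (`1, 1 + s, 1`).
#' @slot trait `"viability"` or `"fecundity"`.
#' @slot capAtOne logical; forced `TRUE` for viability.
#' @export
setClass("FitnessScheme",
  representation(odModel = "character", trait = "character", capAtOne = "logical")
)

setValidity("FitnessScheme", function(object) {
  msg <- character(0)
  if (!object@odModel %in% c("none", "classical", "alternative")) {
    msg <- c(msg, "odModel must be 'none', 'classical' or 'alternative'")
  }
  if (!object@trait %in% c("viability", "fecundity")) {
    msg <- c(msg, "trait must be 'viability' or 'fecundity'")
  }
  if (object@capAtOne != (object@trait == "viability")) {
    msg <- c(msg, "capAtOne must be TRUE exactly when trait is 'viability'")
  }
  if (length(msg)) msg else TRUE
})

#' Create a fitness scheme
#'
#' @param odModel overdominance model: `"none"`, `"classical"` or
#'   `"alternative"`.  An asymmetric classical model is obtained by setting
#'   different `sOWild`/`sOMut` in [dfeConfig()].
#' @param trait `"viability"` (offspring survival probability; individual
#'   fitness capped at one) or `"fecundity"` (parental offspring number).
#'
#' @return a [FitnessScheme-class] object.
#' @examples
#' fitnessScheme("classical", "viability")
#' @export
fitnessScheme <- function(odModel = c("none", "classical", "alternative"),
                          trait = c("viability", "fecundity")) {
  odModel <- match.arg(odModel)
  trait <- match.arg(trait)
  new("FitnessScheme",
    odModel = odModel, trait = trait,
    capAtOne = trait == "viability"
  )
}

#' Recombination map
#'
#' @slot mode `"free"` (every heterozygous site transmits independently) or
#'   `"mapped"` (Poisson crossovers on a chromosome of `totalLength` Morgans,
#'   no interference).
#' @slot totalLength map length in Morgans (used in mapped mode; mutation
#'   positions are uniform on `[0, totalLength)`).
#' @export
setClass("RecombinationMap",
  representation(mode = "character", totalLength = "numeric")
)

setValidity("RecombinationMap", function(object) {
  msg <- character(0)
  if (!object@mode %in% c("free", "mapped")) {
    msg <- c(msg, "mode must be 'free' or 'mapped'")
  }
  if (object@totalLength <= 0) msg <- c(msg, "totalLength must be > 0")
  if (length(msg)) msg else TRUE
})

#' Create a recombination map
#'
#' @param mode `"free"` or `"mapped"`.
#' @param totalLength genome length in Morgans for mapped mode.
#' @return a [RecombinationMap-class] object.
#' @export
recombinationMap <- function(mode = c("free", "mapped"), totalLength = 20) {
  new("RecombinationMap", mode = match.arg(mode), totalLength = as.numeric(totalLength))
}

#' A single mutation
#'
#' Scalar record of one mutation, mainly for single-locus calculations and
#' tests; populations store mutations column-wise in their registry.
#'
#' @slot id integer identifier (unique within a run; infinite sites).
#' @slot mclass `"deleterious"`, `"lethal"`, `"overdominant"` or `"neutral"`.
#' @slot s,h selection and dominance coefficients (dominance-type classes).
#' @slot sHomWild,sHomMut homozygote disadvantages (overdominant class).
#' @slot position map position in Morgans.
#' @slot birthGen generation of origin.
#' @export
setClass("MutationRecord",
  representation(
    id = "integer", mclass = "character", s = "numeric", h = "numeric",
    sHomWild = "numeric", sHomMut = "numeric", position = "numeric",
    birthGen = "integer"
  )
)

setValidity("MutationRecord", function(object) {
  msg <- character(0)
  cl <- object@mclass
  if (!cl %in% c("deleterious", "lethal", "overdominant", "neutral")) {
    msg <- c(msg, "unknown mutation class")
  }
  if (cl %in% c("deleterious", "lethal")) {
    if (is.na(object@s) || object@s < 0 || object@s > 1) {
      msg <- c(msg, "s must lie in [0, 1]")
    }
    if (is.na(object@h) || object@h < 0 || object@h > 1) {
      msg <- c(msg, "h must lie in [0, 1]")
    }
    if (cl == "lethal" && !is.na(object@s) && object@s < 0.9) {
      msg <- c(msg, "lethal mutations require s >= 0.9")
    }
    if (cl == "deleterious" && !is.na(object@s) && object@s >= 0.9) {
      msg <- c(msg, "deleterious mutations require s < 0.9")
    }
  }
  if (cl == "overdominant") {
    if (is.na(object@sHomWild) || is.na(object@sHomMut)) {
      msg <- c(msg, "overdominant mutations need sHomWild and sHomMut")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Create a mutation record
#'
#' @param mclass mutation class.
#' @param s,h selection/dominance coefficients for deleterious or lethal
#'   mutations.
#' @param sHomWild,sHomMut homozygote disadvantages for overdominant
#'   mutations.
#' @param position map position (Morgans).
#' @param birthGen generation of origin.
#' @param id integer id.
#' @return a [MutationRecord-class] object.
#' @examples
#' mutationRecord("deleterious", s = 0.1, h = 0.2)
#' mutationRecord("overdominant", sHomWild = 0.04, sHomMut = 0.04)
#' @export
mutationRecord <- function(mclass, s = NA_real_, h = NA_real_,
                           sHomWild = NA_real_, sHomMut = sHomWild,
                           position = 0, birthGen = 0L, id = 0L) {
  if (mclass == "lethal" && is.na(s)) s <- 1
  if (mclass == "neutral") s <- h <- 0
  new("MutationRecord",
    id = as.integer(id), mclass = mclass, s = as.numeric(s),
    h = as.numeric(h), sHomWild = as.numeric(sHomWild),
    sHomMut = as.numeric(sHomMut), position = as.numeric(position),
    birthGen = as.integer(birthGen)
  )
}

#' A diploid Wright-Fisher population
#'
#' Individuals are pairs of haplotypes; a haplotype is a sorted integer vector
#' of mutation ids.  The registry holds one row per segregating mutation
#' (infinite-sites; fixed and lost mutations are pruned, fixed selective ones
#' being folded into the fixed-load accumulators).
#'
#' @slot n number of diploid individuals.
#' @slot generation current generation index.
#' @slot haplotypes list of length `2 n`; elements `2i - 1` and `2i` are the
#'   two haplotypes of individual `i`.
#' @slot registry data.frame with columns `id`, `class` (integer code: 0
#'   dominance-type, 1 overdominant, 2 neutral), `s`, `h`, `pos`, `birth`,
#'   `count` (copies among the `2 n` haplotypes).  For overdominant rows `s`
#'   and `h` store the wild-type and mutant homozygote disadvantages.
#' @slot nextId next unused mutation id.
#' @slot wFixDel product of `1 - s` over dominance-type mutations fixed since
#'   fixed-load tracking started (line foundation).
#' @slot odFixFactor product of `1 - s_hom` of the surviving allele over
#'   classical overdominant loci that lost polymorphism since tracking
#'   started.
#' @slot nOFixed number of overdominant loci out of polymorphism since
#'   tracking started.
#' @slot status `"ok"` or `"extinct"`.
#' @export
setClass("WFPopulation",
  representation(
    n = "integer", generation = "integer", haplotypes = "list",
    registry = "data.frame", nextId = "integer", wFixDel = "numeric",
    odFixFactor = "numeric", nOFixed = "integer", status = "character"
  )
)

setValidity("WFPopulation", function(object) {
  msg <- character(0)
  if (length(object@haplotypes) != 2L * object@n) {
    msg <- c(msg, "haplotype list must have length 2 * n")
  }
  need <- c("id", "class", "s", "h", "pos", "birth", "count")
  if (!all(need %in% names(object@registry))) {
    msg <- c(msg, paste(
      "registry must have columns",
      paste(need, collapse = ", ")
    ))
  } else if (anyDuplicated(object@registry$id)) {
    msg <- c(msg, "registry ids must be unique")
  }
  if (object@wFixDel < 0 || object@wFixDel > 1) {
    msg <- c(msg, "wFixDel must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' Create an empty (mutation-free) population
#'
#' @param n number of diploid individuals.
#' @param generation starting generation index.
#' @return a [WFPopulation-class] with no segregating mutations.
#' @examples
#' pop <- newPopulation(50)
#' @export
newPopulation <- function(n, generation = 0L) {
  new("WFPopulation",
    n = as.integer(n), generation = as.integer(generation),
    haplotypes = rep(list(integer(0)), 2L * n), registry = .emptyRegistry(),
    nextId = 1L, wFixDel = 1, odFixFactor = 1, nOFixed = 0L, status = "ok"
  )
}

#' Build a population from explicit tables
#'
#' Intended for constructing exact test fixtures and for restoring snapshots.
#' Copy counts are recomputed from the haplotypes.
#'
#' @param registry data.frame with columns `id`, `class`, `s`, `h`, `pos`,
#'   `birth` (a `count` column, if present, is ignored and recomputed).
#' @param haplotypes list of `2 n` integer vectors of mutation ids.
#' @param generation generation index.
#' @param wFixDel,odFixFactor,nOFixed fixed-load accumulators.
#' @return a [WFPopulation-class] object.
#' @export
populationFromTables <- function(registry, haplotypes, generation = 0L,
                                 wFixDel = 1, odFixFactor = 1, nOFixed = 0L) {
  if (length(haplotypes) %% 2L != 0L) {
    stop("haplotypes must contain two haplotypes per individual")
  }
  n <- length(haplotypes) %/% 2L
  registry <- as.data.frame(registry)
  for (col in c("pos", "birth")) {
    if (is.null(registry[[col]])) registry[[col]] <- 0
  }
  haplotypes <- lapply(haplotypes, function(h) sort(unique(as.integer(h))))
  allIds <- unlist(haplotypes, use.names = FALSE)
  if (length(allIds) && !all(allIds %in% registry$id)) {
    stop("haplotypes refer to mutation ids missing from the registry")
  }
  counts <- table(factor(allIds, levels = registry$id))
  registry$count <- as.integer(counts)
  registry <- registry[, c("id", "class", "s", "h", "pos", "birth", "count")]
  registry$id <- as.integer(registry$id)
  registry$class <- as.integer(registry$class)
  registry$birth <- as.integer(registry$birth)
  rownames(registry) <- NULL
  new("WFPopulation",
    n = n, generation = as.integer(generation), haplotypes = haplotypes,
    registry = registry,
    nextId = if (nrow(registry)) max(registry$id) + 1L else 1L,
    wFixDel = wFixDel, odFixFactor = odFixFactor,
    nOFixed = as.integer(nOFixed), status = "ok"
  )
}

#' Result of a selfing assay
#'
#' @slot WO,WS mean genotypic fitness of outbred and selfed progeny.
#' @slot delta inbreeding depression of selfed progeny,
#'   `delta = log(WO / WS)`.
#' @slot deltaStar rate of inbreeding depression,
#'   `delta / (FHatS - FHatO)`; `NA` when `FHatS <= FHatO`.
#' @slot FHatS,FHatO mean marker-based inbreeding coefficients of selfed and
#'   outbred progeny.
#' @export
setClass("SelfingAssayResult",
  representation(
    WO = "numeric", WS = "numeric", delta = "numeric", deltaStar = "numeric",
    FHatS = "numeric", FHatO = "numeric"
  )
)

#' Run configuration for the experimental designs
#'
#' Bundles population size, selfing rate, burn-in length, bottleneck-line
#' design, replication and the scheme/DFE/map settings.  Defaults follow the
#' full-scale study design (n = 1000, 10 000 burn-in generations, samples of
#' 50 founders kept for 250 generations, 200 replicates); [deskPreset()]
#' provides a small configuration for interactive use.
#'
#' @slot nBase base-population size.
#' @slot S selfing rate in `[0, 1]`.
#' @slot burninGens burn-in length in generations.
#' @slot sampleSize number of individuals sampled to found a line.
#' @slot lineGens generations a bottleneck line is maintained.
#' @slot nReplicates number of replicates.
#' @slot reportInterval generations between logged summary rows.
#' @slot baseSeed integer; replicate `r` seeds the RNG with `baseSeed + r`.
#' @slot sharedBase logical; if `TRUE`, one burn-in is shared by all
#'   replicate lines instead of an independent burn-in per replicate.
#' @slot assayPairs,progenyPerSelf,progenyPerPair selfing-assay design.
#' @slot scheme a [FitnessScheme-class].
#' @slot dfe a [DFEConfig-class].
#' @slot map a [RecombinationMap-class].
#' @export
setClass("RunConfig",
  representation(
    nBase = "integer", S = "numeric", burninGens = "integer",
    sampleSize = "integer", lineGens = "integer", nReplicates = "integer",
    reportInterval = "integer", baseSeed = "integer", sharedBase = "logical",
    assayPairs = "integer", progenyPerSelf = "integer",
    progenyPerPair = "integer", scheme = "FitnessScheme", dfe = "DFEConfig",
    map = "RecombinationMap"
  )
)

setValidity("RunConfig", function(object) {
  msg <- character(0)
  if (object@nBase < 1) msg <- c(msg, "nBase must be >= 1")
  if (is.na(object@S) || object@S < 0 || object@S > 1) {
    msg <- c(msg, "S must lie in [0, 1]")
  }
  for (nm in c(
    "burninGens", "sampleSize", "lineGens", "nReplicates",
    "reportInterval", "assayPairs", "progenyPerSelf", "progenyPerPair"
  )) {
    if (slot(object, nm) < 1) msg <- c(msg, sprintf("%s must be >= 1", nm))
  }
  if (object@sampleSize > object@nBase) {
    msg <- c(msg, "sampleSize must not exceed nBase")
  }
  if (length(msg)) msg else TRUE
})

#' Create a run configuration
#'
#' @param nBase,S,burninGens,sampleSize,lineGens,nReplicates,reportInterval
#'   see [RunConfig-class].
#' @param baseSeed base RNG seed; replicate `r` uses `baseSeed + r`.
#' @param sharedBase share one burn-in across replicate lines.
#' @param assayPairs,progenyPerSelf,progenyPerPair selfing-assay design.
#' @param scheme,dfe,map model components.
#' @return a [RunConfig-class] object.
#' @examples
#' cfg <- runConfig(nBase = 200, burninGens = 500, nReplicates = 3)
#' @export
runConfig <- function(nBase = 1000, S = 0, burninGens = 10000,
                      sampleSize = 50, lineGens = 250, nReplicates = 200,
                      reportInterval = 50, baseSeed = 1, sharedBase = FALSE,
                      assayPairs = 50, progenyPerSelf = 1, progenyPerPair = 1,
                      scheme = fitnessScheme(), dfe = dfeConfig(),
                      map = recombinationMap()) {
  new("RunConfig",
    nBase = as.integer(nBase), S = as.numeric(S),
    burninGens = as.integer(burninGens), sampleSize = as.integer(sampleSize),
    lineGens = as.integer(lineGens), nReplicates = as.integer(nReplicates),
    reportInterval = as.integer(reportInterval),
    baseSeed = as.integer(baseSeed), sharedBase = isTRUE(sharedBase),
    assayPairs = as.integer(assayPairs),
    progenyPerSelf = as.integer(progenyPerSelf),
    progenyPerPair = as.integer(progenyPerPair),
    scheme = scheme, dfe = dfe, map = map
  )
}
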