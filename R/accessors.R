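#' @include AllClasses.R
NULL

#' Accessors for WFPopulation objects
#'
#' @param object,pop a [WFPopulation-class].
#' @name population-accessors
NULL

#' @describeIn population-accessors current generation index.
#' @export
setGeneric("generation", function(object) standardGeneric("generation"))

#' @rdname population-accessors
#' @export
setMethod("generation", "WFPopulation", function(object) object@generation)

#' @describeIn population-accessors number of diploid individuals.
#' @export
setGeneric("populationSize", function(object) standardGeneric("populationSize"))

#' @rdname population-accessors
#' @export
setMethod("populationSize", "WFPopulation", function(object) object@n)

#' @describeIn population-accessors list of the `2 n` haplotypes (sorted
#'   integer vectors of mutation ids).
#' @export
setGeneric("haplotypes", function(object) standardGeneric("haplotypes"))

#' @rdname population-accessors
#' @export
setMethod("haplotypes", "WFPopulation", function(object) object@haplotypes)

#' @describeIn population-accessors run status (`"ok"` or `"extinct"`).
#' @export
setGeneric("runStatus", function(object) standardGeneric("runStatus"))

#' @rdname population-accessors
#' @export
setMethod("runStatus", "WFPopulation", function(object) object@status)

#' Segregating-mutation table of a population
#'
#' Returns the mutation registry with human-readable class labels
#' (`deleterious` / `lethal` split at s = 0.9 for dominance-type mutations)
#' and allele frequencies.
#'
#' @param pop a [WFPopulation-class].
#' @return a data.frame with columns `id`, `class`, `s`, `h`, `sHomWild`,
#'   `sHomMut`, `pos`, `birth`, `count`, `q`.
#' @export
mutations <- function(pop) {
  stopifnot(is(pop, "WFPopulation"))
  reg <- pop@registry
  lab <- character(nrow(reg))
  lab[reg$class == .CLS_DOM & reg$s < 0.9] <- "deleterious"
  lab[reg$class == .CLS_DOM & reg$s >= 0.9] <- "lethal"
  lab[reg$class == .CLS_OD] <- "overdominant"
  lab[reg$class == .CLS_NEU] <- "neutral"
  od <- reg$class == .CLS_OD
  data.frame(
    id = reg$id, class = lab,
    s = ifelse(od, NA_real_, reg$s), h = ifelse(od, NA_real_, reg$h),
    sHomWild = ifelse(od, reg$s, NA_real_),
    sHomMut = ifelse(od, reg$h, NA_real_),
    pos = reg$pos, birth = reg$birth, count = reg$count,
    q = reg$count / (2 * pop@n)
  )
}

#' Fixed-load accumulators of a population
#'
#' @param pop a [WFPopulation-class].
#' @return list with `wFixDel` (product of 1 - s over dominance-type
#'   mutations fixed since tracking started), `odFixFactor` (product of
#'   1 - s_hom of the surviving allele over classical overdominant loci out
#'   of polymorphism) and `nOFixed`.
#' @export
fixedLoad <- function(pop) {
  stopifnot(is(pop, "WFPopulation"))
  list(
    wFixDel = pop@wFixDel, odFixFactor = pop@odFixFactor,
    nOFixed = pop@nOFixed
  )
}

setMethod("show", "WFPopulation", function(object) {
  reg <- object@registry
  nDom <- sum(reg$class == .CLS_DOM)
  cat(sprintf(
    "WFPopulation: %d individuals, generation %d (%s)\n",
    object@n, object@generation, object@status
  ))
  cat(sprintf(
    "  segregating mutations: %d dominance-type, %d overdominant, %d neutral\n",
    nDom, sum(reg$class == .CLS_OD), sum(reg$class == .CLS_NEU)
  ))
  cat(sprintf(
    "  fixed load: wFixDel = %.4g, odFixFactor = %.4g, nOFixed = %d\n",
    object@wFixDel, object@odFixFactor, object@nOFixed
  ))
  invisible(object)
})

setMethod("show", "DFEConfig", function(object) {
  cat("DFEConfig\n")
  cat(sprintf(
    "  rates/haploid genome: U = %g, ULet = %g, UO = %g, UN = %g\n",
    object@U, object@ULet, object@UO, object@UN
  ))
  if (object@sShape > 0) {
    cat(sprintf(
      "  deleterious s ~ gamma(shape = %g, mean = %g) on (0, 1]\n",
      object@sShape, object@sMean
    ))
  } else {
    cat(sprintf("  deleterious s fixed at %g\n", object@sMean))
  }
  cat(sprintf(
    "  h = %g * exp(-%g s); lethals: s = 1, h = %g; OD: sW = %g, sM = %g\n",
    object@hMax, object@hRate, object@hLethal, object@sOWild, object@sOMut
  ))
  invisible(object)
})

setMethod("show", "FitnessScheme", function(object) {
  cat(sprintf(
    "FitnessScheme: odModel = %s, trait = %s%s\n",
    object@odModel, object@trait,
    if (object@capAtOne) " (capped at 1)" else ""
  ))
  invisible(object)
})

setMethod("show", "RecombinationMap", function(object) {
  cat(sprintf(
    "RecombinationMap: %s%s\n", object@mode,
    if (object@mode == "mapped") sprintf(" (%g Morgans)", object@totalLength) else ""
  ))
  invisible(object)
})

setMethod("show", "SelfingAssayResult", function(object) {
  cat("SelfingAssayResult\n")
  cat(sprintf("  WO = %.6g, WS = %.6g\n", object@WO, object@WS))
  cat(sprintf(
    "  delta = %.6g, delta* = %.6g (FHatS = %.4g, FHatO = %.4g)\n",
    object@delta, object@deltaStar, object@FHatS, object@FHatO
  ))
  invisible(object)
})

setMethod("show", "RunConfig", function(object) {
  cat(sprintf(
    "RunConfig: nBase = %d, S = %g, burnin = %d, sample = %d, lineGens = %d, replicates = %d\n",
    object@nBase, object@S, object@burninGens, object@sampleSize,
    object@lineGens, object@nReplicates
  ))
  show(object@scheme)
  show(object@dfe)
  show(object@map)
  invisible(object)
})
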