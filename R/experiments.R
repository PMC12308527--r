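#' @include AllClasses.R population-engine.R load-metrics.R
NULL

#' Burn a base population in to mutation-selection-drift balance
#'
#' Evolves a mutation-free population of `nBase` individuals for
#' `burninGens` generations under the configured selfing rate, scheme, DFE
#' and map.  Load fixed during the burn-in is excluded from reported fitness
#' (it precedes line foundation); under the classical overdominance model,
#' overdominant loci fixed or lost during the burn-in are likewise dropped
#' from all accounting.
#'
#' @param cfg a [RunConfig-class].
#' @param seed optional integer seed (`set.seed` is called when supplied;
#'   otherwise the current RNG stream is used).
#' @return list with `population` and `trajectory` (one row every
#'   `reportInterval` generations).
#' @export
runBurnin <- function(cfg, seed = NULL) {
  stopifnot(is(cfg, "RunConfig"))
  if (!is.null(seed)) set.seed(seed)
  evolve(
    newPopulation(cfg@nBase), cfg@burninGens,
    scheme = cfg@scheme, dfe = cfg@dfe, S = cfg@S, map = cfg@map,
    reportEvery = cfg@reportInterval, trackFixed = FALSE
  )
}

#' Found a line from a sample of individuals
#'
#' Draws `k` individuals without replacement and restarts load accounting at
#' generation 0.  Mutations absent from the sample are dropped; mutations
#' fixed in the sample are pruned from the genotypes, dominance-type ones
#' folding into `wFixDel` (they depress fitness uniformly from generation 0
#' on).  Overdominant loci without polymorphism among the founders are
#' excluded from the line's load and `W_max` accounting: under the classical
#' model every such locus would multiply every fitness by `1 - s_o` forever
#' and swamp the within-line dynamics, and under the alternative model the
#' homozygote fitness is one, so dropping them is exactly equivalent to
#' retaining them.
#'
#' @param base a [WFPopulation-class] (the burnt-in base population).
#' @param k number of founders.
#' @param scheme a [FitnessScheme-class] (kept for interface symmetry; the
#'   foundation rule depends only on mutation classes).
#' @return a [WFPopulation-class] of `k` individuals at generation 0.
#' @export
foundSample <- function(base, k, scheme = fitnessScheme()) {
  stopifnot(is(base, "WFPopulation"))
  k <- as.integer(k)
  if (k < 1 || k > base@n) stop("k must lie in 1..populationSize(base)")
  keep <- sort(sample.int(base@n, k))
  haps <- base@haplotypes[as.vector(rbind(2L * keep - 1L, 2L * keep))]
  reg <- base@registry
  ids <- unlist(haps, use.names = FALSE)
  cnt <- as.integer(table(factor(ids, levels = reg$id)))
  fixed <- cnt == 2L * k
  lost <- cnt == 0L
  wFixDel <- base@wFixDel * prod(1 - reg$s[fixed & reg$class == .CLS_DOM])
  if (any(fixed)) {
    fixedIds <- reg$id[fixed]
    haps <- lapply(haps, function(h) h[!(h %in% fixedIds)])
  }
  regKeep <- reg[!fixed & !lost, , drop = FALSE]
  regKeep$count <- cnt[!fixed & !lost]
  rownames(regKeep) <- NULL
  new("WFPopulation",
    n = k, generation = 0L, haplotypes = haps, registry = regKeep,
    nextId = base@nextId, wFixDel = wFixDel, odFixFactor = 1,
    nOFixed = 0L, status = "ok"
  )
}

#' Selfing assay: inbreeding depression and its marker-based rate
#'
#' Produces selfed progeny from every individual and outbred progeny from
#' random pairs of distinct parents, records the deterministic genotypic
#' fitness of each progeny (no survival lottery and no new mutations, so the
#' means estimate expected fitness), and estimates each progeny's inbreeding
#' coefficient from the segregating neutral loci with the parental
#' population as allele-frequency reference panel.
#'
#' @param pop a [WFPopulation-class] with at least 2 individuals.
#' @param scheme a [FitnessScheme-class].
#' @param nPairs number of random outbred parent pairs.
#' @param progenyPerSelf selfed progeny per individual.
#' @param progenyPerPair outbred progeny per pair.
#' @param map a [RecombinationMap-class].
#' @return a [SelfingAssayResult-class]; `deltaStar` is `NA` when no neutral
#'   loci segregate or when `FHatS <= FHatO`.
#' @export
selfingAssay <- function(pop, scheme = fitnessScheme(), nPairs = 50,
                         progenyPerSelf = 1, progenyPerPair = 1,
                         map = recombinationMap()) {
  stopifnot(is(pop, "WFPopulation"))
  if (pop@n < 2) stop("the assay needs at least 2 individuals")
  cfg <- .engineConfig(scheme, dfeConfig(UN = 0), map) # rates unused here
  out <- .cpp_assay(
    pop@haplotypes, pop@registry, pop@n, cfg,
    pop@wFixDel * pop@odFixFactor, as.integer(nPairs),
    as.integer(progenyPerSelf), as.integer(progenyPerPair)
  )
  depressionStats(out$WO, out$WS, out$FHatS, out$FHatO)
}

#' Selfing sweep across selfing rates
#'
#' For each selfing rate, runs replicate burn-ins, samples founders and runs
#' the selfing assay, then averages the inbreeding load (total and
#' partitioned), the number of segregating overdominant loci, `delta` and
#' `delta*` over replicates.  The expectation columns reproduce the
#' closed-form references: `E_Bo = n_o * d / 2` (the per-locus maximum of
#' `2 d p q`) and `E_delta = (B / 2)(1 + F)` with `F = S / (2 - S)`.
#'
#' Replicate `r` at the `m`-th selfing rate seeds the RNG with
#' `baseSeed + 10000 (m - 1) + r`.
#'
#' @param cfg a [RunConfig-class]; `nReplicates` burn-ins are run per
#'   selfing rate (use a desk-scale configuration for interactive work).
#' @param S vector of selfing rates.
#' @return data.frame with one row per selfing rate.
#' @export
selfingSweep <- function(cfg, S = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(is(cfg, "RunConfig"))
  dOD <- if (cfg@scheme@odModel == "alternative") {
    cfg@dfe@sOWild / (1 + cfg@dfe@sOWild)
  } else {
    (cfg@dfe@sOWild + cfg@dfe@sOMut) / 2
  }
  rows <- lapply(seq_along(S), function(m) {
    reps <- lapply(seq_len(cfg@nReplicates), function(r) {
      set.seed(cfg@baseSeed + 10000L * (m - 1L) + r)
      cfgS <- cfg
      cfgS@S <- S[m]
      base <- runBurnin(cfgS)$population
      smp <- foundSample(base, cfg@sampleSize, cfg@scheme)
      B <- inbreedingLoad(smp, cfg@scheme)
      nO <- sum(smp@registry$class == .CLS_OD)
      assay <- tryCatch(
        selfingAssay(smp, cfg@scheme,
          nPairs = cfg@assayPairs,
          progenyPerSelf = cfg@progenyPerSelf,
          progenyPerPair = cfg@progenyPerPair, map = cfg@map
        ),
        error = function(e) NULL
      )
      c(
        B = unname(B["B"]), B_del = unname(B["B_del"]),
        B_let = unname(B["B_let"]), B_o = unname(B["B_o"]), n_o = nO,
        delta = if (is.null(assay)) NA_real_ else assay@delta,
        deltaStar = if (is.null(assay)) NA_real_ else assay@deltaStar
      )
    })
    mt <- do.call(rbind, reps)
    means <- colMeans(mt, na.rm = TRUE)
    data.frame(
      S = S[m], B = means["B"], n_o = means["n_o"], B_o = means["B_o"],
      ratio_od_del = means["B_o"] / (means["B_del"] + means["B_let"]),
      delta = means["delta"], deltaStar = means["deltaStar"],
      E_Bo = means["n_o"] * dOD / 2,
      E_delta = (means["B"] / 2) * (1 + equilibriumF(S[m])),
      nReplicates = nrow(mt), row.names = NULL
    )
  })
  do.call(rbind, rows)
}

## mean/SE aggregation of per-line trajectory matrices on a shared t grid
.aggregateTrajectories <- function(trajs) {
  tGrid <- trajs[[1]]$t
  cols <- setdiff(names(trajs[[1]]), "t")
  arr <- vapply(
    trajs, function(d) as.matrix(d[cols]),
    matrix(0, length(tGrid), length(cols))
  )
  mean2 <- apply(arr, c(1, 2), mean, na.rm = TRUE)
  se2 <- apply(arr, c(1, 2), function(x) {
    x <- x[!is.na(x)]
    if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
  })
  colnames(se2) <- paste0("se_", cols)
  data.frame(t = tGrid, mean2, se2, check.names = FALSE)
}

#' Bottleneck-line experiment
#'
#' Founds panmictic lines of `sampleSize` individuals from burnt-in base
#' populations and maintains each line for `lineGens` generations of random
#' mating under continued mutation, selection and drift, tracking mean
#' fitness, maximum fitness, expressed load and the partitioned inbreeding
#' load every generation.  Fitness declines are reported relative to each
#' line's own generation-0 mean (`dW_pct`), then averaged across lines.
#'
#' With `sharedBase = FALSE` (default) every line gets an independent
#' burn-in; with `sharedBase = TRUE` a single base (seeded with `baseSeed`)
#' is sampled repeatedly, which is far cheaper.  Line `r` seeds the RNG with
#' `baseSeed + r` before (optionally) burning in, sampling founders and
#' running the line.
#'
#' @param cfg a [RunConfig-class]; `nReplicates` is the number of lines.
#' @param base optional pre-computed base [WFPopulation-class] to sample
#'   from (implies shared-base mode and skips the burn-in).
#' @return list with `summary` (means and standard errors across surviving
#'   lines at multiples of `reportInterval`), `trajectories` (per-line
#'   data.frames), `w0` (per-line founding mean fitness), `nLines` and
#'   `nExtinct`.
#' @export
runBottleneckLines <- function(cfg, base = NULL) {
  stopifnot(is(cfg, "RunConfig"))
  shared <- isTRUE(cfg@sharedBase) || !is.null(base)
  if (shared && is.null(base)) {
    set.seed(cfg@baseSeed)
    base <- runBurnin(cfg)$population
  }
  trajs <- list()
  w0 <- numeric(0)
  nExtinct <- 0L
  for (r in seq_len(cfg@nReplicates)) {
    set.seed(cfg@baseSeed + r)
    baseR <- if (shared) base else runBurnin(cfg)$population
    founders <- foundSample(baseR, cfg@sampleSize, cfg@scheme)
    res <- evolve(
      founders, cfg@lineGens,
      scheme = cfg@scheme, dfe = cfg@dfe,
      S = 0, map = cfg@map, reportEvery = 1L, trackFixed = TRUE
    )
    if (res$population@status != "ok") {
      nExtinct <- nExtinct + 1L
      next
    }
    tr <- res$trajectory
    tr$dW_pct <- 100 * (tr$W[1] - tr$W) / tr$W[1]
    w0 <- c(w0, tr$W[1])
    trajs[[length(trajs) + 1L]] <- tr
  }
  if (!length(trajs)) stop("all lines went extinct")
  agg <- .aggregateTrajectories(trajs)
  list(
    summary = agg[agg$t %% cfg@reportInterval == 0, , drop = FALSE],
    trajectories = trajs, w0 = w0,
    nLines = length(trajs), nExtinct = nExtinct
  )
}

#' Replicated experiment orchestrator
#'
#' Runs one of the experimental designs over `nReplicates` replicates with
#' the documented seed derivation (`baseSeed + r`), aggregates means and
#' standard errors, and optionally writes the rounded and full-precision TSV
#' tables plus a JSON run manifest to `outDir`.
#'
#' @param cfg a [RunConfig-class].
#' @param experiment `"burnin"` (replicate base populations; one final-state
#'   summary row each), `"bottleneck"` (see [runBottleneckLines()]) or
#'   `"sweep"` (see [selfingSweep()]).
#' @param outDir optional output directory (created if needed).
#' @param sweepS selfing rates for the sweep design.
#' @return list with the experiment results (`summary` data.frame plus
#'   design-specific components); when `outDir` is given, also `files`.
#' @export
runReplicates <- function(cfg, experiment = c("burnin", "bottleneck", "sweep"),
                          outDir = NULL, sweepS = c(0, 0.25, 0.5, 0.75, 1)) {
  stopifnot(is(cfg, "RunConfig"))
  experiment <- match.arg(experiment)
  res <- switch(experiment,
    burnin = {
      rows <- list()
      status <- character(0)
      for (r in seq_len(cfg@nReplicates)) {
        set.seed(cfg@baseSeed + r)
        out <- runBurnin(cfg)
        status <- c(status, out$population@status)
        if (out$population@status == "ok") {
          rows[[length(rows) + 1L]] <- utils::tail(out$trajectory, 1L)
        }
      }
      if (!length(rows)) stop("all burn-in replicates failed")
      all <- do.call(rbind, rows)
      mu <- colMeans(all)
      se <- vapply(all, function(x) {
        if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else NA_real_
      }, 0)
      list(
        summary = data.frame(
          t(mu),
          t(structure(se, names = paste0("se_", names(se)))),
          check.names = FALSE
        ),
        replicates = all, nFailed = sum(status != "ok")
      )
    },
    bottleneck = runBottleneckLines(cfg),
    sweep = list(summary = selfingSweep(cfg, S = sweepS))
  )
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    tab <- res$summary
    path <- file.path(outDir, paste0(experiment, ".tsv"))
    files <- if (experiment == "sweep") {
      fullPath <- file.path(outDir, paste0(experiment, "_full.tsv"))
      .writeTsv(tab, path)
      .writeTsv(tab, fullPath, fullPrecision = TRUE)
      list(display = path, full = fullPath)
    } else {
      if (!"dW_pct" %in% names(tab)) tab$dW_pct <- NA_real_
      writeSummaryTable(tab, path)
    }
    manifest <- file.path(outDir, paste0(experiment, "_manifest.json"))
    writeManifest(manifest, cfg,
      experiment = experiment,
      files = unlist(files, use.names = FALSE)
    )
    res$files <- c(unlist(files, use.names = FALSE), manifest)
  }
  res
}
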