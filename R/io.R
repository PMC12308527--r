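#' @include AllClasses.R
NULL

.SNAPSHOT_VERSION <- "odload-snapshot v1"

.configAsList <- function(cfg) {
  list(
    nBase = cfg@nBase, S = cfg@S, burninGens = cfg@burninGens,
    sampleSize = cfg@sampleSize, lineGens = cfg@lineGens,
    nReplicates = cfg@nReplicates, reportInterval = cfg@reportInterval,
    baseSeed = cfg@baseSeed, sharedBase = cfg@sharedBase,
    assayPairs = cfg@assayPairs, progenyPerSelf = cfg@progenyPerSelf,
    progenyPerPair = cfg@progenyPerPair,
    scheme = list(odModel = cfg@scheme@odModel, trait = cfg@scheme@trait),
    dfe = list(
      U = cfg@dfe@U, ULet = cfg@dfe@ULet, UO = cfg@dfe@UO, UN = cfg@dfe@UN,
      sShape = cfg@dfe@sShape, sMean = cfg@dfe@sMean, hMax = cfg@dfe@hMax,
      hRate = cfg@dfe@hRate, hLethal = cfg@dfe@hLethal,
      sOWild = cfg@dfe@sOWild, sOMut = cfg@dfe@sOMut
    ),
    map = list(mode = cfg@map@mode, totalLength = cfg@map@totalLength)
  )
}

.applyKeys <- function(args, lst, where, allowed) {
  bad <- setdiff(names(lst), allowed)
  if (length(bad)) {
    stop(sprintf(
      "unknown configuration key%s at %s: %s",
      if (length(bad) > 1) "s" else "", where, paste(bad, collapse = ", ")
    ))
  }
  utils::modifyList(args, lst)
}

.configFromList <- function(lst, where = "top level") {
  topKeys <- c(
    "preset", "nBase", "S", "burninGens", "sampleSize", "lineGens",
    "nReplicates", "reportInterval", "baseSeed", "sharedBase", "assayPairs",
    "progenyPerSelf", "progenyPerPair", "scheme", "dfe", "map"
  )
  bad <- setdiff(names(lst), topKeys)
  if (length(bad)) {
    stop(sprintf(
      "unknown configuration key%s at %s: %s",
      if (length(bad) > 1) "s" else "", where, paste(bad, collapse = ", ")
    ))
  }
  base <- if (!is.null(lst$preset)) {
    switch(lst$preset,
      full = .configAsList(fullPreset()),
      desk = .configAsList(deskPreset()),
      stop("unknown preset: ", lst$preset)
    )
  } else {
    .configAsList(runConfig())
  }
  lst$preset <- NULL
  schemeArgs <- .applyKeys(base$scheme, lst$scheme %||% list(), "scheme",
    allowed = c("odModel", "trait")
  )
  dfeArgs <- .applyKeys(base$dfe, lst$dfe %||% list(), "dfe",
    allowed = names(base$dfe)
  )
  mapArgs <- .applyKeys(base$map, lst$map %||% list(), "map",
    allowed = c("mode", "totalLength")
  )
  lst$scheme <- lst$dfe <- lst$map <- NULL
  top <- utils::modifyList(
    base[setdiff(names(base), c("scheme", "dfe", "map"))], lst
  )
  runConfig(
    nBase = top$nBase, S = top$S, burninGens = top$burninGens,
    sampleSize = top$sampleSize, lineGens = top$lineGens,
    nReplicates = top$nReplicates, reportInterval = top$reportInterval,
    baseSeed = top$baseSeed, sharedBase = top$sharedBase,
    assayPairs = top$assayPairs, progenyPerSelf = top$progenyPerSelf,
    progenyPerPair = top$progenyPerPair,
    scheme = do.call(fitnessScheme, schemeArgs),
    dfe = do.call(dfeConfig, dfeArgs),
    map = do.call(recombinationMap, mapArgs)
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Full-scale study configuration
#'
#' The design of the full-scale experiments: base populations of 1000
#' individuals burnt in for 10 000 generations, samples of 50 founders kept
#' as lines for 250 generations, 200 replicates, summary rows every 50
#' generations.  `odLevel` selects one of the studied overdominance levels
#' (mutation rate and homozygote disadvantage of overdominant mutations).
#'
#' @param odLevel one of `"none"` (dominance model only), `"u1e-4_s0.04"`,
#'   `"u5e-5_s0.04"`, `"u5e-5_s0.02"`, `"u1e-5_s0.2"` or `"asym"`
#'   (`U_o = 1e-4`, disadvantages 0.04 and 0.02).
#' @param trait `"viability"` or `"fecundity"`.
#' @param alternative use the alternative (1, 1+s, 1) overdominance model.
#' @return a [RunConfig-class].
#' @export
fullPreset <- function(odLevel = c(
                          "none", "u1e-4_s0.04", "u5e-5_s0.04",
                          "u5e-5_s0.02", "u1e-5_s0.2", "asym"
                        ),
                        trait = c("viability", "fecundity"),
                        alternative = FALSE) {
  odLevel <- match.arg(odLevel)
  trait <- match.arg(trait)
  od <- switch(odLevel,
    none = c(0, 0.04, 0.04),
    `u1e-4_s0.04` = c(1e-4, 0.04, 0.04),
    `u5e-5_s0.04` = c(5e-5, 0.04, 0.04),
    `u5e-5_s0.02` = c(5e-5, 0.02, 0.02),
    `u1e-5_s0.2` = c(1e-5, 0.2, 0.2),
    asym = c(1e-4, 0.04, 0.02)
  )
  model <- if (od[1] == 0) "none" else if (alternative) "alternative" else "classical"
  runConfig(
    nBase = 1000, S = 0, burninGens = 10000, sampleSize = 50,
    lineGens = 250, nReplicates = 200, reportInterval = 50,
    scheme = fitnessScheme(model, trait),
    dfe = dfeConfig(UO = od[1], sOWild = od[2], sOMut = od[3])
  )
}

#' Small desk-scale configuration
#'
#' A configuration small enough for interactive exploration and examples:
#' everything is scaled down (n = 200, 500 burn-in generations, 5 lines of
#' 100 generations).  Statistical anchors of the full design are not
#' expected to hold at this scale.
#'
#' @inheritParams fullPreset
#' @return a [RunConfig-class].
#' @export
deskPreset <- function(odLevel = c(
                         "none", "u1e-4_s0.04", "u5e-5_s0.04",
                         "u5e-5_s0.02", "u1e-5_s0.2", "asym"
                       ),
                       trait = c("viability", "fecundity"),
                       alternative = FALSE) {
  cfg <- fullPreset(odLevel, trait, alternative)
  cfg@nBase <- 200L
  cfg@burninGens <- 500L
  cfg@sampleSize <- 25L
  cfg@lineGens <- 100L
  cfg@nReplicates <- 5L
  cfg@reportInterval <- 25L
  cfg@sharedBase <- TRUE
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Top-level keys mirror the [runConfig()] arguments, with nested `scheme`,
#' `dfe` and `map` blocks and an optional `preset: full|desk` applied before
#' the explicit keys.  Unknown keys are rejected with their location;
#' invalid values are rejected by the class validity checks, which name the
#' offending field.
#'
#' @param path path to a YAML file.
#' @return a [RunConfig-class].
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  lst <- yaml::read_yaml(path)
  if (is.null(lst)) lst <- list()
  .configFromList(lst, where = path)
}

.fmtFull <- function(x) {
  if (is.double(x)) sprintf("%.17g", x) else as.character(x)
}

.writeTsv <- function(df, path, fullPrecision = FALSE) {
  out <- df
  if (fullPrecision) out <- as.data.frame(lapply(df, .fmtFull), check.names = FALSE)
  con <- file(path, open = "wb") # unix newlines on every platform
  on.exit(close(con))
  utils::write.table(out, con,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA", eol = "\n"
  )
  invisible(path)
}

#' Write a load-summary table
#'
#' Writes the canonical bottleneck-table layout (`t`, `n_del`, `q_del`,
#' `B_del`, `n_let`, `q_let`, `B_let`, `n_o`, `q_o`, `B_o`, `dW_pct`) as a
#' display TSV rounded to the conventional precision (counts 1 decimal,
#' frequencies and loads 2 decimals, fitness decline 1 decimal), together
#' with a full-precision companion file (`*_full.tsv`, `%.17g`, which
#' round-trips doubles exactly) carrying every column of `rows`.
#'
#' @param rows data.frame containing at least the canonical columns.
#' @param path output path of the display file.
#' @return invisibly, list with `display` and `full` paths.
#' @export
writeSummaryTable <- function(rows, path) {
  canon <- c(
    "t", "n_del", "q_del", "B_del", "n_let", "q_let", "B_let",
    "n_o", "q_o", "B_o", "dW_pct"
  )
  rows <- as.data.frame(rows)
  missing <- setdiff(canon, names(rows))
  if (length(missing)) {
    stop("rows lack required columns: ", paste(missing, collapse = ", "))
  }
  disp <- rows[, canon, drop = FALSE]
  rnd <- function(x, d) ifelse(is.na(x), NA, formatC(round(x, d), format = "f", digits = d))
  if (nrow(disp)) {
    disp$t <- as.integer(disp$t)
    for (col in c("n_del", "n_let", "n_o", "dW_pct")) disp[[col]] <- rnd(disp[[col]], 1)
    for (col in c("q_del", "B_del", "q_let", "B_let", "q_o", "B_o")) {
      disp[[col]] <- rnd(disp[[col]], 2)
    }
  }
  .writeTsv(disp, path)
  fullPath <- sub("(\\.[A-Za-z0-9]+)?$", "", path)
  fullPath <- paste0(fullPath, "_full.tsv")
  .writeTsv(rows, fullPath, fullPrecision = TRUE)
  invisible(list(display = path, full = fullPath))
}

#' Read back a full-precision summary table
#'
#' @param path the `*_full.tsv` file written by [writeSummaryTable()].
#' @return a data.frame with numeric columns.
#' @export
readSummaryTable <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
}

#' Snapshot a population to a text file
#'
#' Lossless plain-text serialisation of a [WFPopulation-class] (metadata,
#' registry and haplotypes; doubles as `%.17g`).  A restored population
#' continues a run exactly as the original would, given the same RNG state.
#'
#' @param pop a [WFPopulation-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
snapshotPopulation <- function(pop, path) {
  stopifnot(is(pop, "WFPopulation"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  meta <- jsonlite::toJSON(
    list(
      n = pop@n, generation = pop@generation, nextId = pop@nextId,
      wFixDel = .fmtFull(pop@wFixDel), odFixFactor = .fmtFull(pop@odFixFactor),
      nOFixed = pop@nOFixed, status = pop@status
    ),
    auto_unbox = TRUE
  )
  writeLines(c(
    paste0("#", .SNAPSHOT_VERSION),
    paste0("#meta ", as.character(meta)),
    "#registry"
  ), con, sep = "\n")
  reg <- pop@registry
  writeLines(paste(names(reg), collapse = "\t"), con, sep = "\n")
  if (nrow(reg)) {
    lines <- paste(reg$id, reg$class, .fmtFull(reg$s), .fmtFull(reg$h),
      .fmtFull(reg$pos), reg$birth, reg$count,
      sep = "\t"
    )
    writeLines(lines, con, sep = "\n")
  }
  writeLines("#haplotypes", con, sep = "\n")
  writeLines(
    vapply(pop@haplotypes, function(h) paste(h, collapse = " "), ""),
    con,
    sep = "\n"
  )
  invisible(path)
}

#' Restore a population from a snapshot
#'
#' @param path file written by [snapshotPopulation()].
#' @return a [WFPopulation-class].
#' @export
restorePopulation <- function(path) {
  if (!file.exists(path)) stop("snapshot file not found: ", path)
  lines <- readLines(path)
  if (!length(lines) || lines[1] != paste0("#", .SNAPSHOT_VERSION)) {
    stop(
      "not a readable population snapshot (expected version '",
      .SNAPSHOT_VERSION, "')"
    )
  }
  metaLine <- lines[2]
  if (!startsWith(metaLine, "#meta ")) stop("corrupt snapshot: missing metadata")
  meta <- jsonlite::fromJSON(sub("^#meta ", "", metaLine))
  iReg <- which(lines == "#registry")[1]
  iHap <- which(lines == "#haplotypes")[1]
  if (is.na(iReg) || is.na(iHap) || iHap < iReg) {
    stop("corrupt snapshot: missing sections")
  }
  regLines <- lines[(iReg + 1):(iHap - 1)]
  reg <- utils::read.table(
    text = paste(regLines, collapse = "\n"),
    header = TRUE, sep = "\t",
    colClasses = c(
      "integer", "integer", "numeric", "numeric", "numeric",
      "integer", "integer"
    )
  )
  hapLines <- lines[(iHap + 1):length(lines)]
  n <- as.integer(meta$n)
  if (length(hapLines) != 2L * n) {
    stop("corrupt snapshot: expected ", 2L * n, " haplotypes, found ", length(hapLines))
  }
  haps <- lapply(hapLines, function(x) {
    if (!nzchar(x)) integer(0) else as.integer(strsplit(x, " ", fixed = TRUE)[[1]])
  })
  new("WFPopulation",
    n = n, generation = as.integer(meta$generation), haplotypes = haps,
    registry = reg, nextId = as.integer(meta$nextId),
    wFixDel = as.numeric(meta$wFixDel),
    odFixFactor = as.numeric(meta$odFixFactor),
    nOFixed = as.integer(meta$nOFixed), status = as.character(meta$status)
  )
}

#' Write a JSON run manifest
#'
#' Records the fully resolved configuration, the seed-derivation contract
#' (replicate `r` seeds the RNG with `baseSeed + r`), the artifact version
#' and the output files with MD5 checksums.  [manifestConfig()] turns a
#' manifest back into the [RunConfig-class] that reproduces the run.
#'
#' @param path output JSON path.
#' @param cfg the [RunConfig-class] used.
#' @param experiment experiment label.
#' @param files character vector of produced files.
#' @return invisibly, `path`.
#' @export
writeManifest <- function(path, cfg, experiment = "run", files = character(0)) {
  stopifnot(is(cfg, "RunConfig"))
  info <- list(
    artifact = "odload",
    version = as.character(utils::packageVersion("odload")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    experiment = experiment,
    seedDerivation = "replicate r calls set.seed(baseSeed + r)",
    config = .configAsList(cfg),
    outputs = lapply(files, function(f) {
      list(
        file = basename(f),
        md5 = unname(tools::md5sum(f))
      )
    })
  )
  jsonlite::write_json(info, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Rebuild the run configuration recorded in a manifest
#'
#' @param path a JSON manifest written by [writeManifest()].
#' @return a [RunConfig-class].
#' @export
manifestConfig <- function(path) {
  info <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(info$config)) stop("manifest has no config block: ", path)
  .configFromList(info$config, where = path)
}
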