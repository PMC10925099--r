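defaultPipelineConfig <- function() {
  list(
    mu = 1.5e-8, LS = 1e7, ratio = 2.31,
    demographyTemplate = "three_epoch", demographyStarts = 10L,
    gridPoints = 2000L, cachePoints = 1000L,
    hScan = c(0, 0.05, 0.10, 0.15, 0.25, 0.35, 0.45, 0.50, 0.75, 1.0),
    hChoices = c(0, 0.05, 0.10, 0.15, 0.25, 0.35, 0.45, 0.50),
    deltaLL = 1.92, gammaStarts = 25L, hsStarts = 5L,
    seed = 1L, simulate = NULL, outDir = NULL)
}

pipelineConfigHash <- function(config, keys) {
  paste(vapply(keys, function(k)
    paste(format(config[[k]], digits = 12), collapse = ","),
    character(1)), collapse = ";")
}

#' Run the full dominance/DFE analysis pipeline
#'
#' Orchestrates the stages of the analysis on a synonymous /
#' nonsynonymous SFS pair: demography fit (synonymous), expected-SFS
#' cache construction for every dominance value in use, gamma and
#' discrete DFE fits with a profile scan over a global h, the per-bin
#' dominance-model sweep, the plausibility (1.92 LL units) and
#' monotonic-decay filters, Akaike-weight model averages for the three
#' model sets, and optional forward simulations of the fitted models.
#' Every stage is seeded (per-model seeds derive from the global seed
#' plus the model index) and logged via \code{message()}.
#'
#' @param synSfs,nonsynSfs observed \linkS4class{SFS} objects (or file
#'   paths readable by [readSFS()]).
#' @param config named list overriding entries of the default
#'   configuration (or a YAML file path): \code{mu}, \code{LS},
#'   \code{ratio}, \code{demographyTemplate}, \code{gridPoints},
#'   \code{cachePoints}, \code{hScan}, \code{hChoices}, \code{deltaLL},
#'   \code{gammaStarts}, \code{hsStarts}, \code{seed}, \code{simulate}
#'   (list with \code{models}, \code{reps}, \code{rescale},
#'   \code{chromosomes}), \code{outDir}.
#' @return list with the fitted demography, caches, gamma/discrete fits,
#'   profile tables, the model table, filtered model sets, the three
#'   model averages, and simulation summaries when requested.
#' @export
runPipeline <- function(synSfs, nonsynSfs, config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- modifyList(defaultPipelineConfig(), config)
  if (is.character(synSfs)) synSfs <- readSFS(synSfs)
  if (is.character(nonsynSfs)) nonsynSfs <- readSFS(nonsynSfs)
  outDir <- cfg$outDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  hash <- pipelineConfigHash(cfg, c("mu", "LS", "ratio",
                                    "demographyTemplate", "gridPoints",
                                    "cachePoints", "hScan", "hChoices",
                                    "deltaLL", "gammaStarts", "hsStarts",
                                    "seed"))
  hash <- paste(hash, sum(counts(synSfs)), sum(counts(nonsynSfs)), sep = ";")

  t0 <- proc.time()[3]
  stageLog <- function(fmt, ...)
    message(sprintf("[domfit %7.1fs] ", proc.time()[3] - t0),
            sprintf(fmt, ...))

  grid <- makeFrequencyGrid(as.integer(cfg$gridPoints))
  stageLog("fitting demography (%s, seed %d)", cfg$demographyTemplate,
           cfg$seed)
  demFit <- fitDemography(synSfs, template = cfg$demographyTemplate,
                          nStarts = cfg$demographyStarts, seed = cfg$seed,
                          mu = cfg$mu, LS = cfg$LS, ratio = cfg$ratio,
                          grid = grid)
  demo <- demFit@params$demography
  thetaNS <- demFit@params$thetaNS
  Nanc <- demFit@params$Nanc
  stageLog("thetaS = %.6g, Nanc = %.6g, LL = %.4f", demFit@params$thetaS,
           Nanc, demFit@LL)

  hNeeded <- sort(unique(c(0.5, cfg$hScan, cfg$hChoices)))
  n <- sampleSize(nonsynSfs)
  caches <- list()
  reused <- FALSE
  if (!is.null(outDir)) {
    hfile <- file.path(outDir, "config.hash")
    cfiles <- file.path(outDir, sprintf("cache_h%s.tsv", hNeeded))
    if (file.exists(hfile) && identical(readLines(hfile)[1], hash) &&
        all(file.exists(cfiles))) {
      stageLog("reusing %d cached expected-SFS grids", length(cfiles))
      caches <- lapply(cfiles, readSFSCache)
      reused <- TRUE
    }
  }
  if (!reused) {
    for (i in seq_along(hNeeded)) {
      stageLog("building expected-SFS cache %d/%d (h = %.2f)", i,
               length(hNeeded), hNeeded[i])
      caches[[i]] <- buildGridCache(hNeeded[i], demo, n, Nanc,
                                    nS = as.integer(cfg$cachePoints),
                                    grid = grid)
    }
    if (!is.null(outDir)) {
      for (i in seq_along(hNeeded))
        writeSFSCache(caches[[i]],
                      file.path(outDir, sprintf("cache_h%s.tsv", hNeeded[i])))
      writeLines(hash, file.path(outDir, "config.hash"))
    }
  }

  stageLog("gamma DFE fit (h = 0.5, %d starts)", cfg$gammaStarts)
  gammaFit <- fitDFE(nonsynSfs, caches, "gamma", dominanceMap(0.5),
                     thetaNS, nStarts = cfg$gammaStarts, seed = cfg$seed)
  stageLog("discrete DFE fit (h = 0.5)")
  discFit <- fitDFE(nonsynSfs, caches, "discrete", dominanceMap(0.5),
                    thetaNS, nStarts = cfg$gammaStarts, seed = cfg$seed)
  scanH <- cfg$hScan[cfg$hScan %in% hNeeded]
  stageLog("profile-h scans over %d values", length(scanH))
  gammaScan <- profileHScan(nonsynSfs, caches, "gamma", scanH, thetaNS,
                            nStarts = cfg$hsStarts, seed = cfg$seed)
  discScan <- profileHScan(nonsynSfs, caches, "discrete", scanH, thetaNS,
                           nStarts = cfg$hsStarts, seed = cfg$seed)

  maps <- enumerateHSModels(cfg$hChoices)
  stageLog("fitting %d per-bin dominance models (%d starts each)",
           length(maps), cfg$hsStarts)
  models <- fitHSModels(nonsynSfs, caches, maps, thetaNS,
                        nStarts = cfg$hsStarts, seed = cfg$seed)
  highLL <- plausibilityFilter(models, cfg$deltaLL)
  mono <- monotonicFilter(highLL)
  stageLog("model filters: %d fitted, %d high-LL, %d monotonic",
           length(models), length(highLL), length(mono))

  avgRow <- function(set, label) {
    av <- modelAverage(set)
    data.frame(set = label, nModels = length(set),
               t(setNames(av$proportions, paste0("p_", binNames))),
               t(setNames(av$h, paste0("h_", binNames))),
               overallH = av$overallH)
  }
  averages <- rbind(avgRow(models, "all"),
                    avgRow(highLL, "highLL"),
                    avgRow(mono, "monotonic"))

  sims <- NULL
  if (!is.null(cfg$simulate)) {
    sc <- cfg$simulate
    genome <- genomeModel(chromosomes = sc$chromosomes %||% 2L)
    sims <- lapply(sc$models, function(nm) {
      stageLog("simulating %s (%d replicates, rescale %g)", nm,
               sc$reps %||% 20L, sc$rescale %||% 10)
      res <- simulateReplicates(genome, outOfAfricaDemography(),
                                dominanceModel(nm),
                                reps = sc$reps %||% 20L,
                                rescale = sc$rescale %||% 10,
                                seed = cfg$seed)
      projectToGenome(res, chromosomes = sc$chromosomes %||% 2L)
    })
    names(sims) <- sc$models
  }

  tab <- hsModelTable(models)
  if (!is.null(outDir)) {
    write.table(tab, file.path(outDir, "models.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    write.table(averages, file.path(outDir, "model_averages.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(gammaScan, file.path(outDir, "profile_gamma.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(discScan, file.path(outDir, "profile_discrete.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(sims))
      for (nm in names(sims))
        write.table(simStats(sims[[nm]]),
                    file.path(outDir, sprintf("sim_%s.tsv", nm)),
                    sep = "\t", row.names = FALSE, quote = FALSE)
  }
  stageLog("pipeline complete")
  list(demography = demFit, caches = caches, gammaFit = gammaFit,
       discreteFit = discFit, gammaScan = gammaScan, discScan = discScan,
       models = models, modelTable = tab, highLL = highLL,
       monotonic = mono, averages = averages, simulations = sims,
       seed = cfg$seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
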