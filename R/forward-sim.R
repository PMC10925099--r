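#' Draw mutation fitness effects from a simulation model
#'
#' Samples (s, h) pairs: the bin is chosen by the mixture proportions, s is
#' uniform on the bin's linear interval, h is the bin's dominance value.
#' (Simulation convention, un-rescaled.)
#'
#' @param model a \linkS4class{SimDominanceModel}.
#' @param nDraws number of draws.
#' @param seed optional integer seed (uses R's RNG).
#' @return data.frame with columns \code{bin}, \code{s}, \code{h}.
#' @export
drawMutationEffects <- function(model, nDraws, seed = NULL) {
  stopifnot(is(model, "SimDominanceModel"))
  if (!is.null(seed)) set.seed(seed)
  e <- model@dfe@edges
  b <- sample.int(5L, nDraws, replace = TRUE, prob = model@dfe@proportions)
  s <- runif(nDraws, e[b], e[b + 1L])
  data.frame(bin = b, s = s, h = model@hmap@h[b])
}

#' Forward Wright-Fisher simulation of deleterious variation
#'
#' Simulates the genome model through the demographic schedule under the
#' given DFE/dominance model, with optional population-size rescaling for
#' desk-scale runs: sizes and durations are divided by \code{rescale},
#' while mutation rates, selection coefficients (capped at s = 1) and
#' gene-boundary recombination are multiplied by it.  A burn-in of
#' \code{10 N_anc / rescale} generations at the ancestral size precedes
#' the schedule.  At the final generation a sample of
#' \code{sampleSize} individuals per population is scored for genetic
#' load, inbreeding load B and derived-allele count; the reported values
#' are de-rescaled back to natural units (B and log-fitness scale with
#' the rescaling factor), so results are invariant to the choice of
#' \code{rescale} up to resolution noise.
#'
#' @param genome a \linkS4class{GenomeModel}.
#' @param demography a \linkS4class{TwoPopDemography}.
#' @param model a \linkS4class{SimDominanceModel}.
#' @param rescale rescaling factor \eqn{\lambda \ge 1}.
#' @param burnIn burn-in generations (default \code{10 N_anc / rescale}).
#' @param sampleSize individuals sampled per population (100).
#' @param seed integer seed; runs are bit-reproducible given the seed.
#' @param sweepEvery fixation-sweep interval in generations.
#' @param keepSample if \code{TRUE}, attach the per-population
#'   \linkS4class{SampleGenotypes} as attribute \code{"samples"}.
#' @return a \linkS4class{SimResult} with one row per population.
#' @export
simulateLoad <- function(genome, demography, model, rescale = 1,
                         burnIn = NULL, sampleSize = 100L, seed = 1,
                         sweepEvery = 25L, keepSample = FALSE) {
  stopifnot(is(genome, "GenomeModel"), is(demography, "TwoPopDemography"),
            is(model, "SimDominanceModel"), rescale >= 1)
  sched <- sizeSchedule(demography, rescale, burnIn)
  live <- c(sched$nAfr, sched$nEur[sched$nEur > 0])
  if (any(live < 50))
    stop("rescaling leaves a deme below 50 diploids; reduce rescale")
  res <- .forwardSimulate(
    genome@genesPerChrom, genome@geneLength,
    genome@mutRate * rescale,
    min(0.5, genome@recombBetweenGenes * rescale),
    sched$nAfr, sched$nEur,
    model@dfe@proportions, model@dfe@edges[1:5], model@dfe@edges[2:6],
    model@hmap@h, rescale, as.integer(sampleSize), as.double(seed),
    as.integer(sweepEvery))
  oneRow <- function(raw, popName) {
    sg <- new("SampleGenotypes", geno = raw$geno, s = raw$s, h = raw$h,
              fixedS = raw$fixed_s, fixedH = raw$fixed_h)
    loadRaw <- geneticLoad(sg)
    data.frame(replicate = 1L, population = popName,
               load = 1 - (1 - loadRaw)^(1 / rescale),
               B = inbreedingLoad(sg) / rescale,
               count = derivedAlleleCount(sg),
               projected = FALSE)
  }
  stats <- oneRow(res$afr, "AFR")
  samples <- list(AFR = res$afr)
  if (!is.null(res$eur)) {
    stats <- rbind(stats, oneRow(res$eur, "EUR"))
    samples$EUR <- res$eur
  }
  out <- new("SimResult", stats = stats, lambda = rescale, factor = 1,
             seed = seed)
  if (keepSample) attr(out, "samples") <- samples
  out
}

#' Replicated forward simulations
#'
#' Runs [simulateLoad()] for \code{reps} replicates with derived seeds and
#' row-binds the per-population results.
#'
#' @inheritParams simulateLoad
#' @param reps number of replicates.
#' @return a \linkS4class{SimResult}.
#' @export
simulateReplicates <- function(genome, demography, model, reps = 20L,
                               rescale = 1, burnIn = NULL,
                               sampleSize = 100L, seed = 1,
                               sweepEvery = 25L) {
  rows <- lapply(seq_len(reps), function(r) {
    one <- simulateLoad(genome, demography, model, rescale = rescale,
                        burnIn = burnIn, sampleSize = sampleSize,
                        seed = seed * 1000 + r, sweepEvery = sweepEvery)
    st <- one@stats
    st$replicate <- r
    st
  })
  new("SimResult", stats = do.call(rbind, rows), lambda = rescale,
      factor = 1, seed = seed)
}
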