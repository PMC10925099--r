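#' Coding-genome model for the forward simulator
#'
#' The default models the human exome as 22,500 genes of 1,340 bp on 22
#' autosomes (30.16 Mb), a deleterious (nonsynonymous) mutation rate of
#' 1.05e-8 per site per generation (1.5e-8 x 2.31/3.31), a crossover
#' probability of 1e-3 per between-gene boundary per meiosis, free
#' recombination between chromosomes and none within genes.  Subsets of
#' chromosomes carry a proportional share of the genes (2 chromosomes:
#' 1,023 + 1,022 = 2,045 genes).
#'
#' @param chromosomes number of autosomes to simulate (1..22).
#' @param totalGenes genes in the full 22-autosome genome.
#' @param geneLength gene length in bp.
#' @param recombBetweenGenes per-boundary crossover probability.
#' @param mutRate deleterious mutation rate per site per generation.
#' @param genesPerChrom explicit gene counts per chromosome, overriding
#'   the proportional-share rule (validation genomes).
#' @return a \linkS4class{GenomeModel}.
#' @export
genomeModel <- function(chromosomes = 22L, totalGenes = 22500L,
                        geneLength = 1340, recombBetweenGenes = 1e-3,
                        mutRate = 1.05e-8, genesPerChrom = NULL) {
  if (!is.null(genesPerChrom)) {
    return(new("GenomeModel", genesPerChrom = as.integer(genesPerChrom),
               geneLength = geneLength,
               recombBetweenGenes = recombBetweenGenes, mutRate = mutRate))
  }
  chromosomes <- as.integer(chromosomes)
  if (chromosomes < 1L || chromosomes > 22L)
    stop("chromosomes must be between 1 and 22")
  tot <- round(totalGenes * chromosomes / 22)
  base <- tot %/% chromosomes
  extra <- tot %% chromosomes
  gpc <- rep(base, chromosomes) + c(rep(1L, extra),
                                    rep(0L, chromosomes - extra))
  new("GenomeModel", genesPerChrom = as.integer(gpc),
      geneLength = geneLength, recombBetweenGenes = recombBetweenGenes,
      mutRate = mutRate)
}

#' Two-population out-of-Africa demographic model
#'
#' The two-population African/European history inferred by Tennessen and
#' colleagues from large resequencing samples: an ancestral size of 7,310
#' diploids, African growth to 14,474 at 5,920 generations before present,
#' European divergence 2,040 generations ago into a bottleneck of 1,861
#' for 1,120 generations, a first European growth phase (1,032 growing to
#' 9,300) until 205 generations ago, and recent exponential growth to
#' 424,000 (Africa) and 512,000 (Europe).
#'
#' @param Nanc,NafrGrowth,Nbot,Neu0,Neu1,NafrFinal,NeuFinal diploid sizes.
#' @param Tafr,Tsplit,Tbot,Tgrowth times in generations before present
#'   (Tbot is the bottleneck duration).
#' @return a \linkS4class{TwoPopDemography}.
#' @export
outOfAfricaDemography <- function(Nanc = 7310, NafrGrowth = 14474,
                                  Tafr = 5920, Tsplit = 2040, Nbot = 1861,
                                  Tbot = 1120, Neu0 = 1032, Neu1 = 9300,
                                  Tgrowth = 205, NafrFinal = 424000,
                                  NeuFinal = 512000) {
  new("TwoPopDemography",
      params = c(Nanc = Nanc, NafrGrowth = NafrGrowth, Tafr = Tafr,
                 Tsplit = Tsplit, Nbot = Nbot, Tbot = Tbot, Neu0 = Neu0,
                 Neu1 = Neu1, Tgrowth = Tgrowth, NafrFinal = NafrFinal,
                 NeuFinal = NeuFinal))
}

#' Single-population constant-size demography
#'
#' Convenience for equilibrium simulations (validation runs): one
#' population of constant size and no European deme.
#'
#' @param N diploid size.
#' @return a \linkS4class{TwoPopDemography} degenerate to one population.
#' @export
constantDemography <- function(N) {
  new("TwoPopDemography",
      params = c(Nanc = N, NafrGrowth = N, Tafr = 1, Tsplit = 0, Nbot = N,
                 Tbot = 0, Neu0 = N, Neu1 = N, Tgrowth = 0, NafrFinal = N,
                 NeuFinal = N))
}

# per-generation diploid size schedule after rescaling by lambda;
# returns list(nAfr, nEur, burnIn) with generation 0 the founding one
sizeSchedule <- function(demo, lambda, burnIn = NULL) {
  p <- demo@params
  rs <- function(N) max(1L, as.integer(round(N / lambda)))
  rt <- function(g) as.integer(round(g / lambda))
  NancR <- rs(p["Nanc"])
  if (is.null(burnIn)) burnIn <- 10L * NancR
  Tafr <- rt(p["Tafr"]); Tsplit <- rt(p["Tsplit"]); T1 <- rt(p["Tsplit"] - p["Tbot"])
  Tg <- rt(p["Tgrowth"])
  total <- burnIn + Tafr
  g <- total - seq.int(0, total)          # generations before present
  nAfr <- integer(total + 1L)
  nEur <- integer(total + 1L)
  for (i in seq_along(g)) {
    gb <- g[i]
    nAfr[i] <- if (gb >= Tafr) NancR
      else if (gb > Tg) rs(p["NafrGrowth"])
      else rs(p["NafrGrowth"] * (p["NafrFinal"] / p["NafrGrowth"])^((Tg - gb) / max(Tg, 1)))
    nEur[i] <- if (gb >= Tsplit || Tsplit == 0L) 0L
      else if (gb >= T1) rs(p["Nbot"])
      else if (gb > Tg) rs(p["Neu0"] * (p["Neu1"] / p["Neu0"])^((T1 - gb) / max(T1 - Tg, 1)))
      else rs(p["Neu1"] * (p["NeuFinal"] / p["Neu1"])^((Tg - gb) / max(Tg, 1)))
  }
  list(nAfr = nAfr, nEur = nEur, burnIn = burnIn)
}

#' Published DFE and dominance models for simulation
#'
#' The three discrete-DFE/dominance combinations used to simulate
#' deleterious variation, spanning weakly to strongly recessive dominance
#' of the most deleterious mutations (simulation convention bins; the
#' printed proportions are renormalized to sum exactly to 1).
#'
#' @param name one of \code{"weakly_recessive"},
#'   \code{"moderately_recessive"}, \code{"strongly_recessive"}.
#' @return a \linkS4class{SimDominanceModel}.
#' @examples
#' m <- dominanceModel("weakly_recessive")
#' averageH(m@dfe, m@hmap)  # ~0.40
#' @export
dominanceModel <- function(name = c("weakly_recessive",
                                    "moderately_recessive",
                                    "strongly_recessive")) {
  name <- match.arg(name)
  par <- switch(name,
    weakly_recessive = list(p = c(0.259, 0.125, 0.176, 0.254, 0.186),
                            h = c(0.5, 0.5, 0.5, 0.35, 0.15)),
    moderately_recessive = list(p = c(0.244, 0.152, 0.125, 0.259, 0.22),
                                h = c(0.5, 0.5, 0.45, 0.25, 0.1)),
    strongly_recessive = list(p = c(0.201, 0.222, 0.018, 0.286, 0.274),
                              h = c(0.5, 0.45, 0.25, 0.15, 0.05)))
  new("SimDominanceModel",
      dfe = discreteDFE(par$p / sum(par$p), convention = "simulation"),
      hmap = dominanceMap(par$h), name = name)
}

#' Arbitrary simulation-convention DFE/dominance model
#'
#' @param proportions numeric(5) bin proportions (simulation convention).
#' @param h numeric(5) per-bin dominance.
#' @param name optional label.
#' @param edges optional custom bin edges (validation runs).
#' @return a \linkS4class{SimDominanceModel}.
#' @export
simDominanceModel <- function(proportions, h, name = "custom",
                              edges = NULL) {
  new("SimDominanceModel",
      dfe = discreteDFE(proportions, convention = "simulation",
                        edges = edges),
      hmap = dominanceMap(h), name = name)
}
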