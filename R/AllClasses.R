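#' @useDynLib domfit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats dbinom dpois integrate lfactorial nlminb pgamma rpois runif
#'   setNames splinefun
#' @importFrom utils read.table write.table modifyList
NULL

#' Site frequency spectrum
#'
#' Container for a (possibly folded) site frequency spectrum: a vector of
#' variant counts indexed by derived (or minor) allele count \eqn{i = 0..n}
#' for a haploid sample size \eqn{n}.  Entries 0 and \eqn{n} are always
#' masked; for a folded spectrum all entries above \eqn{n/2} are masked as
#' well.  Counts are stored as reals because expected spectra are
#' non-integer; observed spectra are integer-valued.
#'
#' @slot counts numeric vector of length \code{n + 1}.
#' @slot n haploid sample size.
#' @slot folded logical; \code{TRUE} if the spectrum tabulates minor-allele
#'   counts.
#' @slot mask logical vector of length \code{n + 1}; \code{TRUE} entries are
#'   excluded from all likelihood sums.
#' @export
setClass("SFS",
  representation(counts = "numeric", n = "integer", folded = "logical",
                 mask = "logical"),
  validity = function(object) {
    msg <- character()
    n <- object@n
    if (length(n) != 1L || n < 2L)
      msg <- c(msg, "n must be a single integer >= 2")
    if (length(object@counts) != n + 1L)
      msg <- c(msg, sprintf("counts must have length n + 1 = %d", n + 1L))
    if (length(object@mask) != n + 1L)
      msg <- c(msg, "mask must have length n + 1")
    if (length(object@folded) != 1L)
      msg <- c(msg, "folded must be a single logical")
    if (!length(msg)) {
      if (!object@mask[1L] || !object@mask[n + 1L])
        msg <- c(msg, "entries 0 and n must be masked")
      if (any(!is.finite(object@counts[!object@mask])))
        msg <- c(msg, "unmasked counts must be finite")
      else if (any(object@counts[!object@mask] < 0))
        msg <- c(msg, "unmasked counts must be >= 0")
      if (object@folded) {
        hi <- seq.int(floor(n / 2) + 2L, n + 1L)
        if (any(object@counts[hi] != 0))
          msg <- c(msg, "folded spectra must have zero counts above n/2")
        if (any(!object@mask[hi]))
          msg <- c(msg, "folded spectra must mask entries above n/2")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' Synonymous / nonsynonymous site counts
#'
#' Number of synonymous sites \eqn{L_S}, nonsynonymous sites \eqn{L_{NS}},
#' and their ratio (2.31 for the human exome data the pipeline targets).
#'
#' @slot LS,LNS,ratio positive numerics.
#' @export
setClass("SiteCounts",
  representation(LS = "numeric", LNS = "numeric", ratio = "numeric"),
  validity = function(object) {
    if (any(c(object@LS, object@LNS, object@ratio) <= 0))
      return("all site counts must be positive")
    TRUE
  })

#' Piecewise demographic history for one population
#'
#' Ordered epochs of relative population size \eqn{\nu = N/N_{anc}}.
#' Durations are in units of \eqn{2 N_{anc}} generations.  An implicit
#' equilibrium epoch at \eqn{\nu = 1} precedes the first listed epoch.
#' Constant epochs have \code{nu0 == nu1}; exponential epochs interpolate
#' \eqn{\nu} geometrically from \code{nu0} to \code{nu1}.
#'
#' @slot epochs data.frame with columns \code{nu0}, \code{nu1}, \code{tau},
#'   \code{mode} (\code{"constant"} or \code{"exponential"}).
#' @export
setClass("EpochModel",
  representation(epochs = "data.frame"),
  validity = function(object) {
    e <- object@epochs
    need <- c("nu0", "nu1", "tau", "mode")
    if (!all(need %in% names(e)))
      return("epochs needs columns nu0, nu1, tau, mode")
    if (nrow(e)) {
      if (any(e$nu0 <= 0) || any(e$nu1 <= 0)) return("nu must be > 0")
      if (any(e$tau < 0)) return("durations must be >= 0")
      if (!all(e$mode %in% c("constant", "exponential")))
        return("mode must be 'constant' or 'exponential'")
      if (any(e$mode == "constant" & e$nu0 != e$nu1))
        return("constant epochs must have nu0 == nu1")
    }
    TRUE
  })

#' Selection and dominance parameters for a single mutation class
#'
#' Inference convention: the mutant homozygote has fitness \eqn{1 - 2s} and
#' the heterozygote \eqn{1 - 2sh}; deleterious \eqn{s} is positive with
#' \eqn{s = 0.5} lethal.  \code{gamma} is the population-scaled coefficient
#' \eqn{\gamma = 2 N_{anc} s}.
#'
#' @slot gamma scaled selection coefficient \eqn{2 N_{anc} s}.
#' @slot h dominance coefficient in \eqn{[0, 1]}.
#' @export
setClass("SelectionParams",
  representation(gamma = "numeric", h = "numeric"),
  validity = function(object) {
    if (length(object@gamma) != 1L || length(object@h) != 1L)
      return("gamma and h must be scalars")
    if (!is.finite(object@gamma)) return("gamma must be finite")
    if (object@h < 0 || object@h > 1) return("h must be in [0, 1]")
    TRUE
  })

#' Allele-frequency density on a grid
#'
#' Density of mutant-allele frequency per unit frequency, on an ordered grid
#' of interior frequencies, scaled so that the neutral constant-size
#' equilibrium at unit mutation rate is \eqn{1/q}.
#'
#' @slot grid strictly increasing frequencies in (0, 1).
#' @slot values non-negative density values.
#' @export
setClass("FrequencyDensity",
  representation(grid = "numeric", values = "numeric"),
  validity = function(object) {
    if (length(object@grid) != length(object@values))
      return("grid and values must have equal length")
    if (any(object@grid <= 0) || any(object@grid >= 1))
      return("grid must lie strictly inside (0, 1)")
    if (is.unsorted(object@grid, strictly = TRUE))
      return("grid must be strictly increasing")
    if (any(!is.finite(object@values)))
      return("density values must be finite")
    TRUE
  })

#' Gamma distribution of fitness effects
#'
#' Shape/scale parameterization; the scale is in unscaled \eqn{s} units
#' (i.e. already divided by \eqn{2 N_{anc}}).
#'
#' @slot shape,scale positive numerics.
#' @export
setClass("GammaDFE",
  representation(shape = "numeric", scale = "numeric"),
  validity = function(object) {
    if (object@shape <= 0 || object@scale <= 0)
      return("shape and scale must be > 0")
    TRUE
  })

#' Discrete five-bin distribution of fitness effects
#'
#' Mixture proportions over five selection-coefficient bins.  In the
#' inference convention the bin edges are
#' \eqn{0 < |s| \le 10^{-5}} (neutral), \eqn{10^{-5} < |s| \le 10^{-4}}
#' (nearly neutral), \eqn{10^{-4} < |s| \le 10^{-3}} (weakly deleterious),
#' \eqn{10^{-3} < |s| \le 10^{-2}} (moderately deleterious) and
#' \eqn{10^{-2} < |s| \le 0.5} (strongly deleterious).  The simulation
#' convention (homozygote fitness \eqn{1 - s}) doubles every edge.
#'
#' @slot proportions numeric(5) summing to 1.
#' @slot edges numeric(6) of increasing bin edges (first edge 0).
#' @export
setClass("DiscreteDFE",
  representation(proportions = "numeric", edges = "numeric"),
  validity = function(object) {
    p <- object@proportions
    if (length(p) != 5L) return("proportions must have length 5")
    if (any(p < -1e-12) || any(p > 1 + 1e-12))
      return("proportions must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-8) return("proportions must sum to 1")
    if (length(object@edges) != 6L || is.unsorted(object@edges, strictly = TRUE))
      return("edges must be 6 increasing values")
    TRUE
  })

#' Per-bin dominance coefficients
#'
#' One dominance coefficient per bin of the discrete DFE (a global-h map
#' repeats the same value five times).
#'
#' @slot h numeric(5) of dominance coefficients in [0, 1].
#' @export
setClass("DominanceMap",
  representation(h = "numeric"),
  validity = function(object) {
    if (length(object@h) != 5L) return("h must have length 5")
    if (any(object@h < 0) || any(object@h > 1)) return("h must be in [0, 1]")
    TRUE
  })

#' A fitted discrete-DFE + dominance model
#'
#' @slot dfe a \linkS4class{DiscreteDFE}.
#' @slot hmap a \linkS4class{DominanceMap}.
#' @slot LL fitted Poisson log-likelihood.
#' @slot AIC Akaike information criterion, \eqn{2k - 2 LL} with \eqn{k = 4}.
#' @export
setClass("HSModel",
  representation(dfe = "DiscreteDFE", hmap = "DominanceMap",
                 LL = "numeric", AIC = "numeric"))

#' Cache of expected spectra on a log-spaced selection grid
#'
#' Unit-\eqn{\theta} unfolded expected spectra for a single dominance value,
#' demography and sample size, on a log-spaced grid of (unscaled) selection
#' coefficients.
#'
#' @slot s log-spaced selection coefficients.
#' @slot spectra matrix with \code{length(s)} rows and \code{n + 1} columns.
#' @slot neutral unit-\eqn{\theta} expected spectrum at \eqn{\gamma = 0}
#'   under the same demography (receives the DFE mass below the grid).
#' @slot h dominance coefficient of the cache.
#' @slot n haploid sample size.
#' @slot Nanc ancestral diploid size used to scale \eqn{\gamma = 2 N_{anc} s}.
#' @slot demogHash digest of the demographic model the cache conditions on.
#' @export
setClass("SFSCache",
  representation(s = "numeric", spectra = "matrix", neutral = "numeric",
                 n = "integer", h = "numeric", Nanc = "numeric",
                 demogHash = "character"),
  validity = function(object) {
    if (nrow(object@spectra) != length(object@s))
      return("spectra must have one row per s value")
    if (ncol(object@spectra) != object@n + 1L)
      return("spectra must have n + 1 columns")
    if (length(object@neutral) != object@n + 1L)
      return("neutral spectrum must have n + 1 entries")
    TRUE
  })

#' Result of a maximum-likelihood fit
#'
#' @slot params named list of parameter estimates.
#' @slot LL maximized Poisson log-likelihood.
#' @slot k number of free parameters.
#' @slot AIC \eqn{2k - 2 LL}.
#' @slot converged logical convergence flag.
#' @slot nStarts number of optimizer starts used.
#' @slot seed integer seed that drove the starts.
#' @export
setClass("FitResult",
  representation(params = "list", LL = "numeric", k = "numeric",
                 AIC = "numeric", converged = "logical", nStarts = "numeric",
                 seed = "numeric"),
  validity = function(object) {
    if (is.finite(object@LL) &&
        abs(object@AIC - (2 * object@k - 2 * object@LL)) > 1e-6)
      return("AIC must equal 2k - 2 LL")
    TRUE
  })

#' Genotypes of a simulated sample
#'
#' Per-individual genotypes (0/1/2 copies of the derived allele) at sites
#' segregating in the source population, with per-site selection and
#' dominance coefficients (simulation convention: homozygote fitness
#' \eqn{1 - s}, heterozygote \eqn{1 - sh}), plus the fitness effects of
#' sites fixed in the population.
#'
#' @slot geno integer matrix, sites x individuals, entries in {0, 1, 2}.
#' @slot s,h per-site selection and dominance coefficients.
#' @slot fixedS,fixedH coefficients of fixed sites.
#' @export
setClass("SampleGenotypes",
  representation(geno = "matrix", s = "numeric", h = "numeric",
                 fixedS = "numeric", fixedH = "numeric"),
  validity = function(object) {
    if (nrow(object@geno) != length(object@s) ||
        nrow(object@geno) != length(object@h))
      return("one s and h per genotype row required")
    if (length(object@fixedS) != length(object@fixedH))
      return("fixedS and fixedH must have equal length")
    if (length(object@geno) && !all(object@geno %in% 0:2))
      return("genotypes must be 0, 1 or 2")
    TRUE
  })

#' Coding-genome model for forward simulation
#'
#' Genes of equal length arranged on autosomes; free recombination between
#' chromosomes, a fixed crossover probability at each between-gene boundary,
#' and no recombination within genes.
#'
#' @slot genesPerChrom integer vector of gene counts per chromosome.
#' @slot geneLength gene length in bp.
#' @slot recombBetweenGenes per-boundary crossover probability per meiosis.
#' @slot mutRate deleterious mutation rate per site per generation.
#' @export
setClass("GenomeModel",
  representation(genesPerChrom = "integer", geneLength = "numeric",
                 recombBetweenGenes = "numeric", mutRate = "numeric"),
  validity = function(object) {
    if (any(object@genesPerChrom < 1L)) return("need >= 1 gene per chromosome")
    if (object@recombBetweenGenes < 0 || object@recombBetweenGenes > 0.5)
      return("per-boundary recombination must be in [0, 0.5]")
    if (object@geneLength <= 0 || object@mutRate <= 0)
      return("geneLength and mutRate must be > 0")
    TRUE
  })

#' Two-population out-of-Africa demographic schedule
#'
#' Diploid population sizes on a per-generation schedule for an African and
#' a European deme, described by named parameters (sizes in diploids, times
#' in generations before present).
#'
#' @slot params named numeric vector of sizes and times.
#' @export
setClass("TwoPopDemography",
  representation(params = "numeric"),
  validity = function(object) {
    need <- c("Nanc", "NafrGrowth", "Tafr", "Tsplit", "Nbot", "Tbot",
              "Neu0", "Neu1", "Tgrowth", "NafrFinal", "NeuFinal")
    if (!all(need %in% names(object@params)))
      return(paste("params must contain:", paste(need, collapse = ", ")))
    p <- object@params
    if (any(p[c("Nanc", "NafrGrowth", "Nbot", "Neu0", "Neu1", "NafrFinal",
                "NeuFinal")] <= 0))
      return("population sizes must be positive")
    if (p["Tsplit"] < p["Tbot"] + 0 || p["Tafr"] < p["Tsplit"])
      return("generation schedule inconsistent")
    TRUE
  })

#' DFE + dominance model in the simulation convention
#'
#' @slot dfe a \linkS4class{DiscreteDFE} with simulation-convention edges
#'   (double the inference-convention edges; strongest bin up to s = 1).
#' @slot hmap a \linkS4class{DominanceMap}.
#' @slot name optional model label.
#' @export
setClass("SimDominanceModel",
  representation(dfe = "DiscreteDFE", hmap = "DominanceMap", name = "character"))

#' Forward-simulation results
#'
#' Per-replicate, per-population genetic load, inbreeding load B (haploid
#' lethal equivalents) and mean derived-allele count per individual, in
#' natural (de-rescaled) units, plus the rescaling factor and seeds used.
#'
#' @slot stats data.frame with columns replicate, population, load, B,
#'   count, projected.
#' @slot lambda rescaling factor applied during simulation.
#' @slot factor genome projection factor applied (1 if none).
#' @slot seed integer seed of the run.
#' @export
setClass("SimResult",
  representation(stats = "data.frame", lambda = "numeric",
                 factor = "numeric", seed = "numeric"),
  validity = function(object) {
    need <- c("replicate", "population", "load", "B", "count")
    if (!all(need %in% names(object@stats)))
      return("stats needs columns replicate, population, load, B, count")
    st <- object@stats
    if (nrow(st)) {
      if (any(st$load < 0 | st$load > 1)) return("load must lie in [0, 1]")
      if (any(st$B < 0)) return("B must be >= 0")
      if (any(st$count < 0)) return("counts must be >= 0")
    }
    TRUE
  })

#' Specification of a synthetic SFS dataset
#'
#' @slot demography an \linkS4class{EpochModel}.
#' @slot dfe a \linkS4class{GammaDFE} or \linkS4class{DiscreteDFE}.
#' @slot hmap a \linkS4class{DominanceMap}.
#' @slot thetaS synonymous population-scaled mutation rate.
#' @slot ratio nonsynonymous/synonymous length ratio (2.31).
#' @slot n haploid sample size (864 emulates the study data).
#' @slot Nanc ancestral diploid size used to scale gamma.
#' @slot seed integer seed.
#' @export
setClass("SyntheticSpec",
  representation(demography = "EpochModel", dfe = "ANY", hmap = "DominanceMap",
                 thetaS = "numeric", ratio = "numeric", n = "integer",
                 Nanc = "numeric", seed = "numeric"),
  validity = function(object) {
    if (object@thetaS <= 0) return("thetaS must be > 0")
    if (object@n %% 2L != 0L) return("n must be even so spectra can be folded")
    if (!(is(object@dfe, "GammaDFE") || is(object@dfe, "DiscreteDFE")))
      return("dfe must be a GammaDFE or DiscreteDFE")
    TRUE
  })
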