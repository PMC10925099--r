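#' Specification of a synthetic SFS dataset
#'
#' Defines the generating conditions for a synthetic
#' synonymous/nonsynonymous spectrum pair with the statistical structure
#' the PRF inference assumes: a demography, a DFE with per-bin dominance,
#' \eqn{\theta_S}, the 2.31 nonsynonymous/synonymous length ratio, and a
#' sample size of 864 chromosomes (432 diploids) by default, emulating
#' the European-ancestry exome data the pipeline targets.
#'
#' @param demography an \linkS4class{EpochModel}.
#' @param dfe a \linkS4class{GammaDFE} or \linkS4class{DiscreteDFE}.
#' @param hmap a \linkS4class{DominanceMap}.
#' @param thetaS synonymous mutation-rate scale (study scale is tens of
#'   thousands).
#' @param ratio nonsynonymous/synonymous ratio.
#' @param n haploid sample size (even).
#' @param Nanc ancestral diploid size scaling \eqn{\gamma = 2 N_{anc} s}.
#' @param seed integer seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @export
syntheticSpec <- function(demography, dfe, hmap, thetaS = 20000,
                          ratio = 2.31, n = 864L, Nanc = 20000,
                          seed = 1L) {
  new("SyntheticSpec", demography = demography, dfe = dfe, hmap = hmap,
      thetaS = thetaS, ratio = ratio, n = as.integer(n), Nanc = Nanc,
      seed = seed)
}

#' Poisson-sample an observed SFS around its expectation
#'
#' Each unmasked entry is drawn independently from a Poisson distribution
#' with the expected entry as its mean (the PRF sampling model).
#'
#' @param expected an expected \linkS4class{SFS}.
#' @param seed integer seed (R RNG; deterministic given the seed).
#' @return an observed \linkS4class{SFS} with integer counts.
#' @export
poissonSampleSFS <- function(expected, seed = NULL) {
  stopifnot(is(expected, "SFS"))
  if (!is.null(seed)) set.seed(seed)
  cts <- expected@counts
  idx <- which(!expected@mask)
  cts[idx] <- rpois(length(idx), cts[idx])
  sfs(cts, folded = expected@folded, mask = expected@mask)
}

#' Generate a synthetic synonymous/nonsynonymous dataset
#'
#' The synonymous spectrum is Poisson-sampled around the neutral
#' expectation at \eqn{\theta_S} under the demography; the nonsynonymous
#' spectrum around the DFE/dominance mixture at
#' \eqn{\theta_{NS} = r \theta_S}.  Both are folded.  The truth record
#' stores every generating parameter and round-trips through YAML.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param caches optional list of \linkS4class{SFSCache}s for the h values
#'   in \code{spec@hmap}; built on the fly if missing.
#' @param nS,grid cache-build controls (see [buildGridCache()]).
#' @return list with elements \code{syn}, \code{nonsyn} (observed
#'   \linkS4class{SFS}), \code{expectedSyn}, \code{expectedNonsyn} and
#'   \code{truth}.
#' @export
makeDataset <- function(spec, caches = NULL, nS = 200L,
                        grid = makeFrequencyGrid(400L)) {
  stopifnot(is(spec, "SyntheticSpec"))
  demo <- spec@demography
  n <- spec@n
  neutral <- expectedSFS(demo, selectionParams(h = 0.5, gamma = 0), n,
                         grid = grid, maxRefine = 0L)
  expSyn <- foldSFS(sfs(spec@thetaS * counts(neutral)))
  if (is.null(caches)) {
    hs <- unique(spec@hmap@h)
    caches <- lapply(hs, function(h)
      buildGridCache(h, demo, n, spec@Nanc, nS = nS, grid = grid,
                     maxRefine = 0L))
  }
  thetaNS <- spec@ratio * spec@thetaS
  expNS <- foldSFS(mixtureExpectedSFS(spec@dfe, spec@hmap, caches, thetaNS))
  syn <- poissonSampleSFS(expSyn, seed = spec@seed)
  nonsyn <- poissonSampleSFS(expNS, seed = spec@seed + 1L)
  truth <- list(
    thetaS = spec@thetaS, thetaNS = thetaNS, ratio = spec@ratio,
    n = n, Nanc = spec@Nanc, seed = spec@seed,
    demography = list(nu0 = demo@epochs$nu0, nu1 = demo@epochs$nu1,
                      tau = demo@epochs$tau, mode = demo@epochs$mode),
    dfe = if (is(spec@dfe, "GammaDFE"))
      list(family = "gamma", shape = spec@dfe@shape, scale = spec@dfe@scale)
    else list(family = "discrete",
              proportions = spec@dfe@proportions),
    h = spec@hmap@h)
  list(syn = syn, nonsyn = nonsyn, expectedSyn = expSyn,
       expectedNonsyn = expNS, truth = truth)
}

#' Write / read a synthetic-truth record as YAML
#'
#' @param truth the truth list from [makeDataset()].
#' @param path file path.
#' @return \code{path} (write) or the truth list (read).
#' @export
writeTruth <- function(truth, path) {
  yaml::write_yaml(truth, path)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) yaml::read_yaml(path)
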