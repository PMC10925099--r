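#' Selection-coefficient bin edges
#'
#' The five bins of the discrete DFE.  In the inference convention
#' (genotype fitnesses 1, 1-2sh, 1-2s) the edges are
#' 0, 1e-5, 1e-4, 1e-3, 1e-2, 0.5; the simulation convention (fitnesses
#' 1, 1-sh, 1-s) doubles every edge.
#'
#' @param convention \code{"inference"} or \code{"simulation"}.
#' @return numeric(6) of increasing edges.
#' @export
binEdges <- function(convention = c("inference", "simulation")) {
  convention <- match.arg(convention)
  e <- c(0, 1e-5, 1e-4, 1e-3, 1e-2, 0.5)
  if (convention == "simulation") e <- 2 * e
  e
}

binNames <- c("neutral", "nearly", "weak", "moderate", "strong")

#' Gamma distribution of fitness effects
#'
#' @param shape,scale gamma parameters; scale in unscaled s units.
#' @return a \linkS4class{GammaDFE}.
#' @export
gammaDFE <- function(shape, scale) new("GammaDFE", shape = shape, scale = scale)

#' Discrete five-bin distribution of fitness effects
#'
#' @param proportions numeric(5) of bin proportions summing to 1 (bins:
#'   neutral, nearly neutral, weakly / moderately / strongly deleterious).
#' @param convention bin-edge convention, see [binEdges()].
#' @param edges optional numeric(6) of custom increasing bin edges
#'   (validation runs with degenerate bins).
#' @return a \linkS4class{DiscreteDFE}.
#' @export
discreteDFE <- function(proportions,
                        convention = c("inference", "simulation"),
                        edges = NULL) {
  if (is.null(edges)) edges <- binEdges(match.arg(convention))
  new("DiscreteDFE", proportions = as.numeric(proportions),
      edges = as.numeric(edges))
}

#' Per-bin dominance map
#'
#' @param h a single global dominance coefficient or one per bin (5).
#' @return a \linkS4class{DominanceMap}.
#' @export
dominanceMap <- function(h) {
  if (length(h) == 1L) h <- rep(h, 5L)
  new("DominanceMap", h = as.numeric(h))
}

#' Enumerate per-bin dominance models
#'
#' All combinations of dominance coefficients over the four non-neutral
#' bins of the discrete DFE, with the neutral bin fixed additive
#' (h = 0.5).  With the default eight candidate values this yields
#' \eqn{8^4 = 4096} models, in deterministic lexicographic order over
#' (nearly, weak, moderate, strong).
#'
#' @param hChoices candidate dominance values for each non-neutral bin.
#' @param neutralH dominance of the neutral bin (fixed, default additive).
#' @return list of \linkS4class{DominanceMap}s.
#' @examples
#' length(enumerateHSModels())                    # 4096
#' length(enumerateHSModels(c(0.15, 0.5)))        # 16
#' @export
enumerateHSModels <- function(hChoices = c(0, 0.05, 0.10, 0.15, 0.25,
                                           0.35, 0.45, 0.50),
                              neutralH = 0.5) {
  g <- expand.grid(strong = hChoices, moderate = hChoices, weak = hChoices,
                   nearly = hChoices)
  g <- g[order(g$nearly, g$weak, g$moderate, g$strong), ]
  lapply(seq_len(nrow(g)), function(i)
    dominanceMap(c(neutralH, g$nearly[i], g$weak[i], g$moderate[i],
                   g$strong[i])))
}

# geometric-midpoint cell edges of a log-spaced s grid
cacheCellEdges <- function(s) {
  K <- length(s)
  c(s[1], sqrt(s[-K] * s[-1]), s[K])
}

# mass each grid cell receives from a uniform distribution on [a, b],
# plus the mass falling below the grid (treated as neutral) and above it
# (treated as not segregating)
uniformCellMass <- function(s, a, b) {
  e <- cacheCellEdges(s)
  lo <- pmax(e[-length(e)], a)
  hi <- pmin(e[-1], b)
  cells <- pmax(hi - lo, 0) / (b - a)
  below <- max(min(e[1], b) - a, 0) / (b - a)
  above <- max(b - max(e[length(e)], a), 0) / (b - a)
  list(cells = cells, below = below, above = above)
}

# same for a gamma(shape, scale) DFE on s > 0
gammaCellMass <- function(s, shape, scale) {
  e <- cacheCellEdges(s)
  p <- pgamma(e, shape = shape, scale = scale)
  list(cells = diff(p), below = p[1], above = 1 - p[length(p)])
}

# unit-theta expected spectrum contributed by a uniform s-bin [a, b] under
# one cache's dominance value
binUnitSpectrum <- function(cache, a, b) {
  m <- uniformCellMass(cache@s, a, b)
  as.vector(crossprod(cache@spectra, m$cells)) + m$below * cache@neutral
}

findCache <- function(caches, h) {
  for (cc in caches) if (isTRUE(all.equal(cc@h, h, tolerance = 1e-9))) return(cc)
  stop(sprintf("no expected-SFS cache available for h = %g", h))
}

#' Expected SFS of a DFE/dominance mixture
#'
#' Assembles the expected nonsynonymous spectrum of a gamma or discrete
#' DFE with per-bin dominance: each bin's mass is spread over the cached
#' log-spaced selection grid (uniform in s within discrete bins; gamma
#' density mass per grid cell for the gamma family), using the cache built
#' for that bin's dominance coefficient.  Mass below the grid contributes
#' the neutral spectrum; mass above s = 0.25 contributes nothing.
#'
#' @param dfe a \linkS4class{GammaDFE} or \linkS4class{DiscreteDFE}
#'   (inference convention).
#' @param hmap a \linkS4class{DominanceMap} (for a gamma DFE all five
#'   values must be equal).
#' @param caches list of \linkS4class{SFSCache}s covering every h in
#'   \code{hmap}.
#' @param thetaNS nonsynonymous mutation-rate scale.
#' @return an unfolded expected \linkS4class{SFS}.
#' @export
mixtureExpectedSFS <- function(dfe, hmap, caches, thetaNS = 1) {
  stopifnot(is(hmap, "DominanceMap"))
  if (is(caches, "SFSCache")) caches <- list(caches)
  if (is(dfe, "GammaDFE")) {
    h <- unique(hmap@h)
    if (length(h) != 1L)
      stop("a gamma DFE takes a single global dominance coefficient")
    cache <- findCache(caches, h)
    m <- gammaCellMass(cache@s, dfe@shape, dfe@scale)
    ent <- as.vector(crossprod(cache@spectra, m$cells)) +
      m$below * cache@neutral
  } else if (is(dfe, "DiscreteDFE")) {
    ent <- 0
    for (b in seq_len(5L)) {
      if (dfe@proportions[b] == 0) next
      cache <- findCache(caches, hmap@h[b])
      ent <- ent + dfe@proportions[b] *
        binUnitSpectrum(cache, dfe@edges[b], dfe@edges[b + 1])
    }
  } else stop("dfe must be a GammaDFE or DiscreteDFE")
  out <- thetaNS * ent
  out[1] <- 0; out[length(out)] <- 0
  sfs(out, folded = FALSE)
}

#' Mean dominance coefficient over new mutations
#'
#' Proportion-weighted mean of the per-bin dominance coefficients,
#' \eqn{\bar h = \sum_b p_b h_b}.
#'
#' @param dfe a \linkS4class{DiscreteDFE}.
#' @param hmap a \linkS4class{DominanceMap}.
#' @return the mean dominance of a new mutation.
#' @export
averageH <- function(dfe, hmap) {
  stopifnot(is(dfe, "DiscreteDFE"), is(hmap, "DominanceMap"))
  sum(dfe@proportions * hmap@h)
}

#' Keep models whose dominance decays with selection strength
#'
#' Retains models with a monotonic (non-strict) decay of h from the
#' neutral to the strongly deleterious bin:
#' \eqn{h_1 \ge h_2 \ge h_3 \ge h_4 \ge h_5}.  Ties are allowed.
#'
#' @param models list of \linkS4class{HSModel}s or
#'   \linkS4class{DominanceMap}s.
#' @return the retained sublist.
#' @export
monotonicFilter <- function(models) {
  keep <- vapply(models, function(m) {
    h <- if (is(m, "HSModel")) m@hmap@h else m@h
    all(diff(h) <= 0)
  }, logical(1))
  models[keep]
}
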