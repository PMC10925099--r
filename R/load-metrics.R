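#' Construct a sample-genotypes container
#'
#' @param geno integer matrix (sites x individuals) of 0/1/2 genotypes at
#'   segregating sites.
#' @param s,h per-site selection and dominance coefficients (simulation
#'   convention: genotype fitnesses 1, 1-sh, 1-s).
#' @param fixedS,fixedH coefficients of sites fixed in the population.
#' @return a \linkS4class{SampleGenotypes}.
#' @export
sampleGenotypes <- function(geno, s, h, fixedS = numeric(),
                            fixedH = numeric()) {
  new("SampleGenotypes", geno = as.matrix(geno), s = as.numeric(s),
      h = as.numeric(h), fixedS = as.numeric(fixedS),
      fixedH = as.numeric(fixedH))
}

# log fitness factors with a floor instead of -Inf so matrix products stay
# finite (exp(-745) underflows to 0, i.e. a lethal genotype)
.safeLog1p <- function(x) pmax(log1p(x), -745)

#' Genetic load of a sample
#'
#' Load is the reduction in mean fitness, with fitness multiplicative
#' across sites: genotype 0 contributes 1, a heterozygote \eqn{1 - sh},
#' a mutant homozygote \eqn{1 - s}; every fixed site multiplies all
#' individuals by \eqn{1 - s}.
#'
#' @param sample a \linkS4class{SampleGenotypes}.
#' @return load in [0, 1].
#' @examples
#' # one fixed site of s = 0.1: load = 0.1 regardless of h
#' geneticLoad(sampleGenotypes(matrix(0, 0, 5), numeric(), numeric(),
#'                             fixedS = 0.1, fixedH = 0))
#' @export
geneticLoad <- function(sample) {
  stopifnot(is(sample, "SampleGenotypes"))
  G <- sample@geno
  lfix <- sum(.safeLog1p(-sample@fixedS))
  if (!nrow(G)) return(1 - exp(lfix))
  lhet <- .safeLog1p(-sample@s * sample@h)
  lhom <- .safeLog1p(-sample@s)
  logw <- crossprod(G == 1L, lhet) + crossprod(G == 2L, lhom)
  1 - mean(exp(as.vector(logw) + lfix))
}

#' Inbreeding load (haploid lethal equivalents)
#'
#' The summed selective effects of deleterious alleles concealed in
#' heterozygotes, over segregating sites with sample allele frequency
#' \eqn{q}; fixed sites contribute nothing.  Two related quantities are
#' offered:
#' \describe{
#'   \item{\code{"concealed"} (default)}{\eqn{B = \sum s q (1-q)(1-h)}:
#'     the full-exposure excess effect of heterozygous alleles (what
#'     complete homozygosity would add at a currently heterozygous site).
#'     This is the quantity the simulation study tabulates as the number
#'     of haploid lethal equivalents.}
#'   \item{\code{"slope"}}{\eqn{B = \sum s q (1-q)(1-2h)}: the classical
#'     regression slope of \eqn{-\log} fitness on the inbreeding
#'     coefficient F; exactly zero for additive (h = 0.5) sites.}
#' }
#'
#' @param sample a \linkS4class{SampleGenotypes}.
#' @param kind \code{"concealed"} or \code{"slope"}.
#' @return B (haploid lethal equivalents).
#' @export
inbreedingLoad <- function(sample, kind = c("concealed", "slope")) {
  stopifnot(is(sample, "SampleGenotypes"))
  kind <- match.arg(kind)
  G <- sample@geno
  if (!nrow(G)) return(0)
  q <- rowSums(G) / (2 * ncol(G))
  w <- if (kind == "concealed") 1 - sample@h else 1 - 2 * sample@h
  sum(sample@s * q * (1 - q) * w)
}

#' Mean derived-allele count per individual
#'
#' @param sample a \linkS4class{SampleGenotypes}.
#' @return mean number of derived deleterious alleles per individual
#'   (fixed sites count 2 each).
#' @export
derivedAlleleCount <- function(sample) {
  stopifnot(is(sample, "SampleGenotypes"))
  G <- sample@geno
  seg <- if (nrow(G)) mean(colSums(G)) else 0
  seg + 2 * length(sample@fixedS)
}

#' Project chromosome-subset simulation results to the full genome
#'
#' When only a subset of the 22 autosomes is simulated, results are
#' projected to the whole genome: relative fitness is exponentiated by the
#' factor (so \eqn{load' = 1 - (1 - load)^{f}}) while inbreeding load and
#' allele counts, being genome sums, are multiplied by it.
#'
#' @param result a \linkS4class{SimResult}.
#' @param chromosomes number of autosomes simulated (factor = 22 /
#'   chromosomes; 11 for two-chromosome runs).
#' @param factor projection factor, overriding \code{chromosomes}.
#' @return the projected \linkS4class{SimResult}.
#' @export
projectToGenome <- function(result, chromosomes = NULL, factor = NULL) {
  stopifnot(is(result, "SimResult"))
  if (is.null(factor)) {
    if (is.null(chromosomes)) stop("give chromosomes or factor")
    if (chromosomes %% 1 != 0) stop("chromosome count must be an integer")
    factor <- 22 / chromosomes
  }
  st <- result@stats
  st$load <- 1 - (1 - st$load)^factor
  st$B <- st$B * factor
  st$count <- st$count * factor
  st$projected <- TRUE
  new("SimResult", stats = st, lambda = result@lambda,
      factor = result@factor * factor, seed = result@seed)
}
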