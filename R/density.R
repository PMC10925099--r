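#' Selection/dominance parameters
#'
#' Construct a \linkS4class{SelectionParams}.  Either supply \code{gamma}
#' (\eqn{2 N_{anc} s}) directly, or \code{s} together with \code{Nanc}.
#' Deleterious selection coefficients are positive (inference convention:
#' genotype fitnesses \eqn{1}, \eqn{1 - 2sh}, \eqn{1 - 2s}), so \eqn{s}
#' ranges over \eqn{[0, 0.5]} with 0.5 lethal.
#'
#' @param h dominance coefficient in [0, 1].
#' @param gamma scaled selection coefficient.
#' @param s unscaled selection coefficient in [0, 0.5].
#' @param Nanc ancestral diploid size (required with \code{s}).
#' @return a \linkS4class{SelectionParams}.
#' @export
selectionParams <- function(h, gamma = NULL, s = NULL, Nanc = NULL) {
  if (is.null(gamma)) {
    if (is.null(s) || is.null(Nanc))
      stop("supply gamma, or s together with Nanc")
    if (s < 0 || s > 0.5) stop("s must lie in [0, 0.5]")
    gamma <- 2 * Nanc * s
  }
  new("SelectionParams", gamma = as.numeric(gamma), h = as.numeric(h))
}

#' Demographic epoch model
#'
#' @param nu0,nu1 relative sizes at the start and end of each epoch.
#' @param tau epoch durations in units of \eqn{2 N_{anc}} generations.
#' @param mode \code{"constant"} or \code{"exponential"} per epoch.
#' @return an \linkS4class{EpochModel}.
#' @examples
#' # bottleneck then exponential recovery
#' epochModel(nu0 = c(0.1, 0.1), nu1 = c(0.1, 2), tau = c(0.05, 0.1),
#'            mode = c("constant", "exponential"))
#' @export
epochModel <- function(nu0 = numeric(), nu1 = nu0, tau = numeric(),
                       mode = rep("constant", length(nu0))) {
  new("EpochModel", epochs = data.frame(nu0 = as.numeric(nu0),
                                        nu1 = as.numeric(nu1),
                                        tau = as.numeric(tau),
                                        mode = as.character(mode),
                                        stringsAsFactors = FALSE))
}

#' @rdname epochModel
#' @param x an \linkS4class{EpochModel}.
#' @export
demogHash <- function(x) {
  stopifnot(is(x, "EpochModel"))
  paste(sprintf("%.12g:%.12g:%.12g:%s", x@epochs$nu0, x@epochs$nu1,
                x@epochs$tau, x@epochs$mode), collapse = "|")
}

# exponent G(e) = 4 gamma h e + 2 gamma (1-2h) e^2 of the stationary
# density, in the package's orientation (gamma > 0 deleterious suppresses
# high frequencies; the textbook formula is recovered with gamma -> -gamma)
densityExponent <- function(eps, gamma, h) {
  4 * gamma * h * eps + 2 * gamma * (1 - 2 * h) * eps^2
}

#' Quasi-stationary allele-frequency density at a point
#'
#' Evaluates the equilibrium density of mutant-allele frequency under
#' mutation-selection-drift balance for scaled selection coefficient
#' \eqn{\gamma = 2 N_{anc} s} and dominance \eqn{h}, normalized so that the
#' neutral density is exactly \eqn{1/q} (unit mutation-rate scale):
#' \deqn{f(q) = \frac{e^{-G(q)}}{q(1-q)}
#'   \frac{\int_q^1 e^{G(\epsilon)} d\epsilon}
#'        {\int_0^1 e^{G(\epsilon)} d\epsilon},\quad
#'   G(\epsilon) = 4\gamma h \epsilon + 2\gamma(1-2h)\epsilon^2.}
#' Positive \eqn{\gamma} (deleterious) shifts mass toward low frequency.
#'
#' @param q frequency strictly inside (0, 1); vectorized.
#' @param sel a \linkS4class{SelectionParams}.
#' @param rel.tol relative tolerance of the adaptive quadrature.
#' @return density value(s), non-negative.
#' @examples
#' stationaryDensity(0.5, selectionParams(h = 0.5, gamma = 0))  # 2 = 1/q
#' @export
stationaryDensity <- function(q, sel, rel.tol = 1e-10) {
  stopifnot(is(sel, "SelectionParams"))
  if (any(q <= 0 | q >= 1)) stop("q must lie strictly inside (0, 1)")
  gamma <- sel@gamma; h <- sel@h
  if (gamma == 0) return(1 / q)
  gmax <- max(0, densityExponent(1, gamma, h))
  f1 <- function(e) exp(densityExponent(e, gamma, h) - gmax)
  tot <- integrate(f1, 0, 1, rel.tol = rel.tol, subdivisions = 400L)$value
  vapply(q, function(qi) {
    up <- integrate(f1, qi, 1, rel.tol = rel.tol, subdivisions = 400L)$value
    # the e^{-gmax} scaling cancels between the two integrals
    lg <- -densityExponent(qi, gamma, h) + log(up) - log(tot) -
      log(qi) - log1p(-qi)
    exp(lg)
  }, numeric(1))
}

#' Equilibrium allele-frequency density on a grid
#'
#' Same density as [stationaryDensity()] evaluated on a full solver grid
#' with a vectorized piecewise Gauss-Legendre cumulative quadrature (exact
#' \eqn{1/q} under neutrality).
#'
#' @param sel a \linkS4class{SelectionParams}.
#' @param grid strictly increasing interior frequencies (e.g. from
#'   [makeFrequencyGrid()]).
#' @param gammaMax error out beyond this |gamma| (numerical-stability
#'   guard matching the engine's restriction of s to at most 0.25).
#' @return a \linkS4class{FrequencyDensity}.
#' @export
equilibriumDensity <- function(sel, grid, gammaMax = 1e6) {
  stopifnot(is(sel, "SelectionParams"))
  if (any(grid <= 0 | grid >= 1)) stop("grid must exclude 0 and 1")
  gamma <- sel@gamma; h <- sel@h
  if (abs(gamma) > gammaMax)
    stop(sprintf("|gamma| = %.3g exceeds the numerically stable range (%g)",
                 abs(gamma), gammaMax))
  if (gamma == 0)
    return(new("FrequencyDensity", grid = grid, values = 1 / grid))
  gmax <- max(0, densityExponent(1, gamma, h))
  # 7-point Gauss-Legendre nodes/weights on [0, 1]
  gl <- list(
    x = c(0.0254460438286207, 0.129234407200303, 0.297077424311301, 0.5,
          0.702922575688699, 0.870765592799697, 0.974553956171379),
    w = c(0.0647424830844348, 0.139852695744638, 0.190915025252559,
          0.208979591836735, 0.190915025252559, 0.139852695744638,
          0.0647424830844348))
  edges <- c(0, grid, 1)
  a <- edges[-length(edges)]
  wdt <- diff(edges)
  # integral of exp(G - gmax) over each interval
  iv <- numeric(length(a))
  for (k in seq_along(gl$x)) {
    e <- a + gl$x[k] * wdt
    iv <- iv + gl$w[k] * exp(densityExponent(e, gamma, h) - gmax)
  }
  iv <- iv * wdt
  upper <- rev(cumsum(rev(iv)))        # upper[j] = int over [edges[j], 1]
  tot <- upper[1L]
  up <- upper[-1L]                     # int over [grid[j], 1]
  lg <- -densityExponent(grid, gamma, h) + log(pmax(up, .Machine$double.xmin)) -
    log(tot) - log(grid) - log1p(-grid)
  new("FrequencyDensity", grid = grid, values = exp(lg))
}
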