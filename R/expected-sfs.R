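.domfitEnv <- new.env(parent = emptyenv())

# Gauss-Legendre nodes/weights on [0, 1] via the Golub-Welsch eigenvalue
# method; memoized (used as the sampling quadrature of the binomial kernel)
gaussLegendre01 <- function(K) {
  key <- paste0("gl", K)
  got <- .domfitEnv[[key]]
  if (!is.null(got)) return(got)
  j <- seq_len(K - 1)
  b <- j / sqrt(4 * j^2 - 1)
  J <- matrix(0, K, K)
  J[cbind(j, j + 1)] <- b
  J[cbind(j + 1, j)] <- b
  ev <- eigen(J, symmetric = TRUE)
  x <- ev$values
  w <- 2 * ev$vectors[1, ]^2
  o <- order(x)
  out <- list(x = (x[o] + 1) / 2, w = w[o] / 2)
  .domfitEnv[[key]] <- out
  out
}

# binomial sampling kernel: matrix K_{i,k} = dbinom(i, n, q_k) / (q_k (1-q_k))
# for i = 1..n-1 against Gauss-Legendre nodes; memoized per (n, K)
samplingKernel <- function(n, K = n + 50L) {
  key <- paste0("kern", n, "_", K)
  got <- .domfitEnv[[key]]
  if (!is.null(got)) return(got)
  gl <- gaussLegendre01(K)
  i <- seq_len(n - 1L)
  B <- outer(i, gl$x, function(ii, qq) dbinom(ii, n, qq) / (qq * (1 - qq)))
  out <- list(nodes = gl$x, weights = gl$w, B = B, n = n)
  .domfitEnv[[key]] <- out
  out
}

#' Expected SFS from an allele-frequency density
#'
#' Binomially samples a population density \eqn{f(q)} into the expected
#' spectrum of a sample of \eqn{n} chromosomes:
#' \deqn{E[x_i] = \theta F(n, i) = \theta \int_0^1 \binom{n}{i} q^i
#'   (1-q)^{n-i} f(q) dq, \quad i = 1..n-1.}
#' The integrable endpoint behavior (\eqn{f \sim 1/q} near 0) is handled by
#' integrating \eqn{g(q) = q(1-q) f(q)} against
#' \eqn{\binom{n}{i} q^{i-1} (1-q)^{n-i-1}} with Gauss-Legendre quadrature,
#' interpolating \eqn{g} from the density grid; under neutrality the result
#' is \eqn{\theta/i} to near machine precision.
#'
#' @param phi a \linkS4class{FrequencyDensity}.
#' @param n haploid sample size (>= 2).
#' @param theta mutation-rate scale multiplying the unit spectrum.
#' @return an unfolded expected \linkS4class{SFS} (non-integer counts).
#' @export
sampleExpectedSFS <- function(phi, n, theta = 1) {
  stopifnot(is(phi, "FrequencyDensity"), n >= 2)
  n <- as.integer(n)
  x <- phi@grid
  g <- x * (1 - x) * phi@values
  m <- length(x)
  g0 <- max(0, g[1] - x[1] * (g[2] - g[1]) / (x[2] - x[1]))
  g1 <- max(0, g[m] + (1 - x[m]) * (g[m] - g[m - 1]) / (x[m] - x[m - 1]))
  fun <- splinefun(c(0, x, 1), c(g0, g, g1), method = "monoH.FC")
  kern <- samplingKernel(n)
  gv <- fun(kern$nodes)
  ent <- as.vector(kern$B %*% (kern$weights * gv)) * theta
  sfs(c(0, ent, 0), folded = FALSE)
}

#' Expected SFS under a demography and selection parameters
#'
#' Convenience pipeline: ancestral equilibrium density, diffusion through
#' the epochs, binomial sampling.
#'
#' @inheritParams propagateDensity
#' @inheritParams sampleExpectedSFS
#' @param demo an \linkS4class{EpochModel} (may have zero epochs for a
#'   constant-size history).
#' @param sel a \linkS4class{SelectionParams}.
#' @param grid solver grid (vector from [makeFrequencyGrid()]).
#' @return an unfolded expected \linkS4class{SFS}.
#' @export
expectedSFS <- function(demo, sel, n, theta = 1,
                        grid = makeFrequencyGrid(2000L), dt = 1e-3,
                        rtol = 1e-6, maxRefine = 3L) {
  phi <- equilibriumDensity(sel, grid)
  if (nrow(demo@epochs))
    phi <- propagateDensity(phi, demo, sel, theta = 1, dt = dt, rtol = rtol,
                            maxRefine = maxRefine)
  sampleExpectedSFS(phi, n, theta)
}

#' Wright-Fisher transition-matrix oracle for the expected SFS
#'
#' Exact discrete Wright-Fisher computation of the expected spectrum for a
#' small diploid population: the allele-count distribution is iterated
#' under binomial resampling around the deterministic post-selection
#' frequency
#' \deqn{q' = \frac{q^2 (1-2s) + q(1-q)(1-2sh)}
#'                 {q^2(1-2s) + 2q(1-q)(1-2sh) + (1-q)^2}}
#' with constant mutational influx (rate \eqn{\theta \nu / 2} new mutants
#' per generation entering at count 1).  Serves as an independent check on
#' the diffusion engine; feasible for \eqn{2N \le 1000}.
#'
#' @param N ancestral diploid population size.
#' @param sel a \linkS4class{SelectionParams}; its \code{gamma} is
#'   interpreted as \eqn{2 N s}.
#' @param demo an \linkS4class{EpochModel} (constant epochs recommended;
#'   exponential epochs rebuild the transition matrix every generation).
#' @param n haploid sample size.
#' @param theta mutation-rate scale.
#' @return an unfolded expected \linkS4class{SFS}.
#' @export
wfMatrixSFS <- function(N, sel, demo = epochModel(), n, theta = 1) {
  stopifnot(is(sel, "SelectionParams"))
  if (2 * N > 1000) stop("dense Wright-Fisher matrix needs 2N <= 1000")
  s <- sel@gamma / (2 * N)
  h <- sel@h
  if (abs(s) > 0.5) stop("matrix oracle requires |s| <= 0.5")
  transition <- function(twoN) {
    q <- seq_len(twoN - 1) / twoN
    w11 <- 1 - 2 * s; w01 <- 1 - 2 * s * h
    num <- q^2 * w11 + q * (1 - q) * w01
    den <- q^2 * w11 + 2 * q * (1 - q) * w01 + (1 - q)^2
    qs <- pmin(pmax(num / den, 0), 1)
    # rows: current count 1..2N-1; cols: next count 1..2N-1 (transient)
    t(vapply(qs, function(p) dbinom(seq_len(twoN - 1), twoN, p),
             numeric(twoN - 1)))
  }
  resize <- function(m, twoNold, twoNnew) {
    q <- seq_len(twoNold - 1) / twoNold
    P <- t(vapply(q, function(p) dbinom(seq_len(twoNnew - 1), twoNnew, p),
                  numeric(twoNnew - 1)))
    as.vector(m %*% P)
  }
  twoN <- 2L * as.integer(round(N))
  Tm <- transition(twoN)
  # census follows reproduction and mutation: new mutants are seen at
  # count 1 in the generation they arise
  step <- function(m, Te, rate) {
    as.vector(m %*% Te) + c(rate, numeric(ncol(Te) - 1))
  }
  influx <- c(theta / 2, numeric(twoN - 2))
  m <- solve(diag(twoN - 1) - t(Tm), influx)   # ancestral stationarity
  if (nrow(demo@epochs)) {
    for (i in seq_len(nrow(demo@epochs))) {
      e <- demo@epochs[i, ]
      gens <- round(e$tau * twoN)
      if (e$mode == "constant") {
        twoNe <- max(4L, as.integer(round(twoN * e$nu0)))
        if (twoNe != length(m) + 1L) m <- resize(m, length(m) + 1L, twoNe)
        Te <- transition(twoNe)
        for (g in seq_len(gens)) m <- step(m, Te, theta * e$nu0 / 2)
        rm(Te)
      } else {
        lr <- log(e$nu1 / e$nu0)
        for (g in seq_len(gens)) {
          nu <- e$nu0 * exp(lr * (g - 0.5) / gens)
          twoNe <- max(4L, as.integer(round(twoN * nu)))
          if (twoNe != length(m) + 1L) m <- resize(m, length(m) + 1L, twoNe)
          m <- step(m, transition(twoNe), theta * nu / 2)
        }
      }
    }
  }
  twoNf <- length(m) + 1L
  q <- seq_len(twoNf - 1) / twoNf
  ent <- vapply(seq_len(n - 1), function(i) sum(m * dbinom(i, n, q)),
                numeric(1))
  sfs(c(0, ent, 0), folded = FALSE)
}

#' Precompute expected spectra on a log-spaced selection grid
#'
#' Builds the cache of unit-\eqn{\theta} expected spectra used by the
#' mixture assembly and DFE fits: a grid of log-spaced selection
#' coefficients from \code{sMin} to \code{sMax} (endpoints included), one
#' diffusion solve per grid point at \eqn{\gamma = 2 N_{anc} s}.  The upper
#' bound is capped at 0.25: more strongly selected mutations are treated as
#' not segregating.
#'
#' @param h dominance coefficient of the cache.
#' @param demo an \linkS4class{EpochModel}.
#' @param n haploid sample size.
#' @param Nanc ancestral diploid size scaling \eqn{\gamma}.
#' @param nS number of grid points (1000 for production fits).
#' @param sMin,sMax grid endpoints in s units.
#' @param grid,dt,rtol,maxRefine solver controls, see [propagateDensity()].
#' @return an \linkS4class{SFSCache}.
#' @export
buildGridCache <- function(h, demo, n, Nanc, nS = 1000L, sMin = 1e-5,
                           sMax = 0.25, grid = makeFrequencyGrid(2000L),
                           dt = 1e-3, rtol = 1e-6, maxRefine = 1L) {
  if (sMax > 0.25 + 1e-12)
    stop("s above 0.25 is outside the stable range; such mutations are ",
         "treated as not segregating")
  if (h < 0 || h > 1) stop("h must lie in [0, 1]")
  sv <- exp(seq(log(sMin), log(sMax), length.out = nS))
  sv[1] <- sMin; sv[nS] <- sMax
  n <- as.integer(n)
  spec <- matrix(0, nS, n + 1L)
  hasDemo <- nrow(demo@epochs) > 0L
  oneSpectrum <- function(gamma) {
    sel <- selectionParams(h = h, gamma = gamma)
    phi <- equilibriumDensity(sel, grid)
    if (hasDemo)
      phi <- propagateDensity(phi, demo, sel, dt = dt, rtol = rtol,
                              maxRefine = maxRefine)
    counts(sampleExpectedSFS(phi, n, 1))
  }
  for (k in seq_len(nS)) spec[k, ] <- oneSpectrum(2 * Nanc * sv[k])
  new("SFSCache", s = sv, spectra = spec, neutral = oneSpectrum(0), h = h,
      n = n, Nanc = Nanc, demogHash = demogHash(demo))
}

#' Read/write an expected-SFS cache as a tabular text file
#'
#' The format is self-describing: comment lines \code{#h}, \code{#n},
#' \code{#Nanc}, \code{#demog} followed by one row per selection
#' coefficient (first column s, then the n + 1 spectrum entries).
#'
#' @param cache an \linkS4class{SFSCache}.
#' @param path file path.
#' @return \code{path} (write) or the cache (read).
#' @export
writeSFSCache <- function(cache, path) {
  stopifnot(is(cache, "SFSCache"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("#h ", format(cache@h, digits = 15)),
               paste0("#n ", cache@n),
               paste0("#Nanc ", format(cache@Nanc, digits = 15)),
               paste0("#demog ", cache@demogHash)), con)
  write.table(rbind(c(0, cache@neutral), cbind(cache@s, cache@spectra)),
              con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeSFSCache
#' @export
readSFSCache <- function(path) {
  hdr <- readLines(path, n = 4L)
  val <- function(tag) sub(paste0("^#", tag, " "), "",
                           grep(paste0("^#", tag, " "), hdr, value = TRUE)[1])
  tab <- as.matrix(read.table(path, comment.char = "#"))
  dimnames(tab) <- NULL
  new("SFSCache", s = tab[-1, 1], spectra = tab[-1, -1, drop = FALSE],
      neutral = tab[1, -1], h = as.numeric(val("h")),
      n = as.integer(val("n")), Nanc = as.numeric(val("Nanc")),
      demogHash = val("demog"))
}
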