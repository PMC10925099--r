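#' Poisson random field log-likelihood of an SFS
#'
#' Under the PRF model each unmasked entry is an independent Poisson count
#' with mean given by the model spectrum:
#' \eqn{LL = \sum_i x_i \log m_i - m_i - \log(x_i!)}.
#'
#' @param data observed \linkS4class{SFS}.
#' @param model expected \linkS4class{SFS} (same n, folded state and mask).
#' @return the log-likelihood (\code{-Inf} if some \eqn{m_i = 0} with
#'   \eqn{x_i > 0}).
#' @export
poissonLL <- function(data, model) {
  stopifnot(is(data, "SFS"), is(model, "SFS"))
  if (data@n != model@n || data@folded != model@folded ||
      !identical(data@mask, model@mask))
    stop("data and model spectra must share n, folded state and mask")
  x <- data@counts[!data@mask]
  m <- model@counts[!model@mask]
  .poissonLLVec(x, m)
}

.poissonLLVec <- function(x, m) {
  if (any(m == 0 & x > 0)) return(-Inf)
  ok <- m > 0
  sum(x[ok] * log(m[ok]) - m[ok] - lfactorial(x[ok]))
}

#' Poisson maximum-likelihood mutation-rate scale
#'
#' The MLE of a multiplicative scale \eqn{\theta} applied to a unit model
#' spectrum: \eqn{\hat\theta = \sum_i x_i / \sum_i m_i} over unmasked
#' entries.  This value maximizes [poissonLL()] over \eqn{\theta}.
#'
#' @param data observed \linkS4class{SFS}.
#' @param unitModel expected \linkS4class{SFS} at \eqn{\theta = 1},
#'   strictly positive on unmasked entries.
#' @return \eqn{\hat\theta}.
#' @export
optimalTheta <- function(data, unitModel) {
  stopifnot(is(data, "SFS"), is(unitModel, "SFS"))
  if (data@n != unitModel@n || data@folded != unitModel@folded)
    stop("data and unit model must share n and folded state")
  x <- data@counts[!data@mask]
  m <- unitModel@counts[!data@mask]
  if (all(m == 0)) stop("unit model is identically zero on unmasked entries")
  sum(x) / sum(m)
}

#' Akaike information criterion
#'
#' \eqn{AIC = 2k - 2 LL}.
#'
#' @param fit a \linkS4class{FitResult}, or a log-likelihood value.
#' @param k number of estimated parameters (taken from the fit if omitted).
#' @return the AIC.
#' @export
computeAIC <- function(fit, k = NULL) {
  if (is(fit, "FitResult")) {
    if (is.null(k)) k <- fit@k
    return(2 * k - 2 * fit@LL)
  }
  if (is.null(k)) stop("k is required when fit is a bare log-likelihood")
  2 * k - 2 * fit
}

# fold an unfolded counts vector (length n + 1)
foldCounts <- function(v, n) {
  half <- floor(n / 2)
  out <- numeric(n + 1L)
  i <- seq_len(half)
  out[i + 1L] <- v[i + 1L] + ifelse(n - i == i, 0, v[n - i + 1L])
  out
}

# expected entries aligned with the data's folded state and mask
alignModelCounts <- function(v, data) {
  if (data@folded) v <- foldCounts(v, data@n)
  v[!data@mask]
}

makeDemographyTemplate <- function(template) {
  switch(template,
    two_epoch = list(
      names = c("nu", "tau"),
      lower = log(c(1e-3, 1e-3)), upper = log(c(1e3, 5)),
      start = log(c(1, 0.1)),
      build = function(p) epochModel(nu0 = p[["nu"]], tau = p[["tau"]])),
    bottleneck_growth = list(
      names = c("nuB", "tauB", "nuF", "tauG"),
      lower = log(c(1e-3, 1e-3, 1e-2, 1e-3)),
      upper = log(c(10, 2, 1e4, 1)),
      start = log(c(0.2, 0.1, 5, 0.05)),
      build = function(p) epochModel(nu0 = c(p[["nuB"]], p[["nuB"]]),
                                     nu1 = c(p[["nuB"]], p[["nuF"]]),
                                     tau = c(p[["tauB"]], p[["tauG"]]),
                                     mode = c("constant", "exponential"))),
    three_epoch = list(
      names = c("nuB", "tauB", "nuR", "tauR", "nuF", "tauG"),
      lower = log(c(1e-3, 1e-3, 1e-2, 1e-3, 1e-2, 1e-3)),
      upper = log(c(10, 2, 100, 2, 1e4, 1)),
      start = log(c(0.2, 0.1, 1, 0.1, 10, 0.05)),
      build = function(p) epochModel(
        nu0 = c(p[["nuB"]], p[["nuR"]], p[["nuR"]]),
        nu1 = c(p[["nuB"]], p[["nuR"]], p[["nuF"]]),
        tau = c(p[["tauB"]], p[["tauR"]], p[["tauG"]]),
        mode = c("constant", "constant", "exponential"))),
    stop("unknown demography template: ", template))
}

#' Fit a demographic model to the synonymous SFS
#'
#' Multi-start bounded maximum-likelihood fit of a piecewise demographic
#' history to a (folded) synonymous spectrum under the PRF likelihood,
#' with the mutation-rate scale \eqn{\theta_S} profiled out analytically
#' via [optimalTheta()].  The ancestral size follows from
#' \eqn{\theta_S = 4 N_{anc} \mu L_S} and the nonsynonymous scale from
#' \eqn{\theta_{NS} = r \theta_S} (r = 2.31 for the target exome data).
#'
#' @param synSfs observed synonymous \linkS4class{SFS}.
#' @param template \code{"three_epoch"} (bottleneck, recovery, recent
#'   exponential growth), \code{"bottleneck_growth"} or \code{"two_epoch"}.
#' @param nStarts number of optimizer starts.
#' @param seed integer seed for the start draws.
#' @param mu per-base per-generation mutation rate.
#' @param LS number of synonymous sites.
#' @param ratio nonsynonymous/synonymous length ratio.
#' @param grid,dt,maxRefine diffusion controls (see [propagateDensity()]).
#' @return a \linkS4class{FitResult}; \code{params} holds the epoch
#'   parameters, the fitted \linkS4class{EpochModel} (\code{demography}),
#'   and \code{thetaS}, \code{thetaNS}, \code{Nanc}.
#' @export
fitDemography <- function(synSfs, template = "three_epoch", nStarts = 10L,
                          seed = 1L, mu = 1.5e-8, LS = 1e7, ratio = 2.31,
                          grid = makeFrequencyGrid(600L), dt = 1e-3,
                          maxRefine = 0L) {
  stopifnot(is(synSfs, "SFS"))
  tpl <- makeDemographyTemplate(template)
  n <- synSfs@n
  neutral <- selectionParams(h = 0.5, gamma = 0)
  objective <- function(lp) {
    p <- setNames(exp(lp), tpl$names)
    val <- tryCatch({
      demo <- tpl$build(p)
      unit <- counts(expectedSFS(demo, neutral, n, grid = grid, dt = dt,
                                 maxRefine = maxRefine))
      m <- alignModelCounts(unit, synSfs)
      x <- synSfs@counts[!synSfs@mask]
      th <- sum(x) / sum(m)
      -.poissonLLVec(x, pmax(th * m, 1e-100))
    }, error = function(e) NA_real_)
    if (!is.finite(val)) 1e10 else val
  }
  set.seed(seed)
  starts <- matrix(tpl$start, nStarts, length(tpl$start), byrow = TRUE)
  if (nStarts > 1L)
    starts[-1, ] <- starts[-1, ] +
      matrix(runif((nStarts - 1L) * ncol(starts), -1.5, 1.5),
             nStarts - 1L)
  starts <- pmin(pmax(starts, matrix(tpl$lower, nStarts, ncol(starts),
                                     byrow = TRUE)),
                 matrix(tpl$upper, nStarts, ncol(starts), byrow = TRUE))
  best <- NULL
  conv <- FALSE
  for (r in seq_len(nStarts)) {
    fit <- tryCatch(nlminb(starts[r, ], objective, lower = tpl$lower,
                           upper = tpl$upper,
                           control = list(iter.max = 200, rel.tol = 1e-9)),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$objective)) next
    if (is.null(best) || fit$objective < best$objective) {
      best <- fit
      conv <- fit$convergence == 0
    }
  }
  if (is.null(best)) stop("demography fit failed across all starts")
  p <- setNames(exp(best$par), tpl$names)
  demo <- tpl$build(p)
  unit <- counts(expectedSFS(demo, neutral, n, grid = grid, dt = dt,
                             maxRefine = maxRefine))
  m <- alignModelCounts(unit, synSfs)
  x <- synSfs@counts[!synSfs@mask]
  thetaS <- sum(x) / sum(m)
  LL <- .poissonLLVec(x, thetaS * m)
  k <- length(tpl$names)
  new("FitResult",
      params = c(as.list(p),
                 list(demography = demo, thetaS = thetaS,
                      thetaNS = ratio * thetaS,
                      Nanc = thetaS / (4 * mu * LS))),
      LL = LL, k = k, AIC = 2 * k - 2 * LL, converged = conv,
      nStarts = nStarts, seed = seed)
}

# unconstrained stick-breaking parameterization of the 4-simplex
# (5 proportions, 4 free parameters; last bin by complement)
stickToSimplex <- function(z) {
  p <- numeric(5)
  rem <- 1
  for (b in 1:4) {
    f <- 1 / (1 + exp(-z[b]))
    p[b] <- rem * f
    rem <- rem - p[b]
  }
  p[5] <- rem
  p
}

simplexToStick <- function(p) {
  z <- numeric(4)
  rem <- 1
  for (b in 1:4) {
    f <- min(max(p[b] / rem, 1e-8), 1 - 1e-8)
    z[b] <- log(f / (1 - f))
    rem <- rem - p[b]
  }
  z
}

#' Fit a DFE to the nonsynonymous SFS
#'
#' Maximum-likelihood fit of a gamma (shape, scale; k = 2) or discrete
#' five-bin (four free proportions; k = 4) DFE, conditional on the
#' demography embodied in the expected-SFS caches and a fixed
#' \eqn{\theta_{NS}}.  Dominance is fixed by \code{hmap}.  The best of
#' \code{nStarts} seeded random restarts is returned.
#'
#' @param nonsynSfs observed nonsynonymous \linkS4class{SFS}.
#' @param caches list of \linkS4class{SFSCache}s covering the h values of
#'   \code{hmap}.
#' @param family \code{"gamma"} or \code{"discrete"}.
#' @param hmap a \linkS4class{DominanceMap} (single global h for gamma).
#' @param thetaNS fixed nonsynonymous mutation-rate scale.
#' @param nStarts optimizer restarts (study protocol: 25 for gamma fits,
#'   5 per dominance model for the discrete sweep).
#' @param seed integer seed.
#' @return a \linkS4class{FitResult} (\code{params} holds the fitted
#'   \code{dfe} object and its parameter values).
#' @export
fitDFE <- function(nonsynSfs, caches, family = c("gamma", "discrete"),
                   hmap = dominanceMap(0.5), thetaNS, nStarts = 25L,
                   seed = 1L) {
  family <- match.arg(family)
  stopifnot(is(nonsynSfs, "SFS"))
  if (is(caches, "SFSCache")) caches <- list(caches)
  x <- nonsynSfs@counts[!nonsynSfs@mask]
  edges <- binEdges("inference")
  set.seed(seed)
  if (family == "discrete") {
    # per-bin unit spectra under the map's dominance, aligned to the data
    M <- vapply(1:5, function(b) {
      cache <- findCache(caches, hmap@h[b])
      alignModelCounts(binUnitSpectrum(cache, edges[b], edges[b + 1]),
                       nonsynSfs)
    }, numeric(sum(!nonsynSfs@mask)))
    objective <- function(z) {
      p <- stickToSimplex(z)
      m <- thetaNS * as.vector(M %*% p)
      ll <- .poissonLLVec(x, pmax(m, 1e-100))
      if (!is.finite(ll)) 1e10 else -ll
    }
    starts <- matrix(0, nStarts, 4)
    if (nStarts >= 1) {
      e <- matrix(rexp(nStarts * 5), nStarts)
      for (r in seq_len(nStarts))
        starts[r, ] <- simplexToStick(e[r, ] / sum(e[r, ]))
    }
    best <- NULL; conv <- FALSE
    for (r in seq_len(nStarts)) {
      fit <- tryCatch(nlminb(starts[r, ], objective,
                             control = list(iter.max = 300)),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$objective)) next
      if (is.null(best) || fit$objective < best$objective) {
        best <- fit; conv <- fit$convergence == 0
      }
    }
    if (is.null(best)) stop("discrete DFE fit failed across all starts")
    p <- stickToSimplex(best$par)
    k <- 4
    params <- list(dfe = discreteDFE(p), proportions = p, hmap = hmap)
  } else {
    cache <- findCache(caches, unique(hmap@h))
    Msp <- apply(cache@spectra, 1, alignModelCounts, data = nonsynSfs)
    mneu <- alignModelCounts(cache@neutral, nonsynSfs)
    objective <- function(lp) {
      mcell <- gammaCellMass(cache@s, exp(lp[1]), exp(lp[2]))
      m <- thetaNS * (as.vector(Msp %*% mcell$cells) + mcell$below * mneu)
      ll <- .poissonLLVec(x, pmax(m, 1e-100))
      if (!is.finite(ll)) 1e10 else -ll
    }
    lower <- log(c(1e-3, 1e-6)); upper <- log(c(10, 10))
    starts <- cbind(runif(nStarts, log(0.05), log(1)),
                    runif(nStarts, log(1e-4), log(0.5)))
    best <- NULL; conv <- FALSE
    for (r in seq_len(nStarts)) {
      fit <- tryCatch(nlminb(starts[r, ], objective, lower = lower,
                             upper = upper,
                             control = list(iter.max = 300)),
                      error = function(e) NULL)
      if (is.null(fit) || !is.finite(fit$objective)) next
      if (is.null(best) || fit$objective < best$objective) {
        best <- fit; conv <- fit$convergence == 0
      }
    }
    if (is.null(best)) stop("gamma DFE fit failed across all starts")
    k <- 2
    params <- list(dfe = gammaDFE(exp(best$par[1]), exp(best$par[2])),
                   shape = exp(best$par[1]), scale = exp(best$par[2]),
                   hmap = hmap)
  }
  LL <- -best$objective
  new("FitResult", params = params, LL = LL, k = k, AIC = 2 * k - 2 * LL,
      converged = conv, nStarts = nStarts, seed = seed)
}

#' Profile log-likelihood over a single global dominance coefficient
#'
#' Refits the DFE at each candidate h (one global value for all bins) and
#' tabulates the profile log-likelihood.
#'
#' @inheritParams fitDFE
#' @param hValues candidate dominance values; each must have a cache.
#' @return data.frame with one row per h: \code{h}, \code{LL}, \code{dLL}
#'   (relative to the best), \code{AIC} and the fitted parameters.
#' @export
profileHScan <- function(nonsynSfs, caches, family = c("gamma", "discrete"),
                         hValues = c(0, 0.05, 0.10, 0.15, 0.25, 0.35,
                                     0.45, 0.50, 0.75, 1.0),
                         thetaNS, nStarts = 5L, seed = 1L) {
  family <- match.arg(family)
  rows <- lapply(seq_along(hValues), function(i) {
    # per-h seed derives from the h value so the scan is row-order invariant
    fit <- fitDFE(nonsynSfs, caches, family, dominanceMap(hValues[i]),
                  thetaNS, nStarts = nStarts,
                  seed = seed + as.integer(round(1000 * hValues[i])))
    d <- data.frame(h = hValues[i], LL = fit@LL, AIC = fit@AIC)
    if (family == "gamma") {
      d$shape <- fit@params$shape; d$scale <- fit@params$scale
    } else {
      pm <- matrix(fit@params$proportions, 1)
      colnames(pm) <- paste0("p_", binNames)
      d <- cbind(d, as.data.frame(pm))
    }
    d
  })
  out <- do.call(rbind, rows)
  out$dLL <- out$LL - max(out$LL)
  out[, c("h", "LL", "dLL", setdiff(names(out), c("h", "LL", "dLL")))]
}

#' Filter models by log-likelihood plausibility
#'
#' Retains models within \code{deltaLL} log-likelihood units of the best
#' model (default 1.92, the chi-square 95 percent half-width).
#'
#' @param models list of \linkS4class{HSModel}s or
#'   \linkS4class{FitResult}s.
#' @param deltaLL retention threshold in LL units.
#' @return the retained sublist.
#' @export
plausibilityFilter <- function(models, deltaLL = 1.92) {
  if (!length(models)) stop("no models to filter")
  ll <- vapply(models, function(m) m@LL, numeric(1))
  models[ll >= max(ll) - deltaLL]
}

#' Model averaging with Akaike weights
#'
#' Averages parameters over candidate models using
#' \eqn{w_i = e^{-\Delta AIC_i / 2} / \sum_j e^{-\Delta AIC_j / 2}} with
#' \eqn{\Delta AIC_i = AIC_i - \min_j AIC_j}.  For
#' \linkS4class{HSModel}s the averaged quantities are the five DFE
#' proportions (which remain on the simplex by linearity), the per-bin
#' dominance coefficients, and the overall mean dominance of new
#' mutations.
#'
#' @param models non-empty list of \linkS4class{HSModel}s (or any objects
#'   with \code{AIC} slots when \code{extract} is supplied).
#' @param extract optional function mapping a model to the numeric
#'   parameter (vector) to average.
#' @return a list with \code{weights}, and either \code{value} (custom
#'   extract) or \code{proportions}, \code{h}, \code{overallH}.
#' @export
modelAverage <- function(models, extract = NULL) {
  if (!length(models)) stop("no models to average")
  aic <- vapply(models, function(m) m@AIC, numeric(1))
  d <- aic - min(aic)
  w <- exp(-d / 2)
  w <- w / sum(w)
  if (!is.null(extract)) {
    vals <- vapply(models, extract, numeric(length(extract(models[[1]]))))
    avg <- if (is.matrix(vals)) as.vector(vals %*% w) else sum(vals * w)
    return(list(weights = w, value = avg))
  }
  P <- vapply(models, function(m) m@dfe@proportions, numeric(5))
  H <- vapply(models, function(m) m@hmap@h, numeric(5))
  hb <- vapply(models, function(m) averageH(m@dfe, m@hmap), numeric(1))
  list(weights = w,
       proportions = as.vector(P %*% w),
       h = as.vector(H %*% w),
       overallH = sum(hb * w))
}

#' Fit every enumerated dominance model
#'
#' Runs [fitDFE()] (discrete family) for each \linkS4class{DominanceMap},
#' with a per-model derived seed, and wraps results as
#' \linkS4class{HSModel}s.
#'
#' @inheritParams fitDFE
#' @param maps list of \linkS4class{DominanceMap}s (e.g. from
#'   [enumerateHSModels()]).
#' @param nStarts restarts per model (study protocol: 5).
#' @return list of \linkS4class{HSModel}s.
#' @export
fitHSModels <- function(nonsynSfs, caches, maps, thetaNS, nStarts = 5L,
                        seed = 1L) {
  lapply(seq_along(maps), function(i) {
    fit <- fitDFE(nonsynSfs, caches, "discrete", maps[[i]], thetaNS,
                  nStarts = nStarts, seed = seed + i)
    new("HSModel", dfe = fit@params$dfe, hmap = maps[[i]], LL = fit@LL,
        AIC = fit@AIC)
  })
}

#' Tabulate fitted dominance models
#'
#' @param models list of \linkS4class{HSModel}s.
#' @return data.frame with proportions, h values, LL and AIC per model.
#' @export
hsModelTable <- function(models) {
  do.call(rbind, lapply(models, function(m) {
    d <- as.data.frame(c(setNames(as.list(m@dfe@proportions),
                                  paste0("p_", binNames)),
                         setNames(as.list(m@hmap@h),
                                  paste0("h_", binNames))))
    d$LL <- m@LL; d$AIC <- m@AIC
    d
  }))
}
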