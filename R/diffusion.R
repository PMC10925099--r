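#' Non-uniform frequency grid for the diffusion solver
#'
#' Interior grid on (0, 1) concentrated near both boundaries (tanh map), as
#' is usual for allele-frequency diffusion solvers: the density varies like
#' \eqn{1/q} near 0, so resolution is pushed to the edges.
#'
#' @param G number of interior points (2000 or more for production use;
#'   examples and tests use smaller grids).
#' @param crowding concentration strength; larger values push more points
#'   toward the boundaries.
#' @return strictly increasing numeric vector of length \code{G}.
#' @export
makeFrequencyGrid <- function(G = 2000L, crowding = 2.5) {
  u <- seq_len(G) / (G + 1)
  0.5 * (1 + tanh(crowding * (2 * u - 1)) / tanh(crowding))
}

# discrete mutational source: minus the neutral constant-size operator
# applied to the exact neutral equilibrium 1/x, so that phi = theta/x is an
# exact discrete fixed point (a consistent discretization of the theta/2
# boundary influx)
mutationSource <- function(grid, theta = 1) {
  -theta * .diffusionApplyL(1 / grid, grid, 0, 0.5, 1)
}

#' Propagate an allele-frequency density through a demographic history
#'
#' Integrates the 1D forward diffusion (drift + selection with dominance +
#' mutational influx at the low-frequency boundary) through the epochs of
#' \code{demo}, starting from \code{phi} (normally the ancestral
#' equilibrium).  Within an epoch of relative size \eqn{\nu} the drift
#' term is rescaled by \eqn{1/\nu}; selection per generation is unchanged.
#'
#' @param phi a \linkS4class{FrequencyDensity} (the state at the start).
#' @param demo an \linkS4class{EpochModel}.
#' @param sel a \linkS4class{SelectionParams}.
#' @param theta mutation-rate scale of the influx (1 for unit spectra).
#' @param dt base time step in \eqn{2 N_{anc}}-generation units.
#' @param rtol successive step-halving stops once solutions agree to this
#'   relative tolerance (or after \code{maxRefine} halvings).
#' @param maxRefine maximum number of step halvings.
#' @return a \linkS4class{FrequencyDensity} after all epochs.
#' @export
propagateDensity <- function(phi, demo, sel, theta = 1, dt = 1e-3,
                             rtol = 1e-6, maxRefine = 3L) {
  stopifnot(is(phi, "FrequencyDensity"), is(demo, "EpochModel"),
            is(sel, "SelectionParams"))
  grid <- phi@grid
  src <- mutationSource(grid, theta)
  runAll <- function(dtk) {
    v <- phi@values
    for (i in seq_len(nrow(demo@epochs))) {
      e <- demo@epochs[i, ]
      v <- .diffusionIntegrate(v, grid, sel@gamma, sel@h, e$nu0, e$nu1,
                               e$tau, e$mode == "exponential", dtk, src, 0.5)
    }
    v
  }
  cur <- runAll(dt)
  if (!all(is.finite(cur)))
    stop("diffusion solve diverged (grid size ", length(grid),
         ", dt ", dt, "); refine the grid or reduce dt")
  for (k in seq_len(maxRefine)) {
    dt <- dt / 2
    nxt <- runAll(dt)
    ref <- pmax(abs(cur), max(abs(cur)) * 1e-8)
    if (max(abs(nxt - cur) / ref) < rtol) {
      cur <- nxt
      break
    }
    cur <- nxt
  }
  new("FrequencyDensity", grid = grid, values = cur)
}
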