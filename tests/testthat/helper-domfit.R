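# shared fixtures: small solver grids and expected-SFS caches, memoized so
# independent test files can reuse them without rebuilding

.testEnv <- new.env(parent = emptyenv())

testGrid <- function(G = 400L) {
  key <- paste0("grid", G)
  if (is.null(.testEnv[[key]])) .testEnv[[key]] <- makeFrequencyGrid(G)
  .testEnv[[key]]
}

# two-epoch test demography: a bottleneck then exponential regrowth,
# qualitatively like the European history at a desk-friendly scale
testDemography <- function() {
  epochModel(nu0 = c(0.3, 0.3), nu1 = c(0.3, 3), tau = c(0.08, 0.05),
             mode = c("constant", "exponential"))
}

# cache fixture: nS grid points, sample size n, ancestral size Nanc
testCache <- function(h, demo = testDemography(), n = 24L, Nanc = 500,
                      nS = 120L, G = 300L) {
  key <- paste("cache", h, demogHash(demo), n, Nanc, nS, G, sep = "|")
  if (is.null(.testEnv[[key]]))
    .testEnv[[key]] <- buildGridCache(h, demo, n, Nanc, nS = nS,
                                      grid = testGrid(G), maxRefine = 0L)
  .testEnv[[key]]
}

testCaches <- function(hs, ...) lapply(hs, testCache, ...)

# closed-form genic-selection equilibrium density (h = 1/2), in the
# package's sign convention (gamma > 0 deleterious); independent oracle
genicDensity <- function(q, gamma) {
  if (gamma == 0) return(1 / q)
  (exp(-2 * gamma * q) - exp(-2 * gamma)) /
    (q * (1 - q) * (1 - exp(-2 * gamma)))
}

# Richardson extrapolation of the matrix oracle toward the diffusion limit
# (cancels the O(1/N) discreteness of the discrete Wright-Fisher model)
wfOracleExtrapolated <- function(sel, demo, n, N1 = 100, N2 = 200) {
  o1 <- counts(wfMatrixSFS(N1, sel, demo, n = n))
  o2 <- counts(wfMatrixSFS(N2, sel, demo, n = n))
  2 * o2 - o1
}

# fold an unfolded counts vector (test-side reimplementation)
foldCountsForTest <- function(v, n) {
  half <- floor(n / 2)
  out <- numeric(n + 1L)
  for (i in seq_len(half)) {
    j <- n - i
    out[i + 1L] <- v[i + 1L] + if (j != i) v[j + 1L] else 0
  }
  out
}
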