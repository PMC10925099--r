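test_that("neutral expected SFS is theta/i to 1e-6 relative", {
  g <- testGrid(400L)
  phi <- equilibriumDensity(selectionParams(0.5, gamma = 0), g)
  e4 <- counts(sampleExpectedSFS(phi, 4, theta = 6))
  expect_equal(e4, c(0, 6, 3, 2, 0), tolerance = 1e-9)
  e10 <- counts(sampleExpectedSFS(phi, 10, theta = 10))
  expect_equal(e10[2], 10.0, tolerance = 1e-6)
  expect_equal(e10[6], 2.0, tolerance = 1e-6)
  expect_equal(e10[2:10], 10 / (1:9), tolerance = 1e-6)
  # the full pipeline path (diffusion through a nu = 1 epoch) stays exact
  pip <- counts(expectedSFS(epochModel(nu0 = 1, tau = 0.2),
                            selectionParams(0.5, gamma = 0), 10,
                            theta = 10, grid = g, maxRefine = 0L))
  expect_equal(pip[2:10], 10 / (1:9), tolerance = 1e-6)
})

test_that("diffusion through one neutral epoch leaves equilibrium fixed", {
  g <- testGrid(400L)
  sel <- selectionParams(0.5, gamma = 0)
  phi <- equilibriumDensity(sel, g)
  out <- propagateDensity(phi, epochModel(nu0 = 1, tau = 0.5), sel,
                          maxRefine = 0L)
  expect_equal(out@values, phi@values, tolerance = 1e-6)
})

test_that("after a size change the density converges to the new equilibrium", {
  g <- testGrid(400L)
  sel0 <- selectionParams(0.5, gamma = 0)
  phi <- equilibriumDensity(sel0, g)
  # neutral: equilibrium density scales with nu
  out <- propagateDensity(phi, epochModel(nu0 = 2, tau = 20), sel0,
                          maxRefine = 0L)
  expect_equal(out@values, 2 * phi@values, tolerance = 1e-3)
  # selected: new equilibrium is nu * f(q; nu * gamma) on the bulk
  sel <- selectionParams(0.5, gamma = 4)
  out2 <- propagateDensity(equilibriumDensity(sel, g),
                           epochModel(nu0 = 0.5, tau = 10), sel,
                           maxRefine = 1L)
  ref <- 0.5 * equilibriumDensity(selectionParams(0.5, gamma = 2), g)@values
  keep <- ref > 1e-3 * max(ref)
  expect_equal(out2@values[keep], ref[keep], tolerance = 0.01)
})

test_that("diffusion expected SFS matches the Wright-Fisher matrix oracle", {
  # The discrete WF model deviates from the diffusion limit by O(1/N)
  # (mostly in the singleton class), so the oracle is evaluated at
  # 2N = 200 and 400 and Richardson-extrapolated; agreement within 2%
  # per entry is required on entries carrying mass
  g <- makeFrequencyGrid(800L)
  demo0 <- epochModel()
  cases <- list(list(gamma = 0, h = 0.5, n = 16L, demo = demo0),
                list(gamma = 10, h = 0.5, n = 20L, demo = demo0),
                list(gamma = 25, h = 0.2, n = 16L, demo = demo0),
                list(gamma = 4, h = 0.3, n = 16L,
                     demo = epochModel(nu0 = c(0.3, 2), tau = c(0.1, 0.05))))
  for (cs in cases) {
    sel <- selectionParams(cs$h, gamma = cs$gamma)
    dif <- counts(expectedSFS(cs$demo, sel, cs$n, grid = g, maxRefine = 1L))
    ora <- wfOracleExtrapolated(sel, cs$demo, cs$n)
    i <- seq(2, cs$n)
    keep <- ora[i] > 1e-4 * max(ora)
    expect_true(all(keep[1:3]))
    expect_equal(dif[i][keep], ora[i][keep], tolerance = 0.02)
  }
})

test_that("matrix oracle reproduces classical neutral and lethal behavior", {
  demo0 <- epochModel()
  o <- counts(wfMatrixSFS(100, selectionParams(0.5, gamma = 0), demo0,
                          n = 16))
  expect_equal(o[2:16] * (1:15), rep(1, 15), tolerance = 0.04)
  # lethal (s = 0.5 at 2N = 200): singletons dominate
  lethal <- counts(wfMatrixSFS(100, selectionParams(0.5, gamma = 100),
                               demo0, n = 16))
  expect_lt(max(lethal[4:16]) / lethal[2], 0.01)
})

test_that("deleterious parameters depress the mean sample frequency", {
  g <- testGrid(400L)
  demo <- testDemography()
  meanFreq <- function(gamma, h) {
    e <- counts(expectedSFS(demo, selectionParams(h, gamma = gamma), 20,
                            grid = g, maxRefine = 0L))
    i <- 1:19
    sum(i * e[i + 1]) / (20 * sum(e[i + 1]))
  }
  neutral <- meanFreq(0, 0.5)
  for (h in c(0.1, 0.5)) expect_lt(meanFreq(15, h), neutral)
})

test_that("the selection-grid cache is log-spaced with exact endpoints", {
  cache <- testCache(0.5)
  expect_equal(length(cache@s), 120L)
  expect_equal(min(cache@s), 1e-5)
  expect_equal(max(cache@s), 0.25)
  expect_lt(diff(range(diff(log(cache@s)))), 1e-12)
  expect_error(buildGridCache(0.5, testDemography(), 10, 100, sMax = 0.3),
               "0.25")
  # production grids hold 1000 points
  tiny <- buildGridCache(0.5, epochModel(), 6, 50, nS = 1000L,
                         grid = testGrid(200L))
  expect_equal(length(tiny@s), 1000L)

  # weakest-selection spectrum is close to neutral; spectra shrink with s
  relNeutral <- cache@spectra[1, 2:24] / cache@neutral[2:24]
  expect_equal(relNeutral, rep(1, 23), tolerance = 5e-3)
  tots <- rowSums(cache@spectra[, 2:24])
  expect_true(all(diff(tots[cache@s > 2e-4]) < 0))
})

test_that("cache files round-trip through the tabular format", {
  cache <- testCache(0.15)
  path <- withr::local_tempfile(fileext = ".tsv")
  writeSFSCache(cache, path)
  back <- readSFSCache(path)
  expect_equal(back@s, cache@s)
  expect_equal(back@spectra, cache@spectra, tolerance = 1e-12)
  expect_equal(back@neutral, cache@neutral, tolerance = 1e-12)
  expect_equal(back@h, cache@h)
  expect_equal(back@n, cache@n)
  expect_equal(back@Nanc, cache@Nanc)
  expect_identical(back@demogHash, cache@demogHash)
})
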