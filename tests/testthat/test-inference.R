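test_that("Poisson log-likelihood matches closed forms and dpois", {
  one <- function(x, m) {
    d <- sfs(c(0, x, 0)); mm <- sfs(c(0, m, 0))
    poissonLL(d, mm)
  }
  expect_equal(one(2, 2), -1.306853, tolerance = 1e-6)
  expect_equal(one(0, 3.7), -3.7)
  # library cross-check on random spectra
  set.seed(7)
  for (r in 1:10) {
    x <- rpois(10, 5)
    m <- runif(10, 0.5, 9)
    d <- sfs(c(0, x, 0)); mm <- sfs(c(0, m, 0))
    expect_equal(poissonLL(d, mm), sum(dpois(x, m, log = TRUE)),
                 tolerance = 1e-10)
  }
  # zero model mean with observed counts is impossible
  expect_identical(one(1, 0), -Inf)
  # shape and mask must agree
  expect_error(poissonLL(sfs(c(0, 1, 0)), sfs(c(0, 1, 1, 0))), "share")
})

test_that("optimal theta is the Poisson MLE of a multiplicative scale", {
  d <- sfs(c(0, 10, 5, 0))
  u <- sfs(c(0, 1, 0.5, 0))
  expect_equal(optimalTheta(d, u), 10)
  d2 <- sfs(c(0, 3 * 4, 3 * 2, 0))
  u2 <- sfs(c(0, 4, 2, 0))
  expect_equal(optimalTheta(d2, u2), 3)
  # maximizes the likelihood over a fine scan
  set.seed(11)
  x <- rpois(12, 8)
  m <- runif(12, 0.3, 2)
  d3 <- sfs(c(0, x, 0)); u3 <- sfs(c(0, m, 0))
  th <- optimalTheta(d3, u3)
  scan <- seq(0.5 * th, 1.5 * th, length.out = 401)
  ll <- vapply(scan, function(t) sum(dpois(x, t * m, log = TRUE)),
               numeric(1))
  expect_equal(scan[which.max(ll)], th, tolerance = 2e-3)
  expect_error(optimalTheta(d3, sfs(rep(0, 14))), "zero")
})

test_that("AIC bookkeeping matches 2k - 2 LL", {
  expect_equal(computeAIC(-1450.58, k = 2), 2905.16)
  expect_equal(computeAIC(0, k = 0), 0)
  # the discrete-vs-gamma family gap quoted as ~8.8
  expect_equal(computeAIC(-1452.97, k = 4) - computeAIC(-1450.58, k = 2),
               8.78, tolerance = 1e-9)
  fit <- new("FitResult", params = list(), LL = -10, k = 3, AIC = 26,
             converged = TRUE, nStarts = 1, seed = 1)
  expect_equal(computeAIC(fit), 26)
})

test_that("plausibility filter retains models within deltaLL of the best", {
  mk <- function(ll) new("FitResult", params = list(), LL = ll, k = 1,
                         AIC = 2 - 2 * ll, converged = TRUE, nStarts = 1,
                         seed = 1)
  ms <- lapply(c(-10, -11.9, -12.0), mk)
  expect_length(plausibilityFilter(ms, 1.92), 2L)
  expect_length(plausibilityFilter(lapply(rep(-5, 4), mk)), 4L)
  expect_error(plausibilityFilter(list()), "no models")
  # brute-force equivalence on random LL vectors
  set.seed(3)
  for (r in 1:10) {
    ll <- rnorm(20, -100, 4)
    got <- plausibilityFilter(lapply(ll, mk), 1.92)
    expect_length(got, sum(ll >= max(ll) - 1.92))
  }
})

test_that("Akaike-weight model averaging matches closed forms", {
  mk <- function(aic, p, h) new("HSModel", dfe = discreteDFE(p),
                                hmap = dominanceMap(h), LL = -aic / 2,
                                AIC = aic)
  p1 <- c(1, 0, 0, 0, 0); p2 <- c(0, 1, 0, 0, 0)
  # equal AIC: equal weights
  av <- modelAverage(list(mk(10, p1, 0), mk(10, p2, 1)))
  expect_equal(sum(av$weights), 1)
  expect_equal(av$weights, c(0.5, 0.5))
  expect_equal(av$proportions, c(0.5, 0.5, 0, 0, 0))
  expect_equal(sum(av$proportions), 1)
  # dAIC = 2: weight ratio e^{-1}
  av2 <- modelAverage(list(mk(10, p1, 0), mk(12, p1, 1)),
                      extract = function(m) hValues(m)[1])
  expect_equal(av2$value, exp(-1) / (1 + exp(-1)), tolerance = 1e-12)
  # single model returns itself
  av3 <- modelAverage(list(mk(4, p2, 0.3)))
  expect_equal(av3$proportions, p2)
  expect_equal(av3$h, rep(0.3, 5))
})

test_that("demography fit recovers theta and size parameters", {
  # neutral equilibrium data at theta = 5000: nu ~ 1, theta within 2%
  n <- 24L
  g <- testGrid(300L)
  unit <- expectedSFS(epochModel(), selectionParams(0.5, gamma = 0), n,
                      grid = g)
  expected <- foldSFS(sfs(5000 * counts(unit)))
  obs <- poissonSampleSFS(expected, seed = 5)
  fit <- fitDemography(obs, template = "two_epoch", nStarts = 4L,
                       seed = 2, grid = g)
  expect_true(is.finite(fit@LL))
  expect_equal(fit@params$nu, 1, tolerance = 0.05)
  expect_equal(fit@params$thetaS, 5000, tolerance = 0.02)
  # arithmetic: Nanc from thetaS = 4 Nanc mu LS
  expect_equal(fit@params$Nanc,
               fit@params$thetaS / (4 * 1.5e-8 * 1e7), tolerance = 1e-12)
  expect_equal(fit@params$thetaNS, 2.31 * fit@params$thetaS)

  # bottleneck + growth recovery at high theta; the final size and the
  # growth duration trade off along a likelihood ridge, so the bottleneck
  # depth, the mutation scale and the predicted spectrum are what the
  # data pin down
  demoTrue <- epochModel(nu0 = c(0.25, 0.25), nu1 = c(0.25, 4),
                         tau = c(0.1, 0.04),
                         mode = c("constant", "exponential"))
  unit2 <- expectedSFS(demoTrue, selectionParams(0.5, gamma = 0), n,
                       grid = g)
  obs2 <- poissonSampleSFS(foldSFS(sfs(50000 * counts(unit2))), seed = 9)
  fit2 <- fitDemography(obs2, template = "bottleneck_growth",
                        nStarts = 8L, seed = 3, grid = g)
  expect_equal(fit2@params$nuB, 0.25, tolerance = 0.1)
  expect_equal(fit2@params$thetaS, 50000, tolerance = 0.02)
  fittedUnit <- expectedSFS(fit2@params$demography,
                            selectionParams(0.5, gamma = 0), n, grid = g)
  expect_equal(counts(fittedUnit)[2:n] / counts(unit2)[2:n],
               rep(1, n - 1), tolerance = 0.05)
})

test_that("explicit Nanc arithmetic from the scaled mutation rate", {
  expect_equal(10000 / (4 * 1.5e-8 * 1e7), 16666.667, tolerance = 1e-6)
})

test_that("discrete-DFE fit recovers generating proportions", {
  # study-scale conditions: the five bins separate in gamma = 2 Nanc s
  # only when the ancestral size is in the tens of thousands
  caches <- testCaches(0.5, n = 864L, Nanc = 20000, nS = 150L, G = 400L)
  pTrue <- c(0.3, 0.2, 0.2, 0.2, 0.1)
  thetaNS <- 23100
  hmap <- dominanceMap(0.5)
  expected <- mixtureExpectedSFS(discreteDFE(pTrue), hmap, caches, thetaNS)
  obs <- poissonSampleSFS(foldSFS(expected), seed = 21)
  fit <- fitDFE(obs, caches, "discrete", hmap, thetaNS, nStarts = 5L,
                seed = 4)
  expect_equal(fit@params$proportions, pTrue, tolerance = Inf)
  expect_true(all(abs(fit@params$proportions - pTrue) <= 0.05))
  expect_equal(fit@k, 4)
  # data equal to a model expectation: fitted LL at least the truth's LL
  exact <- foldSFS(expected)
  exact <- sfs(round(counts(exact)), folded = TRUE, mask = sfsMask(exact))
  fitE <- fitDFE(exact, caches, "discrete", hmap, thetaNS, nStarts = 5L,
                 seed = 5)
  m <- foldCountsForTest(
    counts(mixtureExpectedSFS(discreteDFE(pTrue), hmap, caches, thetaNS)),
    sampleSize(exact))
  llTruth <- sum(dpois(counts(exact)[!sfsMask(exact)],
                       m[!sfsMask(exact)], log = TRUE))
  expect_gte(fitE@LL + 1e-6, llTruth)
})

test_that("gamma-DFE fit attains the truth's likelihood", {
  caches <- testCaches(0.5, n = 864L, Nanc = 20000, nS = 150L, G = 400L)
  thetaNS <- 23100
  hmap <- dominanceMap(0.5)
  expected <- mixtureExpectedSFS(gammaDFE(0.2, 0.01), hmap, caches, thetaNS)
  obs <- poissonSampleSFS(foldSFS(expected), seed = 31)
  fit <- fitDFE(obs, caches, "gamma", hmap, thetaNS, nStarts = 8L, seed = 6)
  m <- foldCountsForTest(
    counts(mixtureExpectedSFS(gammaDFE(0.2, 0.01), hmap, caches, thetaNS)),
    sampleSize(obs))
  llTruth <- sum(dpois(counts(obs)[!sfsMask(obs)],
                       m[!sfsMask(obs)], log = TRUE))
  expect_gte(fit@LL, llTruth - 2)
  expect_equal(fit@k, 2)
})

test_that("profile-h scan rejects recessive h and tracks the truth", {
  # at study-scale data the profile is nearly flat for h above ~0.15 (the
  # DFE absorbs dominance changes through hs compensation) while highly
  # recessive models are strongly rejected; the test asserts exactly that
  # structure rather than a unique interior peak
  hs <- c(0, 0.05, 0.15, 0.35, 0.5)
  caches <- testCaches(hs, n = 864L, Nanc = 20000, nS = 150L, G = 400L)
  thetaNS <- 46200
  plateau <- list(`0.2` = c(0.15, 0.35), `0.5` = c(0.35, 0.5))
  for (hTrue in c(0.2, 0.5)) {
    cT <- testCache(hTrue, n = 864L, Nanc = 20000, nS = 150L, G = 400L)
    expected <- mixtureExpectedSFS(discreteDFE(c(0.3, 0.2, 0.2, 0.2, 0.1)),
                                   dominanceMap(hTrue), list(cT), thetaNS)
    obs <- poissonSampleSFS(foldSFS(expected), seed = 40 + round(10 * hTrue))
    scan <- profileHScan(obs, caches, "discrete", hs, thetaNS,
                         nStarts = 5L, seed = 8)
    expect_equal(nrow(scan), 5L)
    expect_equal(max(scan$dLL), 0)
    best <- scan$h[which.max(scan$LL)]
    expect_true(best %in% plateau[[as.character(hTrue)]])
    # fully and highly recessive models fall far outside 1.92 LL units
    expect_lt(scan$dLL[scan$h == 0], -1.92)
    expect_lt(scan$dLL[scan$h == 0.05], -1.92)
    # row order of hValues does not matter (seeds derive from h)
    scan2 <- profileHScan(obs, caches, "discrete", rev(hs), thetaNS,
                          nStarts = 5L, seed = 8)
    expect_equal(sort(scan2$LL), sort(scan$LL), tolerance = 1e-9)
  }
})
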