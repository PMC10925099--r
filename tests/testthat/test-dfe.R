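test_that("dominance-model enumeration matches the combinatorics", {
  maps <- enumerateHSModels()
  expect_length(maps, 4096L)
  expect_true(all(vapply(maps, function(m) hValues(m)[1] == 0.5, logical(1))))
  expect_length(enumerateHSModels(c(0.15, 0.5)), 16L)
  expect_length(enumerateHSModels(c(0, 0.25, 0.5)), 81L)
  # deterministic lexicographic order and uniqueness
  key <- vapply(maps, function(m) paste(hValues(m), collapse = ","),
                character(1))
  expect_identical(key, vapply(enumerateHSModels(), function(m)
    paste(hValues(m), collapse = ","), character(1)))
  expect_equal(anyDuplicated(key), 0L)
})

test_that("mixture spectra are linear in proportions and theta", {
  caches <- testCaches(c(0.15, 0.5))
  hmap <- dominanceMap(c(0.5, 0.5, 0.5, 0.15, 0.15))
  # all-neutral mixture gives the neutral spectrum times theta
  allNeutral <- discreteDFE(c(1, 0, 0, 0, 0))
  m <- counts(mixtureExpectedSFS(allNeutral, hmap, caches, thetaNS = 7))
  expect_equal(m[2:24], 7 * caches[[2]]@neutral[2:24], tolerance = 1e-12)
  # 50/50 two-bin mixture is the average of the single-bin spectra
  d1 <- discreteDFE(c(0, 0, 1, 0, 0))
  d2 <- discreteDFE(c(0, 0, 0, 0, 1))
  d12 <- discreteDFE(c(0, 0, 0.5, 0, 0.5))
  m1 <- counts(mixtureExpectedSFS(d1, hmap, caches, 10))
  m2 <- counts(mixtureExpectedSFS(d2, hmap, caches, 10))
  m12 <- counts(mixtureExpectedSFS(d12, hmap, caches, 10))
  expect_equal(m12, (m1 + m2) / 2, tolerance = 1e-12)
  # theta linearity
  expect_equal(counts(mixtureExpectedSFS(d12, hmap, caches, 30)), 3 * m12,
               tolerance = 1e-12)
  # a missing cache is reported with its h value
  expect_error(
    mixtureExpectedSFS(d1, dominanceMap(0.35), caches, 1), "0.35")
})

test_that("gamma-DFE mixture matches a brute-force fine-grid sum", {
  cache <- testCache(0.5)
  dfe <- gammaDFE(0.2, 0.01)
  got <- counts(mixtureExpectedSFS(dfe, dominanceMap(0.5), list(cache), 1))
  # oracle: Riemann sum over a 10x finer log grid, interpolating cached
  # spectra in log-s (the cache is the shared ingredient; the weighting
  # scheme under test is recomputed independently)
  sFine <- exp(seq(log(1e-5), log(0.25), length.out = 2000))
  wFine <- diff(pgamma(c(sFine[1],
                         sqrt(sFine[-1] * sFine[-2000]), 0.25),
                       shape = 0.2, scale = 0.01))
  interp <- apply(cache@spectra, 2, function(col)
    approx(log(cache@s), col, xout = log(sFine), rule = 2)$y)
  oracle <- as.vector(crossprod(interp, wFine)) +
    pgamma(1e-5, 0.2, scale = 0.01) * cache@neutral
  i <- 2:24
  expect_equal(got[i], oracle[i], tolerance = 5e-3)
})

test_that("average dominance reproduces the published model summaries", {
  rows <- list(
    list(p = c(0.259, 0.125, 0.176, 0.254, 0.186),
         h = c(0.5, 0.5, 0.5, 0.35, 0.15), avg = 0.40),
    list(p = c(0.244, 0.152, 0.125, 0.259, 0.22),
         h = c(0.5, 0.5, 0.45, 0.25, 0.1), avg = 0.34),
    list(p = c(0.201, 0.222, 0.018, 0.286, 0.274),
         h = c(0.5, 0.45, 0.25, 0.15, 0.05), avg = 0.26))
  for (r in rows) {
    got <- averageH(discreteDFE(r$p / sum(r$p)), dominanceMap(r$h))
    expect_equal(round(got, 2), r$avg)
  }
  # constant map: average equals the constant for any proportions
  expect_equal(averageH(discreteDFE(rep(0.2, 5)), dominanceMap(0.3)), 0.3)
  # bounded by the extremes of the map
  set.seed(1)
  for (i in 1:20) {
    p <- rexp(5); p <- p / sum(p)
    h <- runif(5)
    a <- averageH(discreteDFE(p), dominanceMap(h))
    expect_gte(a, min(h)); expect_lte(a, max(h))
  }
})

test_that("monotonic filter keeps non-strict h decay only", {
  keep1 <- dominanceMap(c(0.5, 0.45, 0.25, 0.15, 0.05))
  keep2 <- dominanceMap(rep(0.5, 5))          # ties allowed
  drop1 <- dominanceMap(c(0.5, 0.15, 0.45, 0.25, 0.05))
  out <- monotonicFilter(list(keep1, drop1, keep2))
  expect_length(out, 2L)
  expect_equal(hValues(out[[1]]), hValues(keep1))
  # also operates on fitted models
  hs <- new("HSModel", dfe = discreteDFE(rep(0.2, 5)), hmap = drop1,
            LL = -1, AIC = 10)
  expect_length(monotonicFilter(list(hs)), 0L)
})
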