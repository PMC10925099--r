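test_that("genetic load composes fixed and segregating effects", {
  empty <- matrix(0L, 0, 5)
  # one fixed site of s = 0.1: load = 0.1 for any h
  for (h in c(0, 0.25, 0.5))
    expect_equal(geneticLoad(sampleGenotypes(empty, numeric(), numeric(),
                                             fixedS = 0.1, fixedH = h)),
                 0.1, tolerance = 1e-12)
  # two fixed sites multiply: 1 - 0.9^2
  expect_equal(geneticLoad(sampleGenotypes(empty, numeric(), numeric(),
                                           fixedS = c(0.1, 0.1),
                                           fixedH = c(0, 0))),
               0.19, tolerance = 1e-12)
  # every individual heterozygous at one site s = 0.1, h = 0.5
  sg <- sampleGenotypes(matrix(1L, 1, 4), 0.1, 0.5)
  expect_equal(geneticLoad(sg), 0.05, tolerance = 1e-12)
  # lethal homozygote drives individual fitness to zero
  sg2 <- sampleGenotypes(matrix(c(2L, 0L), 1, 2), 1, 0.1)
  expect_equal(geneticLoad(sg2), 0.5, tolerance = 1e-12)
})

test_that("genetic load is invariant to site order and splitting", {
  set.seed(13)
  G <- matrix(sample(0:2, 60, replace = TRUE, prob = c(0.7, 0.2, 0.1)),
              nrow = 12)
  s <- runif(12, 0, 0.3); h <- runif(12)
  full <- geneticLoad(sampleGenotypes(G, s, h))
  perm <- sample(12)
  expect_equal(geneticLoad(sampleGenotypes(G[perm, ], s[perm], h[perm])),
               full, tolerance = 1e-12)
  # brute-force per-individual fitness oracle
  w <- vapply(1:5, function(i) {
    prod(ifelse(G[, i] == 2L, 1 - s, ifelse(G[, i] == 1L, 1 - s * h, 1)))
  }, numeric(1))
  expect_equal(full, 1 - mean(w), tolerance = 1e-12)
  # fixed-site fitness composes multiplicatively with segregating sites
  withFix <- geneticLoad(sampleGenotypes(G, s, h, fixedS = 0.2,
                                         fixedH = 0.5))
  expect_equal(1 - withFix, (1 - full) * 0.8, tolerance = 1e-12)
})

test_that("inbreeding load is the concealed recessive effect sum", {
  # one site s = 1, h = 0, q = 0.01 in a 50-individual sample
  G <- matrix(0L, 1, 50); G[1, 1] <- 1L
  expect_equal(inbreedingLoad(sampleGenotypes(G, 1, 0)), 0.0099)
  # additive sites contribute exactly zero to the regression-slope form
  G2 <- matrix(sample(0:1, 30, TRUE), 3, 10)
  sgAdd <- sampleGenotypes(G2, rep(0.2, 3), rep(0.5, 3))
  expect_equal(inbreedingLoad(sgAdd, kind = "slope"), 0)
  # while the concealed form still counts their half-exposure excess
  qAdd <- rowSums(G2) / 20
  expect_equal(inbreedingLoad(sgAdd),
               sum(0.2 * qAdd * (1 - qAdd) * 0.5), tolerance = 1e-12)
  # fixed sites contribute zero
  expect_equal(inbreedingLoad(sampleGenotypes(matrix(0L, 0, 10), numeric(),
                                              numeric(), fixedS = 0.5,
                                              fixedH = 0)), 0)
})

test_that("inbreeding load matches a genotype-frequency enumeration", {
  # oracle: expected load difference between fully inbred (F = 1) and
  # outbred (F = 0) genotype frequencies under the small-s linearization
  set.seed(29)
  G <- matrix(sample(0:2, 200, TRUE, prob = c(0.8, 0.15, 0.05)), 20, 10)
  s <- runif(20, 0, 0.05); h <- runif(20, 0, 0.5)
  q <- rowSums(G) / 20
  loadF <- function(F) sum((2 * q * (1 - q) * (1 - F)) * s * h +
                           (q^2 + F * q * (1 - q)) * s)
  expect_equal(inbreedingLoad(sampleGenotypes(G, s, h), kind = "slope"),
               loadF(1) - loadF(0), tolerance = 1e-10)
  # the concealed form exceeds the slope form by the expressed het effect
  expect_equal(inbreedingLoad(sampleGenotypes(G, s, h)) -
                 inbreedingLoad(sampleGenotypes(G, s, h), kind = "slope"),
               sum(s * q * (1 - q) * h), tolerance = 1e-10)
})

test_that("derived-allele counts average genotypes plus fixed sites", {
  G <- matrix(1L, 1, 8)
  expect_equal(derivedAlleleCount(sampleGenotypes(G, 0.1, 0.5)), 1)
  expect_equal(derivedAlleleCount(sampleGenotypes(matrix(0L, 0, 8),
                                                  numeric(), numeric(),
                                                  fixedS = 0.2,
                                                  fixedH = 0.5)), 2)
  set.seed(17)
  G2 <- matrix(sample(0:2, 120, TRUE), 12, 10)
  got <- derivedAlleleCount(sampleGenotypes(G2, runif(12), runif(12),
                                            fixedS = c(0.1, 0.2),
                                            fixedH = c(0, 0)))
  # brute-force double loop
  tot <- 0
  for (i in 1:10) {
    for (r in 1:12) tot <- tot + G2[r, i]
  }
  expect_equal(got, tot / 10 + 4)
})

test_that("genome projection exponentiates fitness and scales sums", {
  st <- data.frame(replicate = 1L, population = "AFR", load = 0.01,
                   B = 0.05, count = 10, projected = FALSE)
  res <- new("SimResult", stats = st, lambda = 1, factor = 1, seed = 1)
  pr <- projectToGenome(res, chromosomes = 2)
  expect_equal(simStats(pr)$load, 1 - 0.99^11, tolerance = 1e-12)
  expect_equal(simStats(pr)$load, 0.10466, tolerance = 1e-4)
  expect_equal(simStats(pr)$B, 0.55)
  expect_equal(simStats(pr)$count, 110)
  # factor 1 is the identity
  id <- projectToGenome(res, factor = 1)
  expect_equal(simStats(id)$load, 0.01)
  expect_error(projectToGenome(res, chromosomes = 2.5), "integer")
})
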