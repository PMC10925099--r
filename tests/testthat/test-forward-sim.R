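test_that("mutation-effect draws follow the bin mixture", {
  # degenerate model: everything in the strong bin
  deg <- simDominanceModel(c(0, 0, 0, 0, 1), c(rep(0.5, 4), 0.05))
  d <- drawMutationEffects(deg, 2000, seed = 1)
  expect_true(all(d$bin == 5L))
  expect_true(all(d$s >= 2e-2 & d$s <= 1))
  expect_true(all(d$h == 0.05))
  # mean s of a uniform draw on the strong bin: (0.02 + 1) / 2
  big <- drawMutationEffects(deg, 1e6, seed = 2)
  expect_equal(mean(big$s), 0.51, tolerance = 0.01)
  # empirical bin frequencies within 3 sigma of multinomial expectation
  mod <- dominanceModel("weakly_recessive")
  dd <- drawMutationEffects(mod, 1e6, seed = 3)
  p <- proportions(mod@dfe)
  freq <- tabulate(dd$bin, 5) / 1e6
  expect_true(all(abs(freq - p) <= 3 * sqrt(p * (1 - p) / 1e6)))
  expect_gt(suppressWarnings(chisq.test(tabulate(dd$bin, 5),
                                        p = p)$p.value), 1e-4)
})

test_that("a fixed seed reproduces the simulation bit-exactly", {
  gm <- genomeModel(genesPerChrom = c(60L, 60L))
  mod <- dominanceModel("strongly_recessive")
  r1 <- simulateLoad(gm, constantDemography(150), mod, burnIn = 400L,
                     seed = 42, keepSample = TRUE)
  r2 <- simulateLoad(gm, constantDemography(150), mod, burnIn = 400L,
                     seed = 42, keepSample = TRUE)
  expect_identical(simStats(r1), simStats(r2))
  expect_identical(attr(r1, "samples"), attr(r2, "samples"))
  r3 <- simulateLoad(gm, constantDemography(150), mod, burnIn = 400L,
                     seed = 43)
  expect_false(identical(simStats(r1)$B, simStats(r3)$B))
})

test_that("neutral equilibrium diversity matches 4 N mu", {
  gm <- genomeModel(genesPerChrom = c(50L, 50L))
  neutral <- simDominanceModel(c(1, 0, 0, 0, 0), rep(0.5, 5))
  L <- 100 * 1340
  pis <- vapply(1:20, function(r) {
    res <- simulateLoad(gm, constantDemography(100), neutral,
                        burnIn = 1500L, seed = 100 + r, keepSample = TRUE)
    sm <- attr(res, "samples")$AFR
    nInd <- ncol(sm$geno)
    q <- rowSums(sm$geno) / (2 * nInd)
    sum(2 * q * (1 - q) * (2 * nInd) / (2 * nInd - 1)) / L
  }, numeric(1))
  expect_equal(mean(pis), 4 * 100 * 1.05e-8, tolerance = 0.10)
})

test_that("segregating input matches mutation-selection balance", {
  # one bin tightly around s = 0.01, h = 0.5 at N = 1000 (4Nhs = 20)
  bal <- simDominanceModel(c(0, 0, 0, 0, 1), rep(0.5, 5),
                           edges = c(0, 1e-9, 2e-9, 3e-9, 0.009, 0.011))
  gm <- genomeModel(genesPerChrom = c(250L, 250L))
  L <- 500 * 1340
  qbar <- vapply(1:3, function(r) {
    res <- simulateLoad(gm, constantDemography(1000), bal, burnIn = 8000L,
                        seed = 300 + r, keepSample = TRUE)
    sm <- attr(res, "samples")$AFR
    sum(rowSums(sm$geno)) / (2 * ncol(sm$geno)) / L
  }, numeric(1))
  # deterministic balance of the mean per-site frequency: mu E[1/(h s)]
  qhat <- 1.05e-8 / 0.5 * (log(0.011 / 0.009) / (0.011 - 0.009))
  expect_equal(mean(qbar), qhat, tolerance = 0.15)
})

test_that("with no selection the two demes are exchangeable", {
  demo <- new("TwoPopDemography",
              params = c(Nanc = 150, NafrGrowth = 150, Tafr = 400,
                         Tsplit = 300, Nbot = 150, Tbot = 150, Neu0 = 150,
                         Neu1 = 150, Tgrowth = 100, NafrFinal = 150,
                         NeuFinal = 150))
  neutral <- simDominanceModel(c(1, 0, 0, 0, 0), rep(0.5, 5))
  gm <- genomeModel(genesPerChrom = c(40L, 40L))
  st <- do.call(rbind, lapply(1:10, function(r)
    simStats(simulateLoad(gm, demo, neutral, seed = 500 + r))))
  cA <- st$count[st$population == "AFR"]
  cE <- st$count[st$population == "EUR"]
  expect_equal(mean(cE) / mean(cA), 1, tolerance = 0.1)
  expect_equal(mean(st$load), 0, tolerance = 1e-4)
})

test_that("results are invariant to the rescaling factor", {
  # same model and demography at lambda 5 vs 10: B and load agree within
  # 10% (means over 20 replicates)
  demo <- new("TwoPopDemography",
              params = c(Nanc = 2000, NafrGrowth = 3000, Tafr = 1600,
                         Tsplit = 800, Nbot = 600, Tbot = 400, Neu0 = 600,
                         Neu1 = 1500, Tgrowth = 100, NafrFinal = 6000,
                         NeuFinal = 8000))
  gm <- genomeModel(genesPerChrom = c(100L, 100L))
  mod <- dominanceModel("strongly_recessive")
  run <- function(lambda) {
    st <- simStats(simulateReplicates(gm, demo, mod, reps = 20L,
                                      rescale = lambda, seed = 11))
    c(B = mean(st$B), load = mean(st$load))
  }
  r5 <- run(5)
  r10 <- run(10)
  expect_equal(r10[["B"]], r5[["B"]], tolerance = 0.1)
  expect_equal(r10[["load"]], r5[["load"]], tolerance = 0.1)
})

test_that("rescaling cannot shrink a deme below the drift guard", {
  gm <- genomeModel(genesPerChrom = c(20L, 20L))
  expect_error(simulateLoad(gm, outOfAfricaDemography(),
                            dominanceModel("weakly_recessive"),
                            rescale = 40, seed = 1),
               "below 50")
})
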