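test_that("neutral stationary density is exactly 1/q", {
  sel <- selectionParams(h = 0.5, gamma = 0)
  expect_equal(stationaryDensity(0.5, sel), 2.0)
  expect_equal(stationaryDensity(0.25, sel), 4.0)
  expect_error(stationaryDensity(0, sel), "inside")
  expect_error(stationaryDensity(1, sel), "inside")
  g <- testGrid(200L)
  eq <- equilibriumDensity(sel, g)
  expect_equal(eq@values, 1 / g)
})

test_that("selected density matches an independent adaptive quadrature", {
  # oracle: direct integrate() of the density formula, written before the
  # engine's piecewise quadrature and sharing no code with it
  oracle <- function(q, gamma, h) {
    G <- function(e) 4 * gamma * h * e + 2 * gamma * (1 - 2 * h) * e^2
    num <- integrate(function(e) exp(G(e)), q, 1, rel.tol = 1e-12)$value
    den <- integrate(function(e) exp(G(e)), 0, 1, rel.tol = 1e-12)$value
    exp(-G(q)) / (q * (1 - q)) * num / den
  }
  cases <- expand.grid(q = c(0.02, 0.1, 0.5, 0.9),
                       gamma = c(0.5, 5, 40), h = c(0, 0.2, 0.5, 1))
  for (i in seq_len(nrow(cases))) {
    sel <- selectionParams(h = cases$h[i], gamma = cases$gamma[i])
    expect_equal(stationaryDensity(cases$q[i], sel),
                 oracle(cases$q[i], cases$gamma[i], cases$h[i]),
                 tolerance = 1e-8)
  }
  # frozen spot value (gamma = 5, h = 0.2, q = 0.1), from the oracle
  expect_equal(stationaryDensity(0.1, selectionParams(0.2, gamma = 5)),
               7.0136563, tolerance = 1e-6)
})

test_that("additive (h = 1/2) density reduces to the genic closed form", {
  g <- testGrid(300L)
  for (gamma in c(0.5, 2, 10, 60)) {
    eq <- equilibriumDensity(selectionParams(0.5, gamma = gamma), g)
    expect_equal(eq@values, genicDensity(g, gamma), tolerance = 1e-8)
  }
})

test_that("deleterious selection shifts mass toward low frequency", {
  g <- testGrid(300L)
  neutral <- equilibriumDensity(selectionParams(0.5, gamma = 0), g)
  for (h in c(0.0, 0.2, 0.5)) {
    del <- equilibriumDensity(selectionParams(h, gamma = 10), g)
    # density mass int q f dq strictly below the neutral mass
    w <- diff(c(0, g)) # crude left widths suffice for an inequality
    expect_lt(sum(w * g * del@values), sum(w * g * neutral@values))
    # high-frequency density suppressed
    expect_lt(del@values[250] / neutral@values[250], 0.5)
  }
  expect_error(
    equilibriumDensity(selectionParams(0.5, gamma = 2e6), testGrid(200L)),
    "stable range")
})
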