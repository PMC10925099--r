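---
title: "Dominance and the DFE from site frequency spectra: models and methods"
author: "domfit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance and the DFE from site frequency spectra: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

The fitness cost of a heterozygous genotype relative to the homozygote —
the dominance coefficient *h* — is one of the most poorly measured
quantities in population genetics, yet it controls how deleterious
variation responds to bottlenecks, how much inbreeding depression a
population conceals, and how selection and drift trade off for rare
variants.  `domfit` implements a complete pipeline for constraining
*h* jointly with the distribution of fitness effects (DFE) of new
nonsynonymous mutations from a folded site frequency spectrum (SFS), and
for propagating the fitted dominance models through forward simulations
of genetic load and inbreeding load in a two-population human history.

The data the pipeline targets are folded synonymous and nonsynonymous
spectra from 432 European-ancestry exomes (864 chromosomes); because no
processed SFS is redistributed with the package, every stage is exercised
on synthetic data drawn from the same generative model the inference
assumes.

# The population-genetic model

## Expected spectra under selection with dominance

Fitness follows the inference convention: genotypes have fitnesses
1, 1 − 2*sh* and 1 − 2*s*, with deleterious *s* in [0, 0.5] (0.5 is a
lethal).  With γ = 2·N~anc~·*s*, the equilibrium density of the mutant
frequency *q* under mutation–selection–drift balance is

f(q; γ, h) = e^−G(q)^ / (q(1−q)) · ∫~q~^1^ e^G(ε)^ dε / ∫~0~^1^ e^G(ε)^ dε,
  G(ε) = 4γhε + 2γ(1−2h)ε²,

normalized so that the neutral case is exactly 1/q per unit mutation
influx.  A sign convention is needed here: the textbook form of this
density treats deleterious coefficients as negative, while the fitting
convention stores them positive.  `domfit` fixes the orientation
internally (γ → −γ relative to the textbook form) so that positive,
deleterious γ always pushes density toward low frequency; an explicit
orientation test asserts this.  At *h* = 1/2 the density reduces to the
classical genic-selection closed form, which the tests verify to 1e−8
relative error.

Demographic change is handled by integrating the 1-D forward diffusion
(drift + selection with dominance + boundary mutation influx) through a
piecewise history of relative sizes ν = N/N~anc~, with drift scaled by
1/ν per epoch and time in units of 2·N~anc~ generations.  The solver uses
Scharfetter–Gummel (exponentially fitted) fluxes on a tanh-stretched grid
concentrated at both boundaries, Crank–Nicolson time stepping with a base
step of 1e−3 and optional step-halving refinement (default tolerance
1e−6, at most 3 halvings), and a discrete mutation source defined as
−L[1/q] under the neutral constant-size operator — which makes the
neutral equilibrium an exact fixed point of the discretization at any
grid size, so the neutral spectrum is θ/i to machine precision along
every code path.

Sampling a density into a spectrum uses the binomial kernel
E[x~i~] = θ ∫ C(n,i) q^i^ (1−q)^n−i^ f(q) dq, computed by Gauss–Legendre
quadrature of g(q) = q(1−q)·f(q) against C(n,i) q^i−1^ (1−q)^n−i−1^; the
1/q and 1/(1−q) endpoint singularities are absorbed analytically and g is
interpolated monotonically from the solver grid.

## Validation against a discrete Wright–Fisher oracle

An independent oracle iterates the exact binomial Wright–Fisher
transition matrix (deterministic post-selection update, influx of θν/2
new mutants per generation at count 1) for 2N ≤ 1000.  The discrete
model differs from the diffusion limit by O(n/2N) in the singleton class
— at 2N = 200 the deficit is several percent, which is a property of
discreteness, not of either implementation — so the comparison tests
Richardson-extrapolate the oracle over 2N ∈ {200, 400} (2·E~400~ −
E~200~) and require agreement within 2% on every entry carrying at least
1e−4 of the spectrum mass.  Entries below that floor sit at the solver's
numerical-diffusion floor (~1e−5 of the leading entry) where relative
comparisons are meaningless.

## DFE families, the dominance grid, and fitting

Two DFE families are fit by maximum Poisson likelihood (the
Poisson-random-field assumption of independent sites), conditional on a
demography estimated first from the synonymous SFS with θ~S~ profiled
out analytically (θ̂ = Σx/Σm), N~anc~ = θ̂~S~/(4μL~S~) with μ = 1.5e−8,
and θ~NS~ = 2.31·θ~S~:

* a gamma distribution (shape, scale; k = 2), and
* a discrete five-bin mixture, uniform in *s* within bins
  (0–1e−5, 1e−5–1e−4, 1e−4–1e−3, 1e−3–1e−2, 1e−2–0.5), with the five
  proportions constrained to the simplex through a stick-breaking
  transform so only k = 4 parameters are free.

Expected spectra are precomputed on a 1000-point log-spaced grid of *s*
from 1e−5 to 0.25 per dominance value in use (desk-scale runs use fewer
points; the endpoints are always exact).  Mutations with s > 0.25 are
treated as not segregating; DFE mass below 1e−5 contributes the neutral
spectrum.  Per-bin dominance models fix the neutral bin at *h* = 0.5 and
let each other bin take one of eight values {0, 0.05, 0.1, 0.15, 0.25,
0.35, 0.45, 0.5}, giving 8⁴ = 4096 models; each is fit with 5 seeded
restarts (25 for gamma fits), filtered at 1.92 log-likelihood units below
the best model, optionally restricted to non-strict monotonic decay of
*h* with *s* (ties allowed), and model-averaged with Akaike weights
w~i~ ∝ e^−ΔAIC~i~/2^.

A genuine feature of this system — visible in the profile scans on
synthetic data — is that the likelihood is nearly flat in *h* above
about 0.15: the DFE proportions absorb dominance changes through *hs*
compensation.  Highly recessive models are rejected by tens to hundreds
of log-likelihood units, but adjacent values on the plateau (0.35 versus
0.5) differ by fractions of a unit.  The test suite therefore asserts the
plateau structure (recessive values rejected beyond 1.92 units, the best
value inside the plateau that contains the truth) rather than a unique
interior maximum, which the data cannot provide at realistic θ.

# The synthetic-data generator

`makeDataset()` draws each unmasked entry of the folded synonymous and
nonsynonymous spectra independently from Poisson distributions around
their expectations under a chosen demography, DFE, dominance map and
θ~S~ — exactly the sampling model the PRF likelihood assumes.  Defaults
are the study conditions: n = 864 chromosomes, θ~S~ = 20,000 (tens of
thousands, the scale of the real exome data), θ~NS~ = 2.31·θ~S~, and
N~anc~ = 20,000 so that adjacent selection bins separate on the γ scale
as they do at the real ancestral size (at toy N~anc~ the nearly-neutral
bins are statistically indistinguishable and per-bin recovery is not a
meaningful check).  What the generator deliberately does not emulate:
linkage between sites (the PRF model is site-independent by assumption),
ancestral-state misidentification, and any real-data filtering artifacts
— so passing recovery tests demonstrates correctness of the inference
machinery under its own assumptions, not robustness to those features of
real data.

# The forward simulator

Deleterious coding variation is simulated under a discrete-generation
Wright–Fisher model: 22,500 genes of 1,340 bp on 22 autosomes (30.16 Mb;
chromosome subsets carry proportional shares), deleterious mutation rate
1.05e−8 = 1.5e−8 × 2.31/3.31 per site per generation, crossover
probability 1e−3 per between-gene boundary per meiosis (the between-element
convention of the simulation literature this follows, not 1e−3 × 1340),
free recombination between chromosomes, none within genes.  Fitness is
multiplicative across sites in the simulation convention (1, 1 − sh,
1 − s), with bins at twice the inference-convention edges and the strong
bin extending to s = 1.  Within-bin effects are drawn uniform in *s* (the
mixture-of-uniforms reading of the discrete DFE; the alternative was not
specified and this choice matches the inference-side mixture).

The demographic schedule is the published two-population African/European
history: N~anc~ = 7,310; African growth to 14,474 at 5,920 generations
before present; European divergence 2,040 generations ago into a
1,861-diploid bottleneck lasting 1,120 generations; a first European
growth phase (1,032 growing exponentially to 9,300) until 205 generations
ago; then growth to 424,000 (Africa) and 512,000 (Europe).  The source
model includes low continental migration, which is omitted here (the
summary the simulations target — per-population load — is insensitive at
the reported precision).  Burn-in is 10·N~anc~/λ generations at the
ancestral size (standard equilibration; the mutation-count summaries
equilibrate within a few N).

## Rescaling and units

For desk-scale runs a rescaling factor λ divides population sizes and
epoch durations and multiplies mutation rates, selection coefficients
(capped at s = 1) and the per-boundary crossover probability (capped at
0.5).  Raw fitness-scale outputs of a rescaled run are λ-fold inflated,
so `simulateLoad()` de-rescales before reporting: B is divided by λ,
load maps through 1 − (1 − load)^1/λ^, and allele counts are already
λ-invariant.  This makes reported quantities invariant to λ (tested at
λ = 5 versus 10 within 10%), and it is what allows λ = 10 runs of two
chromosomes, projected by exponentiating relative fitness by 11 and
multiplying B and counts by 11, to reproduce full-scale results.

## Load metrics

From a 100-individual sample per population at the final generation:

* genetic load = 1 − mean multiplicative fitness (fixed sites, taken
  from the full population, multiply every individual by 1 − s);
* derived-allele count = mean genotype sum plus 2 per fixed site;
* inbreeding load B (haploid lethal equivalents), over segregating
  sites with sample frequency q.

The paper trail defines B only verbally ("the summed selective effects of
heterozygous recessive deleterious alleles"), and two standard formulas
fit that description.  The classical regression slope of −log fitness on
the inbreeding coefficient is Σ s·q(1−q)·(1−2h), exactly zero for
additive sites.  The concealed-load form Σ s·q(1−q)·(1−h) counts the
full-exposure excess of heterozygous alleles.  These differ materially
for partially recessive models, and the choice can be settled
quantitatively: at mutation–selection balance the slope form is bounded
by U·Σ~b~ p~b~(1−2h~b~)/h~b~ ≈ 0.35 for the weakly recessive model
(U = 0.3167 deleterious mutations per haploid genome per generation),
while the concealed form predicts ≈ 0.56 — and the published simulated
loads (≈ 0.55 / 0.92 / 2.1 for the weakly / moderately / strongly
recessive models) are only consistent with the concealed form.
`inbreedingLoad()` therefore defaults to `kind = "concealed"` (used by
`simulateLoad()` and the acceptance targets) and offers
`kind = "slope"` for the classical quantity; both are tested against
genotype-frequency enumerations.

A deterministic cross-check ships with the tests: at constant population
size, simulated B is compared with the per-bin balance prediction
U·Σ p~b~(1−h~b~)/h~b~ restricted to bins with 4Nhs ≫ 1, and agrees
within the stated factor of 1.3.

# Numerical and design choices

* Grid: tanh-stretched, ≥ 2000 points for production fits; tests and
  examples use 300–800 points, which the oracle comparisons show is
  already within a percent.
* Likelihood guards: expected entries are floored at 1e−100 inside
  optimizations so impossible models receive a huge-but-finite penalty.
* Optimizers: `nlminb` with bounded log-scale parameters for demography
  and gamma fits; unconstrained stick-breaking coordinates for the
  simplex.  Restart counts follow the study protocol (25 gamma, 5 per
  dominance model); ties break to the first-found maximum.
* Seeds: every stochastic stage takes an integer seed; per-model seeds
  derive from the global seed plus the model index, and per-h profile
  seeds derive from the h value so scans are row-order invariant.  The
  forward simulator uses a self-contained xoshiro256++ generator, so
  runs are bit-reproducible for a given seed across platforms.
* The simulator packs each haplotype entry into one 64-bit word (gene,
  bfloat16 heterozygous log-effect, serial), which quantizes per-site
  fitness effects by at most 0.8% relative — far below drift noise —
  and lets gamete assembly copy and accumulate in a single stream.
  Sites whose homozygous correction is below 1e−6 in log fitness are
  excluded from the diploid intersection scan; their combined omission
  is orders of magnitude below floating-point accumulation error.

## Desk-scale problem sizes

Full-protocol simulated-load runs (two full autosomes, λ = 10, ≥ 20
replicates per model) take several minutes per model on one CPU.  The
shipped acceptance script and the simulation acceptance tests use the
same protocol with a proportional gene share per chromosome (600 and 280
genes total respectively, with the genome projection factor raised
accordingly) and 16–20 replicates; B is a genome-wide sum, so the mean
is unchanged and only the replicate spread widens (relative SD per
replicate ≈ 12–15%, standard error of the reported means ≈ 3%).  The
recovery and profile tests use n = 864 with 120–150-point caches on
300–400-point grids.  All sizes are stated where they are used.

# Known limitations

* Real-data log-likelihoods and the published surviving-model counts
  depend on the authors' exact filtered SFS, which is not
  redistributable; the pipeline reports those quantities for any
  dadi-format input but the tests assert only synthetic-data behavior.
* The PRF inference ignores linkage; the forward simulator includes it.
  The two agree at the level of per-population means compared here, but
  no joint two-population SFS or LD-based inference is provided.
* Beneficial mutations, lognormal/point-mass DFE families, and
  uncertainty intervals (bootstrap) are out of scope.
* The h–s relationship is explored over a discrete grid of h values per
  bin, not as a parametric functional form.
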