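// Discrete-generation Wright-Fisher forward simulator of deleterious coding
// variation in one or two populations.
//
// Genome: genes of equal length on autosomes; no recombination within genes,
// a fixed crossover probability at each between-gene boundary, independent
// assortment between chromosomes.  Each new mutation is unique (infinite
// sites at the gene scale) with (s, h) drawn from a discrete mixture that is
// uniform in s within each bin (simulation fitness convention: mutant
// homozygote 1-s, heterozygote 1-sh; multiplicative across sites).
//
// Haplotype entries are single 64-bit words
//     [gene:16][log(1-sh) as bfloat16:16][serial:32]
// kept sorted; the embedded effect lets gamete assembly copy and
// accumulate fitness in one stream between crossover breakpoints.  A
// generation is stored as one arena (all haplotypes concatenated, the two
// haplotypes of an individual adjacent), and children are processed in
// first-parent-sorted order so parental data stays cache-resident in
// large generations.  Sites with a non-negligible homozygous correction
// |log((1-s)/(1-sh)^2)| > 1e-6 are mirrored in a small per-haplotype
// subarray, so diploid fitness is two cached haplotype sums plus a short
// sorted intersection.  All randomness comes from a self-contained
// xoshiro256++ generator: runs are bit-reproducible for a given seed.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <cmath>
#include <numeric>
#include <algorithm>
#include <chrono>
using namespace Rcpp;

static bool profOn = false;
static double profT[8];
static inline double nowSec() {
  return std::chrono::duration<double>(
      std::chrono::steady_clock::now().time_since_epoch()).count();
}
struct ProfScope {
  int slot; double t0;
  ProfScope(int s) : slot(s), t0(profOn ? nowSec() : 0) {}
  ~ProfScope() { if (profOn) profT[slot] += nowSec() - t0; }
};

// ---------------------------------------------------------------- RNG -----
struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;                       // splitmix64 expansion
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    uint64_t r = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return r;
  }
  inline double unif() { return (next() >> 11) * 0x1.0p-53; }
  inline int unifInt(int n) { return (int)(unif() * n); }
  inline int poisson(double mean, double expNegMean) {
    double p = expNegMean, F = p, u = unif();
    int k = 0;
    while (u > F && k < 500) { ++k; p *= mean / k; F += p; }
    return k;
  }
};

// key packing: [gene:16][bf16(log(1-sh)):16][serial:32]
static inline uint64_t packKey(uint32_t gene, float lhet, uint32_t serial) {
  uint32_t bits;
  std::memcpy(&bits, &lhet, 4);
  return ((uint64_t)gene << 48) | ((uint64_t)(bits >> 16) << 32) | serial;
}
static inline uint32_t keySerial(uint64_t k) { return (uint32_t)k; }
static inline float keyLh(uint64_t k) {
  uint32_t bits = (uint32_t)((k >> 32) & 0xffffu) << 16;
  float f;
  std::memcpy(&f, &bits, 4);
  return f;
}
static inline uint64_t geneBound(int gene) { return (uint64_t)gene << 48; }

// Walker alias table (fitness-weighted parent sampling; also reused for
// the truncated-geometric crossover gap distribution)
struct Alias {
  std::vector<double> prob;
  std::vector<int> alias;
  void build(const std::vector<double>& w) {
    int n = w.size();
    prob.resize(n); alias.resize(n);
    double tot = 0;
    for (double v : w) tot += v;
    std::vector<double> p(n);
    std::vector<int> small, large;
    small.reserve(n); large.reserve(n);
    for (int i = 0; i < n; ++i) {
      p[i] = w[i] * n / tot;
      (p[i] < 1.0 ? small : large).push_back(i);
    }
    while (!small.empty() && !large.empty()) {
      int s = small.back(); small.pop_back();
      int l = large.back(); large.pop_back();
      prob[s] = p[s];
      alias[s] = l;
      p[l] = (p[l] + p[s]) - 1.0;
      (p[l] < 1.0 ? small : large).push_back(l);
    }
    while (!large.empty()) { prob[large.back()] = 1.0; large.pop_back(); }
    while (!small.empty()) { prob[small.back()] = 1.0; small.pop_back(); }
  }
  inline int draw(Rng& rng) const {
    int i = rng.unifInt(prob.size());
    return (rng.unif() < prob[i]) ? i : alias[i];
  }
};

// ------------------------------------------------ population arena --------
// haplotype j of individual i lives at index 2*i + j
struct Pop {
  std::vector<uint64_t> keys;     // concatenated sorted keys
  std::vector<uint64_t> sel;      // subsequence with |lhom| > threshold
  std::vector<size_t> off, selOff;
  std::vector<double> hapSum;     // per-hap sum of embedded log(1-sh)
  std::vector<double> logFit;     // per-individual log fitness
  int N = 0;
  void reset(int n, size_t capHint) {
    N = n;
    off.assign(1, 0);
    off.reserve(2 * n + 2);
    selOff.assign(1, 0);
    selOff.reserve(2 * n + 2);
    hapSum.clear(); hapSum.reserve(2 * n);
    logFit.clear(); logFit.reserve(n);
    // arenas keep their storage; the valid extent is governed by off
    if (keys.size() < capHint) keys.resize(capHint);
    if (sel.size() < capHint / 4 + 64) sel.resize(capHint / 4 + 64);
  }
  inline size_t hapLen(size_t h) const { return off[h + 1] - off[h]; }
};

// ------------------------------------------------------------- context ----
struct Sim {
  int nGenes = 0;
  std::vector<int> chromFirstGene;
  double muGamete = 0, expNegMu = 1;
  double recomb = 0;
  Alias gapAlias;              // crossover gap distribution (geometric)
  int gapMax = 0;              // gaps >= gapMax mean "no more crossovers"
  double cumProp[5], binLo[5], binHi[5], binH[5];
  double lambda = 1;
  std::vector<float> ms, mh, mlhom;          // mutation tables by serial
  std::vector<uint32_t> fixedSerials;
  uint32_t minAlive = 0;   // serials below this are lost or fixed everywhere
  Rng rng{0};

  void buildGapAlias(int maxBoundaries) {
    // gap k (0-based boundaries skipped) has prob (1-r)^k r; the final
    // entry aggregates the tail = no crossover before the chromosome end
    gapMax = maxBoundaries;
    std::vector<double> w(gapMax + 1);
    double q = 1.0;
    for (int k = 0; k < gapMax; ++k) {
      w[k] = q * recomb;
      q *= 1.0 - recomb;
    }
    w[gapMax] = q;
    gapAlias.build(w);
  }

  // returns the packed key; isSel reports a non-negligible hom correction
  inline uint64_t newMutation(uint32_t gene, bool& isSel) {
    double u = rng.unif();
    int b = 0;
    while (b < 4 && u > cumProp[b]) ++b;
    double sraw = binLo[b] + rng.unif() * (binHi[b] - binLo[b]);
    double s = lambda * sraw;
    if (s > 1.0) s = 1.0;
    double h = binH[b];
    double sh = s * h;
    float lhet = sh >= 1.0 ? -INFINITY : (float)std::log1p(-sh);
    float lhom = s >= 1.0 ? -INFINITY
                          : (float)(std::log1p(-s) - 2.0 * std::log1p(-sh));
    ms.push_back((float)s);
    mh.push_back((float)h);
    mlhom.push_back(lhom);
    isSel = !(std::fabs(lhom) <= 1e-6f);
    uint32_t serial = (uint32_t)(ms.size() - 1);
    return packKey(gene, lhet, serial);
  }
};

// crossover breakpoints (gene indices where the source haplotype toggles)
static void drawBreakpoints(Sim& S, std::vector<int>& bps) {
  bps.clear();
  int nChrom = S.chromFirstGene.size();
  for (int c = 0; c < nChrom; ++c) {
    int g0 = S.chromFirstGene[c];
    int g1 = (c + 1 < nChrom) ? S.chromFirstGene[c + 1] : S.nGenes;
    if (c > 0 && (S.rng.next() & 1)) bps.push_back(g0);   // assortment
    int nb = g1 - g0 - 1;
    if (nb <= 0 || S.recomb <= 0) continue;
    if (S.recomb >= 0.5 - 1e-12) {
      for (int b = 1; b <= nb; ++b)
        if (S.rng.next() & 1) bps.push_back(g0 + b);
      continue;
    }
    int pos = 0;
    for (;;) {
      int skip = S.gapAlias.draw(S.rng);     // truncated-geometric gap
      if (skip >= S.gapMax) break;
      pos += skip + 1;
      if (pos > nb) break;
      bps.push_back(g0 + pos);
    }
  }
}

// assemble one gamete from parent `parentInd` onto the end of the child
// arena; returns the haplotype log(1-sh) sum
static double meiosis(Sim& S, const Pop& pa, size_t parentInd, Pop& out,
                      std::vector<int>& bps) {
  ProfScope prof(1);
  { ProfScope p0(0); drawBreakpoints(S, bps); }
  size_t h0 = 2 * parentInd;
  const uint64_t* K[2] = {pa.keys.data() + pa.off[h0],
                          pa.keys.data() + pa.off[h0 + 1]};
  size_t n[2] = {pa.hapLen(h0), pa.hapLen(h0 + 1)};
  const uint64_t* SK[2] = {pa.sel.data() + pa.selOff[h0],
                           pa.sel.data() + pa.selOff[h0 + 1]};
  size_t sn[2] = {pa.selOff[h0 + 1] - pa.selOff[h0],
                  pa.selOff[h0 + 2] - pa.selOff[h0 + 1]};
  size_t cur[2] = {0, 0}, scur[2] = {0, 0};
  int src = (int)(S.rng.next() & 1);
  size_t base = out.off.back(), sbase = out.selOff.back();
  size_t need = base + n[0] + n[1] + 8;
  if (out.keys.size() < need)
    out.keys.resize(std::max(need, out.keys.size() + out.keys.size() / 2));
  size_t sneed = sbase + sn[0] + sn[1] + 8;
  if (out.sel.size() < sneed)
    out.sel.resize(std::max(sneed, out.sel.size() + out.sel.size() / 2));
  uint64_t* OK = out.keys.data() + base;
  uint64_t* OS = out.sel.data() + sbase;
  size_t w = 0, sw = 0;
  double acc0 = 0, acc1 = 0, acc2 = 0, acc3 = 0;
  size_t nb = bps.size();
  for (size_t i = 0; i <= nb; ++i) {
    uint64_t kHi = geneBound((i < nb) ? bps[i] : S.nGenes);
    const uint64_t* Ks = K[src];
    size_t c = cur[src], ns = n[src];
    // four-way accumulation breaks the floating-point dependency chain
    while (c + 4 <= ns && Ks[c + 3] < kHi) {
      uint64_t k0 = Ks[c], k1 = Ks[c+1], k2 = Ks[c+2], k3 = Ks[c+3];
      OK[w] = k0;   acc0 += keyLh(k0);
      OK[w+1] = k1; acc1 += keyLh(k1);
      OK[w+2] = k2; acc2 += keyLh(k2);
      OK[w+3] = k3; acc3 += keyLh(k3);
      w += 4; c += 4;
    }
    while (c < ns && Ks[c] < kHi) {
      OK[w] = Ks[c];
      acc0 += keyLh(Ks[c]);
      ++w; ++c;
    }
    cur[src] = c;
    const uint64_t* Ss = SK[src];
    size_t sc = scur[src], sns = sn[src];
    while (sc < sns && Ss[sc] < kHi) { OS[sw] = Ss[sc]; ++sw; ++sc; }
    scur[src] = sc;
    int oth = src ^ 1;
    const uint64_t* Ko = K[oth];
    size_t c2 = cur[oth], n2 = n[oth];
    while (c2 < n2 && Ko[c2] < kHi) ++c2;
    cur[oth] = c2;
    const uint64_t* So = SK[oth];
    size_t sc2 = scur[oth], sn2 = sn[oth];
    while (sc2 < sn2 && So[sc2] < kHi) ++sc2;
    scur[oth] = sc2;
    src = oth;
  }
  double sum = (acc0 + acc1) + (acc2 + acc3);
  // new mutations: sorted insertion (almost always at most one)
  int nmut = S.rng.poisson(S.muGamete, S.expNegMu);
  if (nmut > 0) {
    if (base + w + nmut > out.keys.size()) {
      out.keys.resize(base + w + nmut + 64);
      OK = out.keys.data() + base;
    }
    if (sbase + sw + nmut > out.sel.size()) {
      out.sel.resize(sbase + sw + nmut + 64);
      OS = out.sel.data() + sbase;
    }
    for (int m = 0; m < nmut; ++m) {
      uint32_t gene = (uint32_t)S.rng.unifInt(S.nGenes);
      bool isSel = false;
      uint64_t k = S.newMutation(gene, isSel);
      size_t pos = w;
      while (pos > 0 && OK[pos - 1] > k) { OK[pos] = OK[pos - 1]; --pos; }
      OK[pos] = k;
      sum += keyLh(k);
      ++w;
      if (isSel) {
        size_t sp = sw;
        while (sp > 0 && OS[sp - 1] > k) { OS[sp] = OS[sp - 1]; --sp; }
        OS[sp] = k;
        ++sw;
      }
    }
  }
  out.off.push_back(base + w);
  out.selOff.push_back(sbase + sw);
  return sum;
}

// homozygous fitness correction of an individual (selected sites only:
// mirrored sites below the threshold contribute less than 1e-6 each)
static double homCorrection(const Sim& S, const Pop& p, size_t ind) {
  ProfScope prof(2);
  size_t h0 = 2 * ind;
  const uint64_t* a = p.sel.data() + p.selOff[h0];
  const uint64_t* b = p.sel.data() + p.selOff[h0 + 1];
  size_t na = p.selOff[h0 + 1] - p.selOff[h0];
  size_t nb = p.selOff[h0 + 2] - p.selOff[h0 + 1];
  size_t i = 0, j = 0;
  double corr = 0;
  while (i < na && j < nb) {
    uint64_t ka = a[i], kb = b[j];
    if (ka == kb) corr += S.mlhom[keySerial(ka)];
    i += (ka <= kb);
    j += (kb <= ka);
  }
  return corr;
}

// one generation of children, processed in first-parent-sorted order (the
// population is exchangeable, so relabeling children is immaterial)
static void reproduce(Sim& S, const Pop& par, const Alias& al, Pop& out,
                      int nKids, std::vector<int>& bps,
                      std::vector<int>& p1buf, std::vector<int>& p2buf,
                      std::vector<int>& cntbuf, std::vector<int>& ordbuf) {
  size_t capHint = (size_t)((par.off.back() / std::max<size_t>(1, 2 * par.N)
                             + 8) * 2 * (size_t)nKids + 64);
  out.reset(nKids, capHint);
  p1buf.resize(nKids); p2buf.resize(nKids);
  for (int i = 0; i < nKids; ++i) {
    p1buf[i] = al.draw(S.rng);
    p2buf[i] = al.draw(S.rng);
  }
  cntbuf.assign(par.N + 1, 0);
  for (int i = 0; i < nKids; ++i) ++cntbuf[p1buf[i] + 1];
  for (int k = 0; k < par.N; ++k) cntbuf[k + 1] += cntbuf[k];
  ordbuf.resize(nKids);
  for (int i = 0; i < nKids; ++i) ordbuf[cntbuf[p1buf[i]]++] = i;
  for (int idx = 0; idx < nKids; ++idx) {
    int i = ordbuf[idx];
    double s1 = meiosis(S, par, p1buf[i], out, bps);
    double s2 = meiosis(S, par, p2buf[i], out, bps);
    out.hapSum.push_back(s1);
    out.hapSum.push_back(s2);
    size_t ind = out.hapSum.size() / 2 - 1;
    out.logFit.push_back(s1 + s2 + homCorrection(S, out, ind));
  }
}

static void buildAlias(const Pop& pop, Alias& al, std::vector<double>& w) {
  ProfScope prof(3);
  w.resize(pop.N);
  double mx = -INFINITY;
  for (int i = 0; i < pop.N; ++i) mx = std::max(mx, pop.logFit[i]);
  if (!std::isfinite(mx)) stop("population mean fitness collapsed to zero");
  double tot = 0;
  for (int i = 0; i < pop.N; ++i) {
    w[i] = std::exp(pop.logFit[i] - mx);
    tot += w[i];
  }
  if (tot <= 0) stop("population mean fitness collapsed to zero");
  al.build(w);
}

// count allele copies by serial (offset by base) over one or two
// populations; the window [base, nSerial) stays small because serials
// below base are already lost or fixed everywhere
static void countAlleles(const Pop* a, const Pop* b,
                         std::vector<uint32_t>& cnt, uint32_t base,
                         size_t nSerial) {
  cnt.assign(nSerial - base, 0u);
  for (const Pop* pp : {a, b}) {
    if (!pp) continue;
    size_t tot = pp->off.back();
    const uint64_t* K = pp->keys.data();
    for (size_t r = 0; r < tot; ++r) ++cnt[keySerial(K[r]) - base];
  }
}

// remove globally fixed mutations from every haplotype (in place)
static void sweepFixed(Sim& S, Pop* a, Pop* b) {
  ProfScope prof(4);
  size_t nSerial = S.ms.size();
  uint32_t base = S.minAlive;
  std::vector<uint32_t> cnt;
  countAlleles(a, b, cnt, base, nSerial);
  uint64_t H = 2ULL * ((a ? a->N : 0) + (b ? b->N : 0));
  if (!H) return;
  std::vector<uint32_t> fixed;
  uint32_t newMin = (uint32_t)nSerial;
  for (size_t s = 0; s < cnt.size(); ++s) {
    if (cnt[s] == H) fixed.push_back(base + (uint32_t)s);
    else if (cnt[s] > 0 && base + s < newMin) newMin = base + (uint32_t)s;
  }
  S.minAlive = std::min(newMin, (uint32_t)nSerial);
  if (fixed.empty()) return;
  std::vector<char> isFixed(cnt.size(), 0);
  for (uint32_t s : fixed) {
    isFixed[s - base] = 1;
    S.fixedSerials.push_back(s);
  }
  // removing a globally fixed site shifts every individual's log fitness
  // by the same constant, so parent weights are untouched; only the
  // haplotype arrays and cached sums need compaction
  for (Pop* pp : {a, b}) {
    if (!pp) continue;
    size_t nh = pp->off.size() - 1;
    size_t w = 0;
    for (size_t h = 0; h < nh; ++h) {
      size_t start = pp->off[h], end = pp->off[h + 1];
      size_t w0 = w;
      double sum = 0;
      for (size_t r = start; r < end; ++r) {
        uint64_t k = pp->keys[r];
        uint32_t serial = keySerial(k);
        if (serial < base || !isFixed[serial - base]) {
          pp->keys[w++] = k;
          sum += keyLh(k);
        }
      }
      pp->off[h] = w0;
      pp->hapSum[h] = sum;
    }
    pp->off[nh] = w;
    size_t sw = 0;
    for (size_t h = 0; h < nh; ++h) {
      size_t start = pp->selOff[h], end = pp->selOff[h + 1];
      size_t s0 = sw;
      for (size_t r = start; r < end; ++r) {
        uint64_t k = pp->sel[r];
        uint32_t serial = keySerial(k);
        if (serial < base || !isFixed[serial - base]) pp->sel[sw++] = k;
      }
      pp->selOff[h] = s0;
    }
    pp->selOff[nh] = sw;
  }
}

// extract per-population sample output
static List sampleOutput(Sim& S, const Pop& pop, int sampleSize, Rng& rng) {
  size_t nSerial = S.ms.size();
  std::vector<uint32_t> cnt;
  countAlleles(&pop, nullptr, cnt, 0, nSerial);
  uint64_t twoN = 2ULL * pop.N;
  std::vector<uint32_t> popFixed;
  std::vector<char> isPopFixed(nSerial, 0);
  for (size_t s = 0; s < nSerial; ++s)
    if (cnt[s] == twoN) { popFixed.push_back((uint32_t)s); isPopFixed[s] = 1; }
  int N = pop.N;
  int ns = sampleSize < N ? sampleSize : N;
  std::vector<int> idx(N);
  std::iota(idx.begin(), idx.end(), 0);
  for (int i = 0; i < ns; ++i) {
    int j = i + rng.unifInt(N - i);
    std::swap(idx[i], idx[j]);
  }
  idx.resize(ns);
  std::vector<int32_t> row(nSerial, -1);
  std::vector<uint32_t> sites;
  for (int i = 0; i < ns; ++i)
    for (size_t h = 2 * (size_t)idx[i]; h <= 2 * (size_t)idx[i] + 1; ++h)
      for (size_t r = pop.off[h]; r < pop.off[h + 1]; ++r) {
        uint32_t serial = keySerial(pop.keys[r]);
        if (!isPopFixed[serial] && row[serial] < 0) {
          row[serial] = sites.size();
          sites.push_back(serial);
        }
      }
  IntegerMatrix geno(sites.size(), ns);
  for (int i = 0; i < ns; ++i)
    for (size_t h = 2 * (size_t)idx[i]; h <= 2 * (size_t)idx[i] + 1; ++h)
      for (size_t r = pop.off[h]; r < pop.off[h + 1]; ++r) {
        uint32_t serial = keySerial(pop.keys[r]);
        if (!isPopFixed[serial]) geno(row[serial], i) += 1;
      }
  NumericVector sv(sites.size()), hv(sites.size());
  for (size_t r = 0; r < sites.size(); ++r) {
    sv[r] = S.ms[sites[r]];
    hv[r] = S.mh[sites[r]];
  }
  int nFix = S.fixedSerials.size() + popFixed.size();
  NumericVector fs(nFix), fh(nFix);
  int w = 0;
  for (uint32_t s : S.fixedSerials) { fs[w] = S.ms[s]; fh[w] = S.mh[s]; ++w; }
  for (uint32_t s : popFixed)       { fs[w] = S.ms[s]; fh[w] = S.mh[s]; ++w; }
  return List::create(_["geno"] = geno, _["s"] = sv, _["h"] = hv,
                      _["fixed_s"] = fs, _["fixed_h"] = fh,
                      _["N"] = (double)N);
}

// [[Rcpp::export(name = ".forwardSimulate")]]
List forwardSimulate(IntegerVector genesPerChrom, double geneLen,
                     double mutRate, double recombGene,
                     IntegerVector nAfr, IntegerVector nEur,
                     NumericVector binProp, NumericVector binLo,
                     NumericVector binHi, NumericVector binH,
                     double lambda, int sampleSize, double seed,
                     int sweepEvery = 25, bool profile = false) {
  profOn = profile;
  for (int i = 0; i < 8; ++i) profT[i] = 0;
  Sim S;
  S.rng = Rng((uint64_t)seed);
  int nChrom = genesPerChrom.size();
  if (nChrom < 1) stop("need at least one chromosome");
  S.chromFirstGene.resize(nChrom);
  int tot = 0, maxGenes = 0;
  for (int c = 0; c < nChrom; ++c) {
    S.chromFirstGene[c] = tot;
    tot += genesPerChrom[c];
    maxGenes = std::max(maxGenes, (int)genesPerChrom[c]);
  }
  if (tot >= 65536) stop("at most 65535 genes are supported");
  S.nGenes = tot;
  S.muGamete = mutRate * geneLen * tot;
  S.expNegMu = std::exp(-S.muGamete);
  S.recomb = recombGene;
  if (S.recomb > 0 && S.recomb < 0.5 - 1e-12) S.buildGapAlias(maxGenes);
  S.lambda = lambda;
  double cp = 0;
  for (int b = 0; b < 5; ++b) {
    cp += binProp[b];
    S.cumProp[b] = cp;
    S.binLo[b] = binLo[b]; S.binHi[b] = binHi[b]; S.binH[b] = binH[b];
  }
  size_t expMut = (size_t)(2.2 * S.muGamete *
                           (std::accumulate(nAfr.begin(), nAfr.end(), 0.0) +
                            std::accumulate(nEur.begin(), nEur.end(), 0.0)));
  S.ms.reserve(expMut); S.mh.reserve(expMut); S.mlhom.reserve(expMut);

  int T = nAfr.size();
  Pop afrCur, afrNext, eurCur, eurNext;
  std::vector<int> bps, p1b, p2b, cntb, ordb;
  Alias al;
  std::vector<double> wbuf;

  afrCur.reset(nAfr[0], 64);           // founding generation: no variation
  for (int i = 0; i < nAfr[0]; ++i) {
    afrCur.off.push_back(0); afrCur.off.push_back(0);
    afrCur.selOff.push_back(0); afrCur.selOff.push_back(0);
    afrCur.hapSum.push_back(0); afrCur.hapSum.push_back(0);
    afrCur.logFit.push_back(0);
  }
  bool haveEur = false;

  for (int t = 1; t < T; ++t) {
    if ((t & 127) == 0) Rcpp::checkUserInterrupt();
    buildAlias(afrCur, al, wbuf);
    reproduce(S, afrCur, al, afrNext, nAfr[t], bps, p1b, p2b, cntb, ordb);
    if (nEur[t] > 0) {
      if (!haveEur) {
        // split: European founders drawn from the African parent pool
        reproduce(S, afrCur, al, eurNext, nEur[t], bps, p1b, p2b, cntb, ordb);
        haveEur = true;
      } else {
        buildAlias(eurCur, al, wbuf);
        reproduce(S, eurCur, al, eurNext, nEur[t], bps, p1b, p2b, cntb, ordb);
      }
      std::swap(eurCur, eurNext);
    }
    std::swap(afrCur, afrNext);
    if (sweepEvery > 0 && (t % sweepEvery) == 0)
      sweepFixed(S, &afrCur, haveEur ? &eurCur : nullptr);
  }

  if (profOn)
    Rprintf("prof: bps %.2f meiosis %.2f hom %.2f alias %.2f sweep %.2f\n",
            profT[0], profT[1], profT[2], profT[3], profT[4]);
  List out = List::create(
      _["afr"] = sampleOutput(S, afrCur, sampleSize, S.rng),
      _["eur"] = haveEur ? (SEXP)sampleOutput(S, eurCur, sampleSize, S.rng)
                         : R_NilValue,
      _["nMutations"] = (double)S.ms.size());
  return out;
}
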