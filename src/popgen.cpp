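// Forward Wright-Fisher haplotype simulator and EHH/iHS scan kernels.
// All randomness comes from R's RNG so set.seed() governs reproducibility.

#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

struct Pop {
  int n;
  std::vector<double> pos;                   // sorted site positions (bp)
  std::vector<std::vector<uint8_t>> hap;     // n x S, row-major
  std::vector<int> cls;                      // mating class per haplotype
};

// One non-overlapping Wright-Fisher generation: each child recombines two
// uniformly chosen parents (Poisson(recomb) crossovers at uniform
// positions) and receives Poisson(mu) new mutations at uniform positions.
// Monomorphic columns are pruned afterwards.
static void next_gen(Pop &P, double L, double mu, double recomb) {
  const int n = P.n;
  const int S = (int)P.pos.size();
  std::vector<std::vector<uint8_t>> kids(n);
  std::vector<std::pair<double, int>> newmuts;  // (position, child)

  // parent pools per mating class (the whole population when unclassed);
  // child i keeps the class of slot i, so class sizes stay fixed
  std::map<int, std::vector<int>> pools;
  for (int i = 0; i < n; ++i)
    pools[P.cls.empty() ? 0 : P.cls[i]].push_back(i);

  for (int i = 0; i < n; ++i) {
    const std::vector<int> &pool = pools[P.cls.empty() ? 0 : P.cls[i]];
    int np = (int)pool.size();
    int p1 = pool[std::min((int)(unif_rand() * np), np - 1)];
    int p2 = pool[std::min((int)(unif_rand() * np), np - 1)];
    int nx = (int)R::rpois(recomb);
    std::vector<double> xo(nx);
    for (int k = 0; k < nx; ++k) xo[k] = unif_rand() * L;
    std::sort(xo.begin(), xo.end());
    std::vector<uint8_t> child(S);
    int cur = (unif_rand() < 0.5) ? p1 : p2;
    int si = 0;
    for (int k = 0; k <= nx; ++k) {
      double segend = (k < nx) ? xo[k] : L + 1.0;
      const std::vector<uint8_t> &src = P.hap[cur];
      while (si < S && P.pos[si] < segend) { child[si] = src[si]; ++si; }
      cur = (cur == p1) ? p2 : p1;
    }
    int nm = (int)R::rpois(mu);
    for (int k = 0; k < nm; ++k)
      newmuts.push_back(std::make_pair(unif_rand() * L, i));
    kids[i] = std::move(child);
  }
  std::sort(newmuts.begin(), newmuts.end());

  // column sums for pruning
  std::vector<int> colsum(S, 0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < S; ++j) colsum[j] += kids[i][j];

  // merged site plan: (pos, source index; new mutations flagged by -child-1)
  std::vector<double> npos;
  std::vector<int> src;
  npos.reserve(S + newmuts.size());
  size_t mi = 0;
  for (int j = 0; j <= S; ++j) {
    double here = (j < S) ? P.pos[j] : L + 1.0;
    while (mi < newmuts.size() && newmuts[mi].first < here) {
      npos.push_back(newmuts[mi].first);
      src.push_back(-newmuts[mi].second - 1);
      ++mi;
    }
    if (j < S && colsum[j] > 0 && colsum[j] < n) {
      npos.push_back(P.pos[j]);
      src.push_back(j);
    }
  }
  const int NS = (int)npos.size();
  std::vector<std::vector<uint8_t>> nh(n, std::vector<uint8_t>(NS, 0));
  for (int i = 0; i < n; ++i) {
    std::vector<uint8_t> &row = nh[i];
    const std::vector<uint8_t> &old = kids[i];
    for (int j = 0; j < NS; ++j) {
      if (src[j] >= 0) row[j] = old[src[j]];
      else if (-src[j] - 1 == i) row[j] = 1;
    }
  }
  P.pos.swap(npos);
  P.hap.swap(nh);
}

static List pop_to_list(const Pop &P) {
  const int n = P.n, S = (int)P.pos.size();
  IntegerMatrix H(n, S);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < S; ++j) H(i, j) = P.hap[i][j];
  return List::create(Named("haplotypes") = H,
                      Named("positions") = NumericVector(P.pos.begin(),
                                                         P.pos.end()));
}

// [[Rcpp::export]]
List wf_sim_cpp(int n_hap, double genome_len, double mu, double recomb,
                int generations) {
  Pop P;
  P.n = n_hap;
  P.hap.assign(n_hap, std::vector<uint8_t>());
  for (int g = 0; g < generations; ++g) next_gen(P, genome_len, mu, recomb);
  return pop_to_list(P);
}

// [[Rcpp::export]]
List wf_continue_cpp(IntegerMatrix H, NumericVector pos, double genome_len,
                     double mu, double recomb, int generations,
                     Nullable<IntegerVector> mating_class = R_NilValue) {
  Pop P;
  P.n = H.nrow();
  int S = H.ncol();
  P.pos.assign(pos.begin(), pos.end());
  P.hap.assign(P.n, std::vector<uint8_t>(S));
  for (int i = 0; i < P.n; ++i)
    for (int j = 0; j < S; ++j) P.hap[i][j] = (uint8_t)H(i, j);
  if (mating_class.isNotNull()) {
    IntegerVector mc(mating_class);
    P.cls.assign(mc.begin(), mc.end());
  }
  for (int g = 0; g < generations; ++g) next_gen(P, genome_len, mu, recomb);
  return pop_to_list(P);
}

// Selective phase: drift-free recombination with selection. Each haplotype
// slot persists (no lineage copying, so no spurious clonal structure) and
// recombines with a random partner each generation, with rejection so the
// slot keeps its allele at the sweep site: selection pins the sweep
// frequency while recombination moves random backgrounds on and off the
// swept haplotype. Mutation runs at a (typically reduced) rate mu: a rapid
// sweep is brief on the mutational timescale.
// [[Rcpp::export]]
List wf_sweep_cpp(IntegerMatrix Hin, NumericVector pos_in, double genome_len,
                  double mu, double recomb, int generations,
                  double sweep_pos) {
  Pop P;
  P.n = Hin.nrow();
  int S0 = Hin.ncol();
  P.pos.assign(pos_in.begin(), pos_in.end());
  P.hap.assign(P.n, std::vector<uint8_t>(S0));
  for (int i = 0; i < P.n; ++i)
    for (int j = 0; j < S0; ++j) P.hap[i][j] = (uint8_t)Hin(i, j);

  const int n = P.n;
  for (int g = 0; g < generations; ++g) {
    int S = (int)P.pos.size();
    int sw = (int)(std::lower_bound(P.pos.begin(), P.pos.end(), sweep_pos) -
                   P.pos.begin());
    if (sw >= S || P.pos[sw] != sweep_pos)
      stop("sweep site lost during selective phase");
    std::vector<std::vector<uint8_t>> kids(n);
    std::vector<std::pair<double, int>> newmuts;
    for (int i = 0; i < n; ++i) {
      uint8_t want = P.hap[i][sw];
      std::vector<uint8_t> child(S);
      for (int tries = 0; tries < 1000; ++tries) {
        int p1 = i;  // the slot itself: haplotypes persist, no drift
        int p2 = std::min((int)(unif_rand() * n), n - 1);
        int nx = (int)R::rpois(recomb);
        std::vector<double> xo(nx);
        for (int k = 0; k < nx; ++k) xo[k] = unif_rand() * genome_len;
        std::sort(xo.begin(), xo.end());
        int cur = (unif_rand() < 0.5) ? p1 : p2;
        int si = 0;
        for (int k = 0; k <= nx; ++k) {
          double segend = (k < nx) ? xo[k] : genome_len + 1.0;
          const std::vector<uint8_t> &src = P.hap[cur];
          while (si < S && P.pos[si] < segend) { child[si] = src[si]; ++si; }
          cur = (cur == p1) ? p2 : p1;
        }
        if (child[sw] == want) break;
        si = 0;
      }
      int nm = (int)R::rpois(mu);
      for (int k = 0; k < nm; ++k)
        newmuts.push_back(std::make_pair(unif_rand() * genome_len, i));
      kids[i] = std::move(child);
    }
    // merge + prune exactly as in next_gen
    std::sort(newmuts.begin(), newmuts.end());
    std::vector<int> colsum(S, 0);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < S; ++j) colsum[j] += kids[i][j];
    std::vector<double> npos;
    std::vector<int> src;
    size_t mi = 0;
    for (int j = 0; j <= S; ++j) {
      double here = (j < S) ? P.pos[j] : genome_len + 1.0;
      while (mi < newmuts.size() && newmuts[mi].first < here) {
        npos.push_back(newmuts[mi].first);
        src.push_back(-newmuts[mi].second - 1);
        ++mi;
      }
      if (j < S && colsum[j] > 0 && colsum[j] < n) {
        npos.push_back(P.pos[j]);
        src.push_back(j);
      }
    }
    const int NS = (int)npos.size();
    std::vector<std::vector<uint8_t>> nh(n, std::vector<uint8_t>(NS, 0));
    for (int i = 0; i < n; ++i) {
      for (int j = 0; j < NS; ++j) {
        if (src[j] >= 0) nh[i][j] = kids[i][src[j]];
        else if (-src[j] - 1 == i) nh[i][j] = 1;
      }
    }
    P.pos.swap(npos);
    P.hap.swap(nh);
  }
  return pop_to_list(P);
}

// EHH over carriers of `allele` at `core`, integrated outward (trapezoid in
// bp) until EHH < cutoff. Returns the integral, or -1 when the curve never
// drops below cutoff before the chromosome end (truncation failure).
static double ihh_one(const IntegerMatrix &H, const NumericVector &pos,
                      int core, int allele, double cutoff) {
  const int n = H.nrow(), S = H.ncol();
  std::vector<int> car;
  for (int i = 0; i < n; ++i) if (H(i, core) == allele) car.push_back(i);
  const int nc = (int)car.size();
  if (nc < 2) return -1.0;
  const double pairs_tot = nc * (nc - 1) / 2.0;
  double ihh = 0.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> grp(nc, 0);
    int ngrp = 1;
    double ehh_prev = 1.0;
    double pos_prev = pos[core];
    int j = core + dir;
    bool dropped = false;
    while (j >= 0 && j < S) {
      // refine partition by the allele at site j
      std::map<std::pair<int, int>, int> seen;
      int next_id = 0;
      std::vector<int> cnt;
      for (int k = 0; k < nc; ++k) {
        std::pair<int, int> key(grp[k], H(car[k], j));
        std::map<std::pair<int, int>, int>::iterator it = seen.find(key);
        int id;
        if (it == seen.end()) {
          id = next_id++;
          seen.insert(std::make_pair(key, id));
          cnt.push_back(0);
        } else id = it->second;
        grp[k] = id;
        cnt[id]++;
      }
      ngrp = next_id;
      double pr = 0.0;
      for (int g = 0; g < ngrp; ++g) pr += cnt[g] * (cnt[g] - 1) / 2.0;
      double ehh = pr / pairs_tot;
      ihh += 0.5 * (ehh_prev + ehh) * std::abs(pos[j] - pos_prev);
      if (ehh < cutoff) { dropped = true; break; }
      ehh_prev = ehh;
      pos_prev = pos[j];
      j += dir;
    }
    if (!dropped) return -1.0;  // ran off the chromosome end
  }
  return ihh;
}

// [[Rcpp::export]]
DataFrame ehh_scan_cpp(IntegerMatrix H, NumericVector pos, double maf_min,
                       double cutoff) {
  const int n = H.nrow(), S = H.ncol();
  NumericVector freq1(S), ihh0(S), ihh1(S);
  LogicalVector ok(S);
  for (int j = 0; j < S; ++j) {
    int c1 = 0;
    for (int i = 0; i < n; ++i) c1 += H(i, j);
    double f = (double)c1 / n;
    freq1[j] = f;
    double maf = std::min(f, 1.0 - f);
    if (maf < maf_min) { ok[j] = false; continue; }
    double a = ihh_one(H, pos, j, 0, cutoff);
    double d = ihh_one(H, pos, j, 1, cutoff);
    ihh0[j] = a; ihh1[j] = d;
    ok[j] = (a > 0.0 && d > 0.0);
  }
  return DataFrame::create(Named("freq_derived") = freq1,
                           Named("ihh_anc") = ihh0,
                           Named("ihh_der") = ihh1,
                           Named("ok") = ok);
}

// Windowed-consensus imputation of a sparse 1/-1/0 pollen genotype matrix.
// For each missing entry, the k nearest non-missing entries in the same
// column and chromosome vote; the entry becomes the sign of their mean when
// |mean| >= min_conf. chrom_id must be sorted so each chromosome is a
// contiguous row block.
// [[Rcpp::export]]
List impute_consensus_cpp(IntegerMatrix M, IntegerVector chrom_id,
                          NumericVector pos, int k, double min_conf) {
  const int nr = M.nrow(), nc = M.ncol();
  IntegerMatrix out(clone(M));
  NumericMatrix conf(nr, nc);
  std::fill(conf.begin(), conf.end(), NA_REAL);
  // chromosome blocks
  std::vector<int> bstart, bend;
  int s0 = 0;
  for (int i = 1; i <= nr; ++i) {
    if (i == nr || chrom_id[i] != chrom_id[s0]) {
      bstart.push_back(s0); bend.push_back(i); s0 = i;
    }
  }
  for (int c = 0; c < nc; ++c) {
    for (size_t b = 0; b < bstart.size(); ++b) {
      std::vector<int> obs;  // row indices of non-missing entries
      for (int i = bstart[b]; i < bend[b]; ++i)
        if (M(i, c) != 0) obs.push_back(i);
      if ((int)obs.size() == 0) continue;
      for (int i = bstart[b]; i < bend[b]; ++i) {
        if (M(i, c) != 0) continue;
        // two-pointer window of the k nearest observed rows by distance
        int lo = (int)(std::lower_bound(obs.begin(), obs.end(), i) -
                       obs.begin());
        int left = lo - 1, right = lo, taken = 0, sum = 0;
        while (taken < k && (left >= 0 || right < (int)obs.size())) {
          double dl = left >= 0 ? pos[i] - pos[obs[left]] : R_PosInf;
          double dr = right < (int)obs.size() ? pos[obs[right]] - pos[i]
                                              : R_PosInf;
          // ties toward smaller distance, then lower position (= left)
          if (dl <= dr) { sum += M(obs[left], c); --left; }
          else          { sum += M(obs[right], c); ++right; }
          ++taken;
        }
        if (taken == 0) continue;
        double m = (double)sum / taken;
        conf(i, c) = std::abs(m);
        if (std::abs(m) >= min_conf && m != 0.0)
          out(i, c) = (m > 0) ? 1 : -1;
      }
    }
  }
  return List::create(Named("imputed") = out, Named("confidence") = conf);
}
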