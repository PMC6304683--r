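#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <cmath>
using namespace Rcpp;

// Structured coalescent for unlinked biallelic loci.
//
// Populations are fixed slots 0..n_pop-1; demographic change is an ordered
// event table (time, type, a, b, x) with times in generations before present:
//   type 1: split  -- move every lineage in pop a into pop b and close pop a
//   type 2: size   -- diploid size of pop a becomes x
//   type 3: mig    -- backward migration rate a -> b becomes x (per lineage
//                     per generation; a lineage in a jumps to b)
// Exponential growth phases are discretized upstream (R side) into type-2
// steps, so every epoch here is constant-size and waiting times are plain
// competing exponentials.
//
// Each locus is a single biallelic site: one mutation is placed on the tree
// with probability 1 - exp(-mu * L) (L = total branch length), on a branch
// chosen proportionally to its length.
//
// RNG: a local xoshiro256+ stream seeded from the R RNG at entry, so results
// are a pure function of set.seed() while avoiding per-draw R RNG calls.

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    const uint64_t result = s[0] + s[3];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double runif() {  // in (0,1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double rexp() { return -std::log(runif()); }
  void seed_from_R() {
    for (int i = 0; i < 4; ++i) {
      uint64_t hi = (uint64_t)(unif_rand() * 4294967296.0);
      uint64_t lo = (uint64_t)(unif_rand() * 4294967296.0);
      s[i] = (hi << 32) ^ lo;
      if (s[i] == 0) s[i] = 0x9E3779B97F4A7C15ULL + i;
    }
  }
};

struct EventRow { double time; int type, a, b; double x; };

}  // namespace

// [[Rcpp::export(name = ".sim_coalescent_cpp")]]
List sim_coalescent_cpp(IntegerVector sample_sizes,
                        NumericVector pop_sizes,
                        NumericMatrix events,
                        int n_loci,
                        double mu,
                        bool return_haplotypes) {
  const int n_pop = sample_sizes.size();
  if (pop_sizes.size() != n_pop) stop("pop_sizes length mismatch");
  int n_tips = 0;
  for (int p = 0; p < n_pop; ++p) n_tips += sample_sizes[p];
  if (n_tips < 2) stop("need at least 2 sampled haplotypes");
  const int n_nodes = 2 * n_tips - 1;

  std::vector<EventRow> evs;
  for (int i = 0; i < events.nrow(); ++i) {
    EventRow e;
    e.time = events(i, 0);
    e.type = (int)events(i, 1);
    e.a = (int)events(i, 2);
    e.b = (int)events(i, 3);
    e.x = events(i, 4);
    if (e.a < 0 || e.a >= n_pop || e.b < 0 || e.b >= n_pop)
      stop("event population index out of range");
    evs.push_back(e);
  }
  for (size_t i = 1; i < evs.size(); ++i)
    if (evs[i].time < evs[i - 1].time) stop("events must be time-sorted");

  Xoshiro rng;
  { GetRNGstate(); rng.seed_from_R(); PutRNGstate(); }

  IntegerMatrix counts(n_loci, n_pop);
  NumericVector tmrca(n_loci);
  IntegerMatrix haps;
  if (return_haplotypes) haps = IntegerMatrix(n_loci, n_tips);

  // flat preallocated scratch
  std::vector<double> node_time(n_nodes), blen(n_nodes);
  std::vector<int> child1(n_nodes), child2(n_nodes);
  std::vector<int> tip_pop(n_tips);
  {
    int k = 0;
    for (int p = 0; p < n_pop; ++p)
      for (int j = 0; j < sample_sizes[p]; ++j) tip_pop[k++] = p;
  }
  // per-population member lists, flat: members[p * n_tips + i]
  std::vector<int> members(n_pop * n_tips);
  std::vector<int> msize(n_pop);
  std::vector<double> N0(pop_sizes.begin(), pop_sizes.end());
  std::vector<double> N(n_pop), coal_rate(n_pop);
  std::vector<double> mig(n_pop * n_pop), mig_out(n_pop);
  std::vector<char> closed(n_pop);
  std::vector<int> stack(n_nodes);
  const bool any_mig = [&]{
    for (auto &e : evs) if (e.type == 3 && e.x > 0) return true;
    return false;
  }();

  for (int locus = 0; locus < n_loci; ++locus) {
    std::memcpy(N.data(), N0.data(), n_pop * sizeof(double));
    std::fill(mig.begin(), mig.end(), 0.0);
    std::fill(mig_out.begin(), mig_out.end(), 0.0);
    std::fill(closed.begin(), closed.end(), 0);
    std::fill(msize.begin(), msize.end(), 0);
    for (int i = 0; i < n_tips; ++i) {
      const int p = tip_pop[i];
      members[p * n_tips + msize[p]++] = i;
      node_time[i] = 0.0;
    }
    size_t ev_i = 0;
    double t = 0.0;
    int k_total = n_tips;
    int next_node = n_tips;

    while (k_total > 1) {
      double coal_tot = 0.0, mig_tot = 0.0;
      for (int p = 0; p < n_pop; ++p) {
        const double kp = (double)msize[p];
        coal_rate[p] = (kp >= 2.0) ? kp * (kp - 1.0) / (4.0 * N[p]) : 0.0;
        coal_tot += coal_rate[p];
        if (any_mig && kp > 0.0) mig_tot += kp * mig_out[p];
      }
      const double tot = coal_tot + mig_tot;
      const double next_ev_t = (ev_i < evs.size()) ? evs[ev_i].time : R_PosInf;
      const double dt = (tot > 0.0) ? rng.rexp() / tot : R_PosInf;

      if (t + dt >= next_ev_t) {
        if (!R_finite(next_ev_t))
          stop("lineages cannot coalesce: no common ancestor reachable");
        t = next_ev_t;
        const EventRow &e = evs[ev_i++];
        if (e.type == 1) {            // split: a -> b
          int *src = &members[e.a * n_tips];
          int *dst = &members[e.b * n_tips];
          for (int i = 0; i < msize[e.a]; ++i) dst[msize[e.b]++] = src[i];
          msize[e.a] = 0;
          closed[e.a] = 1;
          for (int q = 0; q < n_pop; ++q) {
            mig[e.a * n_pop + q] = 0.0;
            mig[q * n_pop + e.a] = 0.0;
          }
          for (int p = 0; p < n_pop; ++p) {
            mig_out[p] = 0.0;
            for (int q = 0; q < n_pop; ++q) mig_out[p] += mig[p * n_pop + q];
          }
        } else if (e.type == 2) {     // size change
          if (e.x <= 0) stop("population size must be positive");
          N[e.a] = e.x;
        } else if (e.type == 3) {     // migration rate change
          if (!closed[e.a] && !closed[e.b]) {
            mig[e.a * n_pop + e.b] = e.x;
            mig_out[e.a] = 0.0;
            for (int q = 0; q < n_pop; ++q) mig_out[e.a] += mig[e.a * n_pop + q];
          }
        } else stop("unknown event type");
        continue;
      }
      t += dt;
      double u = rng.runif() * tot;
      if (u < coal_tot || mig_tot <= 0.0) {
        int p = n_pop - 1;
        for (int q = 0; q < n_pop; ++q) {
          if (u < coal_rate[q]) { p = q; break; }
          u -= coal_rate[q];
        }
        int *mm = &members[p * n_tips];
        const int kp = msize[p];
        int i1 = (int)(rng.runif() * kp);
        if (i1 >= kp) i1 = kp - 1;
        int i2 = (int)(rng.runif() * (kp - 1));
        if (i2 >= kp - 1) i2 = kp - 2;
        if (i2 >= i1) ++i2;
        const int a = mm[i1], b = mm[i2];
        const int hi = i1 > i2 ? i1 : i2, lo = i1 > i2 ? i2 : i1;
        mm[hi] = mm[kp - 1];
        mm[lo] = mm[kp - 2];
        node_time[next_node] = t;
        child1[next_node] = a;
        child2[next_node] = b;
        mm[kp - 2] = next_node;
        msize[p] = kp - 1;
        ++next_node;
        --k_total;
      } else {
        u -= coal_tot;
        int p = -1, q = -1;
        for (int pp = 0; pp < n_pop && p < 0; ++pp) {
          const double kp = (double)msize[pp];
          if (kp == 0.0 || mig_out[pp] <= 0.0) continue;
          for (int qq = 0; qq < n_pop; ++qq) {
            const double r = kp * mig[pp * n_pop + qq];
            if (r <= 0.0) continue;
            if (u < r) { p = pp; q = qq; break; }
            u -= r;
          }
        }
        if (p >= 0) {
          int *mm = &members[p * n_tips];
          int i1 = (int)(rng.runif() * msize[p]);
          if (i1 >= msize[p]) i1 = msize[p] - 1;
          const int id = mm[i1];
          mm[i1] = mm[msize[p] - 1];
          --msize[p];
          members[q * n_tips + msize[q]++] = id;
        }
      }
    }

    const int root = next_node - 1;
    tmrca[locus] = node_time[root];
    double L = 0.0;
    for (int v = n_tips; v <= root; ++v) {
      blen[child1[v]] = node_time[v] - node_time[child1[v]];
      blen[child2[v]] = node_time[v] - node_time[child2[v]];
      L += blen[child1[v]] + blen[child2[v]];
    }
    const bool mutated = (mu > 0.0) && (rng.runif() < -expm1(-mu * L));
    if (mutated) {
      double target = rng.runif() * L, acc = 0.0;
      int mnode = root - 1;
      for (int v = 0; v < root; ++v) {
        acc += blen[v];
        if (target <= acc) { mnode = v; break; }
      }
      int sp = 0;
      stack[sp++] = mnode;
      while (sp) {
        const int v = stack[--sp];
        if (v < n_tips) {
          counts(locus, tip_pop[v]) += 1;
          if (return_haplotypes) haps(locus, v) = 1;
        } else {
          stack[sp++] = child1[v];
          stack[sp++] = child2[v];
        }
      }
    }
  }

  List out = List::create(_["counts"] = counts,
                          _["sample_sizes"] = sample_sizes,
                          _["tmrca"] = tmrca);
  if (return_haplotypes) out["haplotypes"] = haps;
  return out;
}
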