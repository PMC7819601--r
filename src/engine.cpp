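// Incremental Gillespie engine for the 1D nucleosome lattice model.
//
// Event classes: 1-bp diffusion hops, spacer-enzyme pair moves, histone
// desorption (per nucleosome) and absorption (per free-footprint site).
// Per-nucleosome rates are stored in plain vectors (N is small); per-site
// absorption rates live in a segment tree supporting O(range + log L)
// rebuilds and O(log L) categorical sampling.  After an event only the
// touched terms are recomputed; a from-scratch rebuild must agree exactly
// (tested against the R reference enumeration).

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <cstdint>
#include <random>
#include <vector>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // uniform in [0, 1)
  double unif() { return (gen() >> 11) * 0x1.0p-53; }
  // uniform in (0, 1]
  double unif_pos() { return 1.0 - unif(); }
};

struct SegTree {
  int n2 = 1;
  std::vector<double> t;
  void init(int leaves) {
    n2 = 1;
    while (n2 < leaves) n2 <<= 1;
    t.assign(2 * n2, 0.0);
  }
  double total() const { return t[1]; }
  double leaf(int i) const { return t[n2 + i]; }
  void set_leaf(int i, double v) { t[n2 + i] = v; }
  // recompute internal nodes covering leaf range [lo, hi]
  void rebuild(int lo, int hi) {
    lo += n2; hi += n2;
    while (lo > 1) {
      lo >>= 1; hi >>= 1;
      for (int i = lo; i <= hi; ++i) t[i] = t[2 * i] + t[2 * i + 1];
    }
  }
  // set one leaf and update its path to the root
  void point_set(int s, double v) {
    int i = s + n2;
    t[i] = v;
    for (i >>= 1; i >= 1; i >>= 1) t[i] = t[2 * i] + t[2 * i + 1];
  }
  // indices of nonzero leaves in [qlo, qhi]
  void collect_nonzero(int node, int nlo, int nhi, int qlo, int qhi,
                       std::vector<int>& out) const {
    if (t[node] <= 0 || qhi < nlo || nhi < qlo) return;
    if (nlo == nhi) { out.push_back(nlo); return; }
    int mid = (nlo + nhi) / 2;
    collect_nonzero(2 * node, nlo, mid, qlo, qhi, out);
    collect_nonzero(2 * node + 1, mid + 1, nhi, qlo, qhi, out);
  }
  // sample leaf index with probability proportional to leaf value
  int sample(double u) const {
    double v = u * t[1];
    int i = 1;
    while (i < n2) {
      i <<= 1;
      if (v > t[i]) { v -= t[i]; ++i; }
    }
    return i - n2;
  }
};

struct Engine {
  int L, hc;
  std::vector<double> Ed;   // per-dyad total binding energy
  std::vector<double> att;  // pair attraction at gaps hc, hc+1, ...
  double D, k_enz, r_const, mu;
  int enz_range;

  std::vector<int> dy;                       // sorted dyads
  std::vector<double> hopL, hopR, rem, enz;  // per nucleosome / per gap
  SegTree ins;
  int win;  // refresh radius for absorption rates

  double u_pair(int g) const {
    if (g < hc) return INFINITY;
    int i = g - hc;
    return (i < (int)att.size()) ? att[i] : 0.0;
  }
  int modL(int x) const { x %= L; return x < 0 ? x + L : x; }
  int n() const { return (int)dy.size(); }
  int gap_after(int i) const {  // gap between dy[i] and its successor
    int j = (i + 1 == n()) ? 0 : i + 1;
    int g = dy[j] - dy[i];
    return (i + 1 == n()) ? g + L : g;
  }

  // energy change of inserting a nucleosome at site s; +inf if blocked
  double dU_insert(int s) const {
    int N = n();
    if (N == 0) return (L >= hc) ? Ed[s] : INFINITY;
    int pos = (int)(std::lower_bound(dy.begin(), dy.end(), s) - dy.begin());
    int ri = (pos == N) ? 0 : pos;
    int li = (pos == 0) ? N - 1 : pos - 1;
    if (dy[ri] == s || dy[li] == s) return INFINITY;
    int dl = modL(s - dy[li]);
    int dr = modL(dy[ri] - s);
    if (dl < hc || dr < hc) return INFINITY;
    double dU = Ed[s] + u_pair(dl) + u_pair(dr);
    if (N >= 2) dU -= u_pair(dl + dr);
    return dU;
  }

  double ins_rate(int s) const {
    double dU = dU_insert(s);
    if (std::isinf(dU)) return 0.0;
    return r_const * std::exp(-(dU + mu) / 2.0);
  }

  // recompute hop/removal rates of nucleosome i and the enzyme rates of the
  // gaps on both sides
  void refresh_nuc(int i) {
    int N = n();
    int x = dy[i];
    if (N == 1) {
      if (D > 0) {
        int xl = modL(x - 1), xr = modL(x + 1);
        hopL[i] = D * std::exp(-(Ed[xl] - Ed[x]) / 2.0);
        hopR[i] = D * std::exp(-(Ed[xr] - Ed[x]) / 2.0);
      } else {
        hopL[i] = hopR[i] = 0.0;
      }
      rem[i] = (r_const > 0) ? r_const * std::exp((Ed[x] + mu) / 2.0) : 0.0;
      enz[i] = 0.0;  // a lone nucleosome has no pair
      return;
    }
    int ip = (i == 0) ? N - 1 : i - 1;
    int dl = gap_after(ip);
    int dr = gap_after(i);
    // hops
    if (D > 0) {
      if (dr - 1 < hc) hopR[i] = 0.0;
      else {
        double dU = Ed[modL(x + 1)] - Ed[x] + u_pair(dl + 1) - u_pair(dl)
                    + u_pair(dr - 1) - u_pair(dr);
        hopR[i] = D * std::exp(-dU / 2.0);
      }
      if (dl - 1 < hc) hopL[i] = 0.0;
      else {
        double dU = Ed[modL(x - 1)] - Ed[x] + u_pair(dl - 1) - u_pair(dl)
                    + u_pair(dr + 1) - u_pair(dr);
        hopL[i] = D * std::exp(-dU / 2.0);
      }
    } else {
      hopL[i] = hopR[i] = 0.0;
    }
    // removal (rate of the reverse insertion, r_off = r e^{+dV/2})
    if (r_const > 0) {
      double dU_ins = Ed[x] + u_pair(dl) + u_pair(dr);
      if (N >= 3) dU_ins -= u_pair(dl + dr);
      rem[i] = r_const * std::exp((dU_ins + mu) / 2.0);
    } else {
      rem[i] = 0.0;
    }
    // enzyme eligibility of flanking gaps
    enz[ip] = (k_enz > 0 && dl >= hc + 1 && dl <= enz_range) ? k_enz : 0.0;
    enz[i] = (k_enz > 0 && dr >= hc + 1 && dr <= enz_range) ? k_enz : 0.0;
  }

  void refresh_all_nucs() {
    int N = n();
    hopL.assign(N, 0.0); hopR.assign(N, 0.0);
    rem.assign(N, 0.0); enz.assign(N, 0.0);
    for (int i = 0; i < N; ++i) refresh_nuc(i);
  }

  // recompute absorption rates for sites within `win` of center (circular).
  // Only candidate (free-footprint) sites can have nonzero rate, and at high
  // density they are sparse: clear the previously nonzero leaves in the
  // range, then walk the gap intervals and set rates for free sites only.
  std::vector<int> scratch_nz;
  void refresh_window(int center) {
    if (r_const <= 0) return;
    if (2 * win + 1 >= L) { refresh_all_sites(); return; }
    int lo = center - win, hi = center + win;
    if (lo < 0) {
      refresh_range(modL(lo), L - 1);
      refresh_range(0, hi);
    } else if (hi >= L) {
      refresh_range(lo, L - 1);
      refresh_range(0, modL(hi));
    } else {
      refresh_range(lo, hi);
    }
  }
  void refresh_range(int lo, int hi) {
    scratch_nz.clear();
    ins.collect_nonzero(1, 0, ins.n2 - 1, lo, hi, scratch_nz);
    for (int s : scratch_nz) ins.point_set(s, 0.0);
    int N = n();
    if (N == 0) {
      if (L >= hc)
        for (int s = lo; s <= hi; ++s)
          ins.point_set(s, r_const * std::exp(-(Ed[s] + mu) / 2.0));
      return;
    }
    if (N == 1) {
      // free sites: both circular distances to the lone dyad >= hc
      int x = dy[0];
      for (int s = lo; s <= hi; ++s) {
        int dl = modL(s - x), dr = modL(x - s);
        if (dl >= hc && dr >= hc) {
          double dU = Ed[s] + u_pair(dl) + u_pair(dr);
          ins.point_set(s, r_const * std::exp(-(dU + mu) / 2.0));
        }
      }
      return;
    }
    // walk gap intervals overlapping [lo, hi] in unwrapped coordinates
    int pos = (int)(std::lower_bound(dy.begin(), dy.end(), lo) - dy.begin());
    int li = (pos == 0) ? N - 1 : pos - 1;
    long lx = (pos == 0) ? (long)dy[N - 1] - L : dy[li];  // left dyad, unwrapped
    while (lx <= hi) {
      int ri = (li + 1 == N) ? 0 : li + 1;
      long rx = lx + gap_after(li);
      long a = std::max((long)lo, lx + hc);
      long b = std::min((long)hi, rx - hc);
      int g = (int)(rx - lx);
      for (long s = a; s <= b; ++s) {
        int dl = (int)(s - lx), dr = (int)(rx - s);
        double dU = Ed[(int)s] + u_pair(dl) + u_pair(dr) - u_pair(g);
        ins.point_set((int)s, r_const * std::exp(-(dU + mu) / 2.0));
      }
      li = ri; lx = rx;
    }
  }
  void refresh_all_sites() {
    if (r_const <= 0) return;
    for (int s = 0; s < L; ++s) ins.set_leaf(s, ins_rate(s));
    ins.rebuild(0, L - 1);
  }

  void init_state(const std::vector<int>& init) {
    dy = init;
    std::sort(dy.begin(), dy.end());
    refresh_all_nucs();
    ins.init(L);
    refresh_all_sites();
    win = hc + (int)att.size() + 1;
  }

  // --- event execution -----------------------------------------------------

  // move nucleosome i by dir (+1/-1); handles ring wrap reordering
  void do_hop(int i, int dir) {
    int old = dy[i];
    int nx = modL(old + dir);
    int N = n();
    bool wrapped = false;
    if (dir > 0 && i == N - 1 && nx < dy[0]) wrapped = true;
    if (dir < 0 && i == 0 && nx > dy[N - 1]) wrapped = true;
    if (!wrapped) {
      dy[i] = nx;
      if (N == 1) { refresh_nuc(0); }
      else {
        refresh_nuc((i == 0) ? N - 1 : i - 1);
        refresh_nuc(i);
        refresh_nuc((i == N - 1) ? 0 : i + 1);
      }
    } else {
      // element crosses the origin: rotate and rebuild per-nucleosome state
      if (dir > 0) { dy.pop_back(); dy.insert(dy.begin(), nx); }
      else { dy.erase(dy.begin()); dy.push_back(nx); }
      refresh_all_nucs();
    }
    refresh_window(old);
  }

  void do_insert(int s) {
    int pos = (int)(std::lower_bound(dy.begin(), dy.end(), s) - dy.begin());
    dy.insert(dy.begin() + pos, s);
    hopL.insert(hopL.begin() + pos, 0.0);
    hopR.insert(hopR.begin() + pos, 0.0);
    rem.insert(rem.begin() + pos, 0.0);
    enz.insert(enz.begin() + pos, 0.0);
    int N = n();
    refresh_nuc((pos == 0) ? N - 1 : pos - 1);
    refresh_nuc(pos);
    refresh_nuc((pos == N - 1) ? 0 : pos + 1);
    refresh_window(s);
  }

  void do_remove(int i) {
    int old = dy[i];
    dy.erase(dy.begin() + i);
    hopL.erase(hopL.begin() + i);
    hopR.erase(hopR.begin() + i);
    rem.erase(rem.begin() + i);
    enz.erase(enz.begin() + i);
    int N = n();
    if (N > 0) {
      int ip = (i == 0) ? N - 1 : i % N;
      refresh_nuc((ip == 0) ? N - 1 : ip - 1);
      refresh_nuc(ip);
      if (N > 1) refresh_nuc((ip == N - 1) ? 0 : ip + 1);
    }
    refresh_window(old);
  }
};

int pick_weighted(const std::vector<double>& a, const std::vector<double>& b,
                  double target, int& which) {
  // scan concatenated (a, b); which = 0 if from a, 1 if from b
  for (size_t i = 0; i < a.size(); ++i) {
    if (target < a[i]) { which = 0; return (int)i; }
    target -= a[i];
  }
  for (size_t i = 0; i < b.size(); ++i) {
    if (target < b[i]) { which = 1; return (int)i; }
    target -= b[i];
  }
  // numerical fallback: last positive entry
  for (int i = (int)b.size() - 1; i >= 0; --i)
    if (b[i] > 0) { which = 1; return i; }
  for (int i = (int)a.size() - 1; i >= 0; --i)
    if (a[i] > 0) { which = 0; return i; }
  which = -1; return -1;
}

}  // namespace

// [[Rcpp::export]]
List cpp_gillespie(int L, NumericVector Ed, int hc, NumericVector att,
                   double D, double k_enz, int enz_range,
                   double r_const, double mu,
                   IntegerVector init, NumericVector sample_times,
                   double seed, double max_events, bool return_rates) {
  Engine e;
  e.L = L; e.hc = hc;
  e.Ed.assign(Ed.begin(), Ed.end());
  e.att.assign(att.begin(), att.end());
  e.D = D; e.k_enz = k_enz; e.enz_range = enz_range;
  e.r_const = r_const; e.mu = mu;
  e.init_state(std::vector<int>(init.begin(), init.end()));

  Rng rng((uint64_t)(int64_t)seed);
  double t = 0.0;
  int si = 0, ns = sample_times.size();
  std::vector<std::vector<int>> recorded;
  double events = 0.0;
  bool truncated = false;

  while (si < ns) {
    if (events >= max_events) { truncated = true; break; }
    double S_hop = 0, S_enz = 0, S_rem = 0;
    for (double v : e.hopL) S_hop += v;
    for (double v : e.hopR) S_hop += v;
    for (double v : e.enz) S_enz += v;
    for (double v : e.rem) S_rem += v;
    double S_ins = (r_const > 0) ? e.ins.total() : 0.0;
    double total = S_hop + S_enz + S_rem + S_ins;
    if (total <= 0) {
      // absorbing: hold configuration for all remaining sample times
      while (si < ns) { recorded.push_back(e.dy); ++si; }
      break;
    }
    double dt = -std::log(rng.unif_pos()) / total;
    double t_new = t + dt;
    while (si < ns && sample_times[si] <= t_new) {
      recorded.push_back(e.dy);
      ++si;
    }
    if (si >= ns) break;
    t = t_new;
    // select category and event
    double u = rng.unif() * total;
    if (u < S_hop + S_enz) {
      if (u < S_hop) {
        int which;
        int i = pick_weighted(e.hopL, e.hopR, u, which);
        if (i >= 0) e.do_hop(i, which == 0 ? -1 : +1);
      } else {
        double target = u - S_hop;
        int i = -1;
        for (size_t j = 0; j < e.enz.size(); ++j) {
          if (target < e.enz[j]) { i = (int)j; break; }
          target -= e.enz[j];
        }
        if (i < 0) {
          for (int j = (int)e.enz.size() - 1; j >= 0; --j)
            if (e.enz[j] > 0) { i = j; break; }
        }
        if (i >= 0) {
          // pair (i, i+1): move one member toward the other (both inward
          // moves keep all gaps >= hc because the gap is >= hc + 1)
          int N = e.n();
          int j2 = (i + 1 == N) ? 0 : i + 1;
          if (rng.unif() < 0.5) e.do_hop(i, +1);
          else e.do_hop(j2, -1);
        }
      }
    } else if (u < S_hop + S_enz + S_rem) {
      double target = u - S_hop - S_enz;
      int i = -1;
      for (size_t j = 0; j < e.rem.size(); ++j) {
        if (target < e.rem[j]) { i = (int)j; break; }
        target -= e.rem[j];
      }
      if (i < 0) {
        for (int j = (int)e.rem.size() - 1; j >= 0; --j)
          if (e.rem[j] > 0) { i = j; break; }
      }
      if (i >= 0) e.do_remove(i);
    } else {
      int s = e.ins.sample(rng.unif());
      if (s < L && std::isfinite(e.dU_insert(s))) e.do_insert(s);
    }
    events += 1.0;
    if (((long long)events & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  if (truncated) {
    while (si < ns) { recorded.push_back(e.dy); ++si; }
  }

  List samples(recorded.size());
  for (size_t i = 0; i < recorded.size(); ++i)
    samples[i] = IntegerVector(recorded[i].begin(), recorded[i].end());
  List out = List::create(_["samples"] = samples,
                          _["final"] = IntegerVector(e.dy.begin(), e.dy.end()),
                          _["n_events"] = events,
                          _["t"] = t,
                          _["truncated"] = truncated);
  if (return_rates) {
    NumericVector insr(L);
    for (int s = 0; s < L; ++s) insr[s] = e.ins.n2 > 1 ? e.ins.leaf(s) : 0.0;
    out["rates"] = List::create(
        _["hop_left"] = NumericVector(e.hopL.begin(), e.hopL.end()),
        _["hop_right"] = NumericVector(e.hopR.begin(), e.hopR.end()),
        _["enzyme"] = NumericVector(e.enz.begin(), e.enz.end()),
        _["remove"] = NumericVector(e.rem.begin(), e.rem.end()),
        _["insert"] = insr);
  }
  return out;
}

// Build the engine state for a configuration, run `n_events` events, and
// return both the incremental rate tables and the configuration, so tests
// can compare against a from-scratch enumeration.
// [[Rcpp::export]]
List cpp_engine_rates(int L, NumericVector Ed, int hc, NumericVector att,
                      double D, double k_enz, int enz_range,
                      double r_const, double mu,
                      IntegerVector init, double n_events, double seed) {
  // reuse cpp_gillespie with a far-future single sample time and an event cap
  NumericVector st = NumericVector::create(1e300);
  return cpp_gillespie(L, Ed, hc, att, D, k_enz, enz_range, r_const, mu,
                       init, st, seed, n_events, true);
}
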