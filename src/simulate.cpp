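#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Discrete-event propagation through the dual-pathway AV node network.
//
// Nodes 0..L-1 form the slow-pathway chain (SP_1..SP_L), L..2L-1 the fast
// pathway (FP_1..FP_L), node 2L is the coupling node (CN).  Edges are
// bidirectional: consecutive chain nodes, SP_L--FP_L, SP_L--CN, FP_L--CN.
// Each atrial impulse enters simultaneously at SP_1 and FP_1 (SP first in
// insertion order).  Events are processed in (arrival time, insertion
// sequence) order; an impulse conducts iff the node is fresh or its
// excitation gap is strictly positive.  Blocked impulses leave node state
// untouched; the refractory clock is anchored at the last conducted arrival.
// Conduction at the CN emits a ventricular activation time.
//
// The autonomic-tone scales a_r(t), a_d(t) are right-continuous step
// functions; they are read off at the moment an impulse conducts, which is
// when the node's refractory period and conduction delay are set.

struct Ev {
  double t;
  long long seq;
  int node;
};

struct EvCmp {
  bool operator()(const Ev& a, const Ev& b) const {
    if (a.t != b.t) return a.t > b.t; // min-heap on time
    return a.seq > b.seq;             // FIFO within a timestamp
  }
};

static inline double step_at(const NumericVector& brk, const NumericVector& val,
                             double t) {
  int lo = 0, hi = brk.size() - 1;
  while (lo < hi) { // last breakpoint <= t (t before first => first value)
    int mid = (lo + hi + 1) / 2;
    if (brk[mid] <= t) lo = mid; else hi = mid - 1;
  }
  return val[lo];
}

// params: r_min, delta_r, tau_r, d_min, delta_d, tau_d
// [[Rcpp::export]]
NumericVector cpp_simulate_av(NumericVector aa,
                              NumericVector sp, NumericVector fp,
                              NumericVector cn,
                              NumericVector ar_break, NumericVector ar_value,
                              NumericVector ad_break, NumericVector ad_value,
                              int n_per_chain) {
  const int L = n_per_chain;
  const int n_nodes = 2 * L + 1;
  const int CN = 2 * L;

  // adjacency
  std::vector< std::vector<int> > adj(n_nodes);
  for (int i = 0; i + 1 < L; ++i) {
    adj[i].push_back(i + 1);       adj[i + 1].push_back(i);
    adj[L + i].push_back(L + i + 1); adj[L + i + 1].push_back(L + i);
  }
  adj[L - 1].push_back(2 * L - 1);  adj[2 * L - 1].push_back(L - 1); // SP_L -- FP_L
  adj[L - 1].push_back(CN);         adj[CN].push_back(L - 1);
  adj[2 * L - 1].push_back(CN);     adj[CN].push_back(2 * L - 1);

  // per-node parameter lookup
  std::vector<const double*> par(n_nodes);
  for (int i = 0; i < L; ++i)     par[i] = REAL(sp);
  for (int i = L; i < 2 * L; ++i) par[i] = REAL(fp);
  par[CN] = REAL(cn);

  std::vector<char>   conducted(n_nodes, 0);
  std::vector<double> last_t(n_nodes, 0.0);
  std::vector<double> r_prev(n_nodes, 0.0); // refractory set at last conduction

  std::priority_queue<Ev, std::vector<Ev>, EvCmp> q;
  long long seq = 0;
  const int n_aa = aa.size();
  for (int i = 0; i < n_aa; ++i) {
    q.push(Ev{aa[i], seq++, 0}); // SP_1 before FP_1 within each impulse
    q.push(Ev{aa[i], seq++, L});
  }

  std::vector<double> out;
  out.reserve(n_aa);

  while (!q.empty()) {
    Ev ev = q.top();
    q.pop();
    const int nd = ev.node;
    const double* p = par[nd];

    bool fresh = !conducted[nd];
    double gap = 0.0;
    if (!fresh) {
      gap = ev.t - last_t[nd] - r_prev[nd];
      if (gap <= 0.0) continue; // blocked; state untouched
    }

    const double ar = step_at(ar_break, ar_value, ev.t);
    const double ad = step_at(ad_break, ad_value, ev.t);
    double R, D;
    if (fresh) { // fully recovered: gap -> infinity
      R = ar * (p[0] + p[1]);
      D = ad * p[3];
    } else {
      R = ar * (p[0] + p[1] * (1.0 - std::exp(-gap / p[2])));
      D = ad * (p[3] + p[4] * std::exp(-gap / p[5]));
    }
    conducted[nd] = 1;
    last_t[nd] = ev.t;
    r_prev[nd] = R;

    if (nd == CN) out.push_back(ev.t);

    const double t_next = ev.t + D;
    for (size_t k = 0; k < adj[nd].size(); ++k)
      q.push(Ev{t_next, seq++, adj[nd][k]});
  }

  return wrap(out);
}
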