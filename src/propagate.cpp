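#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>
using namespace Rcpp;

// Signal-propagation and simulated-annealing core.
//
// Node activity update (synchronous, damped):
//   a_v <- (1-d) * a_v + d * tanh(gain * sum_{u->v} w_{uv} * a_u)
// Clamped (stimulated) nodes keep their stimulus value throughout.
// All indices arriving from R are 0-based.

struct Graph {
  int n_nodes;
  std::vector<int> src, dst;     // parallel edge arrays
  // incoming-edge index per node, CSR-like
  std::vector<int> in_ptr, in_edge;
  Graph(int n, const IntegerVector& s, const IntegerVector& d)
      : n_nodes(n), src(s.begin(), s.end()), dst(d.begin(), d.end()) {
    int m = src.size();
    std::vector<int> cnt(n, 0);
    for (int e = 0; e < m; ++e) cnt[dst[e]]++;
    in_ptr.assign(n + 1, 0);
    for (int v = 0; v < n; ++v) in_ptr[v + 1] = in_ptr[v] + cnt[v];
    in_edge.assign(m, 0);
    std::vector<int> fill(in_ptr.begin(), in_ptr.end() - 1);
    for (int e = 0; e < m; ++e) in_edge[fill[dst[e]]++] = e;
  }
};

struct PropResult {
  bool converged;
  int iterations;
};

static PropResult propagate_core(const Graph& g, const std::vector<double>& w,
                                 const std::vector<int>& clamp_idx,
                                 const std::vector<double>& clamp_val,
                                 double gain, double damping, double tol,
                                 int max_iter, std::vector<double>& act) {
  int n = g.n_nodes;
  std::vector<bool> clamped(n, false);
  for (size_t i = 0; i < clamp_idx.size(); ++i) {
    clamped[clamp_idx[i]] = true;
    act[clamp_idx[i]] = clamp_val[i];
  }
  std::vector<double> nxt(n);
  PropResult res{false, 0};
  for (int it = 1; it <= max_iter; ++it) {
    double delta = 0.0;
    for (int v = 0; v < n; ++v) {
      if (clamped[v]) { nxt[v] = act[v]; continue; }
      double s = 0.0;
      for (int k = g.in_ptr[v]; k < g.in_ptr[v + 1]; ++k) {
        int e = g.in_edge[k];
        s += w[e] * act[g.src[e]];
      }
      double target = std::tanh(gain * s);
      double nv = (1.0 - damping) * act[v] + damping * target;
      double d = std::fabs(nv - act[v]);
      if (d > delta) delta = d;
      nxt[v] = nv;
    }
    act.swap(nxt);
    res.iterations = it;
    if (delta < tol) { res.converged = true; break; }
  }
  return res;
}

// [[Rcpp::export]]
List cpp_propagate(int n_nodes, IntegerVector edge_src, IntegerVector edge_dst,
                   NumericVector weights, IntegerVector clamp_idx,
                   NumericVector clamp_val, double gain, double damping,
                   double tol, int max_iter) {
  Graph g(n_nodes, edge_src, edge_dst);
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<int> ci(clamp_idx.begin(), clamp_idx.end());
  std::vector<double> cv(clamp_val.begin(), clamp_val.end());
  std::vector<double> act(n_nodes, 0.0);
  PropResult r = propagate_core(g, w, ci, cv, gain, damping, tol, max_iter, act);
  return List::create(_["activity"] = NumericVector(act.begin(), act.end()),
                      _["converged"] = r.converged,
                      _["iterations"] = r.iterations);
}

// Batch propagation over many clamp-value rows for the same clamp set
// (used by the Sobol sampler: thousands of perturbed stimuli).
// clamp_vals: matrix n_samples x n_clamped.
// [[Rcpp::export]]
NumericMatrix cpp_propagate_batch(int n_nodes, IntegerVector edge_src,
                                  IntegerVector edge_dst, NumericVector weights,
                                  IntegerVector clamp_idx,
                                  NumericMatrix clamp_vals, double gain,
                                  double damping, double tol, int max_iter) {
  Graph g(n_nodes, edge_src, edge_dst);
  std::vector<double> w(weights.begin(), weights.end());
  std::vector<int> ci(clamp_idx.begin(), clamp_idx.end());
  int ns = clamp_vals.nrow();
  NumericMatrix out(ns, n_nodes);
  std::vector<double> cv(ci.size());
  for (int s = 0; s < ns; ++s) {
    for (size_t j = 0; j < ci.size(); ++j) cv[j] = clamp_vals(s, j);
    std::vector<double> act(n_nodes, 0.0);
    propagate_core(g, w, ci, cv, gain, damping, tol, max_iter, act);
    for (int v = 0; v < n_nodes; ++v) out(s, v) = act[v];
  }
  return out;
}

// ---- training ----

struct RuleSet {
  // flattened rules: rule r clamps clamp_idx[cptr[r]..cptr[r+1]) and expects
  // sign exp_sign[e] at node exp_idx[e] for e in eptr[r]..eptr[r+1)
  std::vector<int> cptr, clamp_idx, eptr, exp_idx;
  std::vector<double> clamp_val, exp_sign;
  int n_rules() const { return (int)cptr.size() - 1; }
  int n_expect() const { return (int)exp_idx.size(); }
};

// margin score: mean over expectations of min(sign * activity, cap) / cap.
// Rewarding sign * activity only up to `cap` (and charging wrong signs
// linearly) spreads the optimizer's effort across all expectations instead
// of letting a few saturated ones mask sign violations elsewhere.
// accuracy: fraction of expectations with matching sign and |a| >= thr.
struct EvalOut { double margin; double accuracy; };

static EvalOut eval_rules(const Graph& g, const std::vector<double>& w,
                          const RuleSet& rs, double gain, double damping,
                          double tol, int max_iter, double act_thr,
                          double margin_cap,
                          std::vector<std::vector<double> >* warm) {
  double margin = 0.0;
  int complied = 0;
  for (int r = 0; r < rs.n_rules(); ++r) {
    std::vector<int> ci(rs.clamp_idx.begin() + rs.cptr[r],
                        rs.clamp_idx.begin() + rs.cptr[r + 1]);
    std::vector<double> cv(rs.clamp_val.begin() + rs.cptr[r],
                           rs.clamp_val.begin() + rs.cptr[r + 1]);
    std::vector<double> act;
    if (warm) act = (*warm)[r]; else act.assign(g.n_nodes, 0.0);
    propagate_core(g, w, ci, cv, gain, damping, tol, max_iter, act);
    for (int e = rs.eptr[r]; e < rs.eptr[r + 1]; ++e) {
      double a = act[rs.exp_idx[e]];
      double s = rs.exp_sign[e];
      double m = s * a;
      margin += (m < margin_cap ? m : margin_cap) / margin_cap;
      if (m >= act_thr) complied++;
    }
    if (warm) (*warm)[r].swap(act);
  }
  EvalOut out;
  out.margin = margin / rs.n_expect();
  out.accuracy = (double)complied / rs.n_expect();
  return out;
}

static RuleSet unpack_rules(List rules) {
  RuleSet rs;
  rs.cptr.push_back(0);
  rs.eptr.push_back(0);
  for (int r = 0; r < rules.size(); ++r) {
    List rule = rules[r];
    IntegerVector ci = rule["clamp_idx"];
    NumericVector cv = rule["clamp_val"];
    IntegerVector ei = rule["exp_idx"];
    NumericVector es = rule["exp_sign"];
    rs.clamp_idx.insert(rs.clamp_idx.end(), ci.begin(), ci.end());
    rs.clamp_val.insert(rs.clamp_val.end(), cv.begin(), cv.end());
    rs.exp_idx.insert(rs.exp_idx.end(), ei.begin(), ei.end());
    rs.exp_sign.insert(rs.exp_sign.end(), es.begin(), es.end());
    rs.cptr.push_back((int)rs.clamp_idx.size());
    rs.eptr.push_back((int)rs.exp_idx.size());
  }
  return rs;
}

// [[Rcpp::export]]
List cpp_evaluate_rules(int n_nodes, IntegerVector edge_src,
                        IntegerVector edge_dst, NumericVector weights,
                        List rules, double gain, double damping, double tol,
                        int max_iter, double act_thr, double margin_cap) {
  Graph g(n_nodes, edge_src, edge_dst);
  std::vector<double> w(weights.begin(), weights.end());
  RuleSet rs = unpack_rules(rules);
  EvalOut out = eval_rules(g, w, rs, gain, damping, tol, max_iter, act_thr, margin_cap, NULL);
  return List::create(_["margin"] = out.margin, _["accuracy"] = out.accuracy);
}

// Simulated annealing over edge weights.
// objective = (1 - margin) + lambda * sum_{e: prior != 0, sign(w) != prior} |w_e|
// Metropolis acceptance, geometric cooling, single-edge Gaussian proposals
// reflected at +/- w_max; proposal sd scales with temperature.
// Deterministic given `seed` (own mt19937, independent of R's RNG).
// [[Rcpp::export]]
List cpp_anneal(int n_nodes, IntegerVector edge_src, IntegerVector edge_dst,
                NumericVector sign_prior, List rules, double w_max,
                double init_temp, double cooling, int steps_per_temp,
                double min_temp, double proposal_sigma, double lambda,
                double gain, double damping, double tol, int max_iter,
                double act_thr, double margin_cap, int seed,
                bool stop_at_perfect) {
  Graph g(n_nodes, edge_src, edge_dst);
  RuleSet rs = unpack_rules(rules);
  int m = edge_src.size();
  std::mt19937_64 rng((uint64_t)seed * 2654435761u + 1013904223u);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  std::vector<double> prior(sign_prior.begin(), sign_prior.end());
  std::vector<double> w(m);
  for (int e = 0; e < m; ++e) w[e] = (2.0 * unif(rng) - 1.0) * w_max;

  // warm-start cache: one activity vector per rule, updated on acceptance
  std::vector<std::vector<double> > warm(rs.n_rules(),
                                         std::vector<double>(n_nodes, 0.0));
  std::vector<std::vector<double> > warm_bak;

  // prior penalty is a per-edge mean so lambda stays on the margin's scale
  double penalty = 0.0;
  for (int e = 0; e < m; ++e)
    if (prior[e] != 0.0 && w[e] * prior[e] < 0.0) penalty += std::fabs(w[e]);
  penalty /= m;

  EvalOut cur = eval_rules(g, w, rs, gain, damping, tol, max_iter, act_thr, margin_cap, &warm);
  double obj = (1.0 - cur.margin) + lambda * penalty;

  std::vector<double> best_w = w;
  double best_acc = cur.accuracy, best_obj = obj;
  long n_evals = 1;

  double T = init_temp;
  bool done = (stop_at_perfect && best_acc >= 1.0);
  while (!done && T > min_temp) {
    for (int s = 0; s < steps_per_temp; ++s) {
      int e = (int)(unif(rng) * m);
      if (e >= m) e = m - 1;
      double old_we = w[e];
      double prop;
      if (unif(rng) < 0.15) {
        // sign-flip move: Gaussian steps shrink with temperature and can
        // never cross zero late in the schedule, but the sign pattern is
        // the hard combinatorial part of the fit
        prop = -old_we;
      } else {
        double width = T / init_temp;
        if (width < 0.05) width = 0.05;   // keep refining magnitudes late
        prop = old_we + gauss(rng) * proposal_sigma * width;
        // reflect into [-w_max, w_max]
        while (prop > w_max || prop < -w_max) {
          if (prop > w_max) prop = 2.0 * w_max - prop;
          if (prop < -w_max) prop = -2.0 * w_max - prop;
        }
      }
      w[e] = prop;
      double pen2 = penalty;
      if (prior[e] != 0.0) {
        if (old_we * prior[e] < 0.0) pen2 -= std::fabs(old_we) / m;
        if (prop * prior[e] < 0.0) pen2 += std::fabs(prop) / m;
      }
      warm_bak = warm;
      EvalOut nxt = eval_rules(g, w, rs, gain, damping, tol, max_iter, act_thr, margin_cap, &warm);
      n_evals++;
      double obj2 = (1.0 - nxt.margin) + lambda * pen2;
      bool accept = obj2 <= obj || unif(rng) < std::exp(-(obj2 - obj) / T);
      if (accept) {
        obj = obj2;
        penalty = pen2;
        cur = nxt;
        if (cur.accuracy > best_acc ||
            (cur.accuracy == best_acc && obj < best_obj)) {
          best_acc = cur.accuracy;
          best_obj = obj;
          best_w = w;
          if (stop_at_perfect && best_acc >= 1.0) { done = true; break; }
        }
      } else {
        w[e] = old_we;
        warm.swap(warm_bak);
      }
    }
    T *= cooling;
  }

  // cold re-evaluation of the returned solution (no warm start), so the
  // reported accuracy matches evaluate_accuracy() exactly
  EvalOut fin = eval_rules(g, best_w, rs, gain, damping, tol, max_iter, act_thr, margin_cap, NULL);
  return List::create(_["weights"] = NumericVector(best_w.begin(), best_w.end()),
                      _["accuracy"] = fin.accuracy,
                      _["margin"] = fin.margin,
                      _["objective"] = best_obj,
                      _["final_weights"] = NumericVector(w.begin(), w.end()),
                      _["n_evals"] = (double)n_evals);
}
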