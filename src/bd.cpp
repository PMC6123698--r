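#include <Rcpp.h>
using namespace Rcpp;

// Constant-rate birth-death propagation along one branch of duration t.
// E0 is the probability that a lineage alive at the branch's tipward end
// leaves no sampled descendants; returns E at the rootward end and the log
// of the branch's D factor (density of the observed subtree evolving along
// the branch without unsampled side survivors).
static inline bool branch_terms(double lam, double mu, double t, double E0,
                                double &Etop, double &logDfac) {
  if (lam <= 0.0) return false;
  double r = lam - mu;
  if (std::fabs(r) * std::max(t, 1.0) < 1e-10) {
    // critically balanced rates
    double denom = 1.0 + lam * t * (1.0 - E0);
    Etop = 1.0 - (1.0 - E0) / denom;
    logDfac = -2.0 * std::log(denom);
    return true;
  }
  double m = mu / lam;
  double d = E0 - m;
  if (std::fabs(d) < 1e-14) {
    // E sits at the fixed point mu/lambda
    Etop = E0;
    logDfac = -r * t;
    return true;
  }
  double K = (E0 - 1.0) / d;
  double rt = r * t;
  if (rt > 500.0) {
    // exp(rt) overflows; K e^{rt} dominates both numerator and denominator
    Etop = m;
    logDfac = -rt + 2.0 * (std::log(std::fabs(1.0 - K)) - std::log(std::fabs(K)));
    return true;
  }
  double ert = std::exp(rt);
  double den = 1.0 - K * ert;
  Etop = (1.0 - m * K * ert) / den;
  logDfac = rt + 2.0 * (std::log(std::fabs(1.0 - K)) - std::log(std::fabs(den)));
  return true;
}

// Assign a regime index (1-based; 1 = root regime) to every node given
// shift nodes: a shift governs its whole subtree including the stem branch.
static void assign_regimes(const IntegerMatrix &edge,
                           const IntegerVector &preorder_edges,
                           int root, const IntegerVector &shifts,
                           std::vector<int> &node_regime) {
  node_regime[root - 1] = 1;
  int K = shifts.size();
  for (int i = 0; i < preorder_edges.size(); ++i) {
    int e = preorder_edges[i] - 1;
    int p = edge(e, 0), c = edge(e, 1);
    int reg = node_regime[p - 1];
    for (int k = 0; k < K; ++k)
      if (shifts[k] == c) { reg = k + 2; break; }
    node_regime[c - 1] = reg;
  }
}

// [[Rcpp::export]]
IntegerVector edge_regimes_cpp(IntegerMatrix edge, IntegerVector preorder_edges,
                               int ntip, IntegerVector shifts) {
  int n_nodes = ntip + edge.nrow() + 1;  // upper bound on node count
  std::vector<int> node_regime(n_nodes, 1);
  int root = ntip + 1;
  assign_regimes(edge, preorder_edges, root, shifts, node_regime);
  IntegerVector out(edge.nrow());
  for (int e = 0; e < edge.nrow(); ++e) out[e] = node_regime[edge(e, 1) - 1];
  return out;
}

// [[Rcpp::export]]
double bd_loglik_cpp(IntegerMatrix edge, NumericVector edge_length,
                     IntegerVector postorder_edges, IntegerVector preorder_edges,
                     int ntip, IntegerVector shifts,
                     NumericVector lambda, NumericVector mu,
                     NumericVector tip_e0, bool condition_survival) {
  int nedge = edge.nrow();
  int n_nodes = ntip + nedge + 1;
  int root = ntip + 1;
  std::vector<int> node_regime(n_nodes, 1);
  assign_regimes(edge, preorder_edges, root, shifts, node_regime);

  std::vector<double> E(n_nodes, 0.0), logD(n_nodes, 0.0), esum(n_nodes, 0.0);
  std::vector<int> ecount(n_nodes, 0);
  for (int i = 0; i < ntip; ++i) {
    E[i] = tip_e0[i];
    logD[i] = std::log(1.0 - tip_e0[i]);
  }

  for (int i = 0; i < nedge; ++i) {
    int e = postorder_edges[i] - 1;
    int p = edge(e, 0), c = edge(e, 1);
    if (c > ntip) {
      // all child edges of c already processed: close the node
      int k = ecount[c - 1];
      E[c - 1] = esum[c - 1] / k;
      double lam_c = lambda[node_regime[c - 1] - 1];
      if (lam_c <= 0.0) return R_NegInf;
      logD[c - 1] += (k - 1) * std::log(lam_c);
    }
    int reg = node_regime[c - 1] - 1;
    double Etop, logDfac;
    if (!branch_terms(lambda[reg], mu[reg], edge_length[e], E[c - 1],
                      Etop, logDfac))
      return R_NegInf;
    esum[p - 1] += Etop;
    ecount[p - 1] += 1;
    logD[p - 1] += logD[c - 1] + logDfac;
  }
  int kroot = ecount[root - 1];
  E[root - 1] = esum[root - 1] / kroot;
  double lam_r = lambda[node_regime[root - 1] - 1];
  if (lam_r <= 0.0) return R_NegInf;
  double ll = logD[root - 1];
  if (kroot > 2) ll += (kroot - 2) * std::log(lam_r);
  if (condition_survival) {
    double s = 1.0 - E[root - 1];
    if (s <= 0.0) return R_NegInf;
    ll -= 2.0 * std::log(s);
  }
  if (!R_finite(ll)) return R_NegInf;
  return ll;
}
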