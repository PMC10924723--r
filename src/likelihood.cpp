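// Pruning-algorithm likelihood kernels and fixed-topology branch-length
// optimization for reversible substitution models with discrete-gamma rate
// categories and a proportion of invariant sites.
//
// Trees arrive as a postorder edge matrix (1-based node ids, tips 1..nTip).
// A "partition" is one data set (nucleotide alignment or character matrix)
// compressed to site patterns, together with the eigendecomposition of its
// rate matrix. Several partitions can share one set of edge lengths, each
// partition scaled by its own multiplier (the linked "proportionate" model).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Part {
  int k, ncat, npat;
  mat U, Uinv;
  vec lambda, pi, crates, cweights, weights, invprob;
  double pinv;
  std::vector<mat> tipmats;        // per tip: k x npat conditional likelihoods
  std::vector<cube> down;          // per node: k x npat x ncat
  double scalar;                   // edge-length multiplier for this partition
};

Part build_part(const Rcpp::List& pl, int nTip, int nNode, double scalar) {
  Part p;
  Rcpp::IntegerMatrix ts = pl["tipstates"];   // npat x nTip, -1 = missing
  p.U = Rcpp::as<mat>(pl["U"]);
  p.Uinv = Rcpp::as<mat>(pl["Uinv"]);
  p.lambda = Rcpp::as<vec>(pl["lambda"]);
  p.pi = Rcpp::as<vec>(pl["pi"]);
  p.crates = Rcpp::as<vec>(pl["crates"]);
  p.cweights = Rcpp::as<vec>(pl["cweights"]);
  p.weights = Rcpp::as<vec>(pl["weights"]);
  p.invprob = Rcpp::as<vec>(pl["invprob"]);
  p.pinv = Rcpp::as<double>(pl["pinv"]);
  p.k = p.U.n_rows;
  p.ncat = p.crates.n_elem;
  p.npat = ts.nrow();
  p.scalar = scalar;
  p.tipmats.resize(nTip);
  for (int i = 0; i < nTip; ++i) {
    mat tm(p.k, p.npat, fill::zeros);
    for (int j = 0; j < p.npat; ++j) {
      int s = ts(j, i);
      if (s < 0) tm.col(j).ones();
      else tm(s, j) = 1.0;
    }
    p.tipmats[i] = tm;
  }
  p.down.resize(nNode + 1);
  return p;
}

inline mat pmat(const Part& p, double len_cat) {
  mat P = p.U * diagmat(exp(p.lambda * len_cat)) * p.Uinv;
  P.clamp(0.0, datum::inf);
  return P;
}

// conditional likelihood matrix of node `nd` for category `c`
inline const mat child_mat(const Part& p, int nd, int nTip, int c, mat& buf) {
  if (nd <= nTip) return p.tipmats[nd - 1];
  buf = p.down[nd].slice(c);
  return buf;
}

struct Engine {
  imat edge;               // postorder, 1-based
  int nTip, nNode, root, nEdge;
  vec el;
  double el_max;
  std::vector<Part> parts;
  std::vector<std::vector<int>> child_edges;  // node -> edge indices below it

  void build_index() {
    nEdge = edge.n_rows;
    nNode = edge.max();
    child_edges.assign(nNode + 1, {});
    std::vector<bool> is_child(nNode + 1, false);
    for (int e = 0; e < nEdge; ++e) {
      child_edges[edge(e, 0)].push_back(e);
      is_child[edge(e, 1)] = true;
    }
    root = -1;
    for (int v = nTip + 1; v <= nNode; ++v)
      if (!is_child[v]) { root = v; break; }
  }

  void refresh_down_node(Part& p, int nd) {
    p.down[nd] = cube(p.k, p.npat, p.ncat, fill::ones);
    mat buf;
    for (int e : child_edges[nd]) {
      int ch = edge(e, 1);
      for (int c = 0; c < p.ncat; ++c) {
        const mat& cm = child_mat(p, ch, nTip, c, buf);
        p.down[nd].slice(c) %= pmat(p, el[e] * p.scalar * p.crates[c]) * cm;
      }
    }
  }

  void down_pass(Part& p) {
    // postorder edge order guarantees a node's subtrees are complete once
    // all of its child edges have been seen
    std::vector<size_t> seen(nNode + 1, 0);
    for (int e = 0; e < nEdge; ++e) {
      int par = edge(e, 0);
      if (++seen[par] == child_edges[par].size()) refresh_down_node(p, par);
    }
  }

  double root_loglik(const Part& p) const {
    rowvec site(p.npat, fill::zeros);
    for (int c = 0; c < p.ncat; ++c)
      site += p.cweights[c] * (p.pi.t() * p.down[root].slice(c));
    vec s = (1.0 - p.pinv) * site.t() + p.pinv * p.invprob;
    s.clamp(1e-300, datum::inf);
    return dot(p.weights, log(s));
  }

  double full_loglik() {
    double ll = 0.0;
    for (auto& p : parts) { down_pass(p); ll += root_loglik(p); }
    return ll;
  }

  // log-likelihood of the whole tree as a function of one edge length t,
  // given cached flows G (from the rest of the tree into the parent side)
  // and the child's conditional likelihoods.
  double edge_loglik(double t, const std::vector<cube>& G, int child) {
    double ll = 0.0;
    mat buf;
    for (size_t ip = 0; ip < parts.size(); ++ip) {
      Part& p = parts[ip];
      rowvec site(p.npat, fill::zeros);
      for (int c = 0; c < p.ncat; ++c) {
        const mat& D = child_mat(p, child, nTip, c, buf);
        mat V = pmat(p, t * p.scalar * p.crates[c]).t() * G[ip].slice(c);
        site += p.cweights[c] * sum(V % D, 0);
      }
      vec s = (1.0 - p.pinv) * site.t() + p.pinv * p.invprob;
      s.clamp(1e-300, datum::inf);
      ll += dot(p.weights, log(s));
    }
    return ll;
  }

  // Brent maximization of edge_loglik over [0, el_max]
  double brent_edge(const std::vector<cube>& G, int child, double t0) {
    const double golden = 0.3819660112501051;
    double a = 0.0, b = el_max;
    double x = std::min(std::max(t0, a), b);
    double w = x, v = x;
    double fx = -edge_loglik(x, G, child);
    double fw = fx, fv = fx;
    double d = 0.0, e = 0.0;
    for (int iter = 0; iter < 60; ++iter) {
      double xm = 0.5 * (a + b);
      double tol1 = 1e-10 + 1e-9 * std::fabs(x);
      double tol2 = 2.0 * tol1;
      if (std::fabs(x - xm) <= tol2 - 0.5 * (b - a)) break;
      bool use_golden = true;
      if (std::fabs(e) > tol1) {
        double r = (x - w) * (fx - fv);
        double q = (x - v) * (fx - fw);
        double pn = (x - v) * q - (x - w) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) pn = -pn;
        q = std::fabs(q);
        double etemp = e;
        e = d;
        if (std::fabs(pn) < std::fabs(0.5 * q * etemp) &&
            pn > q * (a - x) && pn < q * (b - x)) {
          d = pn / q;
          double u = x + d;
          if (u - a < tol2 || b - u < tol2)
            d = (xm - x >= 0 ? tol1 : -tol1);
          use_golden = false;
        }
      }
      if (use_golden) {
        e = (x >= xm) ? a - x : b - x;
        d = golden * e;
      }
      double u = (std::fabs(d) >= tol1) ? x + d
                                        : x + (d >= 0 ? tol1 : -tol1);
      double fu = -edge_loglik(u, G, child);
      if (fu <= fx) {
        if (u >= x) a = x; else b = x;
        v = w; w = x; x = u;
        fv = fw; fw = fx; fx = fu;
      } else {
        if (u < x) a = u; else b = u;
        if (fu <= fw || w == x) { v = w; w = u; fv = fw; fw = fu; }
        else if (fu <= fv || v == x || v == w) { v = u; fv = fu; }
      }
    }
    // the boundary t = 0 can beat the interior optimum
    double f0 = -edge_loglik(0.0, G, child);
    return (f0 < fx) ? 0.0 : x;
  }

  // one preorder sweep of single-edge optimizations with exact conditional
  // flows; refreshes down partials on the way back up
  void opt_subtree(int node, std::vector<cube>& up) {
    mat buf;
    for (int e : child_edges[node]) {
      int v = edge(e, 1);
      // flow into `node` from everything except the subtree below v
      std::vector<cube> G(parts.size());
      for (size_t ip = 0; ip < parts.size(); ++ip) {
        Part& p = parts[ip];
        G[ip] = up[ip];
        for (int f : child_edges[node]) {
          if (f == e) continue;
          int c2 = edge(f, 1);
          for (int c = 0; c < p.ncat; ++c) {
            const mat& cm = child_mat(p, c2, nTip, c, buf);
            G[ip].slice(c) %=
              pmat(p, el[f] * p.scalar * p.crates[c]) * cm;
          }
        }
      }
      el[e] = brent_edge(G, v, el[e]);
      if (v > nTip) {
        std::vector<cube> upv(parts.size());
        for (size_t ip = 0; ip < parts.size(); ++ip) {
          Part& p = parts[ip];
          upv[ip] = cube(p.k, p.npat, p.ncat);
          for (int c = 0; c < p.ncat; ++c)
            upv[ip].slice(c) =
              pmat(p, el[e] * p.scalar * p.crates[c]).t() * G[ip].slice(c);
        }
        opt_subtree(v, upv);
        for (auto& p : parts) refresh_down_node(p, v);
      }
    }
  }
};

Engine make_engine(const Rcpp::IntegerMatrix& edge, int nTip,
                   const Rcpp::NumericVector& el, const Rcpp::List& parts,
                   const Rcpp::NumericVector& scalars, double el_max) {
  Engine en;
  en.edge = Rcpp::as<imat>(edge);
  en.nTip = nTip;
  en.el = Rcpp::as<vec>(el);
  en.el_max = el_max;
  en.build_index();
  for (int i = 0; i < parts.size(); ++i)
    en.parts.push_back(build_part(parts[i], nTip, en.nNode, scalars[i]));
  return en;
}

}  // namespace

// [[Rcpp::export]]
double rl_loglik_cpp(Rcpp::IntegerMatrix edge, int nTip,
                     Rcpp::NumericVector el, Rcpp::List parts,
                     Rcpp::NumericVector scalars) {
  Engine en = make_engine(edge, nTip, el, parts, scalars, 10.0);
  return en.full_loglik();
}

// [[Rcpp::export]]
Rcpp::List rl_optim_edges_cpp(Rcpp::IntegerMatrix edge, int nTip,
                              Rcpp::NumericVector el0, Rcpp::List parts,
                              Rcpp::NumericVector scalars, double el_max,
                              double tol, int max_rounds) {
  Engine en = make_engine(edge, nTip, el0, parts, scalars, el_max);
  double ll = en.full_loglik();
  int round = 0;
  bool converged = false;
  for (; round < max_rounds; ++round) {
    std::vector<cube> up(en.parts.size());
    for (size_t ip = 0; ip < en.parts.size(); ++ip) {
      Part& p = en.parts[ip];
      up[ip] = cube(p.k, p.npat, p.ncat);
      for (int c = 0; c < p.ncat; ++c)
        up[ip].slice(c) = repmat(p.pi, 1, p.npat);
    }
    en.opt_subtree(en.root, up);
    double ll_new = en.full_loglik();
    if (ll_new - ll < tol) { ll = std::max(ll, ll_new); converged = true;
                             ++round; break; }
    ll = ll_new;
  }
  return Rcpp::List::create(
      Rcpp::Named("el") = Rcpp::wrap(en.el),
      Rcpp::Named("loglik") = ll,
      Rcpp::Named("rounds") = round,
      Rcpp::Named("converged") = converged);
}
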