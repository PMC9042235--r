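// Compiled evaluation of the coarse-grained restraint score and its
// gradient. The restraint system is pre-flattened in R (compile_system())
// into plain numeric structures; class weights are baked into the per-term
// weights. Semantics mirror the plain-R reference implementation in
// R/restraints.R, which the test suite holds as the oracle.
#include <Rcpp.h>
#include <unordered_set>
using namespace Rcpp;

static inline double dist3(const NumericMatrix& x, int i, int j) {
  double dx = x(i, 0) - x(j, 0);
  double dy = x(i, 1) - x(j, 1);
  double dz = x(i, 2) - x(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export(name = ".xl_score")]]
NumericVector xl_score(const NumericMatrix& coords, const List& sys) {
  const int n = coords.nrow();
  double e_xl = 0, e_inter = 0, e_intra = 0, e_rig = 0, e_anc = 0,
         e_slab = 0, e_ster = 0, e_bond = 0;

  // flat-bottom (crosslink / contact) restraints on ambiguous min distance
  IntegerMatrix fb_pairs = sys["fb_pairs"];
  IntegerVector fb_off = sys["fb_offset"];   // length R+1, 0-based
  NumericVector fb_bound = sys["fb_bound"];
  NumericVector fb_w = sys["fb_weight"];
  IntegerVector fb_class = sys["fb_class"];  // 1 xl, 2 inter, 3 intra
  const int nfb = fb_bound.size();
  for (int r = 0; r < nfb; ++r) {
    if (fb_w[r] == 0) continue;
    double dmin = R_PosInf;
    for (int k = fb_off[r]; k < fb_off[r + 1]; ++k) {
      double d = dist3(coords, fb_pairs(k, 0) - 1, fb_pairs(k, 1) - 1);
      if (d < dmin) dmin = d;
    }
    double exc = dmin - fb_bound[r];
    if (exc > 0) {
      double e = fb_w[r] * exc * exc;
      if (fb_class[r] == 1) e_xl += e;
      else if (fb_class[r] == 2) e_inter += e;
      else e_intra += e;
    }
  }

  // rigid-group internal distance pairs
  NumericMatrix rig = sys["rig_pairs"];  // i, j, dref, w
  for (int k = 0; k < rig.nrow(); ++k) {
    double d = dist3(coords, (int)rig(k, 0) - 1, (int)rig(k, 1) - 1);
    double dev = d - rig(k, 2);
    e_rig += rig(k, 3) * dev * dev;
  }

  // anchors
  IntegerVector anc_idx = sys["anc_idx"];
  NumericMatrix anc_ref = sys["anc_ref"];
  NumericVector anc_w = sys["anc_w"];
  for (int k = 0; k < anc_idx.size(); ++k) {
    int i = anc_idx[k] - 1;
    double dx = coords(i, 0) - anc_ref(k, 0);
    double dy = coords(i, 1) - anc_ref(k, 1);
    double dz = coords(i, 2) - anc_ref(k, 2);
    e_anc += anc_w[k] * (dx * dx + dy * dy + dz * dz);
  }

  // membrane slab on |z|
  IntegerVector slab_idx = sys["slab_idx"];
  NumericVector slab_hw = sys["slab_hw"];
  NumericVector slab_w = sys["slab_w"];
  for (int k = 0; k < slab_idx.size(); ++k) {
    double exc = std::fabs(coords(slab_idx[k] - 1, 2)) - slab_hw[k];
    if (exc > 0) e_slab += slab_w[k] * exc * exc;
  }

  // chain bonds
  IntegerMatrix bond = sys["bond_pairs"];
  const double bond_len = as<double>(sys["bond_len"]);
  const double w_bond = as<double>(sys["w_bond"]);
  for (int k = 0; k < bond.nrow(); ++k) {
    double d = dist3(coords, bond(k, 0) - 1, bond(k, 1) - 1);
    double dev = d - bond_len;
    e_bond += w_bond * dev * dev;
  }

  // soft-core sterics over all non-bonded pairs
  const double w_ster = as<double>(sys["w_ster"]);
  const double d_min = as<double>(sys["d_min"]);
  if (w_ster > 0) {
    std::unordered_set<long long> excl;
    for (int k = 0; k < bond.nrow(); ++k) {
      long long i = bond(k, 0) - 1, j = bond(k, 1) - 1;
      excl.insert(std::min(i, j) * n + std::max(i, j));
    }
    const double d2min = d_min * d_min;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = coords(i, 0) - coords(j, 0);
        double dy = coords(i, 1) - coords(j, 1);
        double dz = coords(i, 2) - coords(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < d2min && !excl.count((long long)i * n + j)) {
          double pen = d_min - std::sqrt(d2);
          e_ster += w_ster * pen * pen;
        }
      }
    }
  }

  double total = e_xl + e_inter + e_intra + e_rig + e_anc + e_slab +
                 e_ster + e_bond;
  NumericVector out = NumericVector::create(
      _["total"] = total, _["crosslink"] = e_xl,
      _["contact_inter"] = e_inter, _["contact_intra"] = e_intra,
      _["rigid"] = e_rig, _["anchor"] = e_anc, _["slab"] = e_slab,
      _["sterics"] = e_ster, _["bond"] = e_bond);
  return out;
}

static inline void add_pair_grad(NumericMatrix& g, const NumericMatrix& x,
                                 int i, int j, double coef, double d) {
  // gradient of coef-weighted radial term: dE/dxi = coef * (xi - xj) / d
  if (d < 1e-9) return;
  for (int c = 0; c < 3; ++c) {
    double u = (x(i, c) - x(j, c)) / d;
    g(i, c) += coef * u;
    g(j, c) -= coef * u;
  }
}

// [[Rcpp::export(name = ".xl_grad")]]
NumericMatrix xl_grad(const NumericMatrix& coords, const List& sys) {
  const int n = coords.nrow();
  NumericMatrix g(n, 3);

  IntegerMatrix fb_pairs = sys["fb_pairs"];
  IntegerVector fb_off = sys["fb_offset"];
  NumericVector fb_bound = sys["fb_bound"];
  NumericVector fb_w = sys["fb_weight"];
  const int nfb = fb_bound.size();
  for (int r = 0; r < nfb; ++r) {
    if (fb_w[r] == 0) continue;
    double dmin = R_PosInf;
    int bi = -1, bj = -1;
    for (int k = fb_off[r]; k < fb_off[r + 1]; ++k) {
      double d = dist3(coords, fb_pairs(k, 0) - 1, fb_pairs(k, 1) - 1);
      if (d < dmin) { dmin = d; bi = fb_pairs(k, 0) - 1; bj = fb_pairs(k, 1) - 1; }
    }
    double exc = dmin - fb_bound[r];
    if (exc > 0) add_pair_grad(g, coords, bi, bj, 2 * fb_w[r] * exc, dmin);
  }

  NumericMatrix rig = sys["rig_pairs"];
  for (int k = 0; k < rig.nrow(); ++k) {
    int i = (int)rig(k, 0) - 1, j = (int)rig(k, 1) - 1;
    double d = dist3(coords, i, j);
    add_pair_grad(g, coords, i, j, 2 * rig(k, 3) * (d - rig(k, 2)), d);
  }

  IntegerVector anc_idx = sys["anc_idx"];
  NumericMatrix anc_ref = sys["anc_ref"];
  NumericVector anc_w = sys["anc_w"];
  for (int k = 0; k < anc_idx.size(); ++k) {
    int i = anc_idx[k] - 1;
    for (int c = 0; c < 3; ++c) {
      g(i, c) += 2 * anc_w[k] * (coords(i, c) - anc_ref(k, c));
    }
  }

  IntegerVector slab_idx = sys["slab_idx"];
  NumericVector slab_hw = sys["slab_hw"];
  NumericVector slab_w = sys["slab_w"];
  for (int k = 0; k < slab_idx.size(); ++k) {
    int i = slab_idx[k] - 1;
    double z = coords(i, 2);
    double exc = std::fabs(z) - slab_hw[k];
    if (exc > 0) g(i, 2) += 2 * slab_w[k] * exc * (z > 0 ? 1 : -1);
  }

  IntegerMatrix bond = sys["bond_pairs"];
  const double bond_len = as<double>(sys["bond_len"]);
  const double w_bond = as<double>(sys["w_bond"]);
  for (int k = 0; k < bond.nrow(); ++k) {
    int i = bond(k, 0) - 1, j = bond(k, 1) - 1;
    double d = dist3(coords, i, j);
    add_pair_grad(g, coords, i, j, 2 * w_bond * (d - bond_len), d);
  }

  const double w_ster = as<double>(sys["w_ster"]);
  const double d_min = as<double>(sys["d_min"]);
  if (w_ster > 0) {
    std::unordered_set<long long> excl;
    for (int k = 0; k < bond.nrow(); ++k) {
      long long i = bond(k, 0) - 1, j = bond(k, 1) - 1;
      excl.insert(std::min(i, j) * n + std::max(i, j));
    }
    const double d2min = d_min * d_min;
    for (int i = 0; i < n - 1; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dx = coords(i, 0) - coords(j, 0);
        double dy = coords(i, 1) - coords(j, 1);
        double dz = coords(i, 2) - coords(j, 2);
        double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < d2min && !excl.count((long long)i * n + j)) {
          double d = std::sqrt(d2);
          add_pair_grad(g, coords, i, j, 2 * w_ster * (d - d_min), d);
        }
      }
    }
  }
  return g;
}
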