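#include <Rcpp.h>
using namespace Rcpp;

// Exact Debye sum: I(q) = sum_i sum_j f_i(q) f_j(q) sinc(q r_ij).
// ff is an nq x natom matrix of per-atom form factors on the q grid
// (constant per atom in point mode, element-dependent otherwise).
// [[Rcpp::export(name = ".debye_sum")]]
NumericVector debye_sum(NumericMatrix xyz, NumericMatrix ff,
                        NumericVector q) {
  const int n = xyz.nrow();
  const int nq = q.size();
  NumericVector out(nq);
  // diagonal terms
  for (int k = 0; k < nq; ++k) {
    double acc = 0.0;
    for (int i = 0; i < n; ++i) acc += ff(k, i) * ff(k, i);
    out[k] = acc;
  }
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = i + 1; j < n; ++j) {
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      for (int k = 0; k < nq; ++k) {
        const double qr = q[k] * r;
        const double s = (qr < 1e-12) ? 1.0 : std::sin(qr) / qr;
        out[k] += 2.0 * ff(k, i) * ff(k, j) * s;
      }
    }
  }
  return out;
}

// Minimum inter-set distance with optional early exit: if `below` > 0 the
// scan stops as soon as a pair closer than `below` is found (the clash
// filters only need the verdict, not the exact minimum).
// [[Rcpp::export(name = ".min_dist")]]
double min_dist(NumericMatrix a, NumericMatrix b, double below) {
  const int na = a.nrow(), nb = b.nrow();
  double best = R_PosInf;
  const double below2 = below > 0 ? below * below : -1.0;
  for (int i = 0; i < na; ++i) {
    const double xi = a(i, 0), yi = a(i, 1), zi = a(i, 2);
    for (int j = 0; j < nb; ++j) {
      const double dx = xi - b(j, 0);
      const double dy = yi - b(j, 1);
      const double dz = zi - b(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (below2 > 0 && best < below2) return std::sqrt(best);
      }
    }
  }
  return std::sqrt(best);
}

// Weighted histogram of all pairwise distances (pair-distance distribution
// before normalization). Bin b covers [b*w, (b+1)*w).
// [[Rcpp::export(name = ".pair_hist")]]
List pair_hist(NumericMatrix xyz, NumericVector wt, double width) {
  const int n = xyz.nrow();
  double dmax = 0.0;
  // first pass for dmax to size the histogram
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > dmax) dmax = d2;
    }
  dmax = std::sqrt(dmax);
  const int nb = std::max(1, (int)std::floor(dmax / width) + 1);
  NumericVector h(nb);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      int b = (int)std::floor(d / width);
      if (b >= nb) b = nb - 1;
      h[b] += wt[i] * wt[j];
    }
  return List::create(_["counts"] = h, _["dmax"] = dmax);
}

// Minimum distance between two atom subsets of one structure, skipping
// pairs whose residue numbers differ by <= excl (chain neighbours across a
// torsion pivot are covalently bonded and must not count as clashes).
// [[Rcpp::export(name = ".min_dist_excl")]]
double min_dist_excl(NumericMatrix xyz, IntegerVector ia, IntegerVector ib,
                     IntegerVector resno, int excl, double below) {
  double best = R_PosInf;
  const double below2 = below > 0 ? below * below : -1.0;
  for (int u = 0; u < ia.size(); ++u) {
    const int i = ia[u] - 1;
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const int ri = resno[i];
    for (int v = 0; v < ib.size(); ++v) {
      const int j = ib[v] - 1;
      if (std::abs(ri - resno[j]) <= excl) continue;
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) {
        best = d2;
        if (below2 > 0 && best < below2) return std::sqrt(best);
      }
    }
  }
  return std::sqrt(best);
}
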