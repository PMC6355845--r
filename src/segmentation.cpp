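// Multiresolution region-merging segmentation.
//
// Regions start as single pixels and merge pairwise while the increase in
// weighted heterogeneity (spectral + shape, Baatz-Schaepe form) stays below
// scale^2. Scheduling is deterministic: raster-order sweeps with local
// mutual best fitting (a merges b only when each is the other's
// minimum-cost neighbour; ties broken by lower cost then lower id),
// repeated until no permitted merge remains.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct Seg {
  // flattened per-region statistics
  std::vector<double> n, e;            // pixel count, exposed edge count
  std::vector<int> r0, r1, c0, c1;     // bbox (0-based, inclusive)
  std::vector<double> sum, sumsq;      // nb bands, region-major [reg*nb + b]
  std::vector<int> parent;
  std::vector<std::vector<std::pair<int, int>>> nb;  // (neighbour, shared edges)
  int nbands;

  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }

  // remap neighbour ids to roots, merge duplicates, drop self, sort by id
  void canonicalize(int a) {
    auto &v = nb[a];
    for (auto &pr : v) pr.first = find(pr.first);
    std::sort(v.begin(), v.end());
    size_t w = 0;
    for (size_t i = 0; i < v.size();) {
      int id = v[i].first;
      int cnt = 0;
      while (i < v.size() && v[i].first == id) { cnt += v[i].second; ++i; }
      if (id != a) v[w++] = {id, cnt};
    }
    v.resize(w);
  }
};

inline double sdev(double n, double s, double ss) {
  double v = ss / n - (s / n) * (s / n);
  return v > 0 ? std::sqrt(v) : 0.0;
}

// heterogeneity increase of merging roots a and b with `shared` common edges
double merge_cost(const Seg &S, int a, int b, int shared,
                  double w_color, double w_cmpct, const std::vector<double> &bw) {
  const int nb_ = S.nbands;
  double na = S.n[a], nbv = S.n[b], nab = na + nbv;
  double dcol = 0.0;
  for (int k = 0; k < nb_; ++k) {
    double sa = S.sum[(size_t)a * nb_ + k], ssa = S.sumsq[(size_t)a * nb_ + k];
    double sb = S.sum[(size_t)b * nb_ + k], ssb = S.sumsq[(size_t)b * nb_ + k];
    double sd_a = sdev(na, sa, ssa), sd_b = sdev(nbv, sb, ssb);
    double sd_ab = sdev(nab, sa + sb, ssa + ssb);
    dcol += bw[k] * (nab * sd_ab - (na * sd_a + nbv * sd_b));
  }
  double e_ab = S.e[a] + S.e[b] - 2.0 * shared;
  double cm_a = std::sqrt(na) * S.e[a], cm_b = std::sqrt(nbv) * S.e[b];
  double cm_ab = std::sqrt(nab) * e_ab;
  double bp_a = 2.0 * ((S.r1[a] - S.r0[a] + 1) + (S.c1[a] - S.c0[a] + 1));
  double bp_b = 2.0 * ((S.r1[b] - S.r0[b] + 1) + (S.c1[b] - S.c0[b] + 1));
  int rr0 = std::min(S.r0[a], S.r0[b]), rr1 = std::max(S.r1[a], S.r1[b]);
  int cc0 = std::min(S.c0[a], S.c0[b]), cc1 = std::max(S.c1[a], S.c1[b]);
  double bp_ab = 2.0 * ((rr1 - rr0 + 1) + (cc1 - cc0 + 1));
  double sm_a = na * S.e[a] / bp_a, sm_b = nbv * S.e[b] / bp_b;
  double sm_ab = nab * e_ab / bp_ab;
  double dcmp = cm_ab - (cm_a + cm_b);
  double dsm = sm_ab - (sm_a + sm_b);
  double dshape = w_cmpct * dcmp + (1.0 - w_cmpct) * dsm;
  return w_color * dcol + (1.0 - w_color) * dshape;
}

// index of minimum-cost neighbour of (canonicalized) root a, or -1;
// cost returned via best_cost. Ties: lower cost wins, then lower id (the
// list is id-sorted and comparison is strict).
int best_neighbour(Seg &S, int a, double w_color, double w_cmpct,
                   const std::vector<double> &bw, double *best_cost) {
  const auto &v = S.nb[a];
  int best = -1;
  double bc = 0.0;
  for (const auto &pr : v) {
    double c = merge_cost(S, a, pr.first, pr.second, w_color, w_cmpct, bw);
    if (best < 0 || c < bc) { best = pr.first; bc = c; }
  }
  *best_cost = bc;
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cpp_segment(NumericVector vals, int nr, int nc, int nbands,
                 double scale, double w_color, double w_cmpct,
                 NumericVector band_weights) {
  const int N = nr * nc;
  if (N == 0) stop("empty raster");
  std::vector<double> bw(band_weights.begin(), band_weights.end());

  Seg S;
  S.nbands = nbands;
  S.n.assign(N, 1.0);
  S.e.assign(N, 4.0);
  S.r0.resize(N); S.r1.resize(N); S.c0.resize(N); S.c1.resize(N);
  S.sum.resize((size_t)N * nbands);
  S.sumsq.resize((size_t)N * nbands);
  S.parent.resize(N);
  S.nb.resize(N);

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int p = r + c * nr;  // column-major like R
      S.parent[p] = p;
      S.r0[p] = S.r1[p] = r;
      S.c0[p] = S.c1[p] = c;
      for (int k = 0; k < nbands; ++k) {
        double v = vals[p + (size_t)k * N];
        S.sum[(size_t)p * nbands + k] = v;
        S.sumsq[(size_t)p * nbands + k] = v * v;
      }
      auto &lst = S.nb[p];
      lst.reserve(4);
      if (r > 0) lst.push_back({p - 1, 1});
      if (r < nr - 1) lst.push_back({p + 1, 1});
      if (c > 0) lst.push_back({p - nr, 1});
      if (c < nc - 1) lst.push_back({p + nr, 1});
    }
  }

  const double thresh = scale * scale;
  bool merged_any = true;
  while (merged_any) {
    merged_any = false;
    for (int a = 0; a < N; ++a) {
      if (S.parent[a] != a) continue;
      S.canonicalize(a);
      if (S.nb[a].empty()) continue;
      double ca;
      int b = best_neighbour(S, a, w_color, w_cmpct, bw, &ca);
      if (b < 0 || ca >= thresh) continue;
      S.canonicalize(b);
      double cb;
      int b2 = best_neighbour(S, b, w_color, w_cmpct, bw, &cb);
      if (b2 != a) continue;
      // merge into the lower id
      int r = std::min(a, b), o = std::max(a, b);
      int shared = 0;
      for (const auto &pr : S.nb[a]) if (pr.first == b) { shared = pr.second; break; }
      S.n[r] += S.n[o];
      S.e[r] = S.e[a] + S.e[b] - 2.0 * shared;
      S.r0[r] = std::min(S.r0[a], S.r0[b]); S.r1[r] = std::max(S.r1[a], S.r1[b]);
      S.c0[r] = std::min(S.c0[a], S.c0[b]); S.c1[r] = std::max(S.c1[a], S.c1[b]);
      for (int k = 0; k < nbands; ++k) {
        S.sum[(size_t)r * nbands + k] += S.sum[(size_t)o * nbands + k];
        S.sumsq[(size_t)r * nbands + k] += S.sumsq[(size_t)o * nbands + k];
      }
      S.parent[o] = r;
      auto &vr = S.nb[r];
      auto &vo = S.nb[o];
      vr.insert(vr.end(), vo.begin(), vo.end());
      std::vector<std::pair<int, int>>().swap(vo);
      S.canonicalize(r);
      merged_any = true;
    }
  }

  // compact ids in column-major first-occurrence order
  std::vector<int> newid(N, -1);
  IntegerMatrix labels(nr, nc);
  int K = 0;
  for (int p = 0; p < N; ++p) {
    int rt = S.find(p);
    if (newid[rt] < 0) newid[rt] = K++;
    labels[p] = newid[rt] + 1;
  }

  IntegerVector seg_id(K), rmin(K), rmax(K), cmin(K), cmax(K);
  NumericVector npix(K), perim(K);
  NumericMatrix sums(K, nbands), sumsqs(K, nbands);
  for (int p = 0; p < N; ++p) {
    if (S.parent[p] != p) continue;
    int id = newid[p];
    seg_id[id] = id + 1;
    npix[id] = S.n[p];
    perim[id] = S.e[p];
    rmin[id] = S.r0[p] + 1; rmax[id] = S.r1[p] + 1;
    cmin[id] = S.c0[p] + 1; cmax[id] = S.c1[p] + 1;
    for (int k = 0; k < nbands; ++k) {
      sums(id, k) = S.sum[(size_t)p * nbands + k];
      sumsqs(id, k) = S.sumsq[(size_t)p * nbands + k];
    }
  }

  // adjacency over compact ids (a < b)
  std::vector<int> ea, eb, esh;
  for (int p = 0; p < N; ++p) {
    if (S.parent[p] != p) continue;
    S.canonicalize(p);
    for (const auto &pr : S.nb[p]) {
      int q = pr.first;
      int i = newid[p], j = newid[q];
      if (i < j) { ea.push_back(i + 1); eb.push_back(j + 1); esh.push_back(pr.second); }
    }
  }

  return List::create(
    _["labels"] = labels,
    _["segment_id"] = seg_id, _["n"] = npix, _["perimeter"] = perim,
    _["rmin"] = rmin, _["rmax"] = rmax, _["cmin"] = cmin, _["cmax"] = cmax,
    _["band_sum"] = sums, _["band_sumsq"] = sumsqs,
    _["edge_a"] = wrap(ea), _["edge_b"] = wrap(eb), _["edge_shared"] = wrap(esh));
}
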