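#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// k-d tree over 3D reference points with nearest-neighbour queries.
// Tie rule: equal squared distances resolve to the lowest reference index,
// matching the exhaustive R oracle exactly (same double arithmetic order:
// dx*dx + dy*dy + dz*dz accumulated left to right).

namespace {

struct KDTree {
  const double *x, *y, *z;   // reference coordinates, length n
  std::vector<int> perm;     // point indices, permuted during build
  std::vector<int> axis;     // split axis per node (node = segment midpoint)

  double coord(int idx, int ax) const {
    return ax == 0 ? x[idx] : (ax == 1 ? y[idx] : z[idx]);
  }

  void build(int lo, int hi) {
    if (hi - lo <= 1) return;
    // split along the widest extent of this segment
    double mn[3], mx[3];
    for (int a = 0; a < 3; ++a) { mn[a] = R_PosInf; mx[a] = R_NegInf; }
    for (int i = lo; i < hi; ++i)
      for (int a = 0; a < 3; ++a) {
        double c = coord(perm[i], a);
        if (c < mn[a]) mn[a] = c;
        if (c > mx[a]) mx[a] = c;
      }
    int ax = 0;
    for (int a = 1; a < 3; ++a)
      if (mx[a] - mn[a] > mx[ax] - mn[ax]) ax = a;
    int mid = (lo + hi) / 2;
    std::nth_element(perm.begin() + lo, perm.begin() + mid, perm.begin() + hi,
                     [&](int a, int b) {
                       double ca = coord(a, ax), cb = coord(b, ax);
                       if (ca != cb) return ca < cb;
                       return a < b;  // deterministic layout
                     });
    axis[mid] = ax;
    build(lo, mid);
    build(mid + 1, hi);
  }

  void search(int lo, int hi, double qx, double qy, double qz,
              double &best, int &besti) const {
    if (hi <= lo) return;
    int mid = (lo + hi) / 2;
    int p = perm[mid];
    double dx = qx - x[p], dy = qy - y[p], dz = qz - z[p];
    double d = dx * dx + dy * dy + dz * dz;
    if (d < best || (d == best && p < besti)) { best = d; besti = p; }
    if (hi - lo == 1) return;
    int ax = axis[mid];
    double qc = ax == 0 ? qx : (ax == 1 ? qy : qz);
    double diff = qc - coord(p, ax);
    // near side first; explore far side whenever it could hold an equal match
    if (diff < 0) {
      search(lo, mid, qx, qy, qz, best, besti);
      if (diff * diff <= best) search(mid + 1, hi, qx, qy, qz, best, besti);
    } else {
      search(mid + 1, hi, qx, qy, qz, best, besti);
      if (diff * diff <= best) search(lo, mid, qx, qy, qz, best, besti);
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".nn_kdtree")]]
List nn_kdtree(NumericMatrix query, NumericMatrix reference) {
  const int nq = query.nrow(), nr = reference.nrow();
  if (nr == 0) stop("reference point set is empty");
  KDTree tree;
  NumericMatrix ref(reference);
  // column-major storage: column pointers are contiguous
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int i = 0; i < nr; ++i) {
    rx[i] = ref(i, 0); ry[i] = ref(i, 1); rz[i] = ref(i, 2);
  }
  tree.x = rx.data(); tree.y = ry.data(); tree.z = rz.data();
  tree.perm.resize(nr);
  for (int i = 0; i < nr; ++i) tree.perm[i] = i;
  tree.axis.assign(nr, 0);
  tree.build(0, nr);

  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    int besti = nr;
    tree.search(0, nr, query(q, 0), query(q, 1), query(q, 2), best, besti);
    idx[q] = besti + 1;  // 1-based for R
    dist[q] = std::sqrt(best);
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}
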