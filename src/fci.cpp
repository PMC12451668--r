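// Determinant-based full-CI kernels: sector Hamiltonian assembly by the
// Slater-Condon rules and <S^2> evaluation.  Determinants are pairs of
// spin-string bitmasks over at most 30 spatial orbitals.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static inline int popcnt(uint32_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcount(x);
#else
  int c = 0; while (x) { x &= x - 1; ++c; } return c;
#endif
}

// parity sign for a p->q excitation within one spin string
static inline double exc_sign(uint32_t mask, int p, int q) {
  int lo = p < q ? p : q, hi = p < q ? q : p;
  uint32_t between = ((1u << hi) - 1u) & ~((1u << (lo + 1)) - 1u);
  return (popcnt(mask & between) % 2) ? -1.0 : 1.0;
}

static inline double below_sign(uint32_t mask, int p) {
  uint32_t below = (1u << p) - 1u;
  return (popcnt(mask & below) % 2) ? -1.0 : 1.0;
}

struct EriView {
  const double *v;
  int M;
  inline double operator()(int p, int q, int r, int s) const {
    return v[((std::size_t)s * M + r) * M * M + (std::size_t)q * M + p];
  }
};

static void occ_virt(uint32_t mask, int M, std::vector<int> &occ,
                     std::vector<int> &vrt) {
  occ.clear(); vrt.clear();
  for (int i = 0; i < M; ++i) {
    if (mask & (1u << i)) occ.push_back(i); else vrt.push_back(i);
  }
}

static inline int64_t det_key(uint32_t up, uint32_t dn) {
  return ((int64_t)up << 31) | (int64_t)dn;
}

// Emit H matrix elements; collector is a callable (i, j, val)
template <class F>
static void build_hamiltonian(const IntegerVector &ups,
                              const IntegerVector &downs,
                              const NumericMatrix &h,
                              const NumericVector &eri, int M, F &&emit) {
  int n = ups.size();
  EriView V{REAL(eri), M};
  std::unordered_map<int64_t, int> index;
  index.reserve(n * 2);
  for (int I = 0; I < n; ++I) {
    index[det_key((uint32_t)ups[I], (uint32_t)downs[I])] = I;
  }
  std::vector<int> ou, vu, od, vd;
  for (int I = 0; I < n; ++I) {
    uint32_t up = (uint32_t)ups[I], dn = (uint32_t)downs[I];
    occ_virt(up, M, ou, vu);
    occ_virt(dn, M, od, vd);

    // diagonal
    double e = 0.0;
    for (int p : ou) e += h(p, p);
    for (int p : od) e += h(p, p);
    for (size_t a = 0; a < ou.size(); ++a)
      for (size_t b = a + 1; b < ou.size(); ++b)
        e += V(ou[a], ou[a], ou[b], ou[b]) - V(ou[a], ou[b], ou[b], ou[a]);
    for (size_t a = 0; a < od.size(); ++a)
      for (size_t b = a + 1; b < od.size(); ++b)
        e += V(od[a], od[a], od[b], od[b]) - V(od[a], od[b], od[b], od[a]);
    for (int p : ou) for (int q : od) e += V(p, p, q, q);
    emit(I, I, e);

    // single excitations, up spin
    for (int i : ou) for (int a : vu) {
      uint32_t up2 = (up & ~(1u << i)) | (1u << a);
      auto it = index.find(det_key(up2, dn));
      if (it == index.end()) continue;
      double val = h(i, a);
      for (int j : ou) if (j != i) val += V(i, a, j, j) - V(i, j, j, a);
      for (int j : od) val += V(i, a, j, j);
      emit(I, it->second, exc_sign(up, i, a) * val);
    }
    // single excitations, down spin
    for (int i : od) for (int a : vd) {
      uint32_t dn2 = (dn & ~(1u << i)) | (1u << a);
      auto it = index.find(det_key(up, dn2));
      if (it == index.end()) continue;
      double val = h(i, a);
      for (int j : od) if (j != i) val += V(i, a, j, j) - V(i, j, j, a);
      for (int j : ou) val += V(i, a, j, j);
      emit(I, it->second, exc_sign(dn, i, a) * val);
    }
    // same-spin doubles, up
    for (size_t i1 = 0; i1 < ou.size(); ++i1)
      for (size_t i2 = i1 + 1; i2 < ou.size(); ++i2)
        for (size_t a1 = 0; a1 < vu.size(); ++a1)
          for (size_t a2 = a1 + 1; a2 < vu.size(); ++a2) {
            int i = ou[i1], j = ou[i2], a = vu[a1], b = vu[a2];
            uint32_t up2 = (up & ~(1u << i) & ~(1u << j)) |
                           (1u << a) | (1u << b);
            auto it = index.find(det_key(up2, dn));
            if (it == index.end()) continue;
            double s = exc_sign(up, i, a);
            uint32_t m1 = (up & ~(1u << i)) | (1u << a);
            s *= exc_sign(m1, j, b);
            emit(I, it->second, s * (V(i, a, j, b) - V(i, b, j, a)));
          }
    // same-spin doubles, down
    for (size_t i1 = 0; i1 < od.size(); ++i1)
      for (size_t i2 = i1 + 1; i2 < od.size(); ++i2)
        for (size_t a1 = 0; a1 < vd.size(); ++a1)
          for (size_t a2 = a1 + 1; a2 < vd.size(); ++a2) {
            int i = od[i1], j = od[i2], a = vd[a1], b = vd[a2];
            uint32_t dn2 = (dn & ~(1u << i) & ~(1u << j)) |
                           (1u << a) | (1u << b);
            auto it = index.find(det_key(up, dn2));
            if (it == index.end()) continue;
            double s = exc_sign(dn, i, a);
            uint32_t m1 = (dn & ~(1u << i)) | (1u << a);
            s *= exc_sign(m1, j, b);
            emit(I, it->second, s * (V(i, a, j, b) - V(i, b, j, a)));
          }
    // opposite-spin doubles
    for (int i : ou) for (int a : vu) {
      uint32_t up2 = (up & ~(1u << i)) | (1u << a);
      double su = exc_sign(up, i, a);
      for (int j : od) for (int b : vd) {
        uint32_t dn2 = (dn & ~(1u << j)) | (1u << b);
        auto it = index.find(det_key(up2, dn2));
        if (it == index.end()) continue;
        emit(I, it->second, su * exc_sign(dn, j, b) * V(i, a, j, b));
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix fci_build_dense(IntegerVector ups, IntegerVector downs,
                              NumericMatrix h, NumericVector eri, int M) {
  int n = ups.size();
  NumericMatrix H(n, n);
  build_hamiltonian(ups, downs, h, eri, M,
                    [&](int i, int j, double v) { H(i, j) = v; });
  return H;
}

// [[Rcpp::export]]
List fci_build_triplets(IntegerVector ups, IntegerVector downs,
                        NumericMatrix h, NumericVector eri, int M,
                        double thresh = 1e-14) {
  std::vector<int> ii, jj;
  std::vector<double> xx;
  build_hamiltonian(ups, downs, h, eri, M, [&](int i, int j, double v) {
    if (i == j || std::abs(v) > thresh) {
      ii.push_back(i + 1); jj.push_back(j + 1); xx.push_back(v);
    }
  });
  return List::create(Named("i") = wrap(ii), Named("j") = wrap(jj),
                      Named("x") = wrap(xx));
}

// <u|S^2|v> bilinear matrix over the columns of Vec, using
// S^2 = Sz(Sz+1) + S-S+
// [[Rcpp::export]]
NumericMatrix s2_bilinear(IntegerVector ups, IntegerVector downs, int M,
                          NumericMatrix Vec) {
  int n = ups.size(), k = Vec.ncol();
  std::unordered_map<int64_t, int> index;
  index.reserve(n * 2);
  for (int I = 0; I < n; ++I) {
    index[det_key((uint32_t)ups[I], (uint32_t)downs[I])] = I;
  }
  // W = S^2 Vec, accumulated row-wise
  NumericMatrix W(n, k);
  for (int I = 0; I < n; ++I) {
    uint32_t up = (uint32_t)ups[I], dn = (uint32_t)downs[I];
    double sz = 0.5 * (popcnt(up) - popcnt(dn));
    double diagc = sz * (sz + 1.0);
    for (int c = 0; c < k; ++c) W(I, c) += diagc * Vec(I, c);
    // S-S+ : flip i from down to up, then j from up to down
    for (int i = 0; i < M; ++i) {
      if (!(dn & (1u << i)) || (up & (1u << i))) continue;
      double s1 = below_sign(dn, i) * below_sign(up, i);
      uint32_t dn1 = dn & ~(1u << i);
      uint32_t up1 = up | (1u << i);
      for (int j = 0; j < M; ++j) {
        if (!(up1 & (1u << j)) || (dn1 & (1u << j))) continue;
        double s2 = below_sign(up1, j) * below_sign(dn1, j);
        uint32_t up2 = up1 & ~(1u << j);
        uint32_t dn2 = dn1 | (1u << j);
        auto it = index.find(det_key(up2, dn2));
        if (it == index.end()) continue;
        int J = it->second;
        for (int c = 0; c < k; ++c) {
          W(J, c) += s1 * s2 * Vec(I, c);
        }
      }
    }
  }
  NumericMatrix out(k, k);
  for (int a = 0; a < k; ++a) {
    for (int b = 0; b < k; ++b) {
      double acc = 0.0;
      for (int I = 0; I < n; ++I) acc += Vec(I, a) * W(I, b);
      out(a, b) = acc;
    }
  }
  return out;
}
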