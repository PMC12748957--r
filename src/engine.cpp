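// Hot-path primitives of the batched statevector engine.
//
// A batched state is a (rows x 2^n) complex matrix, one statevector per row.
// Gates touch a fixed set of column pairs/quads; their 2x2 entries may be
// shared across rows (scalar) or per-row vectors (per-sample parameters,
// e.g. embedding angles). Everything else (column indexing, gate algebra,
// the adjoint sweep) stays in R.

#include <Rcpp.h>
#include <complex>

using namespace Rcpp;

typedef std::complex<double> cplx;

// A gate-matrix entry: scalar or per-row, real or complex.
struct Coef {
  bool per;
  bool is_real;
  const double *pr;
  const cplx *pc;

  explicit Coef(SEXP s) {
    per = Rf_xlength(s) > 1;
    if (TYPEOF(s) == REALSXP) {
      is_real = true;
      pr = REAL(s);
      pc = nullptr;
    } else if (TYPEOF(s) == CPLXSXP) {
      is_real = false;
      pr = nullptr;
      pc = reinterpret_cast<const cplx *>(COMPLEX(s));
    } else {
      stop("gate entry must be numeric or complex");
    }
  }
  inline cplx get(int i) const {
    int k = per ? i : 0;
    return is_real ? cplx(pr[k], 0.0) : pc[k];
  }
};

static inline cplx *state_ptr(ComplexMatrix &A) {
  return reinterpret_cast<cplx *>(COMPLEX(A));
}
static inline const cplx *state_ptr(const ComplexMatrix &A) {
  return reinterpret_cast<const cplx *>(COMPLEX(A));
}

// Apply a 2x2 operator to the column pairs (c0[j], c1[j]) of A (1-based).
// [[Rcpp::export]]
ComplexMatrix cpp_apply_1q(ComplexMatrix A_, IntegerVector c0,
                           IntegerVector c1, SEXP ea, SEXP eb, SEXP ec,
                           SEXP ed, bool inplace = false) {
  ComplexMatrix A = inplace ? A_ : clone(A_);
  const int R = A.nrow();
  cplx *pA = state_ptr(A);
  Coef a(ea), b(eb), c(ec), d(ed);
  for (int j = 0; j < c0.size(); ++j) {
    cplx *col0 = pA + (size_t)(c0[j] - 1) * R;
    cplx *col1 = pA + (size_t)(c1[j] - 1) * R;
    for (int i = 0; i < R; ++i) {
      const cplx x0 = col0[i], x1 = col1[i];
      col0[i] = a.get(i) * x0 + b.get(i) * x1;
      col1[i] = c.get(i) * x0 + d.get(i) * x1;
    }
  }
  return A;
}

// IsingXX-shaped operator: dg on the diagonal, off on the anti-diagonal of
// the two column pairs (g00,g11) and (g01,g10).
// [[Rcpp::export]]
ComplexMatrix cpp_apply_xxpair(ComplexMatrix A_, IntegerVector g00,
                               IntegerVector g01, IntegerVector g10,
                               IntegerVector g11, SEXP edg, SEXP eoff,
                               bool inplace = false) {
  ComplexMatrix A = inplace ? A_ : clone(A_);
  const int R = A.nrow();
  cplx *pA = state_ptr(A);
  Coef dg(edg), off(eoff);
  for (int j = 0; j < g00.size(); ++j) {
    cplx *a00 = pA + (size_t)(g00[j] - 1) * R;
    cplx *a01 = pA + (size_t)(g01[j] - 1) * R;
    cplx *a10 = pA + (size_t)(g10[j] - 1) * R;
    cplx *a11 = pA + (size_t)(g11[j] - 1) * R;
    for (int i = 0; i < R; ++i) {
      const cplx dgi = dg.get(i), offi = off.get(i);
      const cplx x00 = a00[i], x01 = a01[i], x10 = a10[i], x11 = a11[i];
      a00[i] = dgi * x00 + offi * x11;
      a11[i] = offi * x00 + dgi * x11;
      a01[i] = dgi * x01 + offi * x10;
      a10[i] = offi * x01 + dgi * x10;
    }
  }
  return A;
}

// CNOT: swap the target-bit column pairs within the control=1 subspace.
// [[Rcpp::export]]
ComplexMatrix cpp_apply_cnot(ComplexMatrix A_, IntegerVector g10,
                             IntegerVector g11, bool inplace = false) {
  ComplexMatrix A = inplace ? A_ : clone(A_);
  const int R = A.nrow();
  cplx *pA = state_ptr(A);
  for (int j = 0; j < g10.size(); ++j) {
    cplx *a10 = pA + (size_t)(g10[j] - 1) * R;
    cplx *a11 = pA + (size_t)(g11[j] - 1) * R;
    for (int i = 0; i < R; ++i) std::swap(a10[i], a11[i]);
  }
  return A;
}

// Adjoint-sweep inner product on a 1-qubit support:
//   2 Re sum_cols conj(L) * (dU P), per row.
// [[Rcpp::export]]
NumericVector cpp_dot_1q(const ComplexMatrix &L, const ComplexMatrix &P,
                         IntegerVector c0, IntegerVector c1, SEXP ea,
                         SEXP eb, SEXP ec, SEXP ed) {
  const int R = L.nrow();
  NumericVector g(R);
  const cplx *pL = state_ptr(L);
  const cplx *pP = state_ptr(P);
  Coef a(ea), b(eb), c(ec), d(ed);
  for (int j = 0; j < c0.size(); ++j) {
    const cplx *l0 = pL + (size_t)(c0[j] - 1) * R;
    const cplx *l1 = pL + (size_t)(c1[j] - 1) * R;
    const cplx *p0 = pP + (size_t)(c0[j] - 1) * R;
    const cplx *p1 = pP + (size_t)(c1[j] - 1) * R;
    for (int i = 0; i < R; ++i) {
      const cplx t0 = a.get(i) * p0[i] + b.get(i) * p1[i];
      const cplx t1 = c.get(i) * p0[i] + d.get(i) * p1[i];
      g[i] += 2.0 * (std::conj(l0[i]) * t0 + std::conj(l1[i]) * t1).real();
    }
  }
  return g;
}

// Same inner product for the IsingXX sparsity pattern.
// [[Rcpp::export]]
NumericVector cpp_dot_xxpair(const ComplexMatrix &L, const ComplexMatrix &P,
                             IntegerVector g00, IntegerVector g01,
                             IntegerVector g10, IntegerVector g11, SEXP edg,
                             SEXP eoff) {
  const int R = L.nrow();
  NumericVector g(R);
  const cplx *pL = state_ptr(L);
  const cplx *pP = state_ptr(P);
  Coef dg(edg), off(eoff);
  for (int j = 0; j < g00.size(); ++j) {
    const cplx *l00 = pL + (size_t)(g00[j] - 1) * R;
    const cplx *l01 = pL + (size_t)(g01[j] - 1) * R;
    const cplx *l10 = pL + (size_t)(g10[j] - 1) * R;
    const cplx *l11 = pL + (size_t)(g11[j] - 1) * R;
    const cplx *p00 = pP + (size_t)(g00[j] - 1) * R;
    const cplx *p01 = pP + (size_t)(g01[j] - 1) * R;
    const cplx *p10 = pP + (size_t)(g10[j] - 1) * R;
    const cplx *p11 = pP + (size_t)(g11[j] - 1) * R;
    for (int i = 0; i < R; ++i) {
      const cplx dgi = dg.get(i), offi = off.get(i);
      g[i] += 2.0 * (std::conj(l00[i]) * (dgi * p00[i] + offi * p11[i]) +
                     std::conj(l11[i]) * (offi * p00[i] + dgi * p11[i]) +
                     std::conj(l01[i]) * (dgi * p01[i] + offi * p10[i]) +
                     std::conj(l10[i]) * (offi * p01[i] + dgi * p10[i]))
                        .real();
    }
  }
  return g;
}
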