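#include <Rcpp.h>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// The sorter maximizes sum_{i<j} M[i,j] * S[y_i, y_j] over orderings y by
// greedy segment moves. Every move of a contiguous segment to another
// insertion point is a swap of two adjacent blocks X = [i,j), Y = [j,k):
// a forward move of X over Y equals a backward move of Y over X. After the
// swap, nodes in X sit at position + |Y| and nodes in Y at position - |X|.
//
// Matrices are column-major. M must be strictly upper triangular (the R
// wrapper enforces this and zeroes diag(S)); A is S reordered by the current
// ordering, A[q + N*r] = S[y_q, y_r], and At its transpose. Mt is t(M).

static inline double pair_term(const double* M, const double* A, int N,
                               int t1, int q1, int t2, int q2) {
  // contribution of nodes at order-indices t1, t2 placed at candidate
  // positions q1, q2 (q1 != q2)
  if (q1 < q2)
    return M[q1 + (size_t)N * q2] * A[t1 + (size_t)N * t2];
  return M[q2 + (size_t)N * q1] * A[t2 + (size_t)N * t1];
}

// Score change of swapping blocks X = [i,j), Y = [j,k), computed directly.
// Pairs internal to X (or Y) keep their separation but shift position by b
// (resp. -a); for a Toeplitz M those terms vanish and `internal_terms`
// can be false.
static double swap_delta_direct(const double* M, const double* Mt,
                                const double* A, const double* At,
                                int N, int i, int j, int k,
                                bool internal_terms) {
  const int a = j - i, b = k - j;
  double D = 0.0;
  if (internal_terms) {
    for (int q2 = i + 1; q2 < j; ++q2) {
      const double* McN = M + (size_t)N * (q2 + b);
      const double* McO = M + (size_t)N * q2;
      const double* Ac = A + (size_t)N * q2;
      for (int q1 = i; q1 < q2; ++q1)
        D += (McN[q1 + b] - McO[q1]) * Ac[q1];
    }
    for (int r2 = j + 1; r2 < k; ++r2) {
      const double* McN = M + (size_t)N * (r2 - a);
      const double* McO = M + (size_t)N * r2;
      const double* Ac = A + (size_t)N * r2;
      for (int r1 = j; r1 < r2; ++r1)
        D += (McN[r1 - a] - McO[r1]) * Ac[r1];
    }
  }
  // X-Y pairs: old M[q,r]*A[q,r]; new (Y precedes X) M[r-a, q+b]*A[r,q]
  for (int q = i; q < j; ++q) {
    const double* McN = M + (size_t)N * (q + b);
    const double* MtO = Mt + (size_t)N * q;
    const double* Ac = A + (size_t)N * q;   // A[., q]
    const double* AtC = At + (size_t)N * q; // A[q, .]
    for (int r = j; r < k; ++r) {
      D += McN[r - a] * Ac[r];
      D -= MtO[r] * AtC[r];
    }
  }
  // X vs unmoved context
  for (int q = i; q < j; ++q) {
    const double* McN = M + (size_t)N * (q + b);
    const double* McO = M + (size_t)N * q;
    const double* Ac = A + (size_t)N * q;
    for (int t = 0; t < i; ++t) // t < i <= q: M[t, q]
      D += (McN[t] - McO[t]) * Ac[t];
    const double* MtN = Mt + (size_t)N * (q + b);
    const double* MtO = Mt + (size_t)N * q;
    const double* AtC = At + (size_t)N * q;
    for (int t = k; t < N; ++t) // q+b <= k-1 < t: M[q, t] via Mt
      D += (MtN[t] - MtO[t]) * AtC[t];
  }
  // Y vs unmoved context
  for (int r = j; r < k; ++r) {
    const double* McN = M + (size_t)N * (r - a);
    const double* McO = M + (size_t)N * r;
    const double* Ac = A + (size_t)N * r;
    for (int t = 0; t < i; ++t)
      D += (McN[t] - McO[t]) * Ac[t];
    const double* MtN = Mt + (size_t)N * (r - a);
    const double* MtO = Mt + (size_t)N * r;
    const double* AtC = At + (size_t)N * r;
    for (int t = k; t < N; ++t)
      D += (MtN[t] - MtO[t]) * AtC[t];
  }
  return D;
}

// Delta adjustment sliding a fixed-shape swap one step right:
// from candidate (i, i+a, i+a+b) to (i+1, i+1+a, i+1+a+b). Only three nodes
// change candidate position: y[i] (i+b -> i), y[j] (i -> k), y[k] (k -> i+b).
static double swap_step_adjust(const double* M, const double* Mt,
                               const double* A, const double* At,
                               int N, int i, int a, int b) {
  const int j = i + a, k = j + b;
  const int tz[3] = { i, j, k };
  const int qo[3] = { i + b, i, k };
  const int qn[3] = { i, k, i + b };
  double adj = 0.0;
  for (int z = 0; z < 3; ++z) {
    const int t0 = tz[z], q1 = qo[z], q2 = qn[z];
    const double* Ac = A + (size_t)N * t0;   // A[t, t0]
    const double* AtC = At + (size_t)N * t0; // A[t0, t]
    const double* M1 = M + (size_t)N * q1;   // M[pc, q1], pc < q1
    const double* Mt1 = Mt + (size_t)N * q1; // M[q1, pc], q1 < pc
    const double* M2 = M + (size_t)N * q2;
    const double* Mt2 = Mt + (size_t)N * q2;
    // other nodes keep the same candidate position in both shapes:
    // t < i: pc = t; i < t < j: pc = t + b; j < t < k: pc = t - a; t > k: pc = t
    const int tlo[4] = { 0, i + 1, j + 1, k + 1 };
    const int thi[4] = { i, j, k, N };
    const int off[4] = { 0, b, -a, 0 };
    for (int r = 0; r < 4; ++r) {
      for (int t = tlo[r]; t < thi[r]; ++t) {
        const int pc = t + off[r];
        const double sn = (q2 < pc) ? Mt2[pc] * AtC[t] : M2[pc] * Ac[t];
        const double so = (q1 < pc) ? Mt1[pc] * AtC[t] : M1[pc] * Ac[t];
        adj += sn - so;
      }
    }
  }
  // pairs among the three repositioned nodes
  adj += pair_term(M, A, N, tz[0], qn[0], tz[1], qn[1])
       + pair_term(M, A, N, tz[0], qn[0], tz[2], qn[2])
       + pair_term(M, A, N, tz[1], qn[1], tz[2], qn[2]);
  adj -= pair_term(M, A, N, tz[0], qo[0], tz[1], qo[1])
       + pair_term(M, A, N, tz[0], qo[0], tz[2], qo[2])
       + pair_term(M, A, N, tz[1], qo[1], tz[2], qo[2]);
  return adj;
}

// Delta of swapping X = [i,j), Y = [j,k) with the moved segment reversed:
// rev_x reverses X (a forward move of X inserted backwards), otherwise Y is
// reversed (a backward move of Y inserted backwards). Computed directly.
static double swap_delta_rev(const double* M, const double* Mt,
                             const double* A, const double* At,
                             int N, int i, int j, int k, bool rev_x) {
  const int a = j - i, b = k - j;
  double D = 0.0;
  if (rev_x) {
    const int cx = i + j - 1 + b; // X-node q -> position cx - q
    for (int q = i; q < j; ++q) {
      const int p = cx - q;
      const double* McN = M + (size_t)N * p;
      const double* MtN = Mt + (size_t)N * p;
      const double* MtO = Mt + (size_t)N * q;
      const double* McO = M + (size_t)N * q;
      const double* Ac = A + (size_t)N * q;
      const double* AtC = At + (size_t)N * q;
      for (int r = j; r < k; ++r)           // X-Y
        D += McN[r - a] * Ac[r] - MtO[r] * AtC[r];
      for (int t = 0; t < i; ++t)           // X-C left
        D += McN[t] * Ac[t] - McO[t] * Ac[t];
      for (int t = k; t < N; ++t)           // X-C right
        D += MtN[t] * AtC[t] - MtO[t] * AtC[t];
    }
    for (int q2 = i + 1; q2 < j; ++q2) {    // X internal: orientation flips
      const double* McO = M + (size_t)N * q2;
      const double* Ac = A + (size_t)N * q2;   // A[., q2]
      const double* AtC = At + (size_t)N * q2; // A[q2, .]
      for (int q1 = i; q1 < q2; ++q1)
        D += M[(cx - q2) + (size_t)N * (cx - q1)] * AtC[q1] -
             McO[q1] * Ac[q1];
    }
    for (int r2 = j + 1; r2 < k; ++r2) {    // Y internal: shift by -a
      const double* McN = M + (size_t)N * (r2 - a);
      const double* McO = M + (size_t)N * r2;
      const double* Ac = A + (size_t)N * r2;
      for (int r1 = j; r1 < r2; ++r1)
        D += (McN[r1 - a] - McO[r1]) * Ac[r1];
    }
  } else {
    const int cy = i + k - 1; // Y-node r -> position cy - r
    for (int r = j; r < k; ++r) {
      const int p = cy - r;
      const double* McN = M + (size_t)N * p;
      const double* MtN = Mt + (size_t)N * p;
      const double* McO = M + (size_t)N * r;
      const double* MtO = Mt + (size_t)N * r;
      const double* Ac = A + (size_t)N * r;
      const double* AtC = At + (size_t)N * r;
      for (int q = i; q < j; ++q)           // X-Y: M[p, q+b] * A[r, q]
        D += M[p + (size_t)N * (q + b)] * (A + (size_t)N * q)[r];
      for (int t = 0; t < i; ++t)           // Y-C left
        D += McN[t] * Ac[t] - McO[t] * Ac[t];
      for (int t = k; t < N; ++t)           // Y-C right
        D += MtN[t] * AtC[t] - MtO[t] * AtC[t];
    }
    for (int q = i; q < j; ++q) {           // old X-Y terms
      const double* MtO = Mt + (size_t)N * q;
      const double* AtC = At + (size_t)N * q;
      for (int r = j; r < k; ++r)
        D -= MtO[r] * AtC[r];
    }
    for (int r2 = j + 1; r2 < k; ++r2) {    // Y internal: orientation flips
      const double* McO = M + (size_t)N * r2;
      const double* Ac = A + (size_t)N * r2;
      const double* AtC = At + (size_t)N * r2;
      for (int r1 = j; r1 < r2; ++r1)
        D += M[(cy - r2) + (size_t)N * (cy - r1)] * AtC[r1] -
             McO[r1] * Ac[r1];
    }
    for (int q2 = i + 1; q2 < j; ++q2) {    // X internal: shift by +b
      const double* McN = M + (size_t)N * (q2 + b);
      const double* McO = M + (size_t)N * q2;
      const double* Ac = A + (size_t)N * q2;
      for (int q1 = i; q1 < q2; ++q1)
        D += (McN[q1 + b] - McO[q1]) * Ac[q1];
    }
  }
  // X-C for rev_y / Y-C for rev_x keep the plain-swap position shifts
  if (rev_x) {
    for (int r = j; r < k; ++r) {
      const double* McN = M + (size_t)N * (r - a);
      const double* McO = M + (size_t)N * r;
      const double* Ac = A + (size_t)N * r;
      for (int t = 0; t < i; ++t)
        D += (McN[t] - McO[t]) * Ac[t];
      const double* MtN = Mt + (size_t)N * (r - a);
      const double* MtO = Mt + (size_t)N * r;
      const double* AtC = At + (size_t)N * r;
      for (int t = k; t < N; ++t)
        D += (MtN[t] - MtO[t]) * AtC[t];
    }
  } else {
    for (int q = i; q < j; ++q) {
      const double* McN = M + (size_t)N * (q + b);
      const double* McO = M + (size_t)N * q;
      const double* Ac = A + (size_t)N * q;
      for (int t = 0; t < i; ++t)
        D += (McN[t] - McO[t]) * Ac[t];
      const double* MtN = Mt + (size_t)N * (q + b);
      const double* MtO = Mt + (size_t)N * q;
      const double* AtC = At + (size_t)N * q;
      for (int t = k; t < N; ++t)
        D += (MtN[t] - MtO[t]) * AtC[t];
    }
  }
  return D;
}

struct Move { int i, j, k, variant; double delta; bool found; };

// Best segment move of length L within movable positions [lo, hi).
// Pass 0 enumerates forward moves (X of length L over any block), pass 1
// backward moves (any block over Y of length L); a == b tested once.
static bool is_toeplitz_upper(const double* M, int N) {
  for (int c = 1; c < N - 1; ++c)
    for (int r = 0; r < c; ++r) {
      const double d = M[r + (size_t)N * c] - M[(r + 1) + (size_t)N * (c + 1)];
      if (d > 1e-12 || d < -1e-12) return false;
    }
  return true;
}

static Move sweep_len(const double* M, const double* Mt,
                      const double* A, const double* At,
                      int N, int lo, int hi, int L, double tol,
                      bool internal_terms, bool reversals) {
  Move best; best.found = false; best.delta = tol;
  best.i = best.j = best.k = -1; best.variant = 0;
  const int span_lim = hi - lo;
  for (int pass = 0; pass < 2; ++pass) {
    for (int other = 1; other + L <= span_lim; ++other) {
      if (pass == 1 && other == L) continue;
      const int a = (pass == 0) ? L : other;
      const int b = (pass == 0) ? other : L;
      const int span = a + b;
      double D = swap_delta_direct(M, Mt, A, At, N, lo, lo + a, lo + span,
                                   internal_terms);
      if (D > best.delta) {
        best.delta = D; best.i = lo; best.j = lo + a; best.k = lo + span;
        best.variant = 0; best.found = true;
      }
      int since_refresh = 0;
      for (int i = lo + 1; i + span <= hi; ++i) {
        if (++since_refresh == 128) {
          D = swap_delta_direct(M, Mt, A, At, N, i, i + a, i + span,
                                internal_terms);
          since_refresh = 0;
        } else {
          D += swap_step_adjust(M, Mt, A, At, N, i - 1, a, b);
        }
        if (D > best.delta) {
          best.delta = D; best.i = i; best.j = i + a; best.k = i + span;
          best.variant = 0; best.found = true;
        }
      }
      if (reversals) {
        // reversed insertion of the length-L segment (X in pass 0, Y in
        // pass 1; both when the shape is symmetric), evaluated directly
        for (int i = lo; i + span <= hi; ++i) {
          if (pass == 0 || (pass == 1 && a == b)) {
            const double Dr = swap_delta_rev(M, Mt, A, At, N,
                                             i, i + a, i + span, true);
            if (Dr > best.delta) {
              best.delta = Dr; best.i = i; best.j = i + a;
              best.k = i + span; best.variant = 1; best.found = true;
            }
          }
          if (pass == 1 || (pass == 0 && a == b)) {
            const double Dr = swap_delta_rev(M, Mt, A, At, N,
                                             i, i + a, i + span, false);
            if (Dr > best.delta) {
              best.delta = Dr; best.i = i; best.j = i + a;
              best.k = i + span; best.variant = 2; best.found = true;
            }
          }
        }
      }
    }
  }
  return best;
}

static void rebuild_A(const double* S, const std::vector<int>& y,
                      std::vector<double>& A, std::vector<double>& At, int N) {
  for (int r = 0; r < N; ++r) {
    const double* Scol = S + (size_t)N * y[r];
    double* Acol = A.data() + (size_t)N * r;
    for (int q = 0; q < N; ++q) Acol[q] = Scol[y[q]];
  }
  for (int r = 0; r < N; ++r)
    for (int q = 0; q < N; ++q)
      At[q + (size_t)N * r] = A[r + (size_t)N * q];
}

static double full_score(const double* M, const std::vector<double>& A, int N) {
  double s = 0.0;
  for (int c = 1; c < N; ++c) {
    const double* Mc = M + (size_t)N * c;
    const double* Ac = A.data() + (size_t)N * c;
    for (int r = 0; r < c; ++r) s += Mc[r] * Ac[r];
  }
  return s;
}

// [[Rcpp::export]]
double cpp_score_ordering(NumericMatrix S, NumericMatrix M, IntegerVector perm0) {
  const int N = S.nrow();
  if (S.ncol() != N || M.nrow() != N || M.ncol() != N || perm0.size() != N)
    stop("dimension mismatch between S, M and the permutation");
  double s = 0.0;
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i)
      s += M(i, j) * S(perm0[i], perm0[j]);
  return s;
}

// Exposed for testing the direct block-swap delta against naive rescoring.
// [[Rcpp::export]]
double cpp_swap_delta(NumericMatrix S, NumericMatrix M, IntegerVector order0,
                      int i, int j, int k) {
  const int N = S.nrow();
  std::vector<int> y(order0.begin(), order0.end());
  std::vector<double> A((size_t)N * N), At((size_t)N * N), Mt((size_t)N * N);
  for (int c = 0; c < N; ++c)
    for (int r = 0; r < N; ++r)
      Mt[c + (size_t)N * r] = M(r, c);
  rebuild_A(REAL(S), y, A, At, N);
  return swap_delta_direct(REAL(M), Mt.data(), A.data(), At.data(), N, i, j, k,
                           !is_toeplitz_upper(REAL(M), N));
}

// Exposed for testing the reversed-segment delta against naive rescoring.
// [[Rcpp::export]]
double cpp_swap_delta_rev(NumericMatrix S, NumericMatrix M,
                          IntegerVector order0, int i, int j, int k,
                          bool rev_x) {
  const int N = S.nrow();
  std::vector<int> y(order0.begin(), order0.end());
  std::vector<double> A((size_t)N * N), At((size_t)N * N), Mt((size_t)N * N);
  for (int c = 0; c < N; ++c)
    for (int r = 0; r < N; ++r)
      Mt[c + (size_t)N * r] = M(r, c);
  rebuild_A(REAL(S), y, A, At, N);
  return swap_delta_rev(REAL(M), Mt.data(), A.data(), At.data(), N, i, j, k,
                        rev_x);
}

// Exposed for testing the incremental sweep against naive enumeration.
// [[Rcpp::export]]
List cpp_sweep_best(NumericMatrix S, NumericMatrix M, IntegerVector order0,
                    int L, int lo, int hi, double tol, bool reversals) {
  const int N = S.nrow();
  std::vector<int> y(order0.begin(), order0.end());
  std::vector<double> A((size_t)N * N), At((size_t)N * N), Mt((size_t)N * N);
  for (int c = 0; c < N; ++c)
    for (int r = 0; r < N; ++r)
      Mt[c + (size_t)N * r] = M(r, c);
  rebuild_A(REAL(S), y, A, At, N);
  Move mv = sweep_len(REAL(M), Mt.data(), A.data(), At.data(), N, lo, hi, L,
                      tol, !is_toeplitz_upper(REAL(M), N), reversals);
  return List::create(_["found"] = mv.found, _["i"] = mv.i, _["j"] = mv.j,
                      _["k"] = mv.k, _["variant"] = mv.variant,
                      _["delta"] = mv.delta);
}

// [[Rcpp::export]]
List cpp_optimize_ordering(NumericMatrix S, NumericMatrix M, IntegerVector init0,
                           int n_iter, int lo, int hi, int max_len, double tol,
                           bool reversals) {
  const int N = S.nrow();
  if (S.ncol() != N || M.nrow() != N || M.ncol() != N)
    stop("S and M must be square matrices of the same size");
  if ((int)init0.size() != N) stop("init permutation has wrong length");
  if (lo < 0 || hi > N || hi - lo < 0) stop("invalid movable range");

  std::vector<int> y(init0.begin(), init0.end());
  std::vector<double> A((size_t)N * N), At((size_t)N * N), Mt((size_t)N * N);
  const double* Mp = REAL(M);
  for (int c = 0; c < N; ++c)
    for (int r = 0; r < N; ++r)
      Mt[c + (size_t)N * r] = Mp[r + (size_t)N * c];
  rebuild_A(REAL(S), y, A, At, N);

  const bool internal_terms = !is_toeplitz_upper(Mp, N);
  double score = full_score(Mp, A, N);
  std::vector<double> trace;
  trace.push_back(score);
  int applied = 0;
  bool converged = false;
  const int movable = hi - lo;
  const int Lmax = std::max(1, std::min(max_len, movable - 1));

  if (movable >= 2) {
    int L = 1;
    while (applied < n_iter) {
      Move mv = sweep_len(Mp, Mt.data(), A.data(), At.data(), N, lo, hi, L,
                          tol, internal_terms, reversals);
      bool ok = false;
      if (mv.found) {
        // apply swap of [i,j) and [j,k), reversing the moved segment for
        // variant 1 (X) or 2 (Y)
        std::vector<int> ynew(y);
        std::copy(y.begin() + mv.j, y.begin() + mv.k, ynew.begin() + mv.i);
        if (mv.variant == 2)
          std::reverse(ynew.begin() + mv.i,
                       ynew.begin() + mv.i + (mv.k - mv.j));
        std::copy(y.begin() + mv.i, y.begin() + mv.j,
                  ynew.begin() + mv.i + (mv.k - mv.j));
        if (mv.variant == 1)
          std::reverse(ynew.begin() + mv.i + (mv.k - mv.j),
                       ynew.begin() + mv.k);
        std::vector<double> A2(A), At2(At);
        rebuild_A(REAL(S), ynew, A2, At2, N);
        const double snew = full_score(Mp, A2, N);
        if (snew > score) { // guard against accumulated float drift
          y.swap(ynew); A.swap(A2); At.swap(At2);
          score = snew;
          trace.push_back(score);
          ++applied;
          L = 1;
          ok = true;
        }
      }
      if (!ok) {
        if (++L > Lmax) { converged = true; break; }
      }
      if (applied % 64 == 0) Rcpp::checkUserInterrupt();
    }
  } else {
    converged = true;
  }

  return List::create(_["order"] = IntegerVector(y.begin(), y.end()),
                      _["score"] = score,
                      _["score_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["n_moves"] = applied,
                      _["converged"] = converged);
}
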