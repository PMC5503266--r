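#ifndef MORANFIX_RAT_H
#define MORANFIX_RAT_H

#include <gmpxx.h>
#include <string>
#include <vector>
#include <stdexcept>

// Exact rational helpers shared across the package's compiled core.
// Rationals cross the R boundary as canonical "p/q" strings (mpq_class
// canonical form: reduced, positive denominator, "p" when q == 1).

inline mpq_class rat_parse(const std::string &s) {
  mpq_class q;
  if (q.set_str(s, 10) != 0)
    throw std::invalid_argument("not a rational: '" + s + "'");
  if (q.get_den() == 0)
    throw std::invalid_argument("zero denominator: '" + s + "'");
  q.canonicalize();
  return q;
}

inline std::string rat_str(const mpq_class &q) { return q.get_str(); }

// total bit size of a rational, used for pivot selection
inline size_t rat_bits(const mpq_class &q) {
  return mpz_sizeinbase(q.get_num_mpz_t(), 2) +
         mpz_sizeinbase(q.get_den_mpz_t(), 2);
}

typedef std::vector<mpq_class> Poly; // coefficients, ascending degree

inline void poly_trim(Poly &p) {
  while (!p.empty() && p.back() == 0) p.pop_back();
}

inline int poly_deg(const Poly &p) { return (int)p.size() - 1; } // -1 for zero

inline Poly poly_add(const Poly &a, const Poly &b) {
  Poly r(std::max(a.size(), b.size()), mpq_class(0));
  for (size_t i = 0; i < a.size(); ++i) r[i] += a[i];
  for (size_t i = 0; i < b.size(); ++i) r[i] += b[i];
  poly_trim(r);
  return r;
}

inline Poly poly_sub(const Poly &a, const Poly &b) {
  Poly r(std::max(a.size(), b.size()), mpq_class(0));
  for (size_t i = 0; i < a.size(); ++i) r[i] += a[i];
  for (size_t i = 0; i < b.size(); ++i) r[i] -= b[i];
  poly_trim(r);
  return r;
}

inline Poly poly_mul(const Poly &a, const Poly &b) {
  if (a.empty() || b.empty()) return Poly();
  Poly r(a.size() + b.size() - 1, mpq_class(0));
  for (size_t i = 0; i < a.size(); ++i)
    for (size_t j = 0; j < b.size(); ++j)
      r[i + j] += a[i] * b[j];
  poly_trim(r);
  return r;
}

inline Poly poly_scale(const Poly &a, const mpq_class &c) {
  Poly r(a);
  for (auto &x : r) x *= c;
  poly_trim(r);
  return r;
}

// field division: a = q*b + rem, deg(rem) < deg(b)
inline void poly_divrem(const Poly &a, const Poly &b, Poly &q, Poly &rem) {
  if (b.empty()) throw std::invalid_argument("polynomial division by zero");
  rem = a;
  poly_trim(rem);
  q.assign(rem.size() > b.size() ? rem.size() - b.size() + 1 : 1, mpq_class(0));
  const mpq_class &lead = b.back();
  while ((int)rem.size() >= (int)b.size() && !rem.empty()) {
    size_t shift = rem.size() - b.size();
    mpq_class c = rem.back() / lead;
    q[shift] = c;
    for (size_t i = 0; i < b.size(); ++i) rem[shift + i] -= c * b[i];
    // leading term cancels exactly
    rem.pop_back();
    poly_trim(rem);
  }
  poly_trim(q);
}

inline mpq_class poly_eval(const Poly &p, const mpq_class &x) {
  mpq_class v(0);
  for (size_t i = p.size(); i-- > 0;) v = v * x + p[i];
  return v;
}

inline Poly poly_deriv(const Poly &p) {
  Poly r;
  for (size_t i = 1; i < p.size(); ++i) r.push_back(p[i] * mpq_class((long)i));
  poly_trim(r);
  return r;
}

// scale by a positive rational to a primitive integer polynomial (sign kept)
inline void poly_primitive(Poly &p) {
  poly_trim(p);
  if (p.empty()) return;
  mpz_class den_lcm(1), num_gcd(0);
  for (const auto &c : p)
    mpz_lcm(den_lcm.get_mpz_t(), den_lcm.get_mpz_t(), c.get_den_mpz_t());
  for (const auto &c : p) {
    mpz_class n = c.get_num() * (den_lcm / c.get_den());
    mpz_gcd(num_gcd.get_mpz_t(), num_gcd.get_mpz_t(), n.get_mpz_t());
  }
  if (num_gcd == 0) return;
  mpq_class f(den_lcm, num_gcd); // positive
  f.canonicalize();
  for (auto &c : p) c *= f;
}

// monic gcd over Q
inline Poly poly_gcd(Poly a, Poly b) {
  poly_trim(a); poly_trim(b);
  while (!b.empty()) {
    Poly q, r;
    poly_divrem(a, b, q, r);
    poly_primitive(r); // keep coefficients small
    a = b;
    b = r;
  }
  if (!a.empty()) {
    mpq_class lead = a.back();
    for (auto &c : a) c /= lead;
  }
  return a;
}

inline Poly poly_exact_div(const Poly &a, const Poly &b) {
  Poly q, r;
  poly_divrem(a, b, q, r);
  if (!r.empty()) throw std::runtime_error("polynomial division not exact");
  return q;
}

inline int sgn_q(const mpq_class &q) { return sgn(q); }

// ---------------------------------------------------------------------------
// Exact rational dense solve  M X = B  (X overwrites B).
// Pivot = nonzero entry of smallest bit size, to limit coefficient growth.
// Returns false when the matrix is singular.
// ---------------------------------------------------------------------------

typedef std::vector<std::vector<mpq_class>> Mat;

inline bool solve_dense(Mat &M, Mat &B) {
  int n = (int)M.size();
  int m = B.empty() ? 0 : (int)B[0].size();
  for (int col = 0; col < n; ++col) {
    int piv = -1;
    size_t best = 0;
    for (int r = col; r < n; ++r) {
      if (M[r][col] != 0) {
        size_t b = rat_bits(M[r][col]);
        if (piv < 0 || b < best) { piv = r; best = b; }
      }
    }
    if (piv < 0) return false;
    std::swap(M[piv], M[col]);
    std::swap(B[piv], B[col]);
    for (int r = col + 1; r < n; ++r) {
      if (M[r][col] == 0) continue;
      mpq_class f = M[r][col] / M[col][col];
      M[r][col] = 0;
      for (int c = col + 1; c < n; ++c)
        if (M[col][c] != 0) M[r][c] -= f * M[col][c];
      for (int c = 0; c < m; ++c)
        if (B[col][c] != 0) B[r][c] -= f * B[col][c];
    }
  }
  for (int col = n - 1; col >= 0; --col) {
    for (int c = 0; c < m; ++c) {
      mpq_class v = B[col][c];
      for (int k = col + 1; k < n; ++k)
        if (M[col][k] != 0 && B[k][c] != 0) v -= M[col][k] * B[k][c];
      B[col][c] = v / M[col][col];
    }
  }
  return true;
}

#endif
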