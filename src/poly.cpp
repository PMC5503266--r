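#include <Rcpp.h>
#include "rat.h"

using namespace Rcpp;

static Poly parse_poly(const CharacterVector &coef) {
  Poly p;
  for (int i = 0; i < coef.size(); ++i)
    p.push_back(rat_parse(as<std::string>(coef[i])));
  poly_trim(p);
  return p;
}

static CharacterVector poly_out(const Poly &p, int min_len = 1) {
  int n = std::max((int)p.size(), min_len);
  CharacterVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = i < (int)p.size() ? rat_str(p[i]) : "0";
  return out;
}

// ---------------------------------------------------------------------------
// Well-mixed closed forms.
// ---------------------------------------------------------------------------

static mpq_class phi0_q(const mpq_class &r, int N) {
  if (r <= 0) throw std::invalid_argument("fitness r must be positive");
  if (r == 1) return mpq_class(1, N);
  // r^{N-1}(r-1) / (r^N - 1)
  mpq_class rn1(1);
  for (int i = 0; i < N - 1; ++i) rn1 *= r;
  mpq_class num = rn1 * (r - 1);
  mpq_class den = rn1 * r - 1;
  mpq_class v = num / den;
  v.canonicalize();
  return v;
}

// [[Rcpp::export]]
std::string cpp_phi0(std::string r_str, int N) {
  return rat_str(phi0_q(rat_parse(r_str), N));
}

// [[Rcpp::export]]
std::string cpp_phi2(std::string r_str, int N) {
  mpq_class r = rat_parse(r_str);
  return rat_str(phi0_q(r * r, N));
}

// ---------------------------------------------------------------------------
// Rational-function reconstruction from exact evaluations.
//
// With Phi(r) = (sum_{i<=d} a_i r^i) / (sum_{i<=d} b_i r^i), a_d = b_d = 1,
// each evaluation pair (t, phi) yields
//   sum_{i<d} a_i t^i - phi * sum_{i<d} b_i t^i = (phi - 1) t^d,
// a linear system in the 2d unknowns (a_0..a_{d-1}, b_0..b_{d-1}).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_reconstruct(CharacterVector r_vals, CharacterVector phi_vals, int d) {
  int n = 2 * d;
  if (r_vals.size() < n) stop("need at least %d evaluation pairs for degree %d", n, d);
  Mat M(n, std::vector<mpq_class>(n));
  Mat B(n, std::vector<mpq_class>(1));
  for (int row = 0; row < n; ++row) {
    mpq_class t = rat_parse(as<std::string>(r_vals[row]));
    mpq_class phi = rat_parse(as<std::string>(phi_vals[row]));
    mpq_class tp(1);
    for (int i = 0; i < d; ++i) {
      M[row][i] = tp;
      M[row][d + i] = -phi * tp;
      tp *= t;
    }
    B[row][0] = (phi - 1) * tp; // tp == t^d here
  }
  bool ok = solve_dense(M, B);
  if (!ok) {
    // Singular system: the true degree d* is below d and degree-d
    // representations form an affine family of dimension d - d*.  Count the
    // rank defect so the caller can retry once at the right degree.
    int defect = 0;
    Mat M2(n, std::vector<mpq_class>(n));
    for (int row = 0; row < n; ++row) {
      mpq_class t = rat_parse(as<std::string>(r_vals[row]));
      mpq_class phi = rat_parse(as<std::string>(phi_vals[row]));
      mpq_class tp(1);
      for (int i = 0; i < d; ++i) {
        M2[row][i] = tp;
        M2[row][d + i] = -phi * tp;
        tp *= t;
      }
    }
    int prow = 0;
    for (int col = 0; col < n && prow < n; ++col) {
      int piv = -1;
      size_t bits = 0;
      for (int r = prow; r < n; ++r)
        if (M2[r][col] != 0) {
          size_t b = rat_bits(M2[r][col]);
          if (piv < 0 || b < bits) { piv = r; bits = b; }
        }
      if (piv < 0) continue;
      std::swap(M2[piv], M2[prow]);
      for (int r = prow + 1; r < n; ++r) {
        if (M2[r][col] == 0) continue;
        mpq_class f = M2[r][col] / M2[prow][col];
        for (int c = col; c < n; ++c)
          if (M2[prow][c] != 0) M2[r][c] -= f * M2[prow][c];
      }
      ++prow;
    }
    defect = n - prow; // nullity of the 2d x 2d system = d - d*
    return List::create(_["ok"] = false, _["defect"] = defect);
  }
  Poly num(d + 1), den(d + 1);
  for (int i = 0; i < d; ++i) { num[i] = B[i][0]; den[i] = B[d + i][0]; }
  num[d] = 1; den[d] = 1;
  return List::create(_["ok"] = true,
                      _["num"] = poly_out(num, d + 1),
                      _["den"] = poly_out(den, d + 1));
}

// [[Rcpp::export]]
std::string cpp_rf_eval(CharacterVector num, CharacterVector den,
                        std::string r_str) {
  Poly pn = parse_poly(num), pd = parse_poly(den);
  mpq_class r = rat_parse(r_str);
  mpq_class dv = poly_eval(pd, r);
  if (dv == 0) stop("denominator vanishes at r = %s", r_str.c_str());
  mpq_class v = poly_eval(pn, r) / dv;
  v.canonicalize();
  return rat_str(v);
}

// reduce a rational function by the polynomial gcd; normalize so the
// denominator's leading coefficient is positive and both parts are
// primitive integer polynomials
// [[Rcpp::export]]
List cpp_rf_reduce(CharacterVector num, CharacterVector den) {
  Poly pn = parse_poly(num), pd = parse_poly(den);
  if (pd.empty()) stop("zero denominator polynomial");
  if (!pn.empty()) {
    Poly g = poly_gcd(pn, pd);
    if (poly_deg(g) > 0) {
      pn = poly_exact_div(pn, g);
      pd = poly_exact_div(pd, g);
    }
  }
  poly_primitive(pn);
  poly_primitive(pd);
  if (sgn_q(pd.back()) < 0) {
    for (auto &c : pn) c = -c;
    for (auto &c : pd) c = -c;
  }
  return List::create(_["num"] = poly_out(pn), _["den"] = poly_out(pd));
}

// Delta(r) = Phi(r) - Phi0(r) as a reduced quotient:
//   num' = num*(r^N - 1) - (r^N - r^{N-1})*den,  den' = den*(r^N - 1)
// [[Rcpp::export]]
List cpp_delta_rf(CharacterVector num, CharacterVector den, int N) {
  Poly pn = parse_poly(num), pd = parse_poly(den);
  Poly rn(N + 1, mpq_class(0));          // r^N - 1
  rn[0] = -1; rn[N] = 1;
  Poly phi0num(N + 1, mpq_class(0));     // r^N - r^{N-1}
  phi0num[N] = 1; phi0num[N - 1] = -1;
  Poly dn = poly_sub(poly_mul(pn, rn), poly_mul(phi0num, pd));
  Poly dd = poly_mul(pd, rn);
  return cpp_rf_reduce(poly_out(dn), poly_out(dd));
}

// ---------------------------------------------------------------------------
// Sturm-sequence sign certification on an interval.
// ---------------------------------------------------------------------------

static std::vector<Poly> sturm_chain(Poly p) {
  std::vector<Poly> chain;
  poly_primitive(p);
  chain.push_back(p);
  Poly p1 = poly_deriv(p);
  poly_primitive(p1);
  if (!p1.empty()) chain.push_back(p1);
  while (chain.back().size() > 1) {
    Poly q, r;
    poly_divrem(chain[chain.size() - 2], chain.back(), q, r);
    if (r.empty()) break;
    for (auto &c : r) c = -c;
    poly_primitive(r); // positive scaling: sign pattern preserved
    chain.push_back(r);
  }
  return chain;
}

static int sign_at(const Poly &p, const mpq_class &x) {
  return sgn_q(poly_eval(p, x));
}

static int sign_at_inf(const Poly &p) {
  return p.empty() ? 0 : sgn_q(p.back());
}

static int variations(const std::vector<Poly> &chain, const mpq_class &x,
                      bool at_inf) {
  int v = 0, prev = 0;
  for (const auto &p : chain) {
    int s = at_inf ? sign_at_inf(p) : sign_at(p, x);
    if (s == 0) continue;
    if (prev != 0 && s != prev) ++v;
    prev = s;
  }
  return v;
}

// number of distinct real roots in the open interval (a, b), assuming
// p(a) != 0 and (if finite) p(b) != 0
static int count_roots(const Poly &p, const mpq_class &a, bool b_inf,
                       const mpq_class &b) {
  Poly g = poly_gcd(p, poly_deriv(p));
  Poly sf = poly_deg(g) > 0 ? poly_exact_div(p, g) : p;
  std::vector<Poly> chain = sturm_chain(sf);
  int va = variations(chain, a, false);
  int vb = b_inf ? variations(chain, b, true) : variations(chain, b, false);
  return va - vb;
}

// divide out roots at a given rational point
static Poly deflate_at(Poly p, const mpq_class &x, int *mult = nullptr) {
  if (mult) *mult = 0;
  Poly lin = {-x, mpq_class(1)};
  while (!p.empty() && poly_eval(p, x) == 0) {
    p = poly_exact_div(p, lin);
    if (mult) ++(*mult);
  }
  return p;
}

// Certify the sign of p on the open interval (a, b); b may be +Inf.
// Roots exactly at the endpoints are ignored (divided out first).
// Returns "zero", "always+", "always-", or "mixed".
// [[Rcpp::export]]
std::string cpp_certify_sign(CharacterVector coef, std::string a_str,
                             std::string b_str) {
  Poly p = parse_poly(coef);
  if (p.empty()) return "zero";
  mpq_class a = rat_parse(a_str);
  bool b_inf = (b_str == "Inf");
  mpq_class b = b_inf ? mpq_class(0) : rat_parse(b_str);
  if (!b_inf && b <= a) stop("empty interval");
  // endpoint roots do not lie in the open interval: divide them out, but
  // remember that (x - b)^mb is negative on (a, b) when mb is odd
  int ma = 0, mb = 0;
  p = deflate_at(p, a, &ma);
  if (!b_inf) p = deflate_at(p, b, &mb);
  int flip = (mb % 2 == 1) ? -1 : 1;
  if (p.empty()) return "zero";
  if (p.size() > 1 && count_roots(p, a, b_inf, b) > 0) return "mixed";
  mpq_class sample = b_inf ? mpq_class(a + 1) : mpq_class((a + b) / 2);
  int s = sign_at(p, sample) * flip;
  if (s == 0) return "mixed";
  return s > 0 ? "always+" : "always-";
}

// multiplicity of the root at x (0 if p(x) != 0)
// [[Rcpp::export]]
List cpp_deflate_root(CharacterVector coef, std::string x_str) {
  Poly p = parse_poly(coef);
  int mult = 0;
  p = deflate_at(p, rat_parse(x_str), &mult);
  return List::create(_["coef"] = poly_out(p), _["multiplicity"] = mult);
}

// [[Rcpp::export]]
std::string cpp_poly_eval(CharacterVector coef, std::string x_str) {
  Poly p = parse_poly(coef);
  mpq_class v = poly_eval(p, rat_parse(x_str));
  v.canonicalize();
  return rat_str(v);
}

// ---------------------------------------------------------------------------
// Small exact-rational utilities for the R level.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
std::string cpp_rat_canon(std::string x) { return rat_str(rat_parse(x)); }

// [[Rcpp::export]]
int cpp_rat_cmp(std::string a, std::string b) {
  return cmp(rat_parse(a), rat_parse(b));
}

// [[Rcpp::export]]
double cpp_rat_to_double(std::string a) { return rat_parse(a).get_d(); }

// [[Rcpp::export]]
std::string cpp_rat_arith(std::string a, std::string b, std::string op) {
  mpq_class x = rat_parse(a), y = rat_parse(b), z;
  if (op == "+") z = x + y;
  else if (op == "-") z = x - y;
  else if (op == "*") z = x * y;
  else if (op == "/") {
    if (y == 0) stop("division by zero");
    z = x / y;
  } else stop("unknown op '%s'", op.c_str());
  z.canonicalize();
  return rat_str(z);
}

// exact rational from an IEEE double (doubles are dyadic, so this is exact)
// [[Rcpp::export]]
std::string cpp_rat_from_double(double x) {
  if (!R_FINITE(x)) stop("not finite");
  mpq_class q(x);
  q.canonicalize();
  return rat_str(q);
}
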