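// Exact arithmetic for the closed set of values produced by the
// genealogical-coupling edge factors: signed square roots of nonnegative
// rationals and finite sums of such terms.
//
// A value is stored as sum_s c_s * sqrt(s) with s squarefree.  Squarefree
// radicands are represented as bitmasks over a session-global prime registry
// (all primes entering a radicand come from small Clebsch-Gordan integers,
// so the registry stays tiny).  Coefficients are exact rationals over a
// little-endian base-2^32 big-integer magnitude, so denominators built from
// products over many orbital levels never overflow.

#include <Rcpp.h>
#include <cstdint>
#include <map>
#include <string>
#include <vector>

using namespace Rcpp;

typedef std::vector<uint32_t> Mag; // little-endian magnitude, no leading zeros

static void trim(Mag &a) {
  while (!a.empty() && a.back() == 0u) a.pop_back();
}

static bool mag_is_zero(const Mag &a) { return a.empty(); }

static Mag mag_from_u64(uint64_t v) {
  Mag r;
  while (v) { r.push_back((uint32_t)v); v >>= 32; }
  return r;
}

static int mag_cmp(const Mag &a, const Mag &b) {
  if (a.size() != b.size()) return a.size() < b.size() ? -1 : 1;
  for (size_t i = a.size(); i-- > 0;)
    if (a[i] != b[i]) return a[i] < b[i] ? -1 : 1;
  return 0;
}

static Mag mag_add(const Mag &a, const Mag &b) {
  const size_t n = std::max(a.size(), b.size());
  Mag r;
  r.reserve(n + 1);
  uint64_t carry = 0;
  for (size_t i = 0; i < n; ++i) {
    uint64_t s = carry;
    if (i < a.size()) s += a[i];
    if (i < b.size()) s += b[i];
    r.push_back((uint32_t)s);
    carry = s >> 32;
  }
  if (carry) r.push_back((uint32_t)carry);
  return r;
}

// requires a >= b
static Mag mag_sub(const Mag &a, const Mag &b) {
  Mag r(a.size());
  int64_t borrow = 0;
  for (size_t i = 0; i < a.size(); ++i) {
    int64_t s = (int64_t)a[i] - borrow - (i < b.size() ? (int64_t)b[i] : 0);
    if (s < 0) { s += ((int64_t)1 << 32); borrow = 1; } else borrow = 0;
    r[i] = (uint32_t)s;
  }
  trim(r);
  return r;
}

static Mag mag_mul(const Mag &a, const Mag &b) {
  if (a.empty() || b.empty()) return Mag();
  Mag r(a.size() + b.size(), 0u);
  for (size_t i = 0; i < a.size(); ++i) {
    uint64_t carry = 0;
    for (size_t j = 0; j < b.size(); ++j) {
      unsigned __int128 cur = (unsigned __int128)a[i] * b[j] + r[i + j] + carry;
      r[i + j] = (uint32_t)cur;
      carry = (uint64_t)(cur >> 32);
    }
    size_t k = i + b.size();
    while (carry) {
      unsigned __int128 cur = (unsigned __int128)r[k] + carry;
      r[k] = (uint32_t)cur;
      carry = (uint64_t)(cur >> 32);
      ++k;
    }
  }
  trim(r);
  return r;
}

static double mag_dbl(const Mag &a) {
  double r = 0;
  for (size_t i = a.size(); i-- > 0;) r = r * 4294967296.0 + (double)a[i];
  return r;
}

static size_t mag_bitlen(const Mag &a) {
  if (a.empty()) return 0;
  uint32_t t = a.back();
  size_t n = (a.size() - 1) * 32;
  while (t) { ++n; t >>= 1; }
  return n;
}

static bool mag_getbit(const Mag &a, size_t i) {
  size_t w = i / 32;
  return w < a.size() && ((a[w] >> (i % 32)) & 1u);
}

// r = r*2 + bit
static void shl1_add(Mag &r, bool bit) {
  uint32_t carry = bit ? 1u : 0u;
  for (size_t i = 0; i < r.size(); ++i) {
    uint32_t nc = r[i] >> 31;
    r[i] = (r[i] << 1) | carry;
    carry = nc;
  }
  if (carry) r.push_back(carry);
}

// binary long division; sizes here stay small (a few hundred bits)
static Mag mag_divmod(const Mag &a, const Mag &b, Mag &rem) {
  rem.clear();
  size_t n = mag_bitlen(a);
  Mag q((n + 31) / 32, 0u);
  for (size_t i = n; i-- > 0;) {
    shl1_add(rem, mag_getbit(a, i));
    if (mag_cmp(rem, b) >= 0) {
      rem = mag_sub(rem, b);
      q[i / 32] |= (1u << (i % 32));
    }
  }
  trim(q);
  return q;
}

static uint64_t mag_u64(const Mag &a) {
  uint64_t r = 0;
  for (size_t i = a.size(); i-- > 0;) r = (r << 32) | a[i];
  return r;
}

static Mag mag_gcd(Mag a, Mag b) {
  while (!mag_is_zero(b)) {
    if (a.size() <= 2 && b.size() <= 2) { // fast path for 64-bit operands
      uint64_t x = mag_u64(a), y = mag_u64(b);
      while (y) { uint64_t t = x % y; x = y; y = t; }
      return mag_from_u64(x);
    }
    Mag r;
    mag_divmod(a, b, r);
    a = b;
    b = r;
  }
  return a;
}

static uint32_t mag_divmod_small(Mag &a, uint32_t d) {
  uint64_t rem = 0;
  for (size_t i = a.size(); i-- > 0;) {
    uint64_t cur = (rem << 32) | a[i];
    a[i] = (uint32_t)(cur / d);
    rem = cur % d;
  }
  trim(a);
  return (uint32_t)rem;
}

static std::string mag_dec(Mag a) {
  if (a.empty()) return "0";
  std::string out;
  while (!a.empty()) {
    uint32_t r = mag_divmod_small(a, 1000000000u);
    char buf[16];
    if (a.empty()) snprintf(buf, sizeof buf, "%u", r);
    else snprintf(buf, sizeof buf, "%09u", r);
    out = std::string(buf) + out;
  }
  return out;
}

// ---------------------------------------------------------------------------
// exact rationals: value = sg * n / d, d > 0, gcd(n, d) = 1, sg == 0 iff n == 0

struct Rat {
  int sg;
  Mag n, d;
};

static Rat rat_zero() { return Rat{0, Mag(), mag_from_u64(1)}; }

static Rat rat_make(int sg, Mag n, Mag d) {
  if (mag_is_zero(n)) return rat_zero();
  Mag g = mag_gcd(n, d);
  if (!(g.size() == 1 && g[0] == 1u)) {
    Mag r;
    n = mag_divmod(n, g, r);
    d = mag_divmod(d, g, r);
  }
  return Rat{sg, n, d};
}

static Rat rat_from_ll(int64_t num, uint64_t den) {
  int sg = num == 0 ? 0 : (num < 0 ? -1 : 1);
  uint64_t an = num < 0 ? (uint64_t)(-num) : (uint64_t)num;
  return rat_make(sg, mag_from_u64(an), mag_from_u64(den));
}

static Rat rat_add(const Rat &a, const Rat &b) {
  if (a.sg == 0) return b;
  if (b.sg == 0) return a;
  Mag ad = mag_mul(a.n, b.d), bc = mag_mul(b.n, a.d);
  Mag den = mag_mul(a.d, b.d);
  if (a.sg == b.sg) return rat_make(a.sg, mag_add(ad, bc), den);
  int c = mag_cmp(ad, bc);
  if (c == 0) return rat_zero();
  if (c > 0) return rat_make(a.sg, mag_sub(ad, bc), den);
  return rat_make(b.sg, mag_sub(bc, ad), den);
}

static Rat rat_mul(const Rat &a, const Rat &b) {
  if (a.sg == 0 || b.sg == 0) return rat_zero();
  return rat_make(a.sg * b.sg, mag_mul(a.n, b.n), mag_mul(a.d, b.d));
}

static bool rat_eq(const Rat &a, const Rat &b) {
  return a.sg == b.sg && mag_cmp(a.n, b.n) == 0 && mag_cmp(a.d, b.d) == 0;
}

static double rat_dbl(const Rat &a) {
  if (a.sg == 0) return 0.0;
  return a.sg * (mag_dbl(a.n) / mag_dbl(a.d));
}

// ---------------------------------------------------------------------------
// prime registry for squarefree radicands

static std::vector<uint64_t> g_primes;

static uint64_t prime_bit(uint64_t p) {
  for (size_t i = 0; i < g_primes.size(); ++i)
    if (g_primes[i] == p) return 1ULL << i;
  if (g_primes.size() >= 64)
    stop("radical registry exhausted (more than 64 distinct primes)");
  g_primes.push_back(p);
  return 1ULL << (g_primes.size() - 1);
}

// v = sq^2 * (squarefree part); mask accumulates the squarefree primes
static void factor_small(uint64_t v, uint64_t &sq, uint64_t &mask) {
  sq = 1;
  mask = 0;
  if (v > 1000000000ULL)
    stop("radicand too large for trial-division factoring");
  for (uint64_t f = 2; f * f <= v; f += (f == 2 ? 1 : 2)) {
    if (v % f == 0) {
      int e = 0;
      while (v % f == 0) { v /= f; ++e; }
      for (int k = 0; k < e / 2; ++k) sq *= f;
      if (e % 2) mask ^= prime_bit(f);
    }
  }
  if (v > 1) mask ^= prime_bit(v);
}

static Mag mask_product(uint64_t mask) {
  Mag r = mag_from_u64(1);
  for (size_t i = 0; i < g_primes.size(); ++i)
    if ((mask >> i) & 1ULL) r = mag_mul(r, mag_from_u64(g_primes[i]));
  return r;
}

static double mask_product_dbl(uint64_t mask) {
  double r = 1;
  for (size_t i = 0; i < g_primes.size(); ++i)
    if ((mask >> i) & 1ULL) r *= (double)g_primes[i];
  return r;
}

// ---------------------------------------------------------------------------
// radical sums

typedef std::map<uint64_t, Rat> RS;

static void rs_insert(RS &r, uint64_t mask, const Rat &c) {
  if (c.sg == 0) return;
  RS::iterator it = r.find(mask);
  if (it == r.end()) {
    r[mask] = c;
  } else {
    it->second = rat_add(it->second, c);
    if (it->second.sg == 0) r.erase(it);
  }
}

static RS rs_add2(const RS &a, const RS &b) {
  RS r = a;
  for (RS::const_iterator it = b.begin(); it != b.end(); ++it)
    rs_insert(r, it->first, it->second);
  return r;
}

static RS rs_mul2(const RS &a, const RS &b) {
  RS r;
  for (RS::const_iterator ia = a.begin(); ia != a.end(); ++ia)
    for (RS::const_iterator ib = b.begin(); ib != b.end(); ++ib) {
      uint64_t common = ia->first & ib->first;
      uint64_t mask = ia->first ^ ib->first;
      Rat c = rat_mul(ia->second, ib->second);
      if (common)
        c = rat_mul(c, Rat{1, mask_product(common), mag_from_u64(1)});
      rs_insert(r, mask, c);
    }
  return r;
}

static RS rs_negate(const RS &a) {
  RS r = a;
  for (RS::iterator it = r.begin(); it != r.end(); ++it) it->second.sg = -it->second.sg;
  return r;
}

typedef XPtr<RS> RSP;

static RS &deref(SEXP x) {
  RSP p(x);
  return *p;
}

static SEXP wrap_rs(RS *r) { return RSP(r, true); }

static void check_int53(double v, const char *what) {
  if (!R_finite(v) || v != std::floor(v) || std::fabs(v) > 9007199254740992.0)
    stop("%s must be an integer-valued number below 2^53", what);
}

// [[Rcpp::export]]
SEXP rx_zero() { return wrap_rs(new RS()); }

// [[Rcpp::export]]
SEXP rx_rational(double num, double den) {
  check_int53(num, "numerator");
  check_int53(den, "denominator");
  if (den <= 0) stop("denominator must be positive");
  RS *r = new RS();
  Rat c = rat_from_ll((int64_t)num, (uint64_t)den);
  if (c.sg != 0) (*r)[0] = c;
  return wrap_rs(r);
}

// sign * sqrt(p / q)
// [[Rcpp::export]]
SEXP rx_radical(int sign, double p, double q) {
  check_int53(p, "radicand numerator");
  check_int53(q, "radicand denominator");
  if (p < 0 || q <= 0) stop("radicand must be a nonnegative rational");
  RS *r = new RS();
  if (sign != 0 && p > 0) {
    uint64_t sp, mp, sq, mq;
    factor_small((uint64_t)p, sp, mp);
    factor_small((uint64_t)q, sq, mq);
    uint64_t common = mp & mq, mask = mp ^ mq;
    // sqrt(p/q) = (sp/sq) * sqrt(fp)/sqrt(fq) = (sp/(sq*fq)) * sqrt(fp*fq)
    // and fp*fq = (common part)^2 * (xor part)
    Mag num = mag_mul(mag_from_u64(sp), mask_product(common));
    Mag den = mag_mul(mag_from_u64(sq), mask_product(mq));
    Rat c = rat_make(sign < 0 ? -1 : 1, num, den);
    if (c.sg != 0) (*r)[mask] = c;
  }
  return wrap_rs(r);
}

// [[Rcpp::export]]
SEXP rx_add(SEXP a, SEXP b) { return wrap_rs(new RS(rs_add2(deref(a), deref(b)))); }

// [[Rcpp::export]]
SEXP rx_sub(SEXP a, SEXP b) {
  return wrap_rs(new RS(rs_add2(deref(a), rs_negate(deref(b)))));
}

// [[Rcpp::export]]
SEXP rx_neg(SEXP a) { return wrap_rs(new RS(rs_negate(deref(a)))); }

// [[Rcpp::export]]
SEXP rx_mul(SEXP a, SEXP b) { return wrap_rs(new RS(rs_mul2(deref(a), deref(b)))); }

// acc + a * b, used heavily in the overlap sweep and the oracle
// [[Rcpp::export]]
SEXP rx_addmul(SEXP acc, SEXP a, SEXP b) {
  RS *r = new RS(deref(acc));
  RS ab = rs_mul2(deref(a), deref(b));
  for (RS::const_iterator it = ab.begin(); it != ab.end(); ++it)
    rs_insert(*r, it->first, it->second);
  return wrap_rs(r);
}

// [[Rcpp::export]]
double rx_double(SEXP a) {
  const RS &r = deref(a);
  double v = 0;
  for (RS::const_iterator it = r.begin(); it != r.end(); ++it)
    v += rat_dbl(it->second) * std::sqrt(mask_product_dbl(it->first));
  return v;
}

// [[Rcpp::export]]
bool rx_is_zero(SEXP a) { return deref(a).empty(); }

// [[Rcpp::export]]
bool rx_equal(SEXP a, SEXP b) {
  const RS &x = deref(a);
  const RS &y = deref(b);
  if (x.size() != y.size()) return false;
  RS::const_iterator ix = x.begin(), iy = y.begin();
  for (; ix != x.end(); ++ix, ++iy)
    if (ix->first != iy->first || !rat_eq(ix->second, iy->second)) return false;
  return true;
}

// [[Rcpp::export]]
int rx_nterms(SEXP a) { return (int)deref(a).size(); }

// term-by-term view: squarefree radicand (decimal string), coefficient
// numerator/denominator (decimal strings), coefficient as double
// [[Rcpp::export]]
List rx_terms(SEXP a) {
  const RS &r = deref(a);
  size_t n = r.size();
  CharacterVector s(n), num(n), den(n);
  NumericVector cd(n), sd(n);
  size_t k = 0;
  for (RS::const_iterator it = r.begin(); it != r.end(); ++it, ++k) {
    Mag sf = mask_product(it->first);
    s[k] = mag_dec(sf);
    std::string ns = mag_dec(it->second.n);
    num[k] = (it->second.sg < 0 ? "-" : "") + ns;
    den[k] = mag_dec(it->second.d);
    cd[k] = rat_dbl(it->second);
    sd[k] = mag_dbl(sf);
  }
  return List::create(_["radicand"] = s, _["num"] = num, _["den"] = den,
                      _["coef"] = cd, _["sqrt_of"] = sd);
}

// canonical rendering: "0"; single term as [-]sqrt(p/q) with p/q in lowest
// terms; multi-term sums as (+|-) (a/b)*sqrt(s) ordered by increasing s
// [[Rcpp::export]]
std::string rx_format(SEXP a) {
  const RS &r = deref(a);
  if (r.empty()) return "0";
  if (r.size() == 1) {
    RS::const_iterator it = r.begin();
    const Rat &c = it->second;
    Mag p = mag_mul(mag_mul(c.n, c.n), mask_product(it->first));
    Mag q = mag_mul(c.d, c.d);
    Mag g = mag_gcd(p, q);
    if (!(g.size() == 1 && g[0] == 1u)) {
      Mag rem;
      p = mag_divmod(p, g, rem);
      q = mag_divmod(q, g, rem);
    }
    std::string s = (c.sg < 0 ? "-sqrt(" : "sqrt(") + mag_dec(p);
    if (!(q.size() == 1 && q[0] == 1u)) s += "/" + mag_dec(q);
    return s + ")";
  }
  // sort terms by squarefree radicand value
  std::vector<const RS::value_type *> ord;
  for (RS::const_iterator it = r.begin(); it != r.end(); ++it)
    ord.push_back(&*it);
  std::sort(ord.begin(), ord.end(),
            [](const RS::value_type *a, const RS::value_type *b) {
              return mask_product_dbl(a->first) < mask_product_dbl(b->first);
            });
  std::string out;
  for (size_t k = 0; k < ord.size(); ++k) {
    const RS::value_type *it = ord[k];
    const Rat &c = it->second;
    out += (k == 0) ? (c.sg < 0 ? "-" : "") : (c.sg < 0 ? " - " : " + ");
    std::string cs = "(" + mag_dec(c.n);
    if (!(c.d.size() == 1 && c.d[0] == 1u)) cs += "/" + mag_dec(c.d);
    cs += ")";
    if (it->first == 0) out += cs;
    else out += cs + "*sqrt(" + mag_dec(mask_product(it->first)) + ")";
  }
  return out;
}
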