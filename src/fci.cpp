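// Determinant-based complete-active-space configuration interaction.
//
// CI vectors are (n_alpha_strings x n_beta_strings) matrices; strings are
// orbital-occupation bitmasks ordered by integer value.  The sigma vector
// uses the generator decomposition H = sum h'_pq E_pq
// + 1/2 sum (pq|rs) E_pq E_rs with h'_ps = h_ps - 1/2 sum_q (pq|qs).
//
// Orbital-subset reduced quantities map determinants to (subsystem
// configuration, environment configuration) pairs with the fermionic
// parities of (i) interleaving alpha/beta modes site-ascending (up before
// down) and (ii) moving the subsystem modes in front of the environment.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

static int popcount_below(int mask, int p) {
  return __builtin_popcount(mask & ((1 << p) - 1));
}

// [[Rcpp::export]]
IntegerVector cpp_strings(int norb, int ne) {
  std::vector<int> out;
  if (ne < 0 || ne > norb) stop("bad electron count");
  for (int m = 0; m < (1 << norb); ++m)
    if (__builtin_popcount(m) == ne) out.push_back(m);
  return wrap(out);
}

// single-excitation records for one spin channel:
// columns: string index I, string index J, p (created), q (annihilated),
// sign; includes diagonal p == q (occupation) records.
// [[Rcpp::export]]
IntegerMatrix cpp_excitations(IntegerVector strings, int norb) {
  std::unordered_map<int, int> index;
  for (int i = 0; i < strings.size(); ++i) index[strings[i]] = i;
  std::vector<std::array<int, 5>> rec;
  for (int i = 0; i < strings.size(); ++i) {
    int s = strings[i];
    for (int q = 0; q < norb; ++q) {
      if (!(s & (1 << q))) continue;
      // diagonal
      for (int p = 0; p < norb; ++p) {
        if (p == q) { rec.push_back({i, i, p, q, 1}); continue; }
        if (s & (1 << p)) continue;
        int t = (s & ~(1 << q)) | (1 << p);
        // sign: annihilate q then create p
        int sgn = ((popcount_below(s, q) + popcount_below(s & ~(1 << q), p)) % 2)
                    ? -1 : 1;
        rec.push_back({index[t], i, p, q, sgn});
        // record as (I=i source, J=target): store (J, I) columns below
      }
    }
  }
  IntegerMatrix out(rec.size(), 5);
  for (size_t k = 0; k < rec.size(); ++k) {
    out(k, 0) = rec[k][1]; // I (source)
    out(k, 1) = rec[k][0]; // J (target): a+_p a_q |I> = sign |J>
    out(k, 2) = rec[k][2];
    out(k, 3) = rec[k][3];
    out(k, 4) = rec[k][4];
  }
  return out;
}

// apply E_pq to CI matrix for all pq: returns T[pq] stacked in a big array
static void apply_generators(const double* C, int na, int nb, int norb,
                             const IntegerMatrix& exa,
                             const IntegerMatrix& exb,
                             std::vector<double>& T) {
  size_t nd = (size_t)na * nb;
  T.assign((size_t)norb * norb * nd, 0.0);
  // alpha: rows
  for (int k = 0; k < exa.nrow(); ++k) {
    int I = exa(k, 0), J = exa(k, 1), p = exa(k, 2), q = exa(k, 3);
    double sgn = exa(k, 4);
    double* dst = &T[((size_t)p * norb + q) * nd];
    // C stored column-major (na x nb): row I -> row J
    for (int b = 0; b < nb; ++b) dst[J + (size_t)b * na] += sgn * C[I + (size_t)b * na];
  }
  // beta: columns
  for (int k = 0; k < exb.nrow(); ++k) {
    int I = exb(k, 0), J = exb(k, 1), p = exb(k, 2), q = exb(k, 3);
    double sgn = exb(k, 4);
    double* dst = &T[((size_t)p * norb + q) * nd];
    const double* src = &C[(size_t)I * na];
    double* d2 = &T[((size_t)p * norb + q) * nd + (size_t)J * na];
    for (int a = 0; a < na; ++a) d2[a] += sgn * src[a];
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_fci_sigma(NumericMatrix Cmat, NumericMatrix h1,
                            NumericVector g, IntegerMatrix exa,
                            IntegerMatrix exb, int norb) {
  int na = Cmat.nrow(), nb = Cmat.ncol();
  size_t nd = (size_t)na * nb;
  std::vector<double> T;
  apply_generators(REAL(Cmat), na, nb, norb, exa, exb, T);
  int n2 = norb * norb;
  // effective one-electron: h'_ps = h_ps - 1/2 sum_q (pq|qs)
  std::vector<double> hp(n2);
  for (int p = 0; p < norb; ++p)
    for (int s = 0; s < norb; ++s) {
      double v = h1(p, s);
      for (int q = 0; q < norb; ++q)
        v -= 0.5 * g[((size_t)(p * norb + q) * norb + q) * norb + s];
      hp[p * norb + s] = v;
    }
  // M[pq] = h'_pq C + 1/2 sum_rs g[pq,rs] T[rs]
  std::vector<double> M((size_t)n2 * nd, 0.0);
  for (int pq = 0; pq < n2; ++pq) {
    double* dst = &M[(size_t)pq * nd];
    const double hv = hp[pq];
    const double* c = REAL(Cmat);
    for (size_t x = 0; x < nd; ++x) dst[x] = hv * c[x];
    for (int rs = 0; rs < n2; ++rs) {
      double w = 0.5 * g[(size_t)pq * n2 + rs];
      if (w == 0.0) continue;
      const double* src = &T[(size_t)rs * nd];
      for (size_t x = 0; x < nd; ++x) dst[x] += w * src[x];
    }
  }
  // sigma = sum_pq E_pq M[pq]
  NumericMatrix sigma(na, nb);
  double* S = REAL(sigma);
  for (int k = 0; k < exa.nrow(); ++k) {
    int I = exa(k, 0), J = exa(k, 1), p = exa(k, 2), q = exa(k, 3);
    double sgn = exa(k, 4);
    const double* src = &M[((size_t)p * norb + q) * nd];
    for (int b = 0; b < nb; ++b) S[J + (size_t)b * na] += sgn * src[I + (size_t)b * na];
  }
  for (int k = 0; k < exb.nrow(); ++k) {
    int I = exb(k, 0), J = exb(k, 1), p = exb(k, 2), q = exb(k, 3);
    double sgn = exb(k, 4);
    const double* src = &M[((size_t)p * norb + q) * nd + (size_t)I * na];
    double* dst = &S[(size_t)J * na];
    for (int a = 0; a < na; ++a) dst[a] += sgn * src[a];
  }
  return sigma;
}

// diagonal of H for the Davidson preconditioner
// [[Rcpp::export]]
NumericMatrix cpp_fci_hdiag(IntegerVector stra, IntegerVector strb,
                            NumericMatrix h1, NumericVector g, int norb) {
  int na = stra.size(), nb = strb.size();
  NumericMatrix out(na, nb);
  auto gval = [&](int p, int q, int r, int s) {
    return g[((size_t)(p * norb + q) * norb + r) * norb + s];
  };
  for (int a = 0; a < na; ++a) {
    for (int b = 0; b < nb; ++b) {
      double e = 0.0;
      for (int p = 0; p < norb; ++p) {
        int np = ((stra[a] >> p) & 1) + ((strb[b] >> p) & 1);
        if (!np) continue;
        e += np * h1(p, p);
        for (int q = 0; q < norb; ++q) {
          int nq = ((stra[a] >> q) & 1) + ((strb[b] >> q) & 1);
          if (nq) e += 0.5 * np * nq * gval(p, p, q, q);
          int nsame = ((stra[a] >> p) & 1) * ((stra[a] >> q) & 1)
                    + ((strb[b] >> p) & 1) * ((strb[b] >> q) & 1);
          if (nsame) e -= 0.5 * nsame * gval(p, q, q, p);
        }
      }
      out(a, b) = e;
    }
  }
  return out;
}

// gamma_pq (spin-summed 1RDM) from a CI vector
// [[Rcpp::export]]
NumericMatrix cpp_fci_gamma1(NumericMatrix Cmat, IntegerMatrix exa,
                             IntegerMatrix exb, int norb) {
  int na = Cmat.nrow(), nb = Cmat.ncol();
  size_t nd = (size_t)na * nb;
  std::vector<double> T;
  apply_generators(REAL(Cmat), na, nb, norb, exa, exb, T);
  NumericMatrix gam(norb, norb);
  const double* c = REAL(Cmat);
  for (int p = 0; p < norb; ++p)
    for (int q = 0; q < norb; ++q) {
      const double* t = &T[((size_t)p * norb + q) * nd];
      double v = 0.0;
      for (size_t x = 0; x < nd; ++x) v += c[x] * t[x];
      gam(p, q) = v;
    }
  return gam;
}

// per-spin generator applications, returned as (ndet x norb^2) matrices for
// assembling the up/down 2RDM block via crossprod in R
// [[Rcpp::export]]
List cpp_fci_spin_generators(NumericMatrix Cmat, IntegerMatrix exa,
                             IntegerMatrix exb, int norb) {
  int na = Cmat.nrow(), nb = Cmat.ncol();
  size_t nd = (size_t)na * nb;
  int n2 = norb * norb;
  NumericMatrix A(nd, n2), B(nd, n2);
  const double* c = REAL(Cmat);
  double* Ap = REAL(A);
  double* Bp = REAL(B);
  for (int k = 0; k < exa.nrow(); ++k) {
    int I = exa(k, 0), J = exa(k, 1), p = exa(k, 2), q = exa(k, 3);
    double sgn = exa(k, 4);
    double* dst = &Ap[(size_t)(p * norb + q) * nd];
    for (int b = 0; b < nb; ++b) dst[J + (size_t)b * na] += sgn * c[I + (size_t)b * na];
  }
  for (int k = 0; k < exb.nrow(); ++k) {
    int I = exb(k, 0), J = exb(k, 1), p = exb(k, 2), q = exb(k, 3);
    double sgn = exb(k, 4);
    double* dst = &Bp[(size_t)(p * norb + q) * nd + (size_t)J * na];
    const double* src = &c[(size_t)I * na];
    for (int a = 0; a < na; ++a) dst[a] += sgn * src[a];
  }
  return List::create(_["A"] = A, _["B"] = B);
}

// orbital-subset amplitude decomposition of a CI vector:
// returns (subsystem bit-config, environment key, amplitude) triplets with
// all fermionic reordering parities included.  Subsystem bit-config: bit
// 2k = up of subset orbital k, bit 2k+1 = down (subset in ascending order).
// [[Rcpp::export]]
List cpp_ci_subset(NumericMatrix Cmat, IntegerVector stra, IntegerVector strb,
                   int norb, IntegerVector subset0, double tol = 1e-14) {
  int na = stra.size(), nb = strb.size();
  int ns = subset0.size();
  int submask = 0;
  std::vector<int> spos(norb, -1);
  for (int k = 0; k < ns; ++k) {
    submask |= 1 << subset0[k];
  }
  { int k = 0;
    for (int p = 0; p < norb; ++p) if (submask & (1 << p)) spos[p] = k++; }
  std::vector<int> subcfg, envkey;
  std::vector<double> amp;
  const double* c = REAL(Cmat);
  for (int b = 0; b < nb; ++b) {
    int sb = strb[b];
    for (int a = 0; a < na; ++a) {
      double v = c[a + (size_t)b * na];
      if (v == 0.0 || std::abs(v) < tol) continue;
      int sa = stra[a];
      // parity 1: interleave (alpha block then beta block -> site order)
      int par = 0;
      for (int q = 0; q < norb; ++q) {
        if (!(sb & (1 << q))) continue;
        par += __builtin_popcount(sa & ~((1 << (q + 1)) - 1)); // alpha p > q
      }
      // parity 2: move subset modes to the front (ascending site order)
      // crossings: for each subset orbital p, electrons on env orbitals < p
      for (int p = 0; p < norb; ++p) {
        if (!(submask & (1 << p))) continue;
        int np = ((sa >> p) & 1) + ((sb >> p) & 1);
        if (!np) continue;
        int envlow = (~submask) & ((1 << p) - 1);
        int ne = __builtin_popcount(sa & envlow) + __builtin_popcount(sb & envlow);
        par += np * ne;
      }
      int cfg = 0;
      for (int p = 0; p < norb; ++p) {
        if (!(submask & (1 << p))) continue;
        if ((sa >> p) & 1) cfg |= 1 << (2 * spos[p]);
        if ((sb >> p) & 1) cfg |= 1 << (2 * spos[p] + 1);
      }
      int ea = sa & ~submask, eb = sb & ~submask;
      // environment key: pack alpha/beta env occupations
      int key = ea | (eb << norb); // norb <= 15 assumed
      subcfg.push_back(cfg);
      envkey.push_back(key);
      amp.push_back((par % 2) ? -v : v);
    }
  }
  return List::create(_["sub"] = subcfg, _["env"] = envkey, _["amp"] = amp);
}
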