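// Gaussian-orbital integrals: overlap, kinetic, nuclear attraction and
// two-electron repulsion via McMurchie-Davidson Hermite expansion.
//
// Shells are contracted Cartesian Gaussians (s, p, d, f supported); the
// caller supplies a per-shell Cartesian-to-spherical transform (rows =
// normalized spherical AOs over raw Cartesian monomial components), and all
// returned integrals are in the spherical AO basis.  Two-electron
// integrals are stored with 8-fold permutational symmetry in the canonical
// packed order idx(pq, rs) with pq = p(p+1)/2 + q, p >= q, pq >= rs.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <cstdint>
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

// ---------------------------------------------------------------- Boys ----
static void boys(int mmax, double t, double* F) {
  if (t < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2 * m + 1);
    return;
  }
  if (t > 30.0) {
    F[0] = 0.5 * std::sqrt(PI / t);
    double et = std::exp(-t);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2 * m + 1) * F[m] - et) / (2 * t);
    return;
  }
  // series for F_mmax, downward recursion
  double et = std::exp(-t);
  double sum = 1.0 / (2 * mmax + 1);
  double term = sum;
  for (int i = 1; i < 200; ++i) {
    term *= 2 * t / (2 * mmax + 2 * i + 1);
    sum += term;
    if (term < 1e-17 * sum) break;
  }
  F[mmax] = et * sum;
  for (int m = mmax; m > 0; --m)
    F[m - 1] = (2 * t * F[m] + et) / (2 * m - 1);
}

// ------------------------------------------------- Hermite E coefficients --
// E[t] for given (i, j): expansion of x^i_A x^j_B Gaussian product over
// Hermite Gaussians.  Table layout: E(i, j, t) with t <= i + j.
struct ETable {
  int la, lb;
  std::vector<double> v; // (la+1) x (lb+1) x (la+lb+1)
  inline double& at(int i, int j, int t) {
    return v[(i * (lb + 1) + j) * (la + lb + 1) + t];
  }
  inline double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (lb + 1) + j) * (la + lb + 1) + t];
  }
};

static void build_E(ETable& E, int la, int lb, double a, double b, double AB) {
  E.la = la; E.lb = lb;
  E.v.assign((la + 1) * (lb + 1) * (la + lb + 1), 0.0);
  double p = a + b, mu = a * b / p;
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= la; ++i) {
    for (int j = 0; j <= lb; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          val = E.get(i - 1, j, t - 1) / (2 * p)
              - (b / p) * AB * E.get(i - 1, j, t)
              + (t + 1) * E.get(i - 1, j, t + 1);
        } else {
          val = E.get(i, j - 1, t - 1) / (2 * p)
              + (a / p) * AB * E.get(i, j - 1, t)
              + (t + 1) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// ------------------------------------------------ Hermite Coulomb R_tuv ----
// Flat preallocated table: R.v holds the n = 0 slice after build_R; the
// recursion uses a thread-local 4-index work buffer to avoid allocation.
struct RTable {
  int L;
  std::vector<double> v; // (L+1)^3, only t+u+v <= L used
  inline double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (L + 1) + u) * (L + 1) + w];
  }
};

static void build_R(RTable& R, int L, double p, const double* PQ) {
  const int s1 = L + 1, s2 = s1 * s1, s3 = s2 * s1;
  R.L = L;
  R.v.assign(s3, 0.0);
  double r2 = PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2];
  double F[32];
  boys(L, p * r2, F);
  static thread_local std::vector<double> buf;
  buf.assign((size_t)s1 * s3, 0.0); // [n][t][u][w]
  auto at = [&](int n, int t, int u, int w) -> double& {
    return buf[(size_t)n * s3 + (t * s1 + u) * s1 + w];
  };
  double c = 1.0;
  for (int n = 0; n <= L; ++n) { at(n, 0, 0, 0) = c * F[n]; c *= -2.0 * p; }
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= tot; ++t) for (int u = 0; u <= tot - t; ++u) {
      int w = tot - t - u;
      for (int n = 0; n <= L - tot; ++n) {
        double val;
        if (t > 0) {
          val = (t - 1 > 0 ? (t - 1) * at(n + 1, t - 2, u, w) : 0.0)
              + PQ[0] * at(n + 1, t - 1, u, w);
        } else if (u > 0) {
          val = (u - 1 > 0 ? (u - 1) * at(n + 1, t, u - 2, w) : 0.0)
              + PQ[1] * at(n + 1, t, u - 1, w);
        } else {
          val = (w - 1 > 0 ? (w - 1) * at(n + 1, t, u, w - 2) : 0.0)
              + PQ[2] * at(n + 1, t, u, w - 1);
        }
        at(n, t, u, w) = val;
      }
    }
  }
  std::copy(buf.begin(), buf.begin() + s3, R.v.begin());
}

// ----------------------------------------------------------- shell data ----
struct Shell {
  int l, nprim, atom;
  std::vector<double> exps, coefs; // coefs include radial norm factor
  double A[3];
  int cart_n, sph_n, sph_off;
  std::vector<double> T; // sph_n x cart_n, row-major
};

// Cartesian component exponents in canonical order for angular momentum l
static void cart_components(int l, std::vector<std::array<int,3>>& out) {
  out.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      out.push_back({lx, ly, l - lx - ly});
}

static std::vector<Shell> unpack_shells(List shells) {
  IntegerVector l = shells["l"], atom = shells["atom"];
  List exps = shells["exps"], coefs = shells["coefs"], Tm = shells["T"];
  NumericMatrix centers = shells["centers"]; // nshell x 3
  int ns = l.size();
  std::vector<Shell> out(ns);
  int off = 0;
  for (int s = 0; s < ns; ++s) {
    Shell& sh = out[s];
    sh.l = l[s]; sh.atom = atom[s];
    NumericVector e = exps[s], c = coefs[s];
    sh.nprim = e.size();
    sh.exps.assign(e.begin(), e.end());
    sh.coefs.assign(c.begin(), c.end());
    for (int k = 0; k < 3; ++k) sh.A[k] = centers(s, k);
    sh.cart_n = (sh.l + 1) * (sh.l + 2) / 2;
    NumericMatrix T = Tm[s];
    sh.sph_n = T.nrow();
    sh.T.assign(T.begin(), T.end()); // column-major from R
    sh.sph_off = off;
    off += sh.sph_n;
  }
  return out;
}

static int total_sph(const std::vector<Shell>& sh) {
  int n = 0;
  for (auto& s : sh) n += s.sph_n;
  return n;
}

// transform cart block (ca x cb, row-major a-major) to spherical
static void sph_transform2(const Shell& A, const Shell& B,
                           const std::vector<double>& cart,
                           std::vector<double>& sph) {
  sph.assign(A.sph_n * B.sph_n, 0.0);
  for (int i = 0; i < A.sph_n; ++i)
    for (int p = 0; p < A.cart_n; ++p) {
      double ta = A.T[i + p * A.sph_n]; // column-major
      if (ta == 0.0) continue;
      for (int j = 0; j < B.sph_n; ++j)
        for (int q = 0; q < B.cart_n; ++q) {
          double tb = B.T[j + q * B.sph_n];
          if (tb == 0.0) continue;
          sph[i * B.sph_n + j] += ta * tb * cart[p * B.cart_n + q];
        }
    }
}

// ------------------------------------------------------- one-electron ------
// [[Rcpp::export]]
List cpp_one_electron(List shells, NumericMatrix atom_xyz,
                      NumericVector atom_charge) {
  std::vector<Shell> sh = unpack_shells(shells);
  int n = total_sph(sh), natm = atom_xyz.nrow();
  NumericMatrix S(n, n), T(n, n), V(n, n);
  std::vector<std::array<int,3>> ca, cb;
  for (size_t si = 0; si < sh.size(); ++si) {
    for (size_t sj = 0; sj <= si; ++sj) {
      const Shell &A = sh[si], &B = sh[sj];
      cart_components(A.l, ca);
      cart_components(B.l, cb);
      std::vector<double> Sc(A.cart_n * B.cart_n, 0.0),
          Tc(A.cart_n * B.cart_n, 0.0), Vc(A.cart_n * B.cart_n, 0.0);
      for (int pa = 0; pa < A.nprim; ++pa) {
        double a = A.exps[pa];
        for (int pb = 0; pb < B.nprim; ++pb) {
          double b = B.exps[pb];
          double cc = A.coefs[pa] * B.coefs[pb];
          double p = a + b;
          double P[3], PQ[3];
          for (int k = 0; k < 3; ++k)
            P[k] = (a * A.A[k] + b * B.A[k]) / p;
          ETable Ex, Ey, Ez, Ex2, Ey2, Ez2;
          build_E(Ex, A.l, B.l + 2, a, b, A.A[0] - B.A[0]);
          build_E(Ey, A.l, B.l + 2, a, b, A.A[1] - B.A[1]);
          build_E(Ez, A.l, B.l + 2, a, b, A.A[2] - B.A[2]);
          double pref = std::pow(PI / p, 1.5);
          // R table for nuclear attraction
          int L = A.l + B.l;
          RTable R;
          for (int ia = 0; ia < A.cart_n; ++ia) {
            for (int ib = 0; ib < B.cart_n; ++ib) {
              int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
              int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
              // overlap
              double sx = Ex.get(ax, bx, 0), sy = Ey.get(ay, by, 0),
                     sz = Ez.get(az, bz, 0);
              double sval = pref * sx * sy * sz;
              Sc[ia * B.cart_n + ib] += cc * sval;
              // kinetic: T = -1/2 (d2/dx2 + ...)
              auto K1 = [&](ETable& E, int ia1, int ib1) {
                double t = b * (2 * ib1 + 1) * E.get(ia1, ib1, 0)
                         - 2.0 * b * b * E.get(ia1, ib1 + 2, 0);
                if (ib1 >= 2) t -= 0.5 * ib1 * (ib1 - 1) * E.get(ia1, ib1 - 2, 0);
                return t;
              };
              double kx = K1(Ex, ax, bx), ky = K1(Ey, ay, by), kz = K1(Ez, az, bz);
              double tval = pref * (kx * sy * sz + sx * ky * sz + sx * sy * kz);
              Tc[ia * B.cart_n + ib] += cc * tval;
            }
          }
          // nuclear attraction
          for (int at = 0; at < natm; ++at) {
            for (int k = 0; k < 3; ++k) PQ[k] = P[k] - atom_xyz(at, k);
            build_R(R, L, p, PQ);
            double zfac = -atom_charge[at] * 2.0 * PI / p;
            for (int ia = 0; ia < A.cart_n; ++ia) {
              for (int ib = 0; ib < B.cart_n; ++ib) {
                int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
                int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
                double v = 0.0;
                for (int t = 0; t <= ax + bx; ++t)
                  for (int u = 0; u <= ay + by; ++u)
                    for (int w = 0; w <= az + bz; ++w)
                      v += Ex.get(ax, bx, t) * Ey.get(ay, by, u)
                         * Ez.get(az, bz, w) * R.get(t, u, w);
                Vc[ia * B.cart_n + ib] += cc * zfac * v;
              }
            }
          }
        }
      }
      std::vector<double> Ss, Ts, Vs;
      sph_transform2(A, B, Sc, Ss);
      sph_transform2(A, B, Tc, Ts);
      sph_transform2(A, B, Vc, Vs);
      for (int i = 0; i < A.sph_n; ++i)
        for (int j = 0; j < B.sph_n; ++j) {
          int gi = A.sph_off + i, gj = B.sph_off + j;
          S(gi, gj) = S(gj, gi) = Ss[i * B.sph_n + j];
          T(gi, gj) = T(gj, gi) = Ts[i * B.sph_n + j];
          V(gi, gj) = V(gj, gi) = Vs[i * B.sph_n + j];
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T, _["V"] = V);
}

// --------------------------------------------------------------- ERIs ------
static inline int64_t pidx(int64_t p, int64_t q) { // p >= q
  return p * (p + 1) / 2 + q;
}

// contracted cartesian quartet block for shells (A B | C D)
static void eri_quartet(const Shell& A, const Shell& B, const Shell& C,
                        const Shell& D, std::vector<double>& out) {
  std::vector<std::array<int,3>> ca, cb, cc_, cd;
  cart_components(A.l, ca); cart_components(B.l, cb);
  cart_components(C.l, cc_); cart_components(D.l, cd);
  int na = A.cart_n, nb = B.cart_n, nc = C.cart_n, nd = D.cart_n;
  out.assign((size_t)na * nb * nc * nd, 0.0);
  int L = A.l + B.l + C.l + D.l;
  RTable R;
  // precompute ket primitive-pair E tables and screening factors once
  struct PairE { ETable Ex, Ey, Ez; double P[3], p, coef, K; };
  static thread_local std::vector<PairE> kets, bras;
  auto fill_pairs = [](const Shell& X, const Shell& Y,
                       std::vector<PairE>& out2) {
    out2.clear();
    double AB2 = 0.0;
    for (int k = 0; k < 3; ++k)
      AB2 += (X.A[k] - Y.A[k]) * (X.A[k] - Y.A[k]);
    for (int px = 0; px < X.nprim; ++px)
      for (int py = 0; py < Y.nprim; ++py) {
        PairE pe;
        double a = X.exps[px], b = Y.exps[py];
        pe.p = a + b;
        pe.coef = X.coefs[px] * Y.coefs[py];
        pe.K = std::abs(pe.coef) * std::exp(-a * b / pe.p * AB2)
             / pe.p; // overlap-like magnitude bound
        for (int k = 0; k < 3; ++k)
          pe.P[k] = (a * X.A[k] + b * Y.A[k]) / pe.p;
        build_E(pe.Ex, X.l, Y.l, a, b, X.A[0] - Y.A[0]);
        build_E(pe.Ey, X.l, Y.l, a, b, X.A[1] - Y.A[1]);
        build_E(pe.Ez, X.l, Y.l, a, b, X.A[2] - Y.A[2]);
        out2.push_back(std::move(pe));
      }
  };
  fill_pairs(A, B, bras);
  fill_pairs(C, D, kets);
  double PQ[3];
  for (const PairE& bra : bras) {
    for (const PairE& ket : kets) {
      double pref = 2.0 * std::pow(PI, 2.5)
                  / (bra.p * ket.p * std::sqrt(bra.p + ket.p));
      if (bra.K * ket.K * bra.p * ket.p * pref < 1e-14) continue;
      double cfac = bra.coef * ket.coef * pref;
      for (int k = 0; k < 3; ++k) PQ[k] = bra.P[k] - ket.P[k];
      double alpha = bra.p * ket.p / (bra.p + ket.p);
      build_R(R, L, alpha, PQ);
      for (int ia = 0; ia < na; ++ia) for (int ib = 0; ib < nb; ++ib) {
        int ax = ca[ia][0], ay = ca[ia][1], az = ca[ia][2];
        int bx = cb[ib][0], by = cb[ib][1], bz = cb[ib][2];
        int tx1 = ax + bx, ty1 = ay + by, tz1 = az + bz;
        for (int ic = 0; ic < nc; ++ic) for (int id = 0; id < nd; ++id) {
          int cx = cc_[ic][0], cy = cc_[ic][1], cz = cc_[ic][2];
          int dx = cd[id][0], dy = cd[id][1], dz = cd[id][2];
          int tx2 = cx + dx, ty2 = cy + dy, tz2 = cz + dz;
          double val = 0.0;
          for (int t1 = 0; t1 <= tx1; ++t1) {
            double ex1 = bra.Ex.get(ax, bx, t1);
            if (ex1 == 0.0) continue;
            for (int u1 = 0; u1 <= ty1; ++u1) {
              double ey1 = bra.Ey.get(ay, by, u1);
              if (ey1 == 0.0) continue;
              for (int v1 = 0; v1 <= tz1; ++v1) {
                double ez1 = bra.Ez.get(az, bz, v1);
                if (ez1 == 0.0) continue;
                double b1 = ex1 * ey1 * ez1;
                for (int t2 = 0; t2 <= tx2; ++t2) {
                  double ex2 = ket.Ex.get(cx, dx, t2);
                  if (ex2 == 0.0) continue;
                  for (int u2 = 0; u2 <= ty2; ++u2) {
                    double ey2 = ket.Ey.get(cy, dy, u2);
                    if (ey2 == 0.0) continue;
                    for (int v2 = 0; v2 <= tz2; ++v2) {
                      double ez2 = ket.Ez.get(cz, dz, v2);
                      if (ez2 == 0.0) continue;
                      double sgn = ((t2 + u2 + v2) % 2) ? -1.0 : 1.0;
                      val += b1 * ex2 * ey2 * ez2 * sgn
                           * R.get(t1 + t2, u1 + u2, v1 + v2);
                    }
                  }
                }
              }
            }
          }
          out[((size_t)(ia * nb + ib) * nc + ic) * nd + id] += cfac * val;
        }
      }
    }
  }
}

// full spherical transform of a quartet block
static void sph_transform4(const Shell& A, const Shell& B, const Shell& C,
                           const Shell& D, const std::vector<double>& cart,
                           std::vector<double>& sph) {
  int na = A.cart_n, nb = B.cart_n, nc = C.cart_n, nd = D.cart_n;
  int ma = A.sph_n, mb = B.sph_n, mc = C.sph_n, md = D.sph_n;
  // transform one index at a time
  std::vector<double> t1((size_t)ma * nb * nc * nd, 0.0);
  for (int i = 0; i < ma; ++i)
    for (int p = 0; p < na; ++p) {
      double w = A.T[i + p * ma];
      if (w == 0.0) continue;
      const double* src = &cart[(size_t)p * nb * nc * nd];
      double* dst = &t1[(size_t)i * nb * nc * nd];
      for (size_t k = 0; k < (size_t)nb * nc * nd; ++k) dst[k] += w * src[k];
    }
  std::vector<double> t2((size_t)ma * mb * nc * nd, 0.0);
  for (int i = 0; i < ma; ++i)
    for (int j = 0; j < mb; ++j)
      for (int p = 0; p < nb; ++p) {
        double w = B.T[j + p * mb];
        if (w == 0.0) continue;
        const double* src = &t1[((size_t)i * nb + p) * nc * nd];
        double* dst = &t2[((size_t)i * mb + j) * nc * nd];
        for (size_t k = 0; k < (size_t)nc * nd; ++k) dst[k] += w * src[k];
      }
  std::vector<double> t3((size_t)ma * mb * mc * nd, 0.0);
  for (size_t ij = 0; ij < (size_t)ma * mb; ++ij)
    for (int k2 = 0; k2 < mc; ++k2)
      for (int p = 0; p < nc; ++p) {
        double w = C.T[k2 + p * mc];
        if (w == 0.0) continue;
        const double* src = &t2[(ij * nc + p) * nd];
        double* dst = &t3[(ij * mc + k2) * nd];
        for (int k = 0; k < nd; ++k) dst[k] += w * src[k];
      }
  sph.assign((size_t)ma * mb * mc * md, 0.0);
  for (size_t ijk = 0; ijk < (size_t)ma * mb * mc; ++ijk)
    for (int l2 = 0; l2 < md; ++l2)
      for (int p = 0; p < nd; ++p) {
        double w = D.T[l2 + p * md];
        if (w == 0.0) continue;
        sph[ijk * md + l2] += w * t3[ijk * nd + p];
      }
}

// [[Rcpp::export]]
NumericVector cpp_eri(List shells, double screen_tol = 1e-12) {
  std::vector<Shell> sh = unpack_shells(shells);
  int ns = sh.size();
  int n = total_sph(sh);
  int64_t npair = (int64_t)n * (n + 1) / 2;
  int64_t ntot = npair * (npair + 1) / 2;
  NumericVector out((R_xlen_t)ntot);
  // Schwarz bounds per shell pair
  std::vector<double> qbound(ns * ns, 0.0);
  std::vector<double> blk, sphblk;
  for (int i = 0; i < ns; ++i)
    for (int j = 0; j <= i; ++j) {
      eri_quartet(sh[i], sh[j], sh[i], sh[j], blk);
      double mx = 0.0;
      int na = sh[i].cart_n, nb = sh[j].cart_n;
      for (int p = 0; p < na; ++p) for (int q = 0; q < nb; ++q) {
        double v = blk[((size_t)(p * nb + q) * na + p) * nb + q];
        if (v > mx) mx = v;
      }
      qbound[i * ns + j] = qbound[j * ns + i] = std::sqrt(std::max(mx, 0.0));
    }
  for (int si = 0; si < ns; ++si)
   for (int sj = 0; sj <= si; ++sj) {
    double qb1 = qbound[si * ns + sj];
    for (int sk = 0; sk <= si; ++sk)
     for (int sl = 0; sl <= sk; ++sl) {
      // require pair (si,sj) >= (sk,sl) canonically
      if (sk == si && sl > sj) continue;
      if (qb1 * qbound[sk * ns + sl] < screen_tol) continue;
      eri_quartet(sh[si], sh[sj], sh[sk], sh[sl], blk);
      sph_transform4(sh[si], sh[sj], sh[sk], sh[sl], blk, sphblk);
      const Shell &A = sh[si], &B = sh[sj], &C = sh[sk], &D = sh[sl];
      for (int i = 0; i < A.sph_n; ++i)
       for (int j = 0; j < B.sph_n; ++j)
        for (int k = 0; k < C.sph_n; ++k)
         for (int l = 0; l < D.sph_n; ++l) {
          int p = A.sph_off + i, q = B.sph_off + j,
              r = C.sph_off + k, s = D.sph_off + l;
          int P = std::max(p, q), Q = std::min(p, q);
          int Rr = std::max(r, s), Ss = std::min(r, s);
          int64_t pq = pidx(P, Q), rs = pidx(Rr, Ss);
          int64_t idx = (pq >= rs) ? pidx(pq, rs) : pidx(rs, pq);
          out[(R_xlen_t)idx] =
            sphblk[(((size_t)i * B.sph_n + j) * C.sph_n + k) * D.sph_n + l];
         }
     }
   }
  return out;
}

// ------------------------------------------------------- Fock builders -----
// J and K from packed ERIs and a symmetric density matrix.
// [[Rcpp::export]]
List cpp_fock_jk(NumericVector eri, NumericMatrix Dmat) {
  int n = Dmat.nrow();
  NumericMatrix J(n, n), K(n, n);
  const double* D = Dmat.begin();
  double* Jp = J.begin();
  double* Kp = K.begin();
  int64_t idx = 0;
  for (int p = 0; p < n; ++p)
   for (int q = 0; q <= p; ++q) {
    int64_t pq = pidx(p, q);
    for (int64_t rs = 0; rs <= pq; ++rs) {
      double v = eri[(R_xlen_t)idx++];
      if (v == 0.0) continue;
      // decode r >= s from rs
      int r = (int)((std::sqrt(8.0 * rs + 1) - 1) / 2);
      while (pidx(r + 1, 0) <= rs) ++r;
      while (pidx(r, 0) > rs) --r;
      int s = (int)(rs - pidx(r, 0));
      // distinct permutations of (p,q,r,s) under 8-fold symmetry
      int perms[8][4] = {{p,q,r,s},{q,p,r,s},{p,q,s,r},{q,p,s,r},
                         {r,s,p,q},{s,r,p,q},{r,s,q,p},{s,r,q,p}};
      bool used[8] = {false};
      for (int a = 0; a < 8; ++a) {
        if (used[a]) continue;
        for (int b = a + 1; b < 8; ++b) {
          if (!used[b] && perms[b][0]==perms[a][0] && perms[b][1]==perms[a][1]
              && perms[b][2]==perms[a][2] && perms[b][3]==perms[a][3])
            used[b] = true;
        }
        int pp = perms[a][0], qq = perms[a][1], rr = perms[a][2], ss = perms[a][3];
        Jp[pp + n * qq] += D[rr + n * ss] * v;
        Kp[pp + n * rr] += D[qq + n * ss] * v;
      }
    }
   }
  return List::create(_["J"] = J, _["K"] = K);
}

// Coulomb-only builds for a list of symmetric densities (used for active
// space integral transforms): returns J_d for each density d.
// [[Rcpp::export]]
List cpp_j_multi(NumericVector eri, List Dlist) {
  int nd = Dlist.size();
  std::vector<const double*> Ds(nd);
  int n = 0;
  std::vector<NumericMatrix> Js;
  for (int d = 0; d < nd; ++d) {
    NumericMatrix D = Dlist[d];
    n = D.nrow();
    Ds[d] = REAL(D);
    Js.push_back(NumericMatrix(n, n));
  }
  std::vector<double*> Jp(nd);
  for (int d = 0; d < nd; ++d) Jp[d] = REAL(Js[d]);
  int64_t idx = 0;
  for (int p = 0; p < n; ++p)
   for (int q = 0; q <= p; ++q) {
    int64_t pq = pidx(p, q);
    int r = 0;
    for (int64_t rs = 0; rs <= pq; ++rs) {
      double v = eri[(R_xlen_t)idx++];
      if (v == 0.0) continue;
      while (pidx(r + 1, 0) <= rs) ++r;
      while (r > 0 && pidx(r, 0) > rs) --r;
      int s = (int)(rs - pidx(r, 0));
      double fpq = (p == q) ? 1.0 : 2.0;
      double frs = (r == s) ? 1.0 : 2.0;
      for (int d = 0; d < nd; ++d) {
        Jp[d][p + n * q] += frs * Ds[d][r + n * s] * v;
        if (pq != rs) Jp[d][r + n * s] += fpq * Ds[d][p + n * q] * v;
      }
    }
   }
  List out(nd);
  for (int d = 0; d < nd; ++d) {
    NumericMatrix J = Js[d];
    for (int p = 0; p < n; ++p)
      for (int q = 0; q < p; ++q) J(q, p) = J(p, q);
    out[d] = J;
  }
  return out;
}
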