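// McMurchie-Davidson integrals over contracted Cartesian Gaussians (s and p
// shells).  Shells arrive flattened from R: per-shell angular momentum,
// centers, and concatenated primitive exponents/coefficients (coefficients
// already include primitive and contracted normalization).  All quantities in
// atomic units.
#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

namespace {

struct Shell {
  int l;               // 0 (s) or 1 (p)
  double R[3];
  std::vector<double> alpha;
  std::vector<double> coef;
  int offset;          // index of first basis function (0-based)
  int nfun() const { return l == 0 ? 1 : 3; }
};

std::vector<Shell> unpack_shells(const List& basis) {
  IntegerVector l = basis["l"];
  NumericMatrix centers = basis["centers"];   // nshell x 3
  IntegerVector nprim = basis["nprim"];
  NumericVector alpha = basis["alpha"];
  NumericVector coef = basis["coef"];
  std::vector<Shell> shells(l.size());
  int pofs = 0, bofs = 0;
  for (int i = 0; i < l.size(); ++i) {
    Shell& s = shells[i];
    s.l = l[i];
    for (int k = 0; k < 3; ++k) s.R[k] = centers(i, k);
    s.alpha.assign(alpha.begin() + pofs, alpha.begin() + pofs + nprim[i]);
    s.coef.assign(coef.begin() + pofs, coef.begin() + pofs + nprim[i]);
    s.offset = bofs;
    pofs += nprim[i];
    bofs += s.nfun();
  }
  return shells;
}

int n_basis_of(const std::vector<Shell>& sh) {
  return sh.empty() ? 0 : sh.back().offset + sh.back().nfun();
}

// Cartesian exponents for function `f` of a shell: s -> (0,0,0); p -> e_f.
inline void cart_pows(int l, int f, int* n) {
  n[0] = n[1] = n[2] = 0;
  if (l == 1) n[f] = 1;
}

// Hermite expansion coefficient E_t^{ij} for exponents a,b separated by
// Qx = Ax - Bx.  Recursive; i,j <= 2 here so depth is trivial.
double Efun(int i, int j, int t, double Qx, double a, double b) {
  double p = a + b, q = a * b / p;
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return std::exp(-q * Qx * Qx);
  if (i > 0)
    return (1.0 / (2.0 * p)) * Efun(i - 1, j, t - 1, Qx, a, b) -
           (q * Qx / a) * Efun(i - 1, j, t, Qx, a, b) +
           (t + 1.0) * Efun(i - 1, j, t + 1, Qx, a, b);
  return (1.0 / (2.0 * p)) * Efun(i, j - 1, t - 1, Qx, a, b) +
         (q * Qx / b) * Efun(i, j - 1, t, Qx, a, b) +
         (t + 1.0) * Efun(i, j - 1, t + 1, Qx, a, b);
}

// Boys function F_m(x), m = 0..mmax, downward recursion from a series tail.
void boys(double x, int mmax, double* F) {
  if (x < 1e-13) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0) - x / (2.0 * m + 3.0);
    return;
  }
  if (x > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / x);
    for (int m = 0; m < mmax; ++m) F[m + 1] = (2.0 * m + 1.0) / (2.0 * x) * F[m];
    return;
  }
  double s = 0.0, term = 1.0 / (2.0 * mmax + 1.0);
  for (int k = 0; k < 500; ++k) {
    s += term;
    term *= 2.0 * x / (2.0 * mmax + 2.0 * k + 3.0);
    if (term < 1e-17 * s) break;
  }
  double ex = std::exp(-x);
  F[mmax] = s * ex;
  for (int m = mmax; m > 0; --m) F[m - 1] = (2.0 * x * F[m] + ex) / (2.0 * m - 1.0);
}

// Hermite Coulomb repulsion tensor R^0_{tuv}(p, PC); F already holds Boys
// values at p*|PC|^2.
double Rtuv(int t, int u, int v, int n, double p, const double* PC, const double* F) {
  if (t < 0 || u < 0 || v < 0) return 0.0;
  if (t == 0 && u == 0 && v == 0) {
    double f = 1.0;
    for (int k = 0; k < n; ++k) f *= -2.0 * p;
    return f * F[n];
  }
  if (t > 0)
    return (t - 1) * Rtuv(t - 2, u, v, n + 1, p, PC, F) + PC[0] * Rtuv(t - 1, u, v, n + 1, p, PC, F);
  if (u > 0)
    return (u - 1) * Rtuv(t, u - 2, v, n + 1, p, PC, F) + PC[1] * Rtuv(t, u - 1, v, n + 1, p, PC, F);
  return (v - 1) * Rtuv(t, u, v - 2, n + 1, p, PC, F) + PC[2] * Rtuv(t, u, v - 1, n + 1, p, PC, F);
}

// 1D overlap <i|j> for a primitive pair (no prefactor beyond E_0 sqrt(pi/p)).
inline double ov1d(int i, int j, double Qx, double a, double b) {
  return Efun(i, j, 0, Qx, a, b) * std::sqrt(M_PI / (a + b));
}

}  // namespace

// [[Rcpp::export(name = ".md_one_electron")]]
List md_one_electron(List basis) {
  std::vector<Shell> sh = unpack_shells(basis);
  int n = n_basis_of(sh);
  NumericMatrix S(n, n), T(n, n), DX(n, n), DY(n, n), DZ(n, n);
  int na[3], nb[3];
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      double Q[3] = {A.R[0] - B.R[0], A.R[1] - B.R[1], A.R[2] - B.R[2]};
      for (int fa = 0; fa < A.nfun(); ++fa)
        for (int fb = 0; fb < B.nfun(); ++fb) {
          cart_pows(A.l, fa, na);
          cart_pows(B.l, fb, nb);
          double s = 0, t = 0, dip[3] = {0, 0, 0};
          for (size_t pa = 0; pa < A.alpha.size(); ++pa)
            for (size_t pb = 0; pb < B.alpha.size(); ++pb) {
              double a = A.alpha[pa], b = B.alpha[pb];
              double cc = A.coef[pa] * B.coef[pb];
              double p = a + b;
              double P[3], o[3], m1[3];
              for (int k = 0; k < 3; ++k) {
                P[k] = (a * A.R[k] + b * B.R[k]) / p;
                o[k] = ov1d(na[k], nb[k], Q[k], a, b);
                // moment about the origin: (E_1 + P E_0) sqrt(pi/p)
                m1[k] = (Efun(na[k], nb[k], 1, Q[k], a, b) + P[k] * Efun(na[k], nb[k], 0, Q[k], a, b)) *
                        std::sqrt(M_PI / p);
              }
              s += cc * o[0] * o[1] * o[2];
              // kinetic via shifted-overlap formula, one dimension at a time
              double tk[3];
              for (int k = 0; k < 3; ++k) {
                int j = nb[k];
                double term = -2.0 * b * b * ov1d(na[k], j + 2, Q[k], a, b) +
                              b * (2.0 * j + 1.0) * ov1d(na[k], j, Q[k], a, b);
                if (j >= 2) term += -0.5 * j * (j - 1.0) * ov1d(na[k], j - 2, Q[k], a, b);
                tk[k] = term;
              }
              t += cc * (tk[0] * o[1] * o[2] + o[0] * tk[1] * o[2] + o[0] * o[1] * tk[2]);
              dip[0] += cc * m1[0] * o[1] * o[2];
              dip[1] += cc * o[0] * m1[1] * o[2];
              dip[2] += cc * o[0] * o[1] * m1[2];
            }
          int mu = A.offset + fa, nu = B.offset + fb;
          S(mu, nu) = S(nu, mu) = s;
          T(mu, nu) = T(nu, mu) = t;
          DX(mu, nu) = DX(nu, mu) = dip[0];
          DY(mu, nu) = DY(nu, mu) = dip[1];
          DZ(mu, nu) = DZ(nu, mu) = dip[2];
        }
    }
  return List::create(_["S"] = S, _["T"] = T, _["dx"] = DX, _["dy"] = DY, _["dz"] = DZ);
}

// Attraction matrix A_{mu nu} = <mu| sum_c q_c / |r - C_c| |nu>.  For nuclear
// attraction pass q = +Z and negate in R; for an ESP probe pass a single unit
// charge per point.
// [[Rcpp::export(name = ".md_point_charge")]]
NumericMatrix md_point_charge(List basis, NumericMatrix pts, NumericVector q) {
  std::vector<Shell> sh = unpack_shells(basis);
  int n = n_basis_of(sh);
  NumericMatrix V(n, n);
  int na[3], nb[3];
  double F[6];
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      double Q[3] = {A.R[0] - B.R[0], A.R[1] - B.R[1], A.R[2] - B.R[2]};
      for (int fa = 0; fa < A.nfun(); ++fa)
        for (int fb = 0; fb < B.nfun(); ++fb) {
          cart_pows(A.l, fa, na);
          cart_pows(B.l, fb, nb);
          int Ltot = A.l + B.l;
          double acc = 0.0;
          for (size_t pa = 0; pa < A.alpha.size(); ++pa)
            for (size_t pb = 0; pb < B.alpha.size(); ++pb) {
              double a = A.alpha[pa], b = B.alpha[pb];
              double cc = A.coef[pa] * B.coef[pb];
              double p = a + b;
              double P[3];
              for (int k = 0; k < 3; ++k) P[k] = (a * A.R[k] + b * B.R[k]) / p;
              // Hermite coefficients per dimension
              double E[3][3];  // dim, t
              int tmax[3];
              for (int k = 0; k < 3; ++k) {
                tmax[k] = na[k] + nb[k];
                for (int t = 0; t <= tmax[k]; ++t) E[k][t] = Efun(na[k], nb[k], t, Q[k], a, b);
              }
              double pref = cc * 2.0 * M_PI / p;
              for (int ic = 0; ic < pts.nrow(); ++ic) {
                double PC[3] = {P[0] - pts(ic, 0), P[1] - pts(ic, 1), P[2] - pts(ic, 2)};
                double r2 = PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2];
                boys(p * r2, Ltot, F);
                double s = 0.0;
                for (int t = 0; t <= tmax[0]; ++t)
                  for (int u = 0; u <= tmax[1]; ++u)
                    for (int v = 0; v <= tmax[2]; ++v)
                      s += E[0][t] * E[1][u] * E[2][v] * Rtuv(t, u, v, 0, p, PC, F);
                acc += pref * q[ic] * s;
              }
            }
          int mu = A.offset + fa, nu = B.offset + fb;
          V(mu, nu) = V(nu, mu) = acc;
        }
    }
  return V;
}

// Electrostatic potential of the density P (AO, physical normalization) at
// arbitrary points: V(r_k) = sum_{mu nu} P_{mu nu} (mu| 1/|r-r_k| |nu).
// [[Rcpp::export(name = ".md_esp_at_points")]]
NumericVector md_esp_at_points(List basis, NumericMatrix P, NumericMatrix pts) {
  std::vector<Shell> sh = unpack_shells(basis);
  int npt = pts.nrow();
  NumericVector V(npt);
  int na[3], nb[3];
  double F[6];
  for (size_t is = 0; is < sh.size(); ++is)
    for (size_t js = is; js < sh.size(); ++js) {
      const Shell &A = sh[is], &B = sh[js];
      double Q[3] = {A.R[0] - B.R[0], A.R[1] - B.R[1], A.R[2] - B.R[2]};
      for (int fa = 0; fa < A.nfun(); ++fa)
        for (int fb = (is == js ? fa : 0); fb < B.nfun(); ++fb) {
          cart_pows(A.l, fa, na);
          cart_pows(B.l, fb, nb);
          int mu = A.offset + fa, nu = B.offset + fb;
          double dens = (mu == nu) ? P(mu, nu) : P(mu, nu) + P(nu, mu);
          if (std::abs(dens) < 1e-14) continue;
          int Ltot = A.l + B.l;
          for (size_t pa = 0; pa < A.alpha.size(); ++pa)
            for (size_t pb = 0; pb < B.alpha.size(); ++pb) {
              double a = A.alpha[pa], b = B.alpha[pb];
              double cc = A.coef[pa] * B.coef[pb];
              double p = a + b;
              double P3[3];
              for (int k = 0; k < 3; ++k) P3[k] = (a * A.R[k] + b * B.R[k]) / p;
              double E[3][3];
              int tmax[3];
              for (int k = 0; k < 3; ++k) {
                tmax[k] = na[k] + nb[k];
                for (int t = 0; t <= tmax[k]; ++t) E[k][t] = Efun(na[k], nb[k], t, Q[k], a, b);
              }
              double pref = cc * dens * 2.0 * M_PI / p;
              for (int ic = 0; ic < npt; ++ic) {
                double PC[3] = {P3[0] - pts(ic, 0), P3[1] - pts(ic, 1), P3[2] - pts(ic, 2)};
                double r2 = PC[0] * PC[0] + PC[1] * PC[1] + PC[2] * PC[2];
                boys(p * r2, Ltot, F);
                double s = 0.0;
                for (int t = 0; t <= tmax[0]; ++t)
                  for (int u = 0; u <= tmax[1]; ++u)
                    for (int v = 0; v <= tmax[2]; ++v)
                      s += E[0][t] * E[1][u] * E[2][v] * Rtuv(t, u, v, 0, p, PC, F);
                V[ic] += pref * s;
              }
            }
        }
    }
  return V;
}

// Full ERI tensor (mu nu | la si), chemists' notation, returned as an
// n^2 x n^2 matrix with row index mu + n*nu (0-based) and column la + n*si.
// Computed over canonical shell quartets and scattered to all 8 images.
// [[Rcpp::export(name = ".md_eri")]]
NumericMatrix md_eri(List basis) {
  std::vector<Shell> sh = unpack_shells(basis);
  int n = n_basis_of(sh);
  NumericMatrix W(n * n, n * n);
  int ns = sh.size();
  int na[3], nb[3], nc[3], nd[3];
  double F[9];
  for (int is = 0; is < ns; ++is)
    for (int js = 0; js <= is; ++js)
      for (int ks = 0; ks <= is; ++ks)
        for (int ls = 0; ls <= (ks == is ? js : ks); ++ls) {
          const Shell &A = sh[is], &B = sh[js], &C = sh[ks], &D = sh[ls];
          double QAB[3] = {A.R[0] - B.R[0], A.R[1] - B.R[1], A.R[2] - B.R[2]};
          double QCD[3] = {C.R[0] - D.R[0], C.R[1] - D.R[1], C.R[2] - D.R[2]};
          int Ltot = A.l + B.l + C.l + D.l;
          for (int fa = 0; fa < A.nfun(); ++fa)
            for (int fb = 0; fb < B.nfun(); ++fb)
              for (int fc = 0; fc < C.nfun(); ++fc)
                for (int fd = 0; fd < D.nfun(); ++fd) {
                  cart_pows(A.l, fa, na);
                  cart_pows(B.l, fb, nb);
                  cart_pows(C.l, fc, nc);
                  cart_pows(D.l, fd, nd);
                  double val = 0.0;
                  for (size_t pa = 0; pa < A.alpha.size(); ++pa)
                    for (size_t pb = 0; pb < B.alpha.size(); ++pb) {
                      double a = A.alpha[pa], b = B.alpha[pb];
                      double p = a + b;
                      double Pp[3];
                      for (int k = 0; k < 3; ++k) Pp[k] = (a * A.R[k] + b * B.R[k]) / p;
                      double Eab[3][3];
                      int tm[3];
                      for (int k = 0; k < 3; ++k) {
                        tm[k] = na[k] + nb[k];
                        for (int t = 0; t <= tm[k]; ++t) Eab[k][t] = Efun(na[k], nb[k], t, QAB[k], a, b);
                      }
                      double cab = A.coef[pa] * B.coef[pb];
                      for (size_t pc = 0; pc < C.alpha.size(); ++pc)
                        for (size_t pd = 0; pd < D.alpha.size(); ++pd) {
                          double c = C.alpha[pc], d = D.alpha[pd];
                          double qq = c + d;
                          double Qq[3];
                          for (int k = 0; k < 3; ++k) Qq[k] = (c * C.R[k] + d * D.R[k]) / qq;
                          double Ecd[3][3];
                          int um[3];
                          for (int k = 0; k < 3; ++k) {
                            um[k] = nc[k] + nd[k];
                            for (int t = 0; t <= um[k]; ++t) Ecd[k][t] = Efun(nc[k], nd[k], t, QCD[k], c, d);
                          }
                          double alpha = p * qq / (p + qq);
                          double PQ[3] = {Pp[0] - Qq[0], Pp[1] - Qq[1], Pp[2] - Qq[2]};
                          double r2 = PQ[0] * PQ[0] + PQ[1] * PQ[1] + PQ[2] * PQ[2];
                          boys(alpha * r2, Ltot, F);
                          double pref = 2.0 * std::pow(M_PI, 2.5) / (p * qq * std::sqrt(p + qq));
                          double s = 0.0;
                          for (int t = 0; t <= tm[0]; ++t)
                            for (int u = 0; u <= tm[1]; ++u)
                              for (int v = 0; v <= tm[2]; ++v) {
                                double eab = Eab[0][t] * Eab[1][u] * Eab[2][v];
                                if (eab == 0.0) continue;
                                for (int tt = 0; tt <= um[0]; ++tt)
                                  for (int uu = 0; uu <= um[1]; ++uu)
                                    for (int vv = 0; vv <= um[2]; ++vv) {
                                      double ecd = Ecd[0][tt] * Ecd[1][uu] * Ecd[2][vv];
                                      if (ecd == 0.0) continue;
                                      double sgn = ((tt + uu + vv) % 2 == 0) ? 1.0 : -1.0;
                                      s += eab * ecd * sgn * Rtuv(t + tt, u + uu, v + vv, 0, alpha, PQ, F);
                                    }
                              }
                          val += cab * C.coef[pc] * D.coef[pd] * pref * s;
                        }
                    }
                  int mu = A.offset + fa, nu = B.offset + fb;
                  int la = C.offset + fc, si = D.offset + fd;
                  int perms[8][4] = {{mu, nu, la, si}, {nu, mu, la, si}, {mu, nu, si, la}, {nu, mu, si, la},
                                     {la, si, mu, nu}, {si, la, mu, nu}, {la, si, nu, mu}, {si, la, nu, mu}};
                  for (int pidx = 0; pidx < 8; ++pidx)
                    W(perms[pidx][0] + n * perms[pidx][1], perms[pidx][2] + n * perms[pidx][3]) = val;
                }
        }
  return W;
}

// AO values at grid points: N x n_basis matrix.
// [[Rcpp::export(name = ".md_ao_values")]]
NumericMatrix md_ao_values(List basis, NumericMatrix pts) {
  std::vector<Shell> sh = unpack_shells(basis);
  int n = n_basis_of(sh);
  int npt = pts.nrow();
  NumericMatrix out(npt, n);
  for (size_t is = 0; is < sh.size(); ++is) {
    const Shell& A = sh[is];
    for (int ic = 0; ic < npt; ++ic) {
      double d[3] = {pts(ic, 0) - A.R[0], pts(ic, 1) - A.R[1], pts(ic, 2) - A.R[2]};
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double rad = 0.0;
      for (size_t pa = 0; pa < A.alpha.size(); ++pa) {
        double e = A.alpha[pa] * r2;
        if (e < 46.0) rad += A.coef[pa] * std::exp(-e);
      }
      if (A.l == 0) {
        out(ic, A.offset) = rad;
      } else {
        out(ic, A.offset) = rad * d[0];
        out(ic, A.offset + 1) = rad * d[1];
        out(ic, A.offset + 2) = rad * d[2];
      }
    }
  }
  return out;
}

// Pointwise LDA (Slater exchange + VWN5 correlation): potential and energy
// density per volume in one pass.  Densities at or below rho_min give 0.
// [[Rcpp::export(name = ".lda_slater_vwn5")]]
List lda_slater_vwn5(NumericVector rho, double rho_min) {
  const double A = 0.0310907, b = 3.72744, c = 12.9352, x0 = -0.10498;
  const double Q = std::sqrt(4.0 * c - b * b);
  const double X0 = x0 * x0 + b * x0 + c;
  const double cx = std::pow(3.0 / M_PI, 1.0 / 3.0);
  int n = rho.size();
  NumericVector v(n), e(n);
  for (int i = 0; i < n; ++i) {
    double r = rho[i];
    if (r <= rho_min) continue;
    double rs = std::pow(3.0 / (4.0 * M_PI * r), 1.0 / 3.0);
    double x = std::sqrt(rs);
    double X = x * x + b * x + c;
    double atn = std::atan(Q / (2.0 * x + b));
    double lg = std::log((x - x0) * (x - x0) / X);
    double ec = A * (std::log(x * x / X) + 2.0 * b / Q * atn -
                     b * x0 / X0 * (lg + 2.0 * (b + 2.0 * x0) / Q * atn));
    double dX = 2.0 * x + b;
    double datn = -2.0 * Q / (Q * Q + dX * dX);
    double dec = A * (2.0 / x - dX / X + 2.0 * b / Q * datn -
                      b * x0 / X0 * (2.0 / (x - x0) - dX / X +
                                     2.0 * (b + 2.0 * x0) / Q * datn));
    double vc = ec - (x / 6.0) * dec;
    double r13 = std::cbrt(r);
    double vx = -cx * r13;
    double ex = -0.75 * cx * r13;
    v[i] = vx + vc;
    e[i] = r * (ex + ec);
  }
  return List::create(_["v"] = v, _["e"] = e);
}
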