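// Gaussian integral engine (McMurchie-Davidson scheme) over contracted
// Cartesian Gaussians, shells restricted to l <= 3 (s, p, d, f).
//
// Shell data arrive flattened from R:
//   shell_l[s], shell_atom[s] (0-based), shell_cx/cy/cz[s],
//   shell_ptr[s] (0-based offset into primitive arrays), shell_nprim[s],
//   prim_exp[], prim_coef[]  (coefficients already include the primitive
//   and contracted-shell normalisation; the per-component double-factorial
//   factor is applied here).
//
// Cartesian component ordering follows the Molden/GAMESS convention.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const int CART_LX[4][10] = {
  {0,0,0,0,0,0,0,0,0,0},
  {1,0,0,0,0,0,0,0,0,0},
  {2,0,0,1,1,0,0,0,0,0},
  {3,0,0,1,2,2,1,0,0,1}};
static const int CART_LY[4][10] = {
  {0,0,0,0,0,0,0,0,0,0},
  {0,1,0,0,0,0,0,0,0,0},
  {0,2,0,1,0,1,0,0,0,0},
  {0,3,0,2,1,0,0,1,2,1}};
static const int CART_LZ[4][10] = {
  {0,0,0,0,0,0,0,0,0,0},
  {0,0,1,0,0,0,0,0,0,0},
  {0,0,2,0,1,1,0,0,0,0},
  {0,0,3,0,0,1,2,2,1,1}};

static inline int ncart(int l) { return (l + 1) * (l + 2) / 2; }

static double dfact(int n) { // (2n-1)!! with dfact(0)=1
  double r = 1.0;
  for (int k = 2 * n - 1; k > 1; k -= 2) r *= k;
  return r;
}

// component normalisation ratio sqrt((2l-1)!! / ((2lx-1)!!(2ly-1)!!(2lz-1)!!))
static double comp_norm(int l, int lx, int ly, int lz) {
  return std::sqrt(dfact(l) / (dfact(lx) * dfact(ly) * dfact(lz)));
}

// ---------------------------------------------------------------------------
// Boys function F_m(T), m = 0..mmax
static void boys(int mmax, double T, double *F) {
  if (T > 35.0) {
    F[0] = 0.5 * std::sqrt(M_PI / T);
    double eT = std::exp(-T);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2 * m + 1) * F[m] - eT) / (2.0 * T);
  } else {
    // series for F_mmax, then downward recursion
    double eT = std::exp(-T);
    double t = 1.0 / (2.0 * mmax + 1.0);
    double s = t;
    for (int k = 1; k < 300; ++k) {
      t *= (2.0 * T) / (2.0 * mmax + 2.0 * k + 1.0);
      s += t;
      if (t < 1e-17 * s) break;
    }
    F[mmax] = eT * s;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * T * F[m + 1] + eT) / (2.0 * m + 1.0);
  }
}

// ---------------------------------------------------------------------------
// Hermite expansion coefficients E_t^{ij} (one dimension)
static double Ecoef(int i, int j, int t, double p, double PA, double PB,
                    double K) {
  if (t < 0 || t > i + j) return 0.0;
  if (i == 0 && j == 0 && t == 0) return K;
  if (i > 0) {
    return Ecoef(i - 1, j, t - 1, p, PA, PB, K) / (2.0 * p) +
           PA * Ecoef(i - 1, j, t, p, PA, PB, K) +
           (t + 1) * Ecoef(i - 1, j, t + 1, p, PA, PB, K);
  }
  return Ecoef(i, j - 1, t - 1, p, PA, PB, K) / (2.0 * p) +
         PB * Ecoef(i, j - 1, t, p, PA, PB, K) +
         (t + 1) * Ecoef(i, j - 1, t + 1, p, PA, PB, K);
}

// Hermite Coulomb repulsion tensor R^0_{tuv}; F = Boys values at T
static double Rtuv(int t, int u, int v, int n, double p, const double *F,
                   double X, double Y, double Z) {
  if (t == 0 && u == 0 && v == 0) {
    double f = F[n];
    double m = 1.0;
    for (int k = 0; k < n; ++k) m *= -2.0 * p;
    return m * f;
  }
  if (t > 0) {
    double r = X * Rtuv(t - 1, u, v, n + 1, p, F, X, Y, Z);
    if (t > 1) r += (t - 1) * Rtuv(t - 2, u, v, n + 1, p, F, X, Y, Z);
    return r;
  }
  if (u > 0) {
    double r = Y * Rtuv(t, u - 1, v, n + 1, p, F, X, Y, Z);
    if (u > 1) r += (u - 1) * Rtuv(t, u - 2, v, n + 1, p, F, X, Y, Z);
    return r;
  }
  double r = Z * Rtuv(t, u, v - 1, n + 1, p, F, X, Y, Z);
  if (v > 1) r += (v - 1) * Rtuv(t, u, v - 2, n + 1, p, F, X, Y, Z);
  return r;
}

// ---------------------------------------------------------------------------
struct Shell {
  int l, atom, nprim;
  double c[3];
  const double *exp_, *coef_;
};

static std::vector<Shell> unpack(const IntegerVector &sl,
                                 const IntegerVector &satom,
                                 const NumericMatrix &scenter,
                                 const IntegerVector &sptr,
                                 const IntegerVector &snp,
                                 const NumericVector &pexp,
                                 const NumericVector &pcoef) {
  std::vector<Shell> sh(sl.size());
  for (int s = 0; s < sl.size(); ++s) {
    sh[s].l = sl[s];
    sh[s].atom = satom[s];
    sh[s].nprim = snp[s];
    sh[s].c[0] = scenter(s, 0);
    sh[s].c[1] = scenter(s, 1);
    sh[s].c[2] = scenter(s, 2);
    sh[s].exp_ = &pexp[0] + sptr[s];
    sh[s].coef_ = &pcoef[0] + sptr[s];
  }
  return sh;
}

static int total_nao(const std::vector<Shell> &sh) {
  int n = 0;
  for (size_t s = 0; s < sh.size(); ++s) n += ncart(sh[s].l);
  return n;
}

// 1D primitive overlap <x^i e^-a | x^j e^-b> = E_0^{ij} sqrt(pi/p)
static inline double S1d(int i, int j, double p, double PA, double PB,
                         double K) {
  return Ecoef(i, j, 0, p, PA, PB, K) * std::sqrt(M_PI / p);
}

// [[Rcpp::export(name = ".cxx_overlap")]]
NumericMatrix cxx_overlap(IntegerVector sl, IntegerVector satom,
                          NumericMatrix scenter, IntegerVector sptr,
                          IntegerVector snp, NumericVector pexp,
                          NumericVector pcoef) {
  std::vector<Shell> sh = unpack(sl, satom, scenter, sptr, snp, pexp, pcoef);
  int nao = total_nao(sh);
  NumericMatrix S(nao, nao);
  int oa = 0;
  for (size_t a = 0; a < sh.size(); ++a) {
    int ob = 0;
    for (size_t b = 0; b < sh.size(); ++b) {
      if (b > a) { ob += ncart(sh[b].l); continue; }
      int la = sh[a].l, lb = sh[b].l;
      for (int pa = 0; pa < sh[a].nprim; ++pa)
        for (int pb = 0; pb < sh[b].nprim; ++pb) {
          double al = sh[a].exp_[pa], be = sh[b].exp_[pb];
          double p = al + be, mu = al * be / p;
          double cc = sh[a].coef_[pa] * sh[b].coef_[pb];
          double P[3], PA[3], PB[3], K[3];
          for (int d = 0; d < 3; ++d) {
            double AB = sh[a].c[d] - sh[b].c[d];
            P[d] = (al * sh[a].c[d] + be * sh[b].c[d]) / p;
            PA[d] = P[d] - sh[a].c[d];
            PB[d] = P[d] - sh[b].c[d];
            K[d] = std::exp(-mu * AB * AB);
          }
          for (int ia = 0; ia < ncart(la); ++ia)
            for (int ib = 0; ib < ncart(lb); ++ib) {
              double v = cc *
                comp_norm(la, CART_LX[la][ia], CART_LY[la][ia], CART_LZ[la][ia]) *
                comp_norm(lb, CART_LX[lb][ib], CART_LY[lb][ib], CART_LZ[lb][ib]) *
                S1d(CART_LX[la][ia], CART_LX[lb][ib], p, PA[0], PB[0], K[0]) *
                S1d(CART_LY[la][ia], CART_LY[lb][ib], p, PA[1], PB[1], K[1]) *
                S1d(CART_LZ[la][ia], CART_LZ[lb][ib], p, PA[2], PB[2], K[2]);
              S(oa + ia, ob + ib) += v;
            }
        }
      ob += ncart(sh[b].l);
    }
    oa += ncart(sh[a].l);
  }
  for (int i = 0; i < nao; ++i)
    for (int j = i + 1; j < nao; ++j) S(i, j) = S(j, i);
  return S;
}

// [[Rcpp::export(name = ".cxx_kinetic")]]
NumericMatrix cxx_kinetic(IntegerVector sl, IntegerVector satom,
                          NumericMatrix scenter, IntegerVector sptr,
                          IntegerVector snp, NumericVector pexp,
                          NumericVector pcoef) {
  std::vector<Shell> sh = unpack(sl, satom, scenter, sptr, snp, pexp, pcoef);
  int nao = total_nao(sh);
  NumericMatrix T(nao, nao);
  int oa = 0;
  for (size_t a = 0; a < sh.size(); ++a) {
    int ob = 0;
    for (size_t b = 0; b < sh.size(); ++b) {
      int la = sh[a].l, lb = sh[b].l;
      for (int pa = 0; pa < sh[a].nprim; ++pa)
        for (int pb = 0; pb < sh[b].nprim; ++pb) {
          double al = sh[a].exp_[pa], be = sh[b].exp_[pb];
          double p = al + be, mu = al * be / p;
          double cc = sh[a].coef_[pa] * sh[b].coef_[pb];
          double P[3], PA[3], PB[3], K[3];
          for (int d = 0; d < 3; ++d) {
            double AB = sh[a].c[d] - sh[b].c[d];
            P[d] = (al * sh[a].c[d] + be * sh[b].c[d]) / p;
            PA[d] = P[d] - sh[a].c[d];
            PB[d] = P[d] - sh[b].c[d];
            K[d] = std::exp(-mu * AB * AB);
          }
          for (int ia = 0; ia < ncart(la); ++ia)
            for (int ib = 0; ib < ncart(lb); ++ib) {
              int jx = CART_LX[lb][ib], jy = CART_LY[lb][ib],
                  jz = CART_LZ[lb][ib];
              int ix = CART_LX[la][ia], iy = CART_LY[la][ia],
                  iz = CART_LZ[la][ia];
              double sx[5], sy[5], sz[5]; // 1D overlaps at j-2..j+2
              for (int dj = -2; dj <= 2; ++dj) {
                sx[dj + 2] = (jx + dj < 0) ? 0.0
                  : S1d(ix, jx + dj, p, PA[0], PB[0], K[0]);
                sy[dj + 2] = (jy + dj < 0) ? 0.0
                  : S1d(iy, jy + dj, p, PA[1], PB[1], K[1]);
                sz[dj + 2] = (jz + dj < 0) ? 0.0
                  : S1d(iz, jz + dj, p, PA[2], PB[2], K[2]);
              }
              // kinetic = sum over dims of 1D kinetic x other-dim overlaps
              double tx = 0.5 * jx * (jx - 1) * sx[0] -
                          be * (2 * jx + 1) * sx[2] +
                          2.0 * be * be * sx[4];
              double ty = 0.5 * jy * (jy - 1) * sy[0] -
                          be * (2 * jy + 1) * sy[2] +
                          2.0 * be * be * sy[4];
              double tz = 0.5 * jz * (jz - 1) * sz[0] -
                          be * (2 * jz + 1) * sz[2] +
                          2.0 * be * be * sz[4];
              double v = -(tx * sy[2] * sz[2] + sx[2] * ty * sz[2] +
                           sx[2] * sy[2] * tz);
              v *= cc *
                comp_norm(la, ix, iy, iz) * comp_norm(lb, jx, jy, jz);
              T(oa + ia, ob + ib) += v;
            }
        }
      ob += ncart(sh[b].l);
    }
    oa += ncart(sh[a].l);
  }
  return T;
}

// [[Rcpp::export(name = ".cxx_nuclear")]]
NumericMatrix cxx_nuclear(IntegerVector sl, IntegerVector satom,
                          NumericMatrix scenter, IntegerVector sptr,
                          IntegerVector snp, NumericVector pexp,
                          NumericVector pcoef, NumericMatrix atpos,
                          NumericVector atchg) {
  std::vector<Shell> sh = unpack(sl, satom, scenter, sptr, snp, pexp, pcoef);
  int nao = total_nao(sh);
  NumericMatrix V(nao, nao);
  double F[16];
  int oa = 0;
  for (size_t a = 0; a < sh.size(); ++a) {
    int ob = 0;
    for (size_t b = 0; b < sh.size(); ++b) {
      if (b > a) { ob += ncart(sh[b].l); continue; }
      int la = sh[a].l, lb = sh[b].l, L = la + lb;
      for (int pa = 0; pa < sh[a].nprim; ++pa)
        for (int pb = 0; pb < sh[b].nprim; ++pb) {
          double al = sh[a].exp_[pa], be = sh[b].exp_[pb];
          double p = al + be, mu = al * be / p;
          double cc = sh[a].coef_[pa] * sh[b].coef_[pb];
          double P[3], PA[3], PB[3], K[3];
          for (int d = 0; d < 3; ++d) {
            double AB = sh[a].c[d] - sh[b].c[d];
            P[d] = (al * sh[a].c[d] + be * sh[b].c[d]) / p;
            PA[d] = P[d] - sh[a].c[d];
            PB[d] = P[d] - sh[b].c[d];
            K[d] = std::exp(-mu * AB * AB);
          }
          for (int ia = 0; ia < ncart(la); ++ia)
            for (int ib = 0; ib < ncart(lb); ++ib) {
              int ix = CART_LX[la][ia], iy = CART_LY[la][ia],
                  iz = CART_LZ[la][ia];
              int jx = CART_LX[lb][ib], jy = CART_LY[lb][ib],
                  jz = CART_LZ[lb][ib];
              double nrm = comp_norm(la, ix, iy, iz) *
                           comp_norm(lb, jx, jy, jz);
              // Hermite expansion of the charge distribution
              double v = 0.0;
              for (int nc = 0; nc < atpos.nrow(); ++nc) {
                double X = P[0] - atpos(nc, 0), Y = P[1] - atpos(nc, 1),
                       Z = P[2] - atpos(nc, 2);
                double T2 = p * (X * X + Y * Y + Z * Z);
                boys(L, T2, F);
                double acc = 0.0;
                for (int t = 0; t <= ix + jx; ++t) {
                  double ex = Ecoef(ix, jx, t, p, PA[0], PB[0], K[0]);
                  if (ex == 0.0) continue;
                  for (int u = 0; u <= iy + jy; ++u) {
                    double ey = Ecoef(iy, jy, u, p, PA[1], PB[1], K[1]);
                    if (ey == 0.0) continue;
                    for (int w = 0; w <= iz + jz; ++w) {
                      double ez = Ecoef(iz, jz, w, p, PA[2], PB[2], K[2]);
                      if (ez == 0.0) continue;
                      acc += ex * ey * ez *
                             Rtuv(t, u, w, 0, p, F, X, Y, Z);
                    }
                  }
                }
                v += -atchg[nc] * acc;
              }
              V(oa + ia, ob + ib) += cc * nrm * v * 2.0 * M_PI / p;
            }
        }
      ob += ncart(sh[b].l);
    }
    oa += ncart(sh[a].l);
  }
  for (int i = 0; i < nao; ++i)
    for (int j = i + 1; j < nao; ++j) V(i, j) = V(j, i);
  return V;
}

// [[Rcpp::export(name = ".cxx_eri")]]
NumericVector cxx_eri(IntegerVector sl, IntegerVector satom,
                      NumericMatrix scenter, IntegerVector sptr,
                      IntegerVector snp, NumericVector pexp,
                      NumericVector pcoef) {
  std::vector<Shell> sh = unpack(sl, satom, scenter, sptr, snp, pexp, pcoef);
  int ns = sh.size();
  int nao = total_nao(sh);
  std::vector<int> off(ns);
  {
    int o = 0;
    for (int s = 0; s < ns; ++s) { off[s] = o; o += ncart(sh[s].l); }
  }
  NumericVector out((R_xlen_t)nao * nao * nao * nao);
  double *G = &out[0];
  double F[32];
  R_xlen_t n1 = nao, n2 = n1 * nao, n3 = n2 * nao;

  for (int a = 0; a < ns; ++a)
    for (int b = 0; b <= a; ++b)
      for (int c = 0; c <= a; ++c)
        for (int d = 0; d <= (c == a ? b : c); ++d) {
          int la = sh[a].l, lb = sh[b].l, lc = sh[c].l, ld = sh[d].l;
          int na_ = ncart(la), nb_ = ncart(lb), nc_ = ncart(lc),
              nd_ = ncart(ld);
          int L = la + lb + lc + ld;
          std::vector<double> blk(na_ * nb_ * nc_ * nd_, 0.0);
          for (int pa = 0; pa < sh[a].nprim; ++pa)
            for (int pb = 0; pb < sh[b].nprim; ++pb) {
              double al = sh[a].exp_[pa], be = sh[b].exp_[pb];
              double p = al + be, mu = al * be / p;
              double P[3], PA[3], PB[3], Kab[3];
              double cab = sh[a].coef_[pa] * sh[b].coef_[pb];
              double r2ab = 0.0;
              for (int dd = 0; dd < 3; ++dd) {
                double AB = sh[a].c[dd] - sh[b].c[dd];
                r2ab += AB * AB;
                P[dd] = (al * sh[a].c[dd] + be * sh[b].c[dd]) / p;
                PA[dd] = P[dd] - sh[a].c[dd];
                PB[dd] = P[dd] - sh[b].c[dd];
                Kab[dd] = std::exp(-mu * AB * AB);
              }
              if (mu * r2ab > 46.0) continue; // negligible pair
              for (int pc = 0; pc < sh[c].nprim; ++pc)
                for (int pd = 0; pd < sh[d].nprim; ++pd) {
                  double ga = sh[c].exp_[pc], de = sh[d].exp_[pd];
                  double q = ga + de, nu = ga * de / q;
                  double Q[3], QC[3], QD[3], Kcd[3];
                  double ccd = sh[c].coef_[pc] * sh[d].coef_[pd];
                  double r2cd = 0.0;
                  for (int dd = 0; dd < 3; ++dd) {
                    double CD = sh[c].c[dd] - sh[d].c[dd];
                    r2cd += CD * CD;
                    Q[dd] = (ga * sh[c].c[dd] + de * sh[d].c[dd]) / q;
                    QC[dd] = Q[dd] - sh[c].c[dd];
                    QD[dd] = Q[dd] - sh[d].c[dd];
                    Kcd[dd] = std::exp(-nu * CD * CD);
                  }
                  if (nu * r2cd > 46.0) continue;
                  double alpha = p * q / (p + q);
                  double X = P[0] - Q[0], Y = P[1] - Q[1], Z = P[2] - Q[2];
                  double T2 = alpha * (X * X + Y * Y + Z * Z);
                  boys(L, T2, F);
                  double pref = 2.0 * std::pow(M_PI, 2.5) /
                                (p * q * std::sqrt(p + q)) * cab * ccd;
                  int idx = 0;
                  for (int ia = 0; ia < na_; ++ia)
                  for (int ib = 0; ib < nb_; ++ib)
                  for (int ic = 0; ic < nc_; ++ic)
                  for (int id = 0; id < nd_; ++id, ++idx) {
                    int ax = CART_LX[la][ia], ay = CART_LY[la][ia],
                        az = CART_LZ[la][ia];
                    int bx = CART_LX[lb][ib], by = CART_LY[lb][ib],
                        bz = CART_LZ[lb][ib];
                    int cx = CART_LX[lc][ic], cy = CART_LY[lc][ic],
                        cz = CART_LZ[lc][ic];
                    int dx = CART_LX[ld][id], dy = CART_LY[ld][id],
                        dz = CART_LZ[ld][id];
                    double nrm = comp_norm(la, ax, ay, az) *
                                 comp_norm(lb, bx, by, bz) *
                                 comp_norm(lc, cx, cy, cz) *
                                 comp_norm(ld, dx, dy, dz);
                    double acc = 0.0;
                    for (int t = 0; t <= ax + bx; ++t) {
                      double e1 = Ecoef(ax, bx, t, p, PA[0], PB[0], Kab[0]);
                      if (e1 == 0.0) continue;
                      for (int u = 0; u <= ay + by; ++u) {
                        double e2 = Ecoef(ay, by, u, p, PA[1], PB[1], Kab[1]);
                        if (e2 == 0.0) continue;
                        for (int w = 0; w <= az + bz; ++w) {
                          double e3 =
                            Ecoef(az, bz, w, p, PA[2], PB[2], Kab[2]);
                          if (e3 == 0.0) continue;
                          double ebra = e1 * e2 * e3;
                          for (int tt = 0; tt <= cx + dx; ++tt) {
                            double f1 =
                              Ecoef(cx, dx, tt, q, QC[0], QD[0], Kcd[0]);
                            if (f1 == 0.0) continue;
                            for (int uu = 0; uu <= cy + dy; ++uu) {
                              double f2 =
                                Ecoef(cy, dy, uu, q, QC[1], QD[1], Kcd[1]);
                              if (f2 == 0.0) continue;
                              for (int ww = 0; ww <= cz + dz; ++ww) {
                                double f3 = Ecoef(cz, dz, ww, q, QC[2],
                                                  QD[2], Kcd[2]);
                                if (f3 == 0.0) continue;
                                double sgn =
                                  ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
                                acc += ebra * f1 * f2 * f3 * sgn *
                                       Rtuv(t + tt, u + uu, w + ww, 0,
                                            alpha, F, X, Y, Z);
                              }
                            }
                          }
                        }
                      }
                    }
                    blk[idx] += pref * nrm * acc;
                  }
                }
            }
          // scatter block with 8-fold symmetry
          int idx = 0;
          for (int ia = 0; ia < na_; ++ia)
          for (int ib = 0; ib < nb_; ++ib)
          for (int ic = 0; ic < nc_; ++ic)
          for (int id = 0; id < nd_; ++id, ++idx) {
            R_xlen_t i = off[a] + ia, j = off[b] + ib, k = off[c] + ic,
                     l = off[d] + id;
            double v = blk[idx];
            G[i + j * n1 + k * n2 + l * n3] = v;
            G[j + i * n1 + k * n2 + l * n3] = v;
            G[i + j * n1 + l * n2 + k * n3] = v;
            G[j + i * n1 + l * n2 + k * n3] = v;
            G[k + l * n1 + i * n2 + j * n3] = v;
            G[l + k * n1 + i * n2 + j * n3] = v;
            G[k + l * n1 + j * n2 + i * n3] = v;
            G[l + k * n1 + j * n2 + i * n3] = v;
          }
        }
  out.attr("dim") =
    IntegerVector::create(nao, nao, nao, nao);
  return out;
}

// ---------------------------------------------------------------------------
// AO amplitudes (and optionally Cartesian gradients) at arbitrary points.
// Returns list(v = npt x nao [, gx, gy, gz]).
// [[Rcpp::export(name = ".cxx_eval_ao")]]
List cxx_eval_ao(IntegerVector sl, IntegerVector satom, NumericMatrix scenter,
                 IntegerVector sptr, IntegerVector snp, NumericVector pexp,
                 NumericVector pcoef, NumericMatrix pts, bool deriv) {
  std::vector<Shell> sh = unpack(sl, satom, scenter, sptr, snp, pexp, pcoef);
  int nao = total_nao(sh);
  int npt = pts.nrow();
  NumericMatrix V(npt, nao), GX, GY, GZ;
  if (deriv) {
    GX = NumericMatrix(npt, nao);
    GY = NumericMatrix(npt, nao);
    GZ = NumericMatrix(npt, nao);
  }
  int oa = 0;
  for (size_t s = 0; s < sh.size(); ++s) {
    int l = sh[s].l, nc = ncart(l);
    for (int g = 0; g < npt; ++g) {
      double dx = pts(g, 0) - sh[s].c[0];
      double dy = pts(g, 1) - sh[s].c[1];
      double dz = pts(g, 2) - sh[s].c[2];
      double r2 = dx * dx + dy * dy + dz * dz;
      double rad = 0.0, radp = 0.0;
      for (int p = 0; p < sh[s].nprim; ++p) {
        double e = sh[s].coef_[p] * std::exp(-sh[s].exp_[p] * r2);
        rad += e;
        if (deriv) radp += -2.0 * sh[s].exp_[p] * e;
      }
      for (int ic = 0; ic < nc; ++ic) {
        int lx = CART_LX[l][ic], ly = CART_LY[l][ic], lz = CART_LZ[l][ic];
        double nrm = comp_norm(l, lx, ly, lz);
        double px = 1.0, py = 1.0, pz = 1.0;
        for (int k = 0; k < lx; ++k) px *= dx;
        for (int k = 0; k < ly; ++k) py *= dy;
        for (int k = 0; k < lz; ++k) pz *= dz;
        double poly = px * py * pz;
        V(g, oa + ic) = nrm * poly * rad;
        if (deriv) {
          double dpx = (lx > 0) ? lx * (lx > 1 ? px / dx : 1.0) * py * pz
                                : 0.0;
          double dpy = (ly > 0) ? ly * px * (ly > 1 ? py / dy : 1.0) * pz
                                : 0.0;
          double dpz = (lz > 0) ? lz * px * py * (lz > 1 ? pz / dz : 1.0)
                                : 0.0;
          // guard dx==0 with lx>1: px/dx would be 0/0; recompute safely
          if (lx > 1 && dx == 0.0) dpx = 0.0;
          if (ly > 1 && dy == 0.0) dpy = 0.0;
          if (lz > 1 && dz == 0.0) dpz = 0.0;
          if (lx == 1) dpx = py * pz;
          if (ly == 1) dpy = px * pz;
          if (lz == 1) dpz = px * py;
          GX(g, oa + ic) = nrm * (dpx * rad + poly * dx * radp);
          GY(g, oa + ic) = nrm * (dpy * rad + poly * dy * radp);
          GZ(g, oa + ic) = nrm * (dpz * rad + poly * dz * radp);
        }
      }
    }
    oa += nc;
  }
  if (deriv)
    return List::create(_["v"] = V, _["gx"] = GX, _["gy"] = GY,
                        _["gz"] = GZ);
  return List::create(_["v"] = V);
}
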