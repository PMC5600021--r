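// Gaussian-basis molecular integrals (McMurchie-Davidson scheme) and
// numerical-grid support for the monomer SCF engine.
//
// Shells are contracted Cartesian Gaussians.  The R side passes, per shell:
// angular momentum l, centre (bohr) and primitive exponents/coefficients;
// coefficients are final coefficients for *unnormalized* Cartesian
// primitives of type (l,0,0), normalized so that the contracted (l,0,0)
// component has unit self-overlap.  Individual Cartesian components are
// rescaled here by sqrt((2l-1)!! / prod (2li-1)!!) so every component is
// individually normalized (the "6d" convention).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double PI = 3.14159265358979323846;

struct Shell {
  int l;
  arma::vec3 A;
  std::vector<double> exps;
  std::vector<double> coefs;
  int offset;   // first basis-function index of this shell
};

static inline int ncart(int l) { return (l + 1) * (l + 2) / 2; }

static double dfact(int n) { // (2n-1)!! style: dfact(n) = n!! with dfact(<=0)=1
  double r = 1.0;
  for (int k = n; k > 1; k -= 2) r *= k;
  return r;
}

// Cartesian component exponents in lexicographic order (x first)
static void comps(int l, std::vector<std::array<int,3>>& out) {
  out.clear();
  for (int lx = l; lx >= 0; --lx)
    for (int ly = l - lx; ly >= 0; --ly)
      out.push_back({lx, ly, l - lx - ly});
}

static double comp_factor(int l, int lx, int ly, int lz) {
  return std::sqrt(dfact(2 * l - 1) /
                   (dfact(2 * lx - 1) * dfact(2 * ly - 1) * dfact(2 * lz - 1)));
}

static std::vector<Shell> parse_shells(const List& shells) {
  int n = shells.size();
  std::vector<Shell> out(n);
  int off = 0;
  for (int i = 0; i < n; ++i) {
    List s = shells[i];
    Shell sh;
    sh.l = as<int>(s["l"]);
    NumericVector c = s["center"];
    sh.A = {c[0], c[1], c[2]};
    sh.exps = as<std::vector<double>>(s["exps"]);
    sh.coefs = as<std::vector<double>>(s["coefs"]);
    sh.offset = off;
    off += ncart(sh.l);
    out[i] = sh;
  }
  return out;
}

static int nbf_total(const std::vector<Shell>& sh) {
  if (sh.empty()) return 0;
  return sh.back().offset + ncart(sh.back().l);
}

// ---------------------------------------------------------------- Boys F_m(t)
static void boys(int mmax, double t, std::vector<double>& F) {
  F.assign(mmax + 1, 0.0);
  if (t < 1e-14) {
    for (int m = 0; m <= mmax; ++m) F[m] = 1.0 / (2.0 * m + 1.0);
    return;
  }
  if (t < 35.0) {
    // series for F_mmax, then stable downward recursion
    double et = std::exp(-t);
    double c = 1.0 / (2.0 * mmax + 1.0), sum = c;
    for (int k = 1; k < 300; ++k) {
      c *= 2.0 * t / (2.0 * mmax + 2.0 * k + 1.0);
      sum += c;
      if (c < 1e-17 * sum) break;
    }
    F[mmax] = et * sum;
    for (int m = mmax - 1; m >= 0; --m)
      F[m] = (2.0 * t * F[m + 1] + et) / (2.0 * m + 1.0);
  } else {
    F[0] = 0.5 * std::sqrt(PI / t);
    double et = std::exp(-t);
    for (int m = 0; m < mmax; ++m)
      F[m + 1] = ((2.0 * m + 1.0) * F[m] - et) / (2.0 * t);
  }
}

// ------------------------------------------------- Hermite expansion E(i,j,t)
// Table for one dimension: indices i in 0..l1, j in 0..l2, t in 0..i+j
struct ETab {
  int l1, l2;
  std::vector<double> v; // (l1+1)*(l2+1)*(l1+l2+1)
  double& at(int i, int j, int t) { return v[(i * (l2 + 1) + j) * (l1 + l2 + 1) + t]; }
  double get(int i, int j, int t) const {
    if (t < 0 || t > i + j) return 0.0;
    return v[(i * (l2 + 1) + j) * (l1 + l2 + 1) + t];
  }
};

static void fillE(int l1, int l2, double a, double b, double AB, ETab& E) {
  double p = a + b, mu = a * b / p;
  double PA = -b / p * AB; // P - A where AB = A - B
  double PB = a / p * AB;  // P - B
  E.l1 = l1; E.l2 = l2;
  E.v.assign((l1 + 1) * (l2 + 1) * (l1 + l2 + 1), 0.0);
  E.at(0, 0, 0) = std::exp(-mu * AB * AB);
  for (int i = 0; i <= l1; ++i) {
    for (int j = 0; j <= l2; ++j) {
      if (i == 0 && j == 0) continue;
      for (int t = 0; t <= i + j; ++t) {
        double val = 0.0;
        if (i > 0) {
          val = (1.0 / (2.0 * p)) * E.get(i - 1, j, t - 1)
              + PA * E.get(i - 1, j, t)
              + (t + 1.0) * E.get(i - 1, j, t + 1);
        } else {
          val = (1.0 / (2.0 * p)) * E.get(i, j - 1, t - 1)
              + PB * E.get(i, j - 1, t)
              + (t + 1.0) * E.get(i, j - 1, t + 1);
        }
        E.at(i, j, t) = val;
      }
    }
  }
}

// --------------------------------------------- Hermite Coulomb tensor R_tuv
// R_tuv = (d/dax)^t (d/day)^u (d/daz)^v [(-2p)^0 F_0(p |a|^2)]-style tensor,
// computed for all t+u+v <= L; a = P - C.
struct RTab {
  int L;
  std::vector<double> v; // (L+1)^3, only t+u+v<=L valid
  double get(int t, int u, int w) const {
    if (t < 0 || u < 0 || w < 0) return 0.0;
    return v[(t * (L + 1) + u) * (L + 1) + w];
  }
  double& at(int t, int u, int w) { return v[(t * (L + 1) + u) * (L + 1) + w]; }
};

static void fillR(int L, double p, const arma::vec3& a, RTab& R) {
  R.L = L;
  R.v.assign((L + 1) * (L + 1) * (L + 1), 0.0);
  double r2 = a[0]*a[0] + a[1]*a[1] + a[2]*a[2];
  std::vector<double> F;
  boys(L, p * r2, F);
  // Rn[n][t][u][v]; build by decreasing n
  std::vector<std::vector<double>> Rn(L + 1);
  int cube = (L + 1) * (L + 1) * (L + 1);
  for (int n = 0; n <= L; ++n) Rn[n].assign(cube, 0.0);
  auto IDX = [L](int t, int u, int w) { return (t * (L + 1) + u) * (L + 1) + w; };
  for (int n = 0; n <= L; ++n) Rn[n][IDX(0,0,0)] = std::pow(-2.0 * p, n) * F[n];
  for (int tot = 1; tot <= L; ++tot) {
    for (int t = 0; t <= tot; ++t)
      for (int u = 0; u <= tot - t; ++u) {
        int w = tot - t - u;
        for (int n = 0; n <= L - tot; ++n) {
          double val;
          if (t > 0) {
            val = a[0] * Rn[n + 1][IDX(t - 1, u, w)]
                + (t - 1 > 0 ? (t - 1) * Rn[n + 1][IDX(t - 2, u, w)] : 0.0);
          } else if (u > 0) {
            val = a[1] * Rn[n + 1][IDX(t, u - 1, w)]
                + (u - 1 > 0 ? (u - 1) * Rn[n + 1][IDX(t, u - 2, w)] : 0.0);
          } else {
            val = a[2] * Rn[n + 1][IDX(t, u, w - 1)]
                + (w - 1 > 0 ? (w - 1) * Rn[n + 1][IDX(t, u, w - 2)] : 0.0);
          }
          Rn[n][IDX(t, u, w)] = val;
        }
      }
  }
  for (int t = 0; t <= L; ++t)
    for (int u = 0; u <= L - t; ++u)
      for (int w = 0; w <= L - t - u; ++w)
        R.at(t, u, w) = Rn[0][IDX(t, u, w)];
}

// ------------------------------------------------------------- one-electron
// [[Rcpp::export]]
List cpp_one_ints(List shells_in) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nbf = nbf_total(sh);
  arma::mat S(nbf, nbf, arma::fill::zeros), T(nbf, nbf, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for (size_t I = 0; I < sh.size(); ++I) {
    for (size_t J = 0; J <= I; ++J) {
      const Shell &A = sh[I], &B = sh[J];
      comps(A.l, ca); comps(B.l, cb);
      arma::vec3 AB = A.A - B.A;
      int na = ca.size(), nb = cb.size();
      arma::mat Sblk(na, nb, arma::fill::zeros), Tblk(na, nb, arma::fill::zeros);
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb], p = a + b;
          double cc = A.coefs[pa] * B.coefs[pb];
          double pref = std::pow(PI / p, 1.5);
          ETab Ex, Ey, Ez;
          // fill to l+2 in j for kinetic
          fillE(A.l, B.l + 2, a, b, AB[0], Ex);
          fillE(A.l, B.l + 2, a, b, AB[1], Ey);
          fillE(A.l, B.l + 2, a, b, AB[2], Ez);
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
              int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
              double sx = Ex.get(l1, l2, 0), sy = Ey.get(m1, m2, 0), sz = Ez.get(n1, n2, 0);
              double f = comp_factor(A.l, l1, m1, n1) * comp_factor(B.l, l2, m2, n2);
              Sblk(ia, ib) += cc * f * pref * sx * sy * sz;
              auto D2 = [&](ETab& E, int i, int j) {
                double t1 = j >= 2 ? j * (j - 1.0) * E.get(i, j - 2, 0) : 0.0;
                double t2 = -2.0 * b * (2.0 * j + 1.0) * E.get(i, j, 0);
                double t3 = 4.0 * b * b * E.get(i, j + 2, 0);
                return t1 + t2 + t3;
              };
              double kx = D2(Ex, l1, l2) * sy * sz;
              double ky = sx * D2(Ey, m1, m2) * sz;
              double kz = sx * sy * D2(Ez, n1, n2);
              Tblk(ia, ib) += cc * f * pref * (-0.5) * (kx + ky + kz);
            }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          S(A.offset + ia, B.offset + ib) = Sblk(ia, ib);
          S(B.offset + ib, A.offset + ia) = Sblk(ia, ib);
          T(A.offset + ia, B.offset + ib) = Tblk(ia, ib);
          T(B.offset + ib, A.offset + ia) = Tblk(ia, ib);
        }
    }
  }
  return List::create(_["S"] = S, _["T"] = T);
}

// Generic Coulomb 1e matrix: sum_k q_k <p| 1/|r - C_k| |q>  (q_k = +Z for
// nuclear attraction the caller negates or passes -Z).
static arma::mat coulomb_1e(const std::vector<Shell>& sh,
                            const arma::mat& pts, const arma::vec& q) {
  int nbf = nbf_total(sh);
  arma::mat V(nbf, nbf, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for (size_t I = 0; I < sh.size(); ++I)
    for (size_t J = 0; J <= I; ++J) {
      const Shell &A = sh[I], &B = sh[J];
      comps(A.l, ca); comps(B.l, cb);
      arma::vec3 AB = A.A - B.A;
      int na = ca.size(), nb = cb.size();
      int L = A.l + B.l;
      arma::mat blk(na, nb, arma::fill::zeros);
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb], p = a + b;
          double cc = A.coefs[pa] * B.coefs[pb];
          arma::vec3 P = (a * A.A + b * B.A) / p;
          ETab Ex, Ey, Ez;
          fillE(A.l, B.l, a, b, AB[0], Ex);
          fillE(A.l, B.l, a, b, AB[1], Ey);
          fillE(A.l, B.l, a, b, AB[2], Ez);
          double pref = 2.0 * PI / p;
          for (size_t k = 0; k < q.n_elem; ++k) {
            arma::vec3 C = pts.col(k);
            RTab R;
            arma::vec3 PC = P - C;
            fillR(L, p, PC, R);
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
                int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
                double f = comp_factor(A.l, l1, m1, n1) * comp_factor(B.l, l2, m2, n2);
                double s = 0.0;
                for (int t = 0; t <= l1 + l2; ++t) {
                  double ex = Ex.get(l1, l2, t);
                  if (ex == 0.0) continue;
                  for (int u = 0; u <= m1 + m2; ++u) {
                    double ey = Ey.get(m1, m2, u);
                    if (ey == 0.0) continue;
                    for (int w = 0; w <= n1 + n2; ++w)
                      s += ex * ey * Ez.get(n1, n2, w) * R.get(t, u, w);
                  }
                }
                blk(ia, ib) += cc * f * pref * q[k] * s;
              }
          }
        }
      for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          V(A.offset + ia, B.offset + ib) = blk(ia, ib);
          V(B.offset + ib, A.offset + ia) = blk(ia, ib);
        }
    }
  return V;
}

// Nuclear attraction matrix: -sum_k Z_k <p|1/|r-R_k||q>
// [[Rcpp::export]]
arma::mat cpp_nuclear(List shells_in, arma::mat pos, arma::vec Z) {
  std::vector<Shell> sh = parse_shells(shells_in);
  return coulomb_1e(sh, pos, -Z);
}

// Potential integrals <p|1/|r-C||q> for each point: cube nbf x nbf x npts
// [[Rcpp::export]]
arma::cube cpp_point_potential(List shells_in, arma::mat pts) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nbf = nbf_total(sh), np = pts.n_cols;
  arma::cube out(nbf, nbf, np);
  for (int k = 0; k < np; ++k) {
    arma::vec q(1); q[0] = 1.0;
    out.slice(k) = coulomb_1e(sh, pts.cols(k, k), q);
  }
  return out;
}

// Field integrals <p|(r-C)/|r-C|^3|q>; returns cube nbf x nbf x 3*npts
// (slices 3k, 3k+1, 3k+2 are the x,y,z components for point k).
// [[Rcpp::export]]
arma::cube cpp_point_field(List shells_in, arma::mat pts) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nbf = nbf_total(sh), np = pts.n_cols;
  arma::cube out(nbf, nbf, 3 * np, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for (size_t I = 0; I < sh.size(); ++I)
    for (size_t J = 0; J <= I; ++J) {
      const Shell &A = sh[I], &B = sh[J];
      comps(A.l, ca); comps(B.l, cb);
      arma::vec3 AB = A.A - B.A;
      int na = ca.size(), nb = cb.size();
      int L = A.l + B.l + 1;
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb], p = a + b;
          double cc = A.coefs[pa] * B.coefs[pb];
          arma::vec3 P = (a * A.A + b * B.A) / p;
          ETab Ex, Ey, Ez;
          fillE(A.l, B.l, a, b, AB[0], Ex);
          fillE(A.l, B.l, a, b, AB[1], Ey);
          fillE(A.l, B.l, a, b, AB[2], Ez);
          double pref = 2.0 * PI / p;
          for (int k = 0; k < np; ++k) {
            arma::vec3 C = pts.col(k);
            RTab R;
            arma::vec3 PC = P - C;
            fillR(L, p, PC, R);
            for (int ia = 0; ia < na; ++ia)
              for (int ib = 0; ib < nb; ++ib) {
                int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
                int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
                double f = comp_factor(A.l, l1, m1, n1) * comp_factor(B.l, l2, m2, n2);
                double sx = 0.0, sy = 0.0, sz = 0.0;
                for (int t = 0; t <= l1 + l2; ++t)
                  for (int u = 0; u <= m1 + m2; ++u)
                    for (int w = 0; w <= n1 + n2; ++w) {
                      double e = Ex.get(l1, l2, t) * Ey.get(m1, m2, u) * Ez.get(n1, n2, w);
                      if (e == 0.0) continue;
                      sx += e * R.get(t + 1, u, w);
                      sy += e * R.get(t, u + 1, w);
                      sz += e * R.get(t, u, w + 1);
                    }
                // d/dCx V = -d/dax R ... ; field component = -dV/dC sign works out to -pref*s
                double vx = -cc * f * pref * sx;
                double vy = -cc * f * pref * sy;
                double vz = -cc * f * pref * sz;
                out(A.offset + ia, B.offset + ib, 3 * k + 0) += vx;
                out(A.offset + ia, B.offset + ib, 3 * k + 1) += vy;
                out(A.offset + ia, B.offset + ib, 3 * k + 2) += vz;
                // for I == J the ia/ib loops already cover the full block
                if (I != J) {
                  out(B.offset + ib, A.offset + ia, 3 * k + 0) += vx;
                  out(B.offset + ib, A.offset + ia, 3 * k + 1) += vy;
                  out(B.offset + ib, A.offset + ia, 3 * k + 2) += vz;
                }
              }
          }
        }
    }
  return out;
}

// Dipole moment integrals <p| r |q> about a given origin; cube nbf x nbf x 3
// [[Rcpp::export]]
arma::cube cpp_dipole(List shells_in, arma::vec origin) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nbf = nbf_total(sh);
  arma::cube out(nbf, nbf, 3, arma::fill::zeros);
  std::vector<std::array<int,3>> ca, cb;
  for (size_t I = 0; I < sh.size(); ++I)
    for (size_t J = 0; J <= I; ++J) {
      const Shell &A = sh[I], &B = sh[J];
      comps(A.l, ca); comps(B.l, cb);
      arma::vec3 AB = A.A - B.A;
      int na = ca.size(), nb = cb.size();
      for (size_t pa = 0; pa < A.exps.size(); ++pa)
        for (size_t pb = 0; pb < B.exps.size(); ++pb) {
          double a = A.exps[pa], b = B.exps[pb], p = a + b;
          double cc = A.coefs[pa] * B.coefs[pb];
          double pref = std::pow(PI / p, 1.5);
          arma::vec3 P = (a * A.A + b * B.A) / p;
          ETab Ex, Ey, Ez;
          fillE(A.l, B.l, a, b, AB[0], Ex);
          fillE(A.l, B.l, a, b, AB[1], Ey);
          fillE(A.l, B.l, a, b, AB[2], Ez);
          for (int ia = 0; ia < na; ++ia)
            for (int ib = 0; ib < nb; ++ib) {
              int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
              int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
              double f = comp_factor(A.l, l1, m1, n1) * comp_factor(B.l, l2, m2, n2);
              double s0x = Ex.get(l1, l2, 0), s0y = Ey.get(m1, m2, 0), s0z = Ez.get(n1, n2, 0);
              // <x> about origin: E1 + (P - origin) E0 per dimension
              double mx = (Ex.get(l1, l2, 1) + (P[0] - origin[0]) * s0x) * s0y * s0z;
              double my = s0x * (Ey.get(m1, m2, 1) + (P[1] - origin[1]) * s0y) * s0z;
              double mz = s0x * s0y * (Ez.get(n1, n2, 1) + (P[2] - origin[2]) * s0z);
              double w = cc * f * pref;
              out(A.offset + ia, B.offset + ib, 0) += w * mx;
              out(A.offset + ia, B.offset + ib, 1) += w * my;
              out(A.offset + ia, B.offset + ib, 2) += w * mz;
              // for I == J the ia/ib loops already cover the full block
              if (I != J) {
                out(B.offset + ib, A.offset + ia, 0) += w * mx;
                out(B.offset + ib, A.offset + ia, 1) += w * my;
                out(B.offset + ib, A.offset + ia, 2) += w * mz;
              }
            }
        }
    }
  return out;
}

// ------------------------------------------------------------------- ERIs
// Full (pq|rs) tensor in chemists' notation, returned as a flat vector with
// index p + nbf*(q + nbf*(r + nbf*s)).  Intended for small union bases.
// [[Rcpp::export]]
NumericVector cpp_eri(List shells_in) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nbf = nbf_total(sh);
  NumericVector out((R_xlen_t)nbf * nbf * nbf * nbf);
  double* G = out.begin();
  std::vector<std::array<int,3>> ca, cb, cc_, cd;
  int nsh = sh.size();
  auto put = [&](int p, int q, int r, int s, double v) {
    R_xlen_t N = nbf;
    G[p + N*(q + N*(r + N*(R_xlen_t)s))] = v;
    G[q + N*(p + N*(r + N*(R_xlen_t)s))] = v;
    G[p + N*(q + N*(s + N*(R_xlen_t)r))] = v;
    G[q + N*(p + N*(s + N*(R_xlen_t)r))] = v;
    G[r + N*(s + N*(p + N*(R_xlen_t)q))] = v;
    G[s + N*(r + N*(p + N*(R_xlen_t)q))] = v;
    G[r + N*(s + N*(q + N*(R_xlen_t)p))] = v;
    G[s + N*(r + N*(q + N*(R_xlen_t)p))] = v;
  };
  for (int I = 0; I < nsh; ++I)
  for (int J = 0; J <= I; ++J)
  for (int K = 0; K < nsh; ++K)
  for (int Lsh = 0; Lsh <= K; ++Lsh) {
    if (K * (K + 1) / 2 + Lsh > I * (I + 1) / 2 + J) continue;
    const Shell &A = sh[I], &B = sh[J], &C = sh[K], &D = sh[Lsh];
    comps(A.l, ca); comps(B.l, cb); comps(C.l, cc_); comps(D.l, cd);
    int na = ca.size(), nb = cb.size(), nc = cc_.size(), nd = cd.size();
    int Lb = A.l + B.l, Lk = C.l + D.l, Ltot = Lb + Lk;
    arma::vec3 AB = A.A - B.A, CD = C.A - D.A;
    std::vector<double> blk((size_t)na * nb * nc * nd, 0.0);
    for (size_t pa = 0; pa < A.exps.size(); ++pa)
    for (size_t pb = 0; pb < B.exps.size(); ++pb) {
      double a = A.exps[pa], b = B.exps[pb], p = a + b;
      double cab = A.coefs[pa] * B.coefs[pb];
      arma::vec3 P = (a * A.A + b * B.A) / p;
      ETab Exb, Eyb, Ezb;
      fillE(A.l, B.l, a, b, AB[0], Exb);
      fillE(A.l, B.l, a, b, AB[1], Eyb);
      fillE(A.l, B.l, a, b, AB[2], Ezb);
      for (size_t pc = 0; pc < C.exps.size(); ++pc)
      for (size_t pd = 0; pd < D.exps.size(); ++pd) {
        double c = C.exps[pc], d = D.exps[pd], q = c + d;
        double ccd = C.coefs[pc] * D.coefs[pd];
        arma::vec3 Q = (c * C.A + d * D.A) / q;
        ETab Exk, Eyk, Ezk;
        fillE(C.l, D.l, c, d, CD[0], Exk);
        fillE(C.l, D.l, c, d, CD[1], Eyk);
        fillE(C.l, D.l, c, d, CD[2], Ezk);
        double omega = p * q / (p + q);
        double pref = 2.0 * std::pow(PI, 2.5) / (p * q * std::sqrt(p + q));
        RTab R;
        arma::vec3 PQ = P - Q;
        fillR(Ltot, omega, PQ, R);
        for (int ia = 0; ia < na; ++ia)
        for (int ib = 0; ib < nb; ++ib) {
          int l1 = ca[ia][0], m1 = ca[ia][1], n1 = ca[ia][2];
          int l2 = cb[ib][0], m2 = cb[ib][1], n2 = cb[ib][2];
          double fab = comp_factor(A.l, l1, m1, n1) * comp_factor(B.l, l2, m2, n2);
          for (int ic = 0; ic < nc; ++ic)
          for (int id = 0; id < nd; ++id) {
            int l3 = cc_[ic][0], m3 = cc_[ic][1], n3 = cc_[ic][2];
            int l4 = cd[id][0], m4 = cd[id][1], n4 = cd[id][2];
            double fcd = comp_factor(C.l, l3, m3, n3) * comp_factor(D.l, l4, m4, n4);
            double s = 0.0;
            for (int t = 0; t <= l1 + l2; ++t) {
              double exb = Exb.get(l1, l2, t); if (exb == 0.0) continue;
              for (int u = 0; u <= m1 + m2; ++u) {
                double eyb = Eyb.get(m1, m2, u); if (eyb == 0.0) continue;
                for (int w = 0; w <= n1 + n2; ++w) {
                  double ezb = Ezb.get(n1, n2, w); if (ezb == 0.0) continue;
                  double eb = exb * eyb * ezb;
                  for (int tt = 0; tt <= l3 + l4; ++tt) {
                    double exk = Exk.get(l3, l4, tt); if (exk == 0.0) continue;
                    for (int uu = 0; uu <= m3 + m4; ++uu) {
                      double eyk = Eyk.get(m3, m4, uu); if (eyk == 0.0) continue;
                      for (int ww = 0; ww <= n3 + n4; ++ww) {
                        double ezk = Ezk.get(n3, n4, ww); if (ezk == 0.0) continue;
                        double sign = ((tt + uu + ww) % 2 == 0) ? 1.0 : -1.0;
                        s += eb * exk * eyk * ezk * sign * R.get(t + tt, u + uu, w + ww);
                      }
                    }
                  }
                }
              }
            }
            blk[((size_t)ia * nb + ib) * nc * nd + (size_t)ic * nd + id]
              += cab * ccd * fab * fcd * pref * s;
          }
        }
      }
    }
    for (int ia = 0; ia < na; ++ia)
    for (int ib = 0; ib < nb; ++ib)
    for (int ic = 0; ic < nc; ++ic)
    for (int id = 0; id < nd; ++id)
      put(A.offset + ia, B.offset + ib, C.offset + ic, D.offset + id,
          blk[((size_t)ia * nb + ib) * nc * nd + (size_t)ic * nd + id]);
  }
  return out;
}

// ----------------------------------------------------- basis values on grid
// Returns list with phi (npts x nbf) and optionally gx, gy, gz.
// [[Rcpp::export]]
List cpp_basis_eval(List shells_in, arma::mat pts, bool grad) {
  std::vector<Shell> sh = parse_shells(shells_in);
  int nbf = nbf_total(sh), np = pts.n_cols;
  arma::mat phi(np, nbf, arma::fill::zeros);
  arma::mat gx, gy, gz;
  if (grad) {
    gx.zeros(np, nbf); gy.zeros(np, nbf); gz.zeros(np, nbf);
  }
  std::vector<std::array<int,3>> cc;
  for (const Shell& A : sh) {
    comps(A.l, cc);
    for (int k = 0; k < np; ++k) {
      double x = pts(0, k) - A.A[0], y = pts(1, k) - A.A[1], z = pts(2, k) - A.A[2];
      double r2 = x * x + y * y + z * z;
      double e = 0.0, de = 0.0; // radial contracted value and d/d(r2) part
      for (size_t p = 0; p < A.exps.size(); ++p) {
        double g = A.coefs[p] * std::exp(-A.exps[p] * r2);
        e += g;
        de += -A.exps[p] * g;
      }
      for (size_t ic = 0; ic < cc.size(); ++ic) {
        int lx = cc[ic][0], ly = cc[ic][1], lz = cc[ic][2];
        double f = comp_factor(A.l, lx, ly, lz);
        double px = std::pow(x, lx), py = std::pow(y, ly), pz = std::pow(z, lz);
        double poly = px * py * pz;
        phi(k, A.offset + ic) = f * poly * e;
        if (grad) {
          double dpx = lx > 0 ? lx * std::pow(x, lx - 1) : 0.0;
          double dpy = ly > 0 ? ly * std::pow(y, ly - 1) : 0.0;
          double dpz = lz > 0 ? lz * std::pow(z, lz - 1) : 0.0;
          gx(k, A.offset + ic) = f * (dpx * py * pz * e + poly * 2.0 * x * de);
          gy(k, A.offset + ic) = f * (px * dpy * pz * e + poly * 2.0 * y * de);
          gz(k, A.offset + ic) = f * (px * py * dpz * e + poly * 2.0 * z * de);
        }
      }
    }
  }
  if (grad)
    return List::create(_["phi"] = phi, _["gx"] = gx, _["gy"] = gy, _["gz"] = gz);
  return List::create(_["phi"] = phi);
}

// ------------------------------------------------------------ Becke weights
// Standard Becke fuzzy-cell weights (3 iterations of the smoothing
// polynomial, no atomic size adjustment).  patom is the 1-based parent atom
// of each grid point.
// [[Rcpp::export]]
arma::vec cpp_becke_weights(arma::mat atoms, IntegerVector patom, arma::mat pts) {
  int nat = atoms.n_cols, np = pts.n_cols;
  arma::vec w(np, arma::fill::ones);
  if (nat == 1) return w;
  arma::mat Rab(nat, nat, arma::fill::zeros);
  for (int i = 0; i < nat; ++i)
    for (int j = 0; j < nat; ++j)
      if (i != j) Rab(i, j) = arma::norm(atoms.col(i) - atoms.col(j));
  for (int k = 0; k < np; ++k) {
    arma::vec ra(nat);
    for (int i = 0; i < nat; ++i) ra[i] = arma::norm(pts.col(k) - atoms.col(i));
    arma::vec P(nat, arma::fill::ones);
    for (int i = 0; i < nat; ++i)
      for (int j = 0; j < nat; ++j) {
        if (i == j) continue;
        double mu = (ra[i] - ra[j]) / Rab(i, j);
        double f = mu;
        for (int it = 0; it < 3; ++it) f = 1.5 * f - 0.5 * f * f * f;
        P[i] *= 0.5 * (1.0 - f);
      }
    double tot = arma::accu(P);
    int ia = patom[k] - 1;
    w[k] = tot > 0 ? P[ia] / tot : 0.0;
  }
  return w;
}
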