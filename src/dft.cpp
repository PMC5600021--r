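// Exchange-correlation kernels for the hybrid-DFT monomer SCF.
//
// The energy density exc(rho_a, rho_b, sigma_aa, sigma_ab, sigma_bb)
// (energy per volume, atomic units) is coded analytically; the potentials
// vrho / vsigma are obtained by pointwise central differences of the kernel,
// which keeps one authoritative expression per functional.

#include <Rcpp.h>
using namespace Rcpp;

static const double M_PI_ = 3.14159265358979323846;
static const double RHO_CUT = 1e-12;

// Slater (LSDA) exchange, per-spin closed form
static double ex_slater(double ra, double rb) {
  const double Cs = 1.5 * std::pow(3.0 / (4.0 * M_PI_), 1.0 / 3.0);
  double e = 0.0;
  if (ra > RHO_CUT) e += -Cs * std::pow(ra, 4.0 / 3.0);
  if (rb > RHO_CUT) e += -Cs * std::pow(rb, 4.0 / 3.0);
  return e;
}

// Becke 1988 gradient correction to exchange (correction term only)
static double ex_b88(double ra, double rb, double saa, double sbb) {
  const double beta = 0.0042;
  double e = 0.0;
  if (ra > RHO_CUT) {
    double r43 = std::pow(ra, 4.0 / 3.0);
    double x = std::sqrt(std::max(saa, 0.0)) / r43;
    e += -beta * r43 * x * x / (1.0 + 6.0 * beta * x * std::asinh(x));
  }
  if (rb > RHO_CUT) {
    double r43 = std::pow(rb, 4.0 / 3.0);
    double x = std::sqrt(std::max(sbb, 0.0)) / r43;
    e += -beta * r43 * x * x / (1.0 + 6.0 * beta * x * std::asinh(x));
  }
  return e;
}

// VWN correlation, RPA parameterization (the dialect used inside the
// mainstream Gaussian-type B3LYP), simple f(zeta) interpolation.
static double vwn_eps(double rs, double A, double x0, double b, double c) {
  double x = std::sqrt(rs);
  double X = x * x + b * x + c;
  double X0 = x0 * x0 + b * x0 + c;
  double Q = std::sqrt(4.0 * c - b * b);
  double at = std::atan(Q / (2.0 * x + b));
  return A * (std::log(x * x / X) + 2.0 * b / Q * at
              - b * x0 / X0 * (std::log((x - x0) * (x - x0) / X)
                               + 2.0 * (b + 2.0 * x0) / Q * at));
}

static double ec_vwn(double ra, double rb) {
  double rho = ra + rb;
  if (rho < RHO_CUT) return 0.0;
  double rs = std::pow(3.0 / (4.0 * M_PI_ * rho), 1.0 / 3.0);
  double zeta = (ra - rb) / rho;
  if (zeta > 1.0) zeta = 1.0;
  if (zeta < -1.0) zeta = -1.0;
  double eP = vwn_eps(rs, 0.0310907, -0.409286, 13.0720, 42.7198);
  double eF = vwn_eps(rs, 0.01554535, -0.743294, 20.1231, 101.578);
  double f = (std::pow(1.0 + zeta, 4.0 / 3.0) + std::pow(1.0 - zeta, 4.0 / 3.0) - 2.0)
             / (2.0 * (std::pow(2.0, 1.0 / 3.0) - 1.0));
  return rho * (eP + f * (eF - eP));
}

// Lee-Yang-Parr correlation (Miehlich et al. closed form)
static double ec_lyp(double ra, double rb, double saa, double sab, double sbb) {
  const double a = 0.04918, b = 0.132, c = 0.2533, d = 0.349;
  const double CF = 0.3 * std::pow(3.0 * M_PI_ * M_PI_, 2.0 / 3.0);
  double rho = ra + rb;
  if (rho < RHO_CUT) return 0.0;
  if (ra < 0) ra = 0;
  if (rb < 0) rb = 0;
  double st = saa + 2.0 * sab + sbb;        // |grad rho|^2
  double rm13 = std::pow(rho, -1.0 / 3.0);
  double den = 1.0 + d * rm13;
  double omega = std::exp(-c * rm13) * std::pow(rho, -11.0 / 3.0) / den;
  double delta = c * rm13 + d * rm13 / den;
  double t1 = -4.0 * a / den * ra * rb / rho;
  double inner =
      ra * rb * (std::pow(2.0, 11.0 / 3.0) * CF
                     * (std::pow(ra, 8.0 / 3.0) + std::pow(rb, 8.0 / 3.0))
                 + (47.0 / 18.0 - 7.0 * delta / 18.0) * st
                 - (2.5 - delta / 18.0) * (saa + sbb)
                 - (delta - 11.0) / 9.0 * (ra * saa + rb * sbb) / rho)
      - 2.0 / 3.0 * rho * rho * st
      + (2.0 / 3.0 * rho * rho - ra * ra) * sbb
      + (2.0 / 3.0 * rho * rho - rb * rb) * saa;
  return t1 - a * b * omega * inner;
}

struct XCCoef { double slater, b88, vwn, lyp; };

static double exc_kernel(double ra, double rb, double saa, double sab,
                         double sbb, const XCCoef& k) {
  double e = 0.0;
  if (k.slater != 0.0) e += k.slater * ex_slater(ra, rb);
  if (k.b88 != 0.0) e += k.b88 * ex_b88(ra, rb, saa, sbb);
  if (k.vwn != 0.0) e += k.vwn * ec_vwn(ra, rb);
  if (k.lyp != 0.0) e += k.lyp * ec_lyp(ra, rb, saa, sab, sbb);
  return e;
}

// Evaluate exc and its derivatives on a batch of grid points.
// coefs = c(slater, b88, vwn, lyp); B3LYP DFT part is (0.80, 0.72, 0.19, 0.81).
// [[Rcpp::export]]
List cpp_xc_eval(NumericVector rho_a, NumericVector rho_b,
                 NumericVector sigma_aa, NumericVector sigma_ab,
                 NumericVector sigma_bb, NumericVector coefs) {
  int n = rho_a.size();
  XCCoef k{coefs[0], coefs[1], coefs[2], coefs[3]};
  NumericVector exc(n), vra(n), vrb(n), vsaa(n), vsab(n), vsbb(n);
  for (int i = 0; i < n; ++i) {
    double ra = rho_a[i], rb = rho_b[i];
    double saa = sigma_aa[i], sab = sigma_ab[i], sbb = sigma_bb[i];
    if (ra + rb < 1e-11) continue;
    exc[i] = exc_kernel(ra, rb, saa, sab, sbb, k);
    double hr = std::max((ra + rb) * 1e-6, 1e-12);
    vra[i] = (exc_kernel(ra + hr, rb, saa, sab, sbb, k)
              - exc_kernel(std::max(ra - hr, 0.0), rb, saa, sab, sbb, k))
             / (hr + std::min(ra, hr));
    vrb[i] = (exc_kernel(ra, rb + hr, saa, sab, sbb, k)
              - exc_kernel(ra, std::max(rb - hr, 0.0), saa, sab, sbb, k))
             / (hr + std::min(rb, hr));
    double hs = std::max((saa + sbb + std::abs(sab)) * 1e-6, 1e-12);
    vsaa[i] = (exc_kernel(ra, rb, saa + hs, sab, sbb, k)
               - exc_kernel(ra, rb, std::max(saa - hs, 0.0), sab, sbb, k))
              / (hs + std::min(saa, hs));
    vsbb[i] = (exc_kernel(ra, rb, saa, sab, sbb + hs, k)
               - exc_kernel(ra, rb, saa, sab, std::max(sbb - hs, 0.0), k))
              / (hs + std::min(sbb, hs));
    vsab[i] = (exc_kernel(ra, rb, saa, sab + hs, sbb, k)
               - exc_kernel(ra, rb, saa, sab - hs, sbb, k)) / (2.0 * hs);
  }
  return List::create(_["exc"] = exc, _["vrho_a"] = vra, _["vrho_b"] = vrb,
                      _["vsigma_aa"] = vsaa, _["vsigma_ab"] = vsab,
                      _["vsigma_bb"] = vsbb);
}
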