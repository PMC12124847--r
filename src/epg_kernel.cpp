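#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;

typedef std::complex<double> cplx;

// Quadratic RF phase n(n+1)psi/2, reduced mod 360.
// Exact integer arithmetic in units of psi/1000 degrees (millidegrees when psi
// is given to 3 decimals): n(n+1)/2 stays below 2^53 for any pulse count used
// here, so the product and the modulo are exact in double precision.
static double quad_phase_deg(double n, double psi_deg) {
  double tri = n * (n + 1.0) / 2.0;          // triangular number, exact
  double psimd = std::round(psi_deg * 1000.0); // millidegrees, integer-valued
  double x = tri * psimd;                      // exact while below 2^53
  double ph = x - std::floor(x / 360000.0) * 360000.0;
  if (ph < 0) ph += 360000.0;
  if (ph >= 360000.0) ph -= 360000.0;
  return ph / 1000.0;
}

//' @noRd
// [[Rcpp::export]]
NumericVector quad_phase_cpp(NumericVector n, double psi_deg) {
  NumericVector out(n.size());
  for (R_xlen_t i = 0; i < n.size(); ++i) out[i] = quad_phase_deg(n[i], psi_deg);
  return out;
}

// Propagate the configuration-state set of an RF-spoiled GRE sequence over
// `npulse` repetitions and record the demodulated F0 amplitude after each
// pulse (S+), at the echo time (readout sample), and at the end of the TR
// just before the next pulse (S-).
//
// One TR is split into `nint` piecewise-constant intervals. Per interval i:
//   e2[i], e1[i]              relaxation factors exp(-tau/T2), exp(-tau/T1)
//   att_fp(i,m), att_fm(i,m)  diffusion attenuation of transverse orders
//                             +m and -m (exp(-b D), b from the piecewise-
//                             linear k(t) trajectory), columns m = 0..Kmax
//   att_z(i,m)                diffusion attenuation of longitudinal order m
// When use_att is false the attenuation matrices are ignored (D = 0).
// te_boundary: the echo sample is taken after that many intervals (1-based);
// 0 disables echo recording. The per-TR net gradient moment is one
// configuration order: a single +1 shift is applied at the end of each TR.
//
// [[Rcpp::export]]
List epg_propagate_cpp(int npulse, double flip_rad, double psi_deg,
                       NumericVector e2, NumericVector e1,
                       NumericMatrix att_fp, NumericMatrix att_fm,
                       NumericMatrix att_z, bool use_att,
                       int te_boundary, double m0, double floor_amp) {
  int nint = e2.size();
  if (e1.size() != nint) stop("e1/e2 length mismatch");
  if (use_att && (att_fp.nrow() != nint || att_fp.ncol() < npulse + 2))
    stop("attenuation matrices must be nint x (npulse+2)");

  int kcap = npulse + 2;
  std::vector<cplx> Fp(kcap, cplx(0, 0)), Fm(kcap, cplx(0, 0)), Z(kcap, cplx(0, 0));
  Z[0] = cplx(m0, 0);
  int km = 1; // active orders 0..km-1

  ComplexVector f0_pulse(npulse), f0_te(npulse), f0_end(npulse);

  double ca = std::cos(flip_rad), sa = std::sin(flip_rad);
  double c2 = std::cos(flip_rad / 2.0), s2s = std::sin(flip_rad / 2.0);
  double cc = c2 * c2, ss = s2s * s2s;

  for (int n = 0; n < npulse; ++n) {
    double phi = quad_phase_deg((double)n, psi_deg) * M_PI / 180.0;
    cplx ei(std::cos(phi), std::sin(phi));
    cplx ei2 = ei * ei, eic = std::conj(ei), ei2c = std::conj(ei2);
    cplx demod = eic;

    // RF mixing of (F_m, F_-m*, Z_m) for every order
    for (int m = 0; m < km; ++m) {
      cplx fp = Fp[m], fm = Fm[m], z = Z[m];
      Fp[m] = cc * fp + ss * ei2 * fm - cplx(0, 1) * ei * sa * z;
      Fm[m] = ss * ei2c * fp + cc * fm + cplx(0, 1) * eic * sa * z;
      Z[m]  = cplx(0, -0.5) * eic * sa * fp + cplx(0, 0.5) * ei * sa * fm + ca * z;
    }
    cplx s = Fp[0] * demod;
    f0_pulse[n] = Rcomplex{s.real(), s.imag()};

    // relaxation + diffusion over the intervals of one TR
    for (int i = 0; i < nint; ++i) {
      double E2 = e2[i], E1 = e1[i];
      if (use_att) {
        for (int m = 0; m < km; ++m) {
          Fp[m] *= E2 * att_fp(i, m);
          Fm[m] *= E2 * att_fm(i, m);
          Z[m]  *= E1 * att_z(i, m);
        }
      } else {
        for (int m = 0; m < km; ++m) {
          Fp[m] *= E2;
          Fm[m] *= E2;
          Z[m]  *= E1;
        }
      }
      Z[0] += cplx(m0 * (1.0 - E1), 0); // regrowth toward equilibrium
      if (i + 1 == te_boundary) {
        cplx se = Fp[0] * demod;
        f0_te[n] = Rcomplex{se.real(), se.imag()};
      }
    }
    if (te_boundary <= 0) f0_te[n] = Rcomplex{0.0, 0.0};

    // gradient shift by +1 order (per-TR net moment = one quantum)
    if (km < kcap) ++km;
    for (int m = km - 1; m >= 1; --m) Fp[m] = Fp[m - 1];
    Fp[0] = std::conj(Fm[1]);
    for (int m = 0; m < km - 1; ++m) Fm[m] = Fm[m + 1];
    Fm[km - 1] = cplx(0, 0);

    cplx sm = Fp[0] * demod;
    f0_end[n] = Rcomplex{sm.real(), sm.imag()};

    // drop orders that fell below the amplitude floor
    while (km > 1 && std::abs(Fp[km - 1]) < floor_amp &&
           std::abs(Fm[km - 1]) < floor_amp && std::abs(Z[km - 1]) < floor_amp) {
      Fp[km - 1] = Fm[km - 1] = Z[km - 1] = cplx(0, 0);
      --km;
    }
  }

  return List::create(_["f0_pulse"] = f0_pulse, _["f0_te"] = f0_te,
                      _["f0_end"] = f0_end, _["k_active"] = km);
}
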