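#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Correlation sums for the generalized similarity measure.
// Returns c(num, den1, den2) where
//   num  = sum_{|k|<=K} w[|k|] * sum_i I1[i] * I2[i+k]
//   den1 = same with (I1, I1), den2 with (I2, I2).
// w has length K+1 (weight at lag 0 .. K); lags are symmetric.
// [[Rcpp::export]]
NumericVector cpp_s12_sums(NumericVector I1, NumericVector I2, int K,
                           NumericVector w) {
  const int n = I1.size();
  const double *__restrict__ a = I1.begin();
  const double *__restrict__ b = I2.begin();
  double num = 0.0, den1 = 0.0, den2 = 0.0;
  for (int k = 0; k <= K; ++k) {
    double c12p = 0.0, c12m = 0.0, c11 = 0.0, c22 = 0.0;
    const int m = n - k;
    for (int i = 0; i < m; ++i) {
      c12p += a[i] * b[i + k];      // lag +k
      c12m += a[i + k] * b[i];      // lag -k
      c11  += a[i] * a[i + k];
      c22  += b[i] * b[i + k];
    }
    const double wk = w[k];
    if (k == 0) {
      num += wk * c12p; den1 += wk * c11; den2 += wk * c22;
    } else {
      num += wk * (c12p + c12m);
      den1 += 2.0 * wk * c11;
      den2 += 2.0 * wk * c22;
    }
  }
  return NumericVector::create(num, den1, den2);
}

// Raw discrete cross-correlation profile c12(k) for k = -K..K.
// [[Rcpp::export]]
NumericVector cpp_xcorr(NumericVector I1, NumericVector I2, int K) {
  const int n = I1.size();
  NumericVector out(2 * K + 1);
  for (int k = -K; k <= K; ++k) {
    double s = 0.0;
    const int lo = std::max(0, -k), hi = std::min(n, n - k);
    for (int i = lo; i < hi; ++i) s += I1[i] * I2[i + k];
    out[k + K] = s;
  }
  return out;
}

// Render reflections onto a uniform 2theta grid with unit-area profiles.
// kind: 0 = gaussian, 1 = lorentzian, 2 = pseudo-Voigt (eta * L + (1-eta) * G)
// Profiles truncated at trunc * fwhm from the centre.
// [[Rcpp::export]]
NumericVector cpp_render(NumericVector centers, NumericVector intens,
                         double fwhm, int kind, double eta,
                         double start, double step, int n, double trunc) {
  NumericVector y(n);
  const double sg = fwhm / (2.0 * std::sqrt(2.0 * std::log(2.0)));
  const double gnorm = 1.0 / (sg * std::sqrt(2.0 * M_PI));
  const double hwhm = fwhm / 2.0;
  const double cut = trunc * fwhm;
  // normalize the Lorentzian over its truncated support so the rendered
  // peak area equals the reflection intensity
  const double lnorm = 1.0 / (2.0 * hwhm * std::atan(cut / hwhm));
  for (int r = 0; r < centers.size(); ++r) {
    const double c = centers[r], I = intens[r];
    if (I == 0.0) continue;
    int i0 = (int)std::ceil((c - cut - start) / step);
    int i1 = (int)std::floor((c + cut - start) / step);
    if (i0 < 0) i0 = 0;
    if (i1 >= n) i1 = n - 1;
    for (int i = i0; i <= i1; ++i) {
      const double d = start + i * step - c;
      double p;
      if (kind == 0) {
        p = gnorm * std::exp(-0.5 * d * d / (sg * sg));
      } else if (kind == 1) {
        p = lnorm / (1.0 + (d * d) / (hwhm * hwhm));
      } else {
        const double g = gnorm * std::exp(-0.5 * d * d / (sg * sg));
        const double l = lnorm / (1.0 + (d * d) / (hwhm * hwhm));
        p = eta * l + (1.0 - eta) * g;
      }
      y[i] += I * p;
    }
  }
  return y;
}

// Squared structure-factor amplitudes |F_hkl|^2 from 4-term Gaussian
// scattering factors f(s) = c + sum_j a_j exp(-b_j s^2), s = sin(theta)/lambda,
// with one overall isotropic displacement factor exp(-B s^2).
// elem: 0-based row index into (a, b, cc) per atom.
// [[Rcpp::export]]
NumericVector cpp_f2(IntegerVector h, IntegerVector k, IntegerVector l,
                     NumericVector stol2, IntegerVector elem,
                     NumericMatrix a, NumericMatrix b, NumericVector cc,
                     NumericVector x, NumericVector y, NumericVector z,
                     double B) {
  const int nr = h.size(), na = x.size(), ne = cc.size();
  NumericVector F2(nr);
  std::vector<double> f(ne);
  for (int r = 0; r < nr; ++r) {
    const double s2 = stol2[r];
    for (int e = 0; e < ne; ++e) {
      double fe = cc[e];
      for (int j = 0; j < 4; ++j) fe += a(e, j) * std::exp(-b(e, j) * s2);
      f[e] = fe;
    }
    double re = 0.0, im = 0.0;
    for (int aidx = 0; aidx < na; ++aidx) {
      const double ph = 2.0 * M_PI *
        (h[r] * x[aidx] + k[r] * y[aidx] + l[r] * z[aidx]);
      const double fa = f[elem[aidx]];
      re += fa * std::cos(ph);
      im += fa * std::sin(ph);
    }
    const double dw = std::exp(-B * s2);
    F2[r] = (re * re + im * im) * dw * dw;
  }
  return F2;
}

// Enumerate symmetry-unique reflections.
// rots: L x 9 matrix of Laue rotation matrices (row-major 3x3 each);
// ops: n x 12 matrix of symmetry operators (R row-major, then t) used for
// the systematic-absence test. Gs: reciprocal metric tensor.
// Returns a matrix with columns h, k, l, invd2, mult.
// [[Rcpp::export]]
NumericMatrix cpp_enumerate(int hmax, int kmax, int lmax, NumericMatrix Gs,
                            double invd2_lo, double invd2_hi,
                            NumericMatrix rots, NumericMatrix ops) {
  const int L = rots.nrow(), nops = ops.nrow();
  const int S = std::max(hmax, std::max(kmax, lmax)) + 1;
  const double Mb = 2.0 * S + 1.0;
  std::vector<double> out;
  const double g11 = Gs(0,0), g22 = Gs(1,1), g33 = Gs(2,2);
  const double g12 = Gs(0,1), g13 = Gs(0,2), g23 = Gs(1,2);
  for (int h = -hmax; h <= hmax; ++h)
  for (int k = -kmax; k <= kmax; ++k)
  for (int l = -lmax; l <= lmax; ++l) {
    if (h == 0 && k == 0 && l == 0) continue;
    const double invd2 = g11*h*h + g22*k*k + g33*l*l
      + 2.0*(g12*h*k + g13*h*l + g23*k*l);
    if (invd2 < invd2_lo || invd2 > invd2_hi) continue;
    const double self = (h + S) * Mb * Mb + (k + S) * Mb + (l + S);
    double codes[48];
    bool is_rep = true;
    for (int r = 0; r < L; ++r) {
      const int th = (int)std::lround(rots(r,0))*h + (int)std::lround(rots(r,1))*k + (int)std::lround(rots(r,2))*l;
      const int tk = (int)std::lround(rots(r,3))*h + (int)std::lround(rots(r,4))*k + (int)std::lround(rots(r,5))*l;
      const int tl = (int)std::lround(rots(r,6))*h + (int)std::lround(rots(r,7))*k + (int)std::lround(rots(r,8))*l;
      const double code = (th + S) * Mb * Mb + (tk + S) * Mb + (tl + S);
      codes[r] = code;
      if (code > self) { is_rep = false; break; }
    }
    if (!is_rep) continue;
    int mult = 0;
    for (int r = 0; r < L; ++r) {
      bool seen = false;
      for (int rr = 0; rr < r; ++rr) if (codes[rr] == codes[r]) { seen = true; break; }
      if (!seen) ++mult;
    }
    // systematic absence: an operator fixing hkl with non-integral phase
    bool absent = false;
    for (int o = 0; o < nops && !absent; ++o) {
      const double tx = ops(o,9), ty = ops(o,10), tz = ops(o,11);
      if (tx == 0.0 && ty == 0.0 && tz == 0.0) continue;
      // hR = (h,k,l) %*% R
      const int rh = (int)std::lround(h*ops(o,0) + k*ops(o,3) + l*ops(o,6));
      const int rk = (int)std::lround(h*ops(o,1) + k*ops(o,4) + l*ops(o,7));
      const int rl = (int)std::lround(h*ops(o,2) + k*ops(o,5) + l*ops(o,8));
      if (rh == h && rk == k && rl == l) {
        const double ph = h*tx + k*ty + l*tz;
        if (std::fabs(ph - std::round(ph)) > 1e-9) absent = true;
      }
    }
    if (absent) continue;
    out.push_back(h); out.push_back(k); out.push_back(l);
    out.push_back(invd2); out.push_back(mult);
  }
  const int n = out.size() / 5;
  NumericMatrix res(n, 5);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < 5; ++j) res(i, j) = out[5 * i + j];
  return res;
}

// Minimum contact margin between two Cartesian coordinate sets under the
// given Cartesian lattice shifts: min over pairs of (d_ij - (ra_i + rb_j)).
// skip_zero_shift excludes the s-th row given as index (or -1 for none),
// used when A and B are the same molecule copy.
// [[Rcpp::export]]
double cpp_min_margin(NumericMatrix A, NumericMatrix B,
                      NumericVector ra, NumericVector rb,
                      NumericMatrix shifts, int skip_shift) {
  double best = R_PosInf;
  for (int s = 0; s < shifts.nrow(); ++s) {
    if (s == skip_shift) continue;
    const double sx = shifts(s, 0), sy = shifts(s, 1), sz = shifts(s, 2);
    for (int i = 0; i < A.nrow(); ++i) {
      const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
      for (int j = 0; j < B.nrow(); ++j) {
        const double dx = ax - B(j, 0) - sx;
        const double dy = ay - B(j, 1) - sy;
        const double dz = az - B(j, 2) - sz;
        const double m = std::sqrt(dx * dx + dy * dy + dz * dz)
          - (ra[i] + rb[j]);
        if (m < best) best = m;
      }
    }
  }
  return best;
}

// Full intermolecular contact check in one call: atoms carry a copy index;
// pairs within the same copy are checked only across non-zero lattice
// shifts. Returns the minimal margin min(d - (r_i + r_j)); early exit at
// the first violation if stop_at_violation.
// [[Rcpp::export]]
double cpp_contact_margin(NumericMatrix X, IntegerVector copy,
                          NumericVector radii, NumericMatrix shifts,
                          int zero_shift, bool stop_at_violation) {
  const int n = X.nrow(), ns = shifts.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; ++i) {
    const double xi = X(i, 0), yi = X(i, 1), zi = X(i, 2), ri = radii[i];
    for (int j = i; j < n; ++j) {
      const bool same = copy[i] == copy[j];
      const double rj = radii[j] + ri;
      for (int s = 0; s < ns; ++s) {
        if (same && s == zero_shift) continue;
        const double dx = xi - X(j, 0) - shifts(s, 0);
        const double dy = yi - X(j, 1) - shifts(s, 1);
        const double dz = zi - X(j, 2) - shifts(s, 2);
        const double m = std::sqrt(dx * dx + dy * dy + dz * dz) - rj;
        if (m < best) {
          best = m;
          if (stop_at_violation && best < 0) return best;
        }
      }
    }
  }
  return best;
}

// Minimum intermolecular distance between two Cartesian coordinate sets,
// considering lattice translations given as a matrix of Cartesian shifts.
// Returns the smallest pair distance found (no early exit; sets are small).
// [[Rcpp::export]]
double cpp_min_dist(NumericMatrix A, NumericMatrix B, NumericMatrix shifts) {
  double best = R_PosInf;
  for (int s = 0; s < shifts.nrow(); ++s) {
    const double sx = shifts(s, 0), sy = shifts(s, 1), sz = shifts(s, 2);
    for (int i = 0; i < A.nrow(); ++i) {
      const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
      for (int j = 0; j < B.nrow(); ++j) {
        const double dx = ax - B(j, 0) - sx;
        const double dy = ay - B(j, 1) - sy;
        const double dz = az - B(j, 2) - sz;
        const double d2 = dx * dx + dy * dy + dz * dz;
        if (d2 < best) best = d2;
      }
    }
  }
  return std::sqrt(best);
}
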