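// Numerical kernels: complex Hankel function of the first kind (order 0),
// Born-approximation forward scattering, Green's-function back-propagation,
// and linear-time horizontal visibility graph construction.
#include <Rcpp.h>
#include <complex>
#include <vector>
#include <cmath>

using namespace Rcpp;
typedef std::complex<double> cplx;

static const double EULER_GAMMA = 0.5772156649015328606;

// H0^(1)(z) for complex z with Re(z) > 0.
// |z| < 10: ascending series for J0 and Y0 (cancellation loss ~|z| digits,
// acceptable below the switch point). |z| >= 10: Hankel asymptotic expansion,
// truncated at the smallest term.
static cplx hankel1_0(cplx z) {
  double az = std::abs(z);
  if (az < 10.0) {
    cplx q = z * z / 4.0;
    cplx term(1.0, 0.0);
    cplx j0 = term;
    cplx ysum(0.0, 0.0);
    double hk = 0.0;
    for (int k = 1; k <= 80; ++k) {
      term *= -q / double(k) / double(k);
      j0 += term;
      hk += 1.0 / k;
      ysum -= term * hk;  // (-1)^{k+1} H_k q^k/(k!)^2
      if (std::abs(term) < 1e-18 * std::abs(j0) && k > 4) break;
    }
    cplx y0 = (2.0 / M_PI) * ((std::log(z / 2.0) + EULER_GAMMA) * j0 + ysum);
    return j0 + cplx(0.0, 1.0) * y0;
  }
  // asymptotic: H0^(1)(z) ~ sqrt(2/(pi z)) e^{i(z - pi/4)} sum_k i^k A_k / z^k
  cplx zi = 1.0 / z;
  cplx t(1.0, 0.0);
  cplx sum = t;
  double prev = 1e300;
  for (int k = 1; k <= 40; ++k) {
    double m = 2.0 * k - 1.0;
    t *= cplx(0.0, 1.0) * zi * (-(m * m) / (8.0 * k));
    double at = std::abs(t);
    if (at >= prev) break;  // truncate at smallest term
    sum += t;
    prev = at;
    if (at < 1e-17) break;
  }
  cplx amp = std::sqrt(2.0 / (M_PI * z));
  cplx ph = std::exp(cplx(0.0, 1.0) * z - cplx(0.0, M_PI / 4.0));
  return amp * ph * sum;
}

// [[Rcpp::export]]
ComplexVector hankel0_cpp(ComplexVector z) {
  int n = z.size();
  ComplexVector out(n);
  for (int i = 0; i < n; ++i) {
    cplx zz(z[i].r, z[i].i);
    cplx h = hankel1_0(zz);
    out[i].r = h.real();
    out[i].i = h.imag();
  }
  return out;
}

static inline cplx green(const cplx &k, double dx, double dy) {
  double r = std::sqrt(dx * dx + dy * dy);
  // G(r, r') = (i/4) H0^(1)(k |r - r'|)
  return cplx(0.0, 0.25) * hankel1_0(k * r);
}

// Born forward model: S_ab(f) = k^2 * sum_p G(r_a, r_p) chi_p G(r_p, r_b) dA
// ant: Na x 2, pix: Np x 2, chi: Np x Nf, k: length Nf, dA pixel area.
// Returns Na x Na x Nf complex array (symmetric in a,b by construction).
// [[Rcpp::export]]
ComplexVector born_scatter_cpp(NumericMatrix ant, NumericMatrix pix,
                               ComplexMatrix chi, ComplexVector k, double dA) {
  int na = ant.nrow(), np = pix.nrow(), nf = k.size();
  ComplexVector out(na * na * nf);
  std::vector<cplx> G((size_t)na * np);
  for (int f = 0; f < nf; ++f) {
    cplx kf(k[f].r, k[f].i);
    for (int a = 0; a < na; ++a)
      for (int p = 0; p < np; ++p)
        G[(size_t)a * np + p] =
            green(kf, ant(a, 0) - pix(p, 0), ant(a, 1) - pix(p, 1));
    std::vector<cplx> S((size_t)na * na, cplx(0.0, 0.0));
    cplx k2dA = kf * kf * dA;
    for (int p = 0; p < np; ++p) {
      cplx c(chi(p, f).r, chi(p, f).i);
      if (c == cplx(0.0, 0.0)) continue;
      c *= k2dA;
      for (int a = 0; a < na; ++a) {
        cplx gac = G[(size_t)a * np + p] * c;
        for (int b = a; b < na; ++b)
          S[(size_t)a * na + b] += gac * G[(size_t)b * np + p];
      }
    }
    for (int a = 0; a < na; ++a)
      for (int b = a; b < na; ++b) {
        cplx v = S[(size_t)a * na + b];
        size_t i1 = (size_t)f * na * na + (size_t)b * na + a;
        size_t i2 = (size_t)f * na * na + (size_t)a * na + b;
        out[i1].r = v.real(); out[i1].i = v.imag();
        out[i2].r = v.real(); out[i2].i = v.imag();
      }
  }
  out.attr("dim") = IntegerVector::create(na, na, nf);
  return out;
}

// Phase-conjugate (matched-filter) back-propagation:
// I_p = sum_f sum_{a,b} u_ab dS_ab(f) conj(G(r_a,r_p) G(r_p,r_b))
// dS: Na x Na x Nf, u: Na x Na real weights. Returns complex length Np.
// [[Rcpp::export]]
ComplexVector backprop_cpp(NumericMatrix ant, NumericMatrix pix,
                           ComplexVector dS, NumericMatrix u,
                           ComplexVector k) {
  int na = ant.nrow(), np = pix.nrow(), nf = k.size();
  std::vector<cplx> acc(np, cplx(0.0, 0.0));
  std::vector<cplx> G((size_t)na * np);
  std::vector<cplx> M((size_t)na * na);
  for (int f = 0; f < nf; ++f) {
    cplx kf(k[f].r, k[f].i);
    for (int a = 0; a < na; ++a)
      for (int p = 0; p < np; ++p)
        G[(size_t)a * np + p] =
            green(kf, ant(a, 0) - pix(p, 0), ant(a, 1) - pix(p, 1));
    for (int b = 0; b < na; ++b)
      for (int a = 0; a < na; ++a) {
        size_t idx = (size_t)f * na * na + (size_t)b * na + a;
        M[(size_t)a * na + b] = u(a, b) * cplx(dS[idx].r, dS[idx].i);
      }
    for (int p = 0; p < np; ++p) {
      cplx s(0.0, 0.0);
      for (int a = 0; a < na; ++a) {
        cplx ga = std::conj(G[(size_t)a * np + p]);
        cplx row(0.0, 0.0);
        for (int b = 0; b < na; ++b)
          row += M[(size_t)a * na + b] * std::conj(G[(size_t)b * np + p]);
        s += ga * row;
      }
      acc[p] += s;
    }
  }
  ComplexVector out(np);
  for (int p = 0; p < np; ++p) {
    out[p].r = acc[p].real();
    out[p].i = acc[p].imag();
  }
  return out;
}

// Horizontal visibility graph, stack-based, O(n) amortized.
// Edge (i,j), i<j, iff x_k < min(x_i, x_j) for all i<k<j.
// Returns 1-based endpoint vectors.
// [[Rcpp::export]]
List hvg_edges_cpp(NumericVector x) {
  int n = x.size();
  std::vector<int> from, to;
  from.reserve(2 * n);
  to.reserve(2 * n);
  std::vector<int> stack;
  stack.reserve(n);
  for (int t = 0; t < n; ++t) {
    while (!stack.empty()) {
      int i = stack.back();
      if (x[i] < x[t]) {
        from.push_back(i + 1);
        to.push_back(t + 1);
        stack.pop_back();
      } else {
        from.push_back(i + 1);
        to.push_back(t + 1);
        if (x[i] == x[t]) stack.pop_back();  // equal value blocks both onward
        break;
      }
    }
    stack.push_back(t);
  }
  return List::create(Named("i") = wrap(from), Named("j") = wrap(to));
}
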