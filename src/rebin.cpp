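#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Pixel -> bin coefficient engine shared by the CSR builder and the direct
// (scatter) integrator.  Schemes: 0 = nosplit, 1 = bounding box, 2 = full
// polygon splitting.  Radial/azimuthal grids are strictly increasing edge
// vectors; bins are half-open [lo, hi) except the last (closed).  Azimuthal
// coordinates of pixel corners are unwrapped to within pi of their circular
// mean; contributions crossing the +/-pi cut are re-entered through shifted
// (+/- 2*pi) copies so coefficients still sum to one.

static const double TWOPI = 6.283185307179586476925286766559;

static inline double overlap1(double lo, double hi, double e0, double e1) {
  double a = lo > e0 ? lo : e0, b = hi < e1 ? hi : e1;
  return b > a ? b - a : 0.0;
}

// half-open bin lookup; last bin closed; -1 outside the grid
static inline int find_bin(const double* e, int nedge, double x) {
  if (x < e[0] || x > e[nedge - 1]) return -1;
  if (x == e[nedge - 1]) return nedge - 2;
  int k = (int)(std::upper_bound(e, e + nedge, x) - e) - 1;
  return k;
}

// first/last bin whose interval intersects [lo, hi]
static inline void bin_span(const double* e, int nedge, double lo, double hi,
                            int& k0, int& k1) {
  k0 = (int)(std::upper_bound(e, e + nedge, lo) - e) - 1;
  if (k0 < 0) k0 = 0;
  k1 = (int)(std::lower_bound(e, e + nedge, hi) - e) - 1;
  if (k1 > nedge - 2) k1 = nedge - 2;
}

// Sutherland-Hodgman clip of a polygon against one half-plane.
// keep: sign * coord[axis] <= sign * bound
static int clip_halfplane(const double* px, const double* py, int n,
                          int axis, double bound, int sign,
                          double* qx, double* qy) {
  int m = 0;
  for (int k = 0; k < n; ++k) {
    double cx = px[k], cy = py[k];
    double nxp = px[(k + 1) % n], nyp = py[(k + 1) % n];
    double cv = axis == 0 ? cx : cy, nv = axis == 0 ? nxp : nyp;
    bool cin = sign * cv <= sign * bound, nin = sign * nv <= sign * bound;
    if (cin) { qx[m] = cx; qy[m] = cy; ++m; }
    if (cin != nin) {
      double t = (bound - cv) / (nv - cv);
      qx[m] = cx + t * (nxp - cx);
      qy[m] = cy + t * (nyp - cy);
      ++m;
    }
  }
  return m;
}

// area of quad (u, a) clipped to rectangle [u0,u1] x [a0,a1]
static double clip_area(const double* qu, const double* qa,
                        double u0, double u1, double a0, double a1) {
  double ax[16], ay[16], bx[16], by[16];
  int n = 4;
  for (int k = 0; k < 4; ++k) { ax[k] = qu[k]; ay[k] = qa[k]; }
  n = clip_halfplane(ax, ay, n, 0, u0, -1, bx, by); if (n < 3) return 0.0;
  n = clip_halfplane(bx, by, n, 0, u1, +1, ax, ay); if (n < 3) return 0.0;
  n = clip_halfplane(ax, ay, n, 1, a0, -1, bx, by); if (n < 3) return 0.0;
  n = clip_halfplane(bx, by, n, 1, a1, +1, ax, ay); if (n < 3) return 0.0;
  double s = 0.0;
  for (int k = 0; k < n; ++k) {
    int k2 = (k + 1) % n;
    s += ax[k] * ay[k2] - ax[k2] * ay[k];
  }
  return std::fabs(s) * 0.5;
}

static double quad_area(const double* qu, const double* qa) {
  double s = 0.0;
  for (int k = 0; k < 4; ++k) {
    int k2 = (k + 1) % 4;
    s += qu[k] * qa[k2] - qu[k2] * qa[k];
  }
  return std::fabs(s) * 0.5;
}

// unwrap 4 azimuths to within pi of their circular mean
static void unwrap4(double* a) {
  double ss = 0, cc = 0;
  for (int k = 0; k < 4; ++k) { ss += std::sin(a[k]); cc += std::cos(a[k]); }
  double m = std::atan2(ss, cc);
  for (int k = 0; k < 4; ++k) a[k] += TWOPI * std::floor((m - a[k]) / TWOPI + 0.5);
}

// Compute all (bin, coef) pairs for one pixel.  bins are 0-based flat indices
// ir * na + ia (radial-major).  Returns through `out`.
static void pixel_coefs(int scheme,
                        const double* cu, const double* ca_in,
                        double ctr_u, double ctr_a,
                        const double* ue, int nue,
                        const double* ae, int nae, bool use_azim,
                        std::vector<std::pair<int, double> >& out) {
  out.clear();
  int na = use_azim ? nae - 1 : 1;

  if (scheme == 0) {  // nosplit: Dirac at the pixel centre
    int ir = find_bin(ue, nue, ctr_u);
    if (ir < 0) return;
    int ia = 0;
    if (use_azim) {
      double a = ctr_a;
      if (a <= ae[0]) a += TWOPI;
      if (a > ae[nae - 1]) a -= TWOPI;
      ia = find_bin(ae, nae, a);
      if (ia < 0) return;
    }
    out.push_back(std::make_pair(ir * na + ia, 1.0));
    return;
  }

  double ca[4];
  for (int k = 0; k < 4; ++k) ca[k] = ca_in[k];
  unwrap4(ca);

  double umin = cu[0], umax = cu[0], amin = ca[0], amax = ca[0];
  for (int k = 1; k < 4; ++k) {
    if (cu[k] < umin) umin = cu[k];
    if (cu[k] > umax) umax = cu[k];
    if (ca[k] < amin) amin = ca[k];
    if (ca[k] > amax) amax = ca[k];
  }

  if (scheme == 1) {  // bounding box: separable product of 1-D overlaps
    double uw = umax - umin;
    if (uw <= 0.0) {  // degenerate box -> nosplit point
      pixel_coefs(0, cu, ca_in, ctr_u, ctr_a, ue, nue, ae, nae, use_azim, out);
      return;
    }
    int ir0, ir1;
    bin_span(ue, nue, umin, umax, ir0, ir1);
    if (!use_azim) {
      for (int ir = ir0; ir <= ir1; ++ir) {
        double f = overlap1(umin, umax, ue[ir], ue[ir + 1]) / uw;
        if (f > 0) out.push_back(std::make_pair(ir, f));
      }
      return;
    }
    double aw = amax - amin;
    for (int w = -1; w <= 1; ++w) {
      double s = w * TWOPI;
      if (amax + s < ae[0] || amin + s > ae[nae - 1]) continue;
      int ia0, ia1;
      bin_span(ae, nae, amin + s, amax + s, ia0, ia1);
      for (int ia = ia0; ia <= ia1; ++ia) {
        double fa = aw > 0.0
          ? overlap1(amin + s, amax + s, ae[ia], ae[ia + 1]) / aw
          : (find_bin(ae, nae, amin + s) == ia ? 1.0 : 0.0);
        if (fa <= 0) continue;
        for (int ir = ir0; ir <= ir1; ++ir) {
          double fu = overlap1(umin, umax, ue[ir], ue[ir + 1]) / uw;
          if (fu > 0) out.push_back(std::make_pair(ir * na + ia, fu * fa));
        }
      }
    }
    return;
  }

  // scheme 2: full polygon splitting
  double area = quad_area(cu, ca);
  if (area <= 0.0) {
    pixel_coefs(0, cu, ca_in, ctr_u, ctr_a, ue, nue, ae, nae, use_azim, out);
    return;
  }
  int ir0, ir1;
  bin_span(ue, nue, umin, umax, ir0, ir1);
  if (!use_azim) {
    for (int ir = ir0; ir <= ir1; ++ir) {
      double f = clip_area(cu, ca, ue[ir], ue[ir + 1], amin - 1.0, amax + 1.0) / area;
      if (f > 0) out.push_back(std::make_pair(ir, f));
    }
    return;
  }
  for (int w = -1; w <= 1; ++w) {
    double s = w * TWOPI;
    if (amax + s < ae[0] || amin + s > ae[nae - 1]) continue;
    int ia0, ia1;
    bin_span(ae, nae, amin + s, amax + s, ia0, ia1);
    for (int ir = ir0; ir <= ir1; ++ir)
      for (int ia = ia0; ia <= ia1; ++ia) {
        double f = clip_area(cu, ca, ue[ir], ue[ir + 1],
                             ae[ia] - s, ae[ia + 1] - s) / area;
        if (f > 0) out.push_back(std::make_pair(ir * na + ia, f));
      }
  }
}

// [[Rcpp::export]]
List cpp_rebin_triplets(const NumericMatrix& corner_u, const NumericMatrix& corner_a,
                        const NumericVector& center_u, const NumericVector& center_a,
                        const LogicalVector& mask,
                        const NumericVector& ue, const NumericVector& ae,
                        int scheme, bool use_azim) {
  int npix = center_u.size();
  std::vector<int> pix, bin;
  std::vector<double> coef;
  std::vector<std::pair<int, double> > buf;
  double cu[4], ca[4];
  for (int p = 0; p < npix; ++p) {
    if (mask[p]) continue;
    if (scheme != 0)
      for (int k = 0; k < 4; ++k) { cu[k] = corner_u(p, k); ca[k] = corner_a(p, k); }
    pixel_coefs(scheme, cu, ca, center_u[p], center_a[p],
                &ue[0], ue.size(), &ae[0], ae.size(), use_azim, buf);
    for (size_t t = 0; t < buf.size(); ++t) {
      pix.push_back(p + 1);
      bin.push_back(buf[t].first + 1);
      coef.push_back(buf[t].second);
    }
  }
  return List::create(_["pix"] = wrap(pix), _["bin"] = wrap(bin),
                      _["coef"] = wrap(coef));
}

// [[Rcpp::export]]
List cpp_rebin_direct(const NumericMatrix& corner_u, const NumericMatrix& corner_a,
                      const NumericVector& center_u, const NumericVector& center_a,
                      const LogicalVector& mask,
                      const NumericVector& ue, const NumericVector& ae,
                      int scheme, bool use_azim,
                      const NumericVector& signal, const NumericVector& variance) {
  int npix = center_u.size();
  int na = use_azim ? ae.size() - 1 : 1;
  int nbins = (ue.size() - 1) * na;
  NumericVector sum_c(nbins), sum_c2(nbins), sum_cs(nbins), sum_cs2(nbins),
      sum_c2v(nbins);
  IntegerVector count(nbins);
  std::vector<std::pair<int, double> > buf;
  double cu[4], ca[4];
  bool has_var = variance.size() == npix;
  for (int p = 0; p < npix; ++p) {
    if (mask[p]) continue;
    if (scheme != 0)
      for (int k = 0; k < 4; ++k) { cu[k] = corner_u(p, k); ca[k] = corner_a(p, k); }
    pixel_coefs(scheme, cu, ca, center_u[p], center_a[p],
                &ue[0], ue.size(), &ae[0], ae.size(), use_azim, buf);
    double s = signal[p], v = has_var ? variance[p] : 0.0;
    for (size_t t = 0; t < buf.size(); ++t) {
      int b = buf[t].first;
      double c = buf[t].second;
      sum_c[b] += c;
      sum_c2[b] += c * c;
      sum_cs[b] += c * s;
      sum_cs2[b] += c * s * s;
      sum_c2v[b] += c * c * v;
      count[b] += 1;
    }
  }
  return List::create(_["sum_c"] = sum_c, _["sum_c2"] = sum_c2,
                      _["sum_cs"] = sum_cs, _["sum_cs2"] = sum_cs2,
                      _["sum_c2v"] = sum_c2v, _["count"] = count);
}

// Per-bin fractions for a single pixel quad (used by bbox_fractions /
// polygon_fractions).  Returns 1-based flat bin indices.
// [[Rcpp::export]]
List cpp_quad_fractions(const NumericVector& qu, const NumericVector& qa,
                        const NumericVector& ue, const NumericVector& ae,
                        int scheme, bool use_azim) {
  std::vector<std::pair<int, double> > buf;
  double cu[4], ca[4], su = 0, sa = 0;
  for (int k = 0; k < 4; ++k) { cu[k] = qu[k]; ca[k] = qa[k]; su += qu[k]; sa += qa[k]; }
  pixel_coefs(scheme, cu, ca, su / 4.0, sa / 4.0,
              &ue[0], ue.size(), &ae[0], ae.size(), use_azim, buf);
  IntegerVector bin(buf.size());
  NumericVector coef(buf.size());
  for (size_t t = 0; t < buf.size(); ++t) {
    bin[t] = buf[t].first + 1;
    coef[t] = buf[t].second;
  }
  return List::create(_["bin"] = bin, _["coef"] = coef);
}
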