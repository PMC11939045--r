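#include <Rcpp.h>
#include <complex>
#include <cmath>
#include <vector>

using namespace Rcpp;

// strip-element far-field directivity in the steering plane:
// |sinc(width * sin(theta) / lambda)| * cos(theta), 1 at broadside
static inline double directivity(double du, double z, double width,
                                 double lambda) {
  double r = std::sqrt(du * du + z * z);
  if (r <= 0) return 1.0;
  double s = du / r;        // sin(theta)
  double ct = z / r;        // cos(theta)
  double x = width * s / lambda;
  double sc = (std::fabs(x) < 1e-12) ? 1.0 : std::sin(M_PI * x) / (M_PI * x);
  return std::fabs(sc) * ct;
}

static inline double interp_table(const double* tab, int n, double pos) {
  // linear interpolation at fractional index pos; 0 outside
  if (pos <= 0 || pos >= n - 1) return 0.0;
  int i = (int)pos;
  double w = pos - i;
  return tab[i] * (1 - w) + tab[i + 1] * w;
}

// Simulate one frame of channel data for a set of transmit events.
//
// scat: n x 3 (x, y, z); amp: n
// tx_axis: per event, 0 = rows (steer along y), 1 = cols (steer along x)
// tx_mode: per event, 0 = discrete element superposition, 1 = ideal plane wave
// pol: n_elem x n_ev polarity matrix (element mode; ignored entries 0)
// fire: n_elem x n_ev firing delays (element mode)
// angle: per-event steering angle (radians, plane mode)
// tau0: per-event plane-wave time origin (plane mode)
// elem_pos: element positions along either axis (square array)
// pulse_tab / env_tab: RF pulse (domain 0) or envelope (domain 1) sampled at
// fs_tab, starting at t = 0, duration n_tab / fs_tab
// Returns numeric (domain 0) or complex (domain 1) array [nt, n_rx, n_ev].
// [[Rcpp::export(name = ".sim_frame_cpp")]]
SEXP sim_frame_cpp(NumericMatrix scat, NumericVector amp,
                   IntegerVector tx_axis, IntegerVector tx_mode,
                   NumericMatrix pol, NumericMatrix fire,
                   NumericVector angle, NumericVector tau0,
                   NumericVector elem_pos,
                   NumericVector tab, double fs_tab,
                   int domain, double f0,
                   double fs, double t0, int nt,
                   double c, double elem_width, bool use_directivity) {
  const int n_scat = scat.nrow();
  const int n_ev = tx_axis.size();
  const int n_el = elem_pos.size();
  const int n_tab = tab.size();
  const double lambda = c / f0;
  const double dur = (n_tab - 1) / fs_tab;
  const double* tabp = REAL(tab);

  NumericVector out_r;
  ComplexVector out_c;
  double* pr = nullptr;
  std::complex<double>* pc = nullptr;
  if (domain == 0) {
    out_r = NumericVector(Dimension(nt, n_el, n_ev));
    pr = REAL(out_r);
  } else {
    out_c = ComplexVector(Dimension(nt, n_el, n_ev));
    pc = reinterpret_cast<std::complex<double>*>(COMPLEX(out_c));
  }

  std::vector<double> tau_rx(n_el), d_rx(n_el);
  std::vector<double> tau_tx, a_tx;

  for (int e = 0; e < n_ev; ++e) {
    const int ax = tx_axis[e]; // 0: steer along y, rx along x; 1: reverse
    for (int k = 0; k < n_scat; ++k) {
      const double x = scat(k, 0), y = scat(k, 1), z = scat(k, 2);
      const double u = (ax == 0) ? y : x; // transmit-plane coordinate
      const double w = (ax == 0) ? x : y; // receive-plane coordinate
      // receive paths (strip elements: distance in the plane orthogonal to
      // the strip's long axis)
      for (int j = 0; j < n_el; ++j) {
        double dw = w - elem_pos[j];
        tau_rx[j] = std::sqrt(dw * dw + z * z) / c;
        d_rx[j] = use_directivity ? directivity(dw, z, elem_width, lambda)
                                  : 1.0;
      }
      // transmit arrivals
      tau_tx.clear(); a_tx.clear();
      if (tx_mode[e] == 1) { // ideal plane wave
        double th = angle[e];
        tau_tx.push_back(tau0[e] + (u * std::sin(th) + z * std::cos(th)) / c);
        a_tx.push_back(1.0);
      } else {
        for (int i = 0; i < n_el; ++i) {
          double p = pol(i, e);
          if (p == 0.0) continue;
          double duu = u - elem_pos[i];
          tau_tx.push_back(fire(i, e) + std::sqrt(duu * duu + z * z) / c);
          double g = use_directivity ? directivity(duu, z, elem_width, lambda)
                                     : 1.0;
          a_tx.push_back(p * g);
        }
      }
      const double a0 = amp[k];
      if (a0 == 0.0) continue;
      for (size_t it = 0; it < tau_tx.size(); ++it) {
        const double tt = tau_tx[it];
        const double at = a_tx[it] * a0;
        for (int j = 0; j < n_el; ++j) {
          const double taur = tt + tau_rx[j];
          const double a = at * d_rx[j];
          // samples covering [taur, taur + dur]
          int i0 = (int)std::ceil((taur - t0) * fs);
          int i1 = (int)std::floor((taur + dur - t0) * fs);
          if (i0 < 0) i0 = 0;
          if (i1 > nt - 1) i1 = nt - 1;
          if (i1 < i0) continue;
          if (domain == 0) {
            double* dst = pr + ((size_t)e * n_el + j) * nt;
            for (int i = i0; i <= i1; ++i) {
              double ts = (t0 + i / fs - taur) * fs_tab;
              dst[i] += a * interp_table(tabp, n_tab, ts);
            }
          } else {
            std::complex<double>* dst = pc + ((size_t)e * n_el + j) * nt;
            double ph = -2.0 * M_PI * f0 * taur;
            std::complex<double> ca =
              a * std::complex<double>(std::cos(ph), std::sin(ph));
            for (int i = i0; i <= i1; ++i) {
              double ts = (t0 + i / fs - taur) * fs_tab;
              dst[i] += ca * interp_table(tabp, n_tab, ts);
            }
          }
        }
      }
    }
  }
  if (domain == 0) return out_r;
  return out_c;
}

// Delay-and-sum beamforming of a baseband ensemble on a voxel grid.
//
// data: complex [nt, n_rx, n_ev, n_fr]
// per event: tx_axis (0 rows / 1 cols), tx_kind (0 plane, 1 single-element),
// angle (rad), tau0, src_pos (active element position, SA)
// Returns a list with the coherent per-orientation sums over events
// (complex [n_vox, n_fr]) and the per-orientation event counts.
// [[Rcpp::export(name = ".das_series_cpp")]]
List das_series_cpp(ComplexVector data, IntegerVector dims,
                    NumericVector gx, NumericVector gy, NumericVector gz,
                    IntegerVector tx_axis, IntegerVector tx_kind,
                    NumericVector angle, NumericVector tau0,
                    NumericVector src_pos, NumericVector ev_weight,
                    NumericVector rx_pos,
                    double c, double f0, double fs, double t0,
                    double fnumber, int apod_hann) {
  const int nt = dims[0], n_rx = dims[1], n_ev = dims[2], n_fr = dims[3];
  const int nx = gx.size(), ny = gy.size(), nz = gz.size();
  const size_t n_vox = (size_t)nx * ny * nz;
  const std::complex<double>* d =
    reinterpret_cast<std::complex<double>*>(COMPLEX(data));

  ComplexVector acc0_(n_vox * (size_t)n_fr), acc1_(n_vox * (size_t)n_fr);
  std::complex<double>* acc0 =
    reinterpret_cast<std::complex<double>*>(COMPLEX(acc0_));
  std::complex<double>* acc1 =
    reinterpret_cast<std::complex<double>*>(COMPLEX(acc1_));
  std::fill(acc0, acc0 + n_vox * (size_t)n_fr, std::complex<double>(0, 0));
  std::fill(acc1, acc1 + n_vox * (size_t)n_fr, std::complex<double>(0, 0));
  double w_ev0 = 0, w_ev1 = 0;

  // per-event lookup tables (voxel, rx) -> sample index, weight, phase
  std::vector<size_t> t_vox;
  std::vector<int> t_rx, t_idx;
  std::vector<double> t_w;
  std::vector<std::complex<double>> t_ph;

  for (int e = 0; e < n_ev; ++e) {
    const int ax = tx_axis[e];
    std::complex<double>* acc = (ax == 0) ? acc0 : acc1;
    const double we = ev_weight[e];
    if (ax == 0) w_ev0 += we; else w_ev1 += we;
    if (we == 0.0) continue;
    const double st = std::sin(angle[e]), ct = std::cos(angle[e]);
    t_vox.clear(); t_rx.clear(); t_idx.clear(); t_w.clear(); t_ph.clear();

    size_t v = 0;
    for (int iz = 0; iz < nz; ++iz) {
      const double z = gz[iz];
      const double half_ap = (fnumber > 0) ? z / (2.0 * fnumber) : 1e9;
      for (int iy = 0; iy < ny; ++iy) {
        for (int ix = 0; ix < nx; ++ix, ++v) {
          const double u = (ax == 0) ? gy[iy] : gx[ix];
          const double w = (ax == 0) ? gx[ix] : gy[iy];
          double ttx;
          if (tx_kind[e] == 0) {
            ttx = tau0[e] + (u * st + z * ct) / c;
          } else {
            double duu = u - src_pos[e];
            ttx = std::sqrt(duu * duu + z * z) / c;
          }
          for (int j = 0; j < n_rx; ++j) {
            const double dw = w - rx_pos[j];
            if (std::fabs(dw) > half_ap) continue;
            const double tau = ttx + std::sqrt(dw * dw + z * z) / c;
            const double pos = (tau - t0) * fs;
            if (pos <= 0 || pos >= nt - 1) continue;
            double a = we;
            if (apod_hann && fnumber > 0) {
              a *= 0.5 + 0.5 * std::cos(M_PI * dw / half_ap);
            }
            const double ph = 2.0 * M_PI * f0 * tau;
            t_vox.push_back(v);
            t_rx.push_back(j);
            t_idx.push_back((int)pos);
            t_w.push_back(pos - (int)pos);
            t_ph.push_back(a * std::complex<double>(std::cos(ph),
                                                    std::sin(ph)));
          }
        }
      }
    }
    const size_t n_tab = t_vox.size();
    for (int f = 0; f < n_fr; ++f) {
      const std::complex<double>* df =
        d + ((size_t)f * n_ev + e) * n_rx * nt;
      std::complex<double>* af = acc + (size_t)f * n_vox;
      for (size_t q = 0; q < n_tab; ++q) {
        const std::complex<double>* tr = df + (size_t)t_rx[q] * nt;
        const std::complex<double> val =
          tr[t_idx[q]] * (1.0 - t_w[q]) + tr[t_idx[q] + 1] * t_w[q];
        af[t_vox[q]] += val * t_ph[q];
      }
    }
  }
  return List::create(_["rows_tx"] = acc0_, _["cols_tx"] = acc1_,
                      _["w_rows_ev"] = w_ev0, _["w_cols_ev"] = w_ev1);
}

static inline double cubic_w(double t, int i) {
  // Catmull-Rom weights for offsets i = -1..2
  double t2 = t * t, t3 = t2 * t;
  switch (i) {
  case -1: return 0.5 * (-t3 + 2 * t2 - t);
  case 0:  return 0.5 * (3 * t3 - 5 * t2 + 2);
  case 1:  return 0.5 * (-3 * t3 + 4 * t2 + t);
  default: return 0.5 * (t3 - t2);
  }
}

// Resample a volume under a rigid transform (ZYX Euler about `center`,
// then translation). out(p) = vol(Tinv(p)); order 1 (trilinear) or 3
// (Catmull-Rom tricubic). Returns values and an inside-support mask.
// [[Rcpp::export(name = ".resample_rigid_cpp")]]
List resample_rigid_cpp(NumericVector vol, IntegerVector dims,
                        NumericVector ox, NumericVector oy, NumericVector oz,
                        NumericMatrix rot, NumericVector trans,
                        NumericVector center, int order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = ox.size(), my = oy.size(), mz = oz.size();
  const double* v = REAL(vol);
  NumericVector out(Dimension(mx, my, mz));
  LogicalVector inside(Dimension(mx, my, mz));
  // voxel -> physical uses the (assumed uniform) input grid
  // here grids are passed as coordinate vectors; index = (p - g0)/dg
  const double x0 = ox[0], dxg = (mx > 1) ? ox[1] - ox[0] : 1;
  // the input grid equals the output grid in this package (same FOV)
  double R[3][3];
  for (int a = 0; a < 3; ++a)
    for (int b = 0; b < 3; ++b) R[a][b] = rot(a, b);
  size_t q = 0;
  for (int iz = 0; iz < mz; ++iz) {
    for (int iy = 0; iy < my; ++iy) {
      for (int ix = 0; ix < mx; ++ix, ++q) {
        double p[3] = {ox[ix], oy[iy], oz[iz]};
        double s[3], r[3];
        for (int a = 0; a < 3; ++a) s[a] = p[a] - center[a] - trans[a];
        // inverse rotation = transpose
        for (int a = 0; a < 3; ++a) {
          r[a] = R[0][a] * s[0] + R[1][a] * s[1] + R[2][a] * s[2];
          r[a] += center[a];
        }
        // physical -> fractional index on the input grid
        double fx = (r[0] - ox[0]) / ((mx > 1) ? ox[1] - ox[0] : 1);
        double fy = (r[1] - oy[0]) / ((my > 1) ? oy[1] - oy[0] : 1);
        double fz = (r[2] - oz[0]) / ((mz > 1) ? oz[1] - oz[0] : 1);
        if (fx < 0 || fy < 0 || fz < 0 ||
            fx > nx - 1 || fy > ny - 1 || fz > nz - 1) {
          out[q] = 0; inside[q] = false; continue;
        }
        inside[q] = true;
        int jx = (int)fx, jy = (int)fy, jz = (int)fz;
        if (jx == nx - 1) jx--;
        if (jy == ny - 1) jy--;
        if (jz == nz - 1) jz--;
        double tx = fx - jx, ty = fy - jy, tz = fz - jz;
        double acc = 0;
        if (order == 1) {
          for (int a = 0; a <= 1; ++a)
            for (int b = 0; b <= 1; ++b)
              for (int cc = 0; cc <= 1; ++cc) {
                double wgt = (a ? tx : 1 - tx) * (b ? ty : 1 - ty) *
                             (cc ? tz : 1 - tz);
                acc += wgt *
                  v[(size_t)(jz + cc) * nx * ny + (size_t)(jy + b) * nx +
                    (jx + a)];
              }
        } else {
          for (int a = -1; a <= 2; ++a) {
            int kx = std::min(std::max(jx + a, 0), nx - 1);
            double wx = cubic_w(tx, a);
            for (int b = -1; b <= 2; ++b) {
              int ky = std::min(std::max(jy + b, 0), ny - 1);
              double wxy = wx * cubic_w(ty, b);
              for (int cc = -1; cc <= 2; ++cc) {
                int kz = std::min(std::max(jz + cc, 0), nz - 1);
                acc += wxy * cubic_w(tz, cc) *
                  v[(size_t)kz * nx * ny + (size_t)ky * nx + kx];
              }
            }
          }
        }
        out[q] = acc;
      }
    }
  }
  (void)x0; (void)dxg;
  return List::create(_["values"] = out, _["inside"] = inside);
}
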