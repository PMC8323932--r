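#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Apex height of the probe (hemisphere radius r, cone half-apex angle theta)
// at first contact with a spherical atom of radius ar centred at height az,
// lateral distance d from the probe axis.  Contact is on the hemisphere when
// d <= (r+ar)*cos(theta), on the cone flank otherwise; the two branches meet
// continuously at the boundary.
static inline double tip_height(double r, double sin_t, double cos_t,
                                double az, double ar, double d) {
  const double R = r + ar;
  if (d <= R * cos_t) {
    return az + std::sqrt(R * R - d * d) - r;
  }
  return az + (ar + r - d * cos_t) / sin_t - r;
}

// Lateral reach of the tip around one atom: the largest d at which the tip
// apex can still sit at or above the stage (z_tip >= 0) while touching the
// atom.  Used to size the rendering frame; an overestimate is harmless.
static inline double atom_reach(double r, double sin_t, double cos_t,
                                double az, double ar) {
  const double R = r + ar;
  double ds = 0.0;
  const double dz = r - az;               // apex at stage level
  if (dz <= 0.0) {
    ds = R;                               // whole hemisphere can touch
  } else if (dz < R) {
    ds = std::sqrt(R * R - dz * dz);
  }
  const double dc = (ar + r - (r - az) * sin_t) / cos_t;
  return std::max(ds, std::max(dc, 0.0));
}

// Render atoms into a ny x nx (column-major) height buffer initialised to
// zero.  Per atom only the pixels within its lateral reach are visited:
// beyond the reach the contact height is below the stage floor, so
// skipping them is exact.
static void render_to(const double *ax, const double *ay, const double *az,
                      const double *ar, int n, double r, double sin_t,
                      double cos_t, double px, double ox, double oy,
                      int nx, int ny, double *out) {
  for (int a = 0; a < n; ++a) {
    const double rr = atom_reach(r, sin_t, cos_t, az[a], ar[a]) + px;
    int j0 = (int)std::ceil((ax[a] - rr - ox) / px - 0.5);
    int j1 = (int)std::floor((ax[a] + rr - ox) / px - 0.5);
    int i0 = (int)std::ceil((ay[a] - rr - oy) / px - 0.5);
    int i1 = (int)std::floor((ay[a] + rr - oy) / px - 0.5);
    if (j0 < 0) j0 = 0;
    if (i0 < 0) i0 = 0;
    if (j1 >= nx) j1 = nx - 1;
    if (i1 >= ny) i1 = ny - 1;
    for (int j = j0; j <= j1; ++j) {
      const double dx = ox + (j + 0.5) * px - ax[a];
      double *col = out + (size_t)j * ny;
      for (int i = i0; i <= i1; ++i) {
        const double dy = oy + (i + 0.5) * px - ay[a];
        const double d = std::sqrt(dx * dx + dy * dy);
        const double zt = tip_height(r, sin_t, cos_t, az[a], ar[a], d);
        if (zt > col[i]) col[i] = zt;
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_render(NumericMatrix xyz, NumericVector radii,
                         double r, double theta_deg, double px,
                         double ox, double oy, int nx, int ny) {
  const int n = xyz.nrow();
  const double th = theta_deg * M_PI / 180.0;
  const double sin_t = std::sin(th), cos_t = std::cos(th);
  NumericMatrix out(ny, nx);
  std::vector<double> ax(n), ay(n), az(n), ar(n);
  for (int a = 0; a < n; ++a) {
    ax[a] = xyz(a, 0); ay[a] = xyz(a, 1); az[a] = xyz(a, 2);
    ar[a] = radii[a];
  }
  render_to(ax.data(), ay.data(), az.data(), ar.data(), n, r, sin_t, cos_t,
            px, ox, oy, nx, ny, REAL(out));
  return out;
}

// Exhaustive search core.  For every orientation (3x3 rotations stacked
// column-major in `rot`) and probe (rows of `probes`: radius_nm, angle_deg)
// the rotated model is re-grounded, rendered, trimmed to its non-zero
// bounding rectangle, slid over the reference at integer pixel offsets
// (row-major) with Z offsets 0, z_step, ... applied to non-zero pixels, and
// the best cost is kept (strict improvement, so first-found wins on ties
// in offset-then-Z enumeration order).
//
// Returns a (K*M) x 13 matrix, one row per (orientation, probe):
//   1 orient  2 probe  3 cost  4 off_row  5 off_col  6 z_idx  7 z_off
//   8 tx  9 ty  10 tz  11 win_rows  12 win_cols  13 n_zoff
// (tx, ty, tz) is the full translation so that the fitted placement is
// x' = R x + t in reference-frame coordinates; offsets are 0-based.
// [[Rcpp::export]]
NumericMatrix cpp_search(NumericMatrix xyz, NumericVector radii,
                         NumericVector rot, int K, NumericMatrix probes,
                         NumericMatrix ref, double ref_ox, double ref_oy,
                         double px, double z_step, int score_id,
                         double thickness, double k_penalty, double k_reward,
                         int max_frame) {
  const int n = xyz.nrow();
  const int M = probes.nrow();
  const int Hr = ref.nrow(), Wr = ref.ncol();
  const double inf = R_PosInf;

  double maxref = R_NegInf;
  for (int idx = 0; idx < Hr * Wr; ++idx)
    if (ref[idx] > maxref) maxref = ref[idx];

  NumericMatrix res(K * M, 13);
  std::vector<double> rx(n), ry(n), rz(n);
  std::vector<double> u;  // ref - sim differences for the penalty score

  for (int k = 0; k < K; ++k) {
    const double *Rm = &rot[9 * k];  // column-major 3x3
    double zmin = R_PosInf;
    double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
    for (int a = 0; a < n; ++a) {
      const double X = xyz(a, 0), Y = xyz(a, 1), Z = xyz(a, 2);
      rx[a] = Rm[0] * X + Rm[3] * Y + Rm[6] * Z;
      ry[a] = Rm[1] * X + Rm[4] * Y + Rm[7] * Z;
      rz[a] = Rm[2] * X + Rm[5] * Y + Rm[8] * Z;
      if (rz[a] - radii[a] < zmin) zmin = rz[a] - radii[a];
      if (rx[a] < xmin) xmin = rx[a];
      if (rx[a] > xmax) xmax = rx[a];
      if (ry[a] < ymin) ymin = ry[a];
      if (ry[a] > ymax) ymax = ry[a];
    }
    const double dzg = -zmin;  // grounding shift: min(z - radius) = 0
    for (int a = 0; a < n; ++a) rz[a] += dzg;

    for (int m = 0; m < M; ++m) {
      const int row = k * M + m;
      res(row, 0) = k + 1;
      res(row, 1) = m + 1;
      res(row, 2) = inf;

      const double pr = probes(m, 0), ang = probes(m, 1);
      const double th = ang * M_PI / 180.0;
      const double sin_t = std::sin(th), cos_t = std::cos(th);

      double pad = 0.0;
      for (int a = 0; a < n; ++a) {
        const double re = atom_reach(pr, sin_t, cos_t, rz[a], radii[a]);
        if (re > pad) pad = re;
      }
      pad += px;
      const double ox = xmin - pad, oy = ymin - pad;
      const int nx = (int)std::ceil((xmax + pad - ox) / px);
      const int ny = (int)std::ceil((ymax + pad - oy) / px);
      if (nx < 1 || ny < 1 || nx > max_frame || ny > max_frame) continue;

      // render the pseudo-AFM image on its own frame
      std::vector<double> simbuf((size_t)nx * ny, 0.0);
      {
        std::vector<double> arad(radii.begin(), radii.end());
        render_to(rx.data(), ry.data(), rz.data(), arad.data(), n, pr,
                  sin_t, cos_t, px, ox, oy, nx, ny, simbuf.data());
      }
      double maxsim = 0.0;
      int r0 = ny, r1 = -1, c0 = nx, c1 = -1;
      for (int j = 0; j < nx; ++j)
        for (int i = 0; i < ny; ++i) {
          const double h = simbuf[(size_t)j * ny + i];
          if (h > 0.0) {
            if (i < r0) r0 = i;
            if (i > r1) r1 = i;
            if (j < c0) c0 = j;
            if (j > c1) c1 = j;
            if (h > maxsim) maxsim = h;
          }
        }
      if (r1 < 0) continue;  // all-zero image
      const int h = r1 - r0 + 1, w = c1 - c0 + 1;
      if (h > Hr || w > Wr) continue;  // window does not fit the reference

      const int nzoff =
          (maxsim < maxref) ? (int)std::floor((maxref - maxsim) / z_step) : 0;
      res(row, 12) = nzoff + 1;

      // window statistics independent of the offset
      const int N = h * w;
      double s_sum = 0.0, s_sq = 0.0;
      int mcnt = 0;
      for (int wi = 0; wi < h; ++wi)
        for (int wj = 0; wj < w; ++wj) {
          const double v = simbuf[(size_t)(c0 + wj) * ny + (r0 + wi)];
          if (v > 0.0) {
            ++mcnt;
            s_sum += v;
            s_sq += v * v;
          }
        }

      double best = inf;
      int b_or = -1, b_oc = -1, b_zi = -1;
      for (int orow = 0; orow + h <= Hr; ++orow) {
        for (int ocol = 0; ocol + w <= Wr; ++ocol) {
          if (score_id == 4) {  // penalty: piecewise, handled separately
            u.clear();
            double base = 0.0;
            for (int wi = 0; wi < h; ++wi)
              for (int wj = 0; wj < w; ++wj) {
                const double s = simbuf[(size_t)(c0 + wj) * ny + (r0 + wi)];
                const double rv = ref(orow + wi, ocol + wj);
                if (s > 0.0) {
                  u.push_back(rv - s);
                } else {
                  if (rv < 0.0)
                    base += k_penalty;
                  else if (rv < thickness)
                    base -= k_reward;
                }
              }
            std::sort(u.begin(), u.end());
            for (int zi = 0; zi <= nzoff; ++zi) {
              const double z = zi * z_step;
              const long npen =
                  std::lower_bound(u.begin(), u.end(), z) - u.begin();
              const long nrew =
                  (std::lower_bound(u.begin(), u.end(), z + thickness) -
                   u.begin()) - npen;
              const double cost =
                  base + k_penalty * npen - k_reward * nrew;
              if (cost < best) {
                best = cost; b_or = orow; b_oc = ocol; b_zi = zi;
              }
            }
          } else {
            double r_sum = 0.0, r_sq = 0.0, sr = 0.0, r_mask = 0.0;
            for (int wi = 0; wi < h; ++wi)
              for (int wj = 0; wj < w; ++wj) {
                const double s = simbuf[(size_t)(c0 + wj) * ny + (r0 + wi)];
                const double rv = ref(orow + wi, ocol + wj);
                r_sum += rv;
                r_sq += rv * rv;
                sr += s * rv;
                if (s > 0.0) r_mask += rv;
              }
            for (int zi = 0; zi <= nzoff; ++zi) {
              const double z = zi * z_step;
              const double s1 = s_sum + z * mcnt;
              const double s2 = s_sq + 2.0 * z * s_sum + z * z * mcnt;
              const double srz = sr + z * r_mask;
              double cost;
              if (score_id == 1) {  // cosine
                if (s2 <= 0.0 || r_sq <= 0.0) continue;
                cost = 1.0 - srz / std::sqrt(s2 * r_sq);
              } else if (score_id == 2) {  // correlation
                const double vs = s2 - s1 * s1 / N;
                const double vr = r_sq - r_sum * r_sum / N;
                if (vs <= 1e-300 || vr <= 1e-300) continue;
                cost = 1.0 - (srz - s1 * r_sum / N) / std::sqrt(vs * vr);
              } else {  // pixel-RMSD
                double ss = s2 - 2.0 * srz + r_sq;
                if (ss < 0.0) ss = 0.0;
                cost = std::sqrt(ss / N);
              }
              if (cost < best) {
                best = cost; b_or = orow; b_oc = ocol; b_zi = zi;
              }
            }
          }
        }
      }
      if (!std::isfinite(best)) continue;

      res(row, 2) = best;
      res(row, 3) = b_or;
      res(row, 4) = b_oc;
      res(row, 5) = b_zi;
      res(row, 6) = b_zi * z_step;
      res(row, 7) = ref_ox + (b_oc - c0) * px - ox;          // tx
      res(row, 8) = ref_oy + (b_or - r0) * px - oy;          // ty
      res(row, 9) = dzg + b_zi * z_step;                     // tz
      res(row, 10) = h;
      res(row, 11) = w;
    }
    Rcpp::checkUserInterrupt();
  }
  return res;
}

// Blind tip reconstruction refinement.  Tip heights p (w x w, apex 0 at
// the center, values <= 0) are tightened iteratively: for every interior
// image position x and tip pixel d, the bound
//   p(d) <= max over feasible contacts d' of
//           I(x + d' - d) - I(x) + p(d') + thresh
// holds, where d' is feasible when assuming contact there does not push
// the implied surface above the image: I(x + d') >= I(x) - p(d') - thresh.
// Only positions whose full (2w-1)-neighbourhood lies inside the image
// contribute (border positions give no certain constraint).  Iterates to
// a fixed point; the estimate is monotonically non-increasing.
// [[Rcpp::export]]
NumericMatrix cpp_blind_tip(NumericMatrix img, int w, double thresh,
                            int max_iter) {
  const int nr = img.nrow(), nc = img.ncol();
  const int c = (w - 1) / 2;
  NumericMatrix p(w, w);  // zeros: flat upper bound
  if (nr < 2 * w - 1 || nc < 2 * w - 1) return p;

  for (int it = 0; it < max_iter; ++it) {
    bool changed = false;
    NumericMatrix pn(clone(p));
    for (int i = w - 1; i <= nr - w; ++i) {
      for (int j = w - 1; j <= nc - w; ++j) {
        const double Ix = img(i, j);
        for (int di = 0; di < w; ++di) {
          for (int dj = 0; dj < w; ++dj) {
            double tmp = R_NegInf;
            for (int ei = 0; ei < w; ++ei) {
              for (int ej = 0; ej < w; ++ej) {
                const double pd = p(ei, ej);
                const double Ixd = img(i + ei - c, j + ej - c);
                if (Ixd < Ix - pd - thresh) continue;  // infeasible
                const double v =
                    img(i + ei - di, j + ej - dj) - Ix + pd + thresh;
                if (v > tmp) tmp = v;
              }
            }
            if (tmp < pn(di, dj)) {
              pn(di, dj) = tmp;
            }
          }
        }
      }
    }
    pn(c, c) = 0.0;  // apex pinned
    for (int idx = 0; idx < w * w; ++idx) {
      if (pn[idx] > 0.0) pn[idx] = 0.0;
      if (pn[idx] < p[idx] - 1e-12) changed = true;
      p[idx] = pn[idx];
    }
    if (!changed) break;
    Rcpp::checkUserInterrupt();
  }
  return p;
}
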